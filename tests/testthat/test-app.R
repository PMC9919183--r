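test_that("run configurations round-trip through JSON", {
  cfg <- run_config(seed = 9, epochs = 7, nk = 64, class_weighting = TRUE)
  path <- file.path(withr::local_tempdir(), "cfg.json")
  write_run_config(cfg, path)
  back <- read_run_config(path)
  expect_equal(back, cfg)
})

test_that("the synthetic pipeline writes a complete, reproducible manifest", {
  dir1 <- file.path(withr::local_tempdir(), "run1")
  cfg <- run_config(
    synthetic = TRUE, synthetic_duration = 90, epochs = 4, seed = 5,
    out_dir = dir1
  )
  out <- run_pipeline(cfg)
  man <- attr(out, "manifest")
  expect_equal(man$n_templates, 3) # one template per configured class
  expect_true(all(c("accuracy", "macro", "confusion") %in% names(man$metrics)))
  expect_equal(man$param_count$total, man$param_count$introspected$total)
  expect_true(file.exists(file.path(dir1, "manifest.json")))
  expect_true(file.exists(file.path(dir1, "history.csv")))
  expect_true(file.exists(file.path(dir1, "bank.json")))

  # re-running the same configuration reproduces the manifest exactly
  dir2 <- file.path(withr::local_tempdir(), "run2")
  cfg2 <- cfg
  cfg2$out_dir <- dir2
  man2 <- attr(run_pipeline(cfg2), "manifest")
  man$config$out_dir <- man2$config$out_dir <- NULL
  expect_equal(man, man2)

  # the manifest alone reconstructs every knob of the run
  cfg3 <- do.call(run_config, man2$config[setdiff(names(man2$config), "out_dir")])
  cfg3$out_dir <- file.path(withr::local_tempdir(), "run3")
  man3 <- attr(run_pipeline(cfg3), "manifest")
  expect_equal(man3$metrics, man2$metrics)
})

test_that("pipeline failures abort with the stage name and partial manifest", {
  dir <- file.path(withr::local_tempdir(), "runf")
  cfg <- run_config(synthetic = FALSE, fixture_paths = character(), out_dir = dir)
  expect_error(run_pipeline(cfg), "stage 'segment' failed")
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$failed_stage, "segment")
})

test_that("the CLI chains simulate, segment, templates, train and evaluate", {
  dir <- withr::local_tempdir()
  fix <- file.path(dir, "rec")
  segs <- file.path(dir, "segs.csv")
  bankp <- file.path(dir, "bank")
  modeld <- file.path(dir, "model")

  expect_equal(suppressMessages(mfbeat_main(c(
    "simulate", "--out", fix, "--duration", "120", "--seed", "3",
    "--noise-percent", "5"
  ))), 0L)
  expect_equal(suppressMessages(mfbeat_main(c(
    "segment", fix, "--out", segs
  ))), 0L)
  expect_equal(suppressMessages(mfbeat_main(c(
    "extract-templates", "--segments", segs, "--out", bankp, "--nk", "32"
  ))), 0L)
  bank <- read_template_bank(bankp)
  expect_equal(bank$nk, 32L)
  expect_output(
    expect_equal(mfbeat_main(c("param-count", "--classes", "3", "--nk", "32")), 0L),
    "Total params: 1267"
  )
  expect_equal(suppressMessages(mfbeat_main(c(
    "train", "--train", segs, "--val", segs, "--out-dir", modeld,
    "--epochs", "2", "--nk", "32"
  ))), 0L)
  capture.output(expect_equal(suppressMessages(mfbeat_main(c(
    "evaluate", "--model", file.path(modeld, "model.json"),
    "--segments", segs, "--out", file.path(dir, "eval.json")
  ))), 0L))
  expect_true(file.exists(file.path(dir, "eval.json")))

  expect_equal(suppressMessages(mfbeat_main("frobnicate")), 1L)
  expect_equal(suppressMessages(mfbeat_main(c("segment", "--out", segs))), 1L)
  expect_equal(suppressWarnings(suppressMessages(mfbeat_main(c(
    "evaluate", "--model", "/nonexistent.json", "--segments", segs
  )))), 2L)
})

test_that("the CLI converts WFDB records to the fixture dialect", {
  dir <- withr::local_tempdir()
  path <- write_wfdb_fixture(
    dir,
    signals = list(sin(1:3000 / 10), cos(1:3000 / 10)),
    ann_samples = c(400L, 800L, 1200L), ann_codes = c(1L, 5L, 1L)
  )
  out <- file.path(dir, "converted")
  expect_equal(suppressMessages(mfbeat_main(c(
    "convert", "--record", path, "--out", out
  ))), 0L)
  rec <- read_fixture(out)
  expect_identical(rec$peaks, c(400L, 800L, 1200L))
  expect_identical(rec$symbols, c("N", "V", "N"))
})
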