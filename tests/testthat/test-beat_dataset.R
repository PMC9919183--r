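test_that("sub-class symbols map onto their AAMI super-classes", {
  expect_identical(map_to_aami(c("V", "A", "L")), c("VEB", "SVEB", "N"))
  m <- aami_mapping()
  expect_setequal(names(m), beat_symbol_whitelist())
  expect_setequal(unique(unname(m)), c("N", "SVEB", "VEB", "F", "Q"))
  expect_true(is.na(map_to_aami("~")))
})

test_that("resampling rescales peaks exactly and preserves constants", {
  rec <- beat_record("r", 360, rep(1, 3600), c(360L, 1800L), c("N", "N"))
  out <- resample_record(rec, 128)
  expect_equal(out$fs, 128)
  expect_identical(out$peaks, c(128L, 640L))
  expect_equal(length(out$signal), ceiling(3600 * 128 / 360))
  # constant signal stays constant away from filter edge transients
  core <- out$signal[50:(length(out$signal) - 50)]
  expect_lt(max(abs(core - 1)), 5e-3) # FIR passband ripple
})

test_that("a pure tone survives 360 -> 128 Hz resampling", {
  fs <- 360
  t <- (0:(fs * 10 - 1)) / fs
  rec <- beat_record("s", fs, sin(2 * pi * 5 * t), c(1000L), "N")
  out <- resample_record(rec, 128)
  t2 <- (seq_along(out$signal) - 1) / 128
  ref <- sin(2 * pi * 5 * t2)
  core <- 100:(length(out$signal) - 100)
  expect_lt(max(abs(out$signal[core] - ref[core])), 0.05)
})

test_that("upsampling is rejected", {
  rec <- beat_record("r", 128, rep(0.5, 256), 10L, "N")
  expect_error(resample_record(rec, 360), "upsampling")
  expect_identical(resample_record(rec, 128), rec)
})

test_that("segmentation centers, pads and conserves beats", {
  n <- 1000
  sig <- rnorm(n)
  peaks <- c(5L, 500L, 995L)
  rec <- beat_record("r", 128, sig, peaks, c("N", "V", "A"))
  seg <- segment_beats(rec, 64L)
  expect_equal(n_beats(seg), 3)
  # left overrun: first 32 - 5 samples repeat signal[0]
  expect_true(all(seg$windows[1, 1:27] == sig[1]))
  expect_equal(seg$windows[1, 28:64], sig[1:37])
  # interior beat: raw slice with the peak at 0-based index 32
  expect_equal(seg$windows[2, ], sig[(500 - 32 + 1):(500 + 31 + 1)])
  expect_equal(seg$windows[2, 33], sig[501])
  # right overrun mirrors the edge value
  expect_true(all(seg$windows[3, 38:64] == sig[n]))
  expect_equal(seg$windows[3, 1:37], sig[964:1000])
  expect_identical(seg$super_label, c("N", "VEB", "SVEB"))
})

test_that("unknown symbols are skipped with a warning, known ones conserved", {
  rec <- beat_record(
    "r", 128, rnorm(2000), c(100L, 400L, 800L, 1200L),
    c("N", "+", "V", "~")
  )
  expect_warning(seg <- segment_beats(rec), "skipped 2")
  expect_equal(n_beats(seg), 2)
  expect_identical(seg$sub_label, c("N", "V"))
})

test_that("inter-patient split partitions by record id without leakage", {
  mk <- function(id, k) {
    new_segments <- segment_beats(beat_record(
      id, 128, rnorm(5000), as.integer(seq(200, 4800, length.out = k)),
      rep("N", k)
    ))
  }
  segs <- bind_segments(mk("101", 5), mk("205", 4), mk("100", 6))
  sp <- split_inter_patient(segs)
  expect_identical(unique(sp$ds1_train$record_id), "101")
  expect_identical(unique(sp$ds1_val$record_id), "205")
  expect_identical(unique(sp$ds2_test$record_id), "100")
  # conservation and pairwise disjointness
  expect_equal(
    n_beats(sp$ds1_train) + n_beats(sp$ds1_val) + n_beats(sp$ds2_test),
    n_beats(segs)
  )
  parts <- list(sp$ds1_train$record_id, sp$ds1_val$record_id, sp$ds2_test$record_id)
  for (i in 1:2) {
    for (j in (i + 1):3) {
      expect_length(intersect(parts[[i]], parts[[j]]), 0)
    }
  }

  expect_error(split_inter_patient(mk("999", 3)), "999")
  empty <- subset_segments(segs, integer(0))
  sp0 <- split_inter_patient(empty)
  expect_equal(vapply(sp0, n_beats, numeric(1)), c(ds1_train = 0, ds1_val = 0, ds2_test = 0))
})

test_that("split spec lists 22 disjoint records per part", {
  sp <- split_spec()
  expect_length(sp$ds1_records, 22)
  expect_length(sp$ds2_records, 22)
  expect_length(intersect(sp$ds1_records, sp$ds2_records), 0)
  expect_error(split_spec("100", "100"), "disjoint")
})

test_that("segment store round-trips windows, labels and RR features", {
  segs <- small_sets()$train
  path <- file.path(withr::local_tempdir(), "segs.csv")
  write_segments(segs, path)
  back <- read_segments(path)
  expect_equal(back$windows, segs$windows, ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(back$sub_label, segs$sub_label)
  expect_identical(back$super_label, segs$super_label)
  expect_equal(back$rr, segs$rr, ignore_attr = TRUE, tolerance = 1e-12)
})
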