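#' End-to-end run configuration
#'
#' Declarative configuration for [run_pipeline()]. Model defaults follow
#' the best-scoring published variant: 3 classes, derivative input,
#' kernel length 32, kernels initialized from matched-filter templates,
#' correlator trainable, class weighting off.
#'
#' @param synthetic Logical; generate seeded synthetic train/val/test
#'   records instead of reading fixtures.
#' @param synthetic_duration Seconds of synthetic signal per part.
#' @param fixture_paths Character vector of fixture stems (read with
#'   [read_fixture()] and split by [split_inter_patient()]) when
#'   `synthetic = FALSE`.
#' @param wfdb_paths Character vector of WFDB record paths (no extension)
#'   read with [read_wfdb_record()] when `synthetic = FALSE`.
#' @param lead_name WFDB lead to read.
#' @param n_classes,nk,nf,input_feature,conv_trainable,conv_init,class_weighting,seed
#'   Passed to [mf_model_spec()].
#' @param granularity Template grouping for [extract_templates()].
#' @param target_fs Model sampling rate (Hz).
#' @param window_len Beat window length in samples.
#' @param local_w,global_w RR trailing-window lengths in intervals.
#' @param epochs,batch_size Training schedule.
#' @param out_dir Run directory to create.
#' @return List of class `run_config`.
#' @export
run_config <- function(synthetic = TRUE, synthetic_duration = 300,
                       fixture_paths = character(), wfdb_paths = character(),
                       lead_name = "MLII",
                       n_classes = 3L, nk = 32L, nf = NULL,
                       input_feature = "derivative", conv_trainable = TRUE,
                       conv_init = "mf_templates", class_weighting = FALSE,
                       granularity = "sub_class",
                       target_fs = 128, window_len = 64L,
                       local_w = 80L, global_w = 400L,
                       epochs = 100L, batch_size = 512L,
                       seed = 1L, out_dir = tempfile("mfbeat-run-")) {
  structure(
    list(
      synthetic = isTRUE(synthetic), synthetic_duration = synthetic_duration,
      fixture_paths = fixture_paths, wfdb_paths = wfdb_paths,
      lead_name = lead_name,
      n_classes = as.integer(n_classes), nk = as.integer(nk),
      nf = if (is.null(nf)) NULL else as.integer(nf),
      input_feature = input_feature, conv_trainable = isTRUE(conv_trainable),
      conv_init = conv_init, class_weighting = isTRUE(class_weighting),
      granularity = granularity,
      target_fs = target_fs, window_len = as.integer(window_len),
      local_w = as.integer(local_w), global_w = as.integer(global_w),
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      seed = as.integer(seed), out_dir = out_dir
    ),
    class = "run_config"
  )
}

#' Write / read a run configuration as JSON
#' @param config A [run_config()].
#' @param path JSON path.
#' @return `path` invisibly (writer); a `run_config` (reader).
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("fixture_paths", "wfdb_paths")) {
    vals[[f]] <- as.character(unlist(vals[[f]]))
  }
  do.call(run_config, vals)
}

prepare_record <- function(record, target_fs, window_len, local_w, global_w) {
  rec <- resample_record(record, target_fs)
  seg <- segment_beats(rec, window_len)
  seg <- append_rr_features(seg, rec, local_w, global_w)
  drop_unavailable_rr(seg)
}

# Synthetic train/val/test parts: one generated record per part, distinct
# seeds, emulating the inter-patient principle that no record spans parts.
synthetic_parts <- function(config) {
  gen <- function(seed_off, dur) {
    cfg <- synthetic_config(
      duration = dur,
      seed = config$seed + seed_off
    )
    prepare_record(
      synthesize_record(cfg), config$target_fs, config$window_len,
      config$local_w, config$global_w
    )
  }
  list(
    train = gen(0L, config$synthetic_duration),
    val = gen(1L, config$synthetic_duration / 2),
    test = gen(2L, config$synthetic_duration)
  )
}

#' Run the full pipeline: segment, features, templates, train, evaluate
#'
#' Executes every stage under one configuration and writes a run
#' directory: `manifest.json` (configuration, seeds, template count,
#' parameter counts, metrics, package version — everything needed to
#' reproduce the run), `history.csv`, `metrics.json`, and the template
#' bank. Any stage failure aborts with the stage name and a partial
#' manifest.
#'
#' @param config A [run_config()].
#' @return The run directory path, invisibly; the manifest as attribute
#'   `"manifest"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    tool = "mfbeat", version = as.character(utils::packageVersion("mfbeat")),
    config = unclass(config)
  )
  fail <- function(stage, err) {
    manifest$failed_stage <<- stage
    manifest$error <<- conditionMessage(err)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, null = "null", force = TRUE
    )
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(err))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) fail(name, e))
  }

  parts <- stage("segment", {
    if (config$synthetic) {
      synthetic_parts(config)
    } else {
      recs <- c(
        lapply(config$fixture_paths, read_fixture),
        lapply(config$wfdb_paths, read_wfdb_record, lead_name = config$lead_name)
      )
      if (length(recs) == 0L) stop("no input records configured")
      segs <- lapply(
        recs, prepare_record, config$target_fs, config$window_len,
        config$local_w, config$global_w
      )
      sp <- split_inter_patient(do.call(bind_segments, segs))
      list(train = sp$ds1_train, val = sp$ds1_val, test = sp$ds2_test)
    }
  })
  manifest$n_beats <- lapply(parts, n_beats)

  bank <- stage("extract_templates", {
    if (config$conv_init != "mf_templates") {
      NULL
    } else if (config$input_feature == "both") {
      list(
        signal = extract_templates(parts$train, config$granularity, "signal", config$nk),
        derivative = extract_templates(parts$train, config$granularity, "derivative", config$nk)
      )
    } else {
      extract_templates(
        parts$train, config$granularity, config$input_feature, config$nk
      )
    }
  })
  n_templates <- if (is.null(bank)) {
    NA_integer_
  } else if (inherits(bank, "template_bank")) {
    length(bank$labels)
  } else {
    length(bank$derivative$labels)
  }
  manifest$n_templates <- n_templates
  if (!is.null(bank)) {
    b1 <- if (inherits(bank, "template_bank")) bank else bank$derivative
    write_template_bank(b1, file.path(config$out_dir, "bank.json"))
  }

  spec <- stage("build", {
    mf_model_spec(
      n_classes = config$n_classes, nk = config$nk,
      nf = if (is.null(config$nf)) {
        if (is.null(bank)) NULL else n_templates
      } else {
        config$nf
      },
      input_feature = config$input_feature,
      conv_trainable = config$conv_trainable, conv_init = config$conv_init,
      class_weighting = config$class_weighting, window_len = config$window_len,
      seed = config$seed
    )
  })
  model <- stage("build", build_model(spec, bank))
  pc_closed <- count_params(spec)
  pc_introspect <- model_param_count(model)
  manifest$param_count <- list(
    total = pc_closed$total, trainable = pc_closed$trainable,
    non_trainable = pc_closed$non_trainable,
    introspected = pc_introspect
  )

  model <- stage("train", train_mf(model, parts$train, parts$val,
    epochs = config$epochs, batch_size = config$batch_size
  ))
  utils::write.csv(model$history, file.path(config$out_dir, "history.csv"),
    row.names = FALSE
  )

  report <- stage("evaluate", evaluate_model(model, parts$test))
  manifest$metrics <- list(
    accuracy = report$accuracy,
    macro = as.list(report$macro),
    per_class = report$per_class,
    confusion = unclass(report$confusion)
  )
  jsonlite::write_json(manifest$metrics, file.path(config$out_dir, "metrics.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null", force = TRUE
  )
  out <- config$out_dir
  attr(out, "manifest") <- manifest
  attr(out, "model") <- model
  invisible(out)
}
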