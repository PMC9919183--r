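#' Sub-class to AAMI super-class mapping
#'
#' Maps every annotated beat symbol to its AAMI super-class: N (normal and
#' bundle-branch/escape beats), SVEB (supraventricular ectopics), VEB
#' (ventricular ectopics), F (fusion of ventricular and normal) and Q
#' (unknown/paced).
#'
#' @return Named character vector: names are sub-class symbols, values the
#'   super-class labels.
#' @export
aami_mapping <- function() {
  c(
    N = "N", L = "N", R = "N", e = "N", j = "N",
    A = "SVEB", a = "SVEB", J = "SVEB", S = "SVEB",
    V = "VEB", E = "VEB",
    F = "F",
    Q = "Q", f = "Q", `/` = "Q"
  )
}

#' Map a beat symbol to its AAMI super-class
#'
#' @param symbol Character vector of sub-class symbols.
#' @return Character vector of super-class labels; `NA` for unknown symbols.
#' @export
#' @examples
#' map_to_aami(c("V", "A", "L"))
map_to_aami <- function(symbol) {
  unname(aami_mapping()[symbol])
}

new_beat_segments <- function(windows, record_id, center_index, sub_label,
                              super_label, fs, rr = NULL) {
  k <- nrow(windows)
  stopifnot(
    length(record_id) == k, length(center_index) == k,
    length(sub_label) == k, length(super_label) == k
  )
  structure(
    list(
      windows = windows, record_id = as.character(record_id),
      center_index = as.integer(center_index),
      sub_label = as.character(sub_label),
      super_label = as.character(super_label),
      fs = fs, rr = rr
    ),
    class = "beat_segments"
  )
}

#' @export
print.beat_segments <- function(x, ...) {
  cat(sprintf(
    "<beat_segments> %d beats x %d samples @ %g Hz%s\n",
    nrow(x$windows), ncol(x$windows), x$fs,
    if (is.null(x$rr)) "" else " (+4 RR features)"
  ))
  tab <- sort(table(x$super_label), decreasing = TRUE)
  cat("  classes:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Number of beats in a beat_segments set
#' @param segments A `beat_segments` object.
#' @return Integer count.
#' @export
n_beats <- function(segments) nrow(segments$windows)

#' Subset a beat_segments set by index
#' @param segments A `beat_segments` object.
#' @param idx Integer or logical index vector over beats.
#' @return A `beat_segments` object.
#' @export
subset_segments <- function(segments, idx) {
  new_beat_segments(
    segments$windows[idx, , drop = FALSE],
    segments$record_id[idx], segments$center_index[idx],
    segments$sub_label[idx], segments$super_label[idx],
    segments$fs,
    rr = if (is.null(segments$rr)) NULL else segments$rr[idx, , drop = FALSE]
  )
}

#' Concatenate beat_segments sets
#' @param ... `beat_segments` objects with equal window length and rate.
#' @return A single `beat_segments` object.
#' @export
bind_segments <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, function(p) n_beats(p) > 0L, logical(1))]
  if (length(parts) == 0L) stop("bind_segments: nothing to bind")
  stopifnot(length(unique(vapply(parts, function(p) ncol(p$windows), numeric(1)))) == 1L)
  has_rr <- vapply(parts, function(p) !is.null(p$rr), logical(1))
  new_beat_segments(
    do.call(rbind, lapply(parts, `[[`, "windows")),
    unlist(lapply(parts, `[[`, "record_id")),
    unlist(lapply(parts, `[[`, "center_index")),
    unlist(lapply(parts, `[[`, "sub_label")),
    unlist(lapply(parts, `[[`, "super_label")),
    parts[[1L]]$fs,
    rr = if (all(has_rr)) do.call(rbind, lapply(parts, `[[`, "rr")) else NULL
  )
}

#' Cut a record into fixed-length labeled beat windows
#'
#' Extracts one `window_len`-sample window per annotated beat from a record
#' (expected at the model rate, 128 Hz by convention). With even
#' `window_len` the R-peak sits at 0-based window index `window_len / 2`
#' (32 samples before, 31 after for the default 64). Where the window
#' overruns the record, missing samples repeat the nearest edge value.
#' Beats with symbols outside [aami_mapping()] are skipped with one warning
#' reporting the count.
#'
#' @param record A [beat_record()].
#' @param window_len Window length in samples (default 64, i.e. 0.5 s at
#'   128 Hz).
#' @return A `beat_segments` object (no RR features attached; see
#'   [append_rr_features()]).
#' @export
segment_beats <- function(record, window_len = 64L) {
  validate_beat_record(record)
  L <- as.integer(window_len)
  map <- aami_mapping()
  known <- record$symbols %in% names(map)
  n_skip <- sum(!known)
  if (n_skip > 0L) {
    warning("segment_beats: skipped ", n_skip, " beats with unknown symbols")
  }
  peaks <- record$peaks[known]
  syms <- record$symbols[known]
  k <- length(peaks)
  half <- L %/% 2L
  n <- length(record$signal)
  windows <- matrix(0, nrow = k, ncol = L)
  if (k > 0L) {
    offs <- seq.int(-half, half + (L %% 2L) - 1L) # peak at 0-based index half
    for (i in seq_len(k)) {
      idx <- peaks[i] + offs # 0-based sample indices
      idx <- pmin(pmax(idx, 0L), n - 1L) # edge padding by clamping
      windows[i, ] <- record$signal[idx + 1L]
    }
  }
  new_beat_segments(
    windows,
    record_id = rep(record$record_id, k), center_index = peaks,
    sub_label = syms, super_label = unname(map[syms]),
    fs = record$fs
  )
}

#' Inter-patient record split specification
#'
#' The standard inter-patient division of the 44 usable arrhythmia-database
#' records into a development set DS1 and a held-out test set DS2 (22
#' records each, disjoint), plus the rule subdividing DS1: record ids
#' numerically below 200 train the model, the rest validate it.
#'
#' @param ds1_records,ds2_records Character vectors of record ids.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(
    ds1_records = c(
      "101", "106", "108", "109", "112", "114", "115", "116", "118", "119",
      "122", "124", "201", "203", "205", "207", "208", "209", "215", "220",
      "223", "230"
    ),
    ds2_records = c(
      "100", "103", "105", "111", "113", "117", "121", "123", "200", "202",
      "210", "212", "213", "214", "219", "221", "222", "228", "231", "232",
      "233", "234"
    )) {
  ds1_records <- as.character(ds1_records)
  ds2_records <- as.character(ds2_records)
  if (length(intersect(ds1_records, ds2_records)) > 0L) {
    stop("split_spec: DS1 and DS2 must be disjoint")
  }
  structure(
    list(ds1_records = ds1_records, ds2_records = ds2_records),
    class = "split_spec"
  )
}

#' Partition beat segments by patient record
#'
#' Assigns every beat to DS1-train (DS1 records with numeric id < 200),
#' DS1-validation (remaining DS1 records) or DS2-test, by its record id.
#' No record ever contributes to two parts.
#'
#' @param segments A `beat_segments` object.
#' @param spec A [split_spec()].
#' @return List with `beat_segments` elements `ds1_train`, `ds1_val`,
#'   `ds2_test`.
#' @export
split_inter_patient <- function(segments, spec = split_spec()) {
  ids <- segments$record_id
  unknown <- setdiff(unique(ids), c(spec$ds1_records, spec$ds2_records))
  if (length(unknown) > 0L) {
    stop(
      "record id(s) in neither DS1 nor DS2: ",
      paste(unknown, collapse = ", ")
    )
  }
  num_id <- suppressWarnings(as.numeric(ids))
  in_ds1 <- ids %in% spec$ds1_records
  list(
    ds1_train = subset_segments(segments, which(in_ds1 & !is.na(num_id) & num_id < 200)),
    ds1_val = subset_segments(segments, which(in_ds1 & (is.na(num_id) | num_id >= 200))),
    ds2_test = subset_segments(segments, which(!in_ds1))
  )
}

#' Write / read a beat-segment store as CSV
#'
#' Columnar plain-text store: one row per beat with `record_id`,
#' `center_index`, `sub_label`, `super_label`, window samples `w1..wL` and,
#' when present, the four RR features.
#'
#' @param segments A `beat_segments` object.
#' @param path CSV path.
#' @return `path` invisibly (writer); a `beat_segments` object (reader).
#' @export
write_segments <- function(segments, path) {
  df <- data.frame(
    record_id = segments$record_id,
    center_index = segments$center_index,
    sub_label = segments$sub_label,
    super_label = segments$super_label,
    fs = segments$fs
  )
  w <- segments$windows
  colnames(w) <- paste0("w", seq_len(ncol(w)))
  df <- cbind(df, as.data.frame(w))
  if (!is.null(segments$rr)) {
    rr <- segments$rr
    colnames(rr) <- rr_feature_names()
    df <- cbind(df, as.data.frame(rr))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  wcols <- grep("^w[0-9]+$", names(df), value = TRUE)
  wcols <- wcols[order(as.integer(sub("^w", "", wcols)))]
  rrcols <- intersect(rr_feature_names(), names(df))
  new_beat_segments(
    as.matrix(df[, wcols, drop = FALSE]),
    df$record_id, df$center_index, df$sub_label, df$super_label,
    fs = df$fs[1L],
    rr = if (length(rrcols) == 4L) as.matrix(df[, rrcols]) else NULL
  )
}
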