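#' Annotated single-lead ECG record
#'
#' A `beat_record` bundles one lead of a continuous ECG signal with its beat
#' annotations: the sample index of each annotated R-peak and the
#' single-character beat symbol attached to it. Sample indices are 0-based
#' throughout the package, matching WFDB sample numbering and the on-disk
#' fixture dialect; `signal[peaks[i] + 1]` is the annotated sample in R.
#'
#' @param record_id Character scalar naming the record (e.g. `"100"`).
#' @param fs Sampling rate in Hz (positive scalar).
#' @param signal Numeric vector of samples, one lead.
#' @param peaks Integer vector of 0-based R-peak sample indices, strictly
#'   increasing, each in `[0, length(signal) - 1]`.
#' @param symbols Character vector of per-beat annotation symbols, same
#'   length as `peaks`.
#'
#' @return An object of class `beat_record`: a list with fields
#'   `record_id`, `fs`, `signal`, `peaks`, `symbols`.
#' @export
#' @examples
#' rec <- beat_record("toy", 128, sin(seq_len(640) / 10), c(99L, 299L), c("N", "V"))
#' rec
beat_record <- function(record_id, fs, signal, peaks, symbols) {
  rec <- structure(
    list(
      record_id = as.character(record_id)[1],
      fs = as.numeric(fs)[1],
      signal = as.numeric(signal),
      peaks = as.integer(peaks),
      symbols = as.character(symbols)
    ),
    class = "beat_record"
  )
  validate_beat_record(rec)
  rec
}

#' Validate the invariants of a beat_record
#'
#' Stops with an informative message when any invariant is violated:
#' positive sampling rate, non-empty signal, strictly increasing in-range
#' 0-based peaks, and one symbol per peak.
#'
#' @param rec A `beat_record`.
#' @return `rec`, invisibly.
#' @export
validate_beat_record <- function(rec) {
  stopifnot(inherits(rec, "beat_record"))
  if (!is.finite(rec$fs) || rec$fs <= 0) {
    stop("beat_record: fs must be a positive finite number, got ", rec$fs)
  }
  if (length(rec$signal) == 0L) {
    stop("beat_record: signal must be non-empty")
  }
  if (length(rec$peaks) != length(rec$symbols)) {
    stop(
      "beat_record: peaks (", length(rec$peaks), ") and symbols (",
      length(rec$symbols), ") must have equal length"
    )
  }
  if (length(rec$peaks) > 0L) {
    if (anyNA(rec$peaks)) stop("beat_record: peaks contain NA")
    if (any(diff(rec$peaks) <= 0L)) {
      stop("beat_record: peaks must be strictly increasing")
    }
    if (rec$peaks[1L] < 0L || rec$peaks[length(rec$peaks)] >= length(rec$signal)) {
      stop(
        "beat_record: peaks must lie in [0, ", length(rec$signal) - 1L,
        "] (0-based)"
      )
    }
  }
  invisible(rec)
}

#' @export
print.beat_record <- function(x, ...) {
  cat(
    sprintf(
      "<beat_record '%s'> %d samples @ %g Hz (%.1f s), %d annotated beats\n",
      x$record_id, length(x$signal), x$fs, length(x$signal) / x$fs,
      length(x$peaks)
    )
  )
  if (length(x$symbols)) {
    tab <- sort(table(x$symbols), decreasing = TRUE)
    cat("  symbols:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  }
  invisible(x)
}
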