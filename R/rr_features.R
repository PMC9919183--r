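#' Names of the four normalized RR-interval features
#' @return Character vector of length 4.
#' @export
rr_feature_names <- function() {
  c("pre_rr_local", "pre_rr_global", "post_rr_local", "post_rr_global")
}

#' RR intervals from annotated peak indices
#'
#' @param peaks Ascending integer vector of R-peak sample indices (at least
#'   two).
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of `length(peaks) - 1` intervals in seconds.
#' @export
#' @examples
#' rr_intervals(c(0, 128, 256), 128)
rr_intervals <- function(peaks, fs) {
  if (length(peaks) < 2L) stop("rr_intervals: need at least 2 peaks")
  if (any(diff(peaks) <= 0)) stop("rr_intervals: peaks must be ascending")
  diff(peaks) / fs
}

#' Causal trailing means of an RR-interval sequence
#'
#' At interval `i`, the local (global) mean is the average of the last
#' `local_w` (`global_w`) intervals ending at `i`, inclusive; while history
#' is shorter than the window, the average runs over what exists. Strictly
#' causal: position `i` depends only on intervals `1..i`. Defaults of 80
#' and 400 intervals correspond to roughly one and five minutes of normal
#' rhythm.
#'
#' @param rr Numeric vector of RR intervals (seconds).
#' @param local_w,global_w Trailing window lengths in intervals.
#' @return List with numeric vectors `local` and `global`, same length as
#'   `rr`.
#' @export
dynamic_means <- function(rr, local_w = 80L, global_w = 400L) {
  if (length(rr) == 0L) stop("dynamic_means: rr must be non-empty")
  if (local_w < 1L || global_w < 1L) stop("dynamic_means: windows must be >= 1")
  trailing <- function(x, w) {
    cs <- cumsum(x)
    n <- length(x)
    i <- seq_len(n)
    lo <- pmax(i - w, 0L)
    tot <- cs - c(0, cs)[lo + 1L]
    tot / (i - lo)
  }
  list(local = trailing(rr, local_w), global = trailing(rr, global_w))
}

#' Normalized RR features for one beat
#'
#' For beat `i` of a record, the pre-RR interval (`rr[i-1]`, ending at this
#' beat) and post-RR interval (`rr[i]`, starting at this beat) are each
#' divided by the local and global trailing means available at the beat —
#' the means over intervals up to and including the pre-RR interval. The
#' first and last beats of a record have no pre- or post-RR interval and
#' return `NA` features (such beats are excluded from training and
#' evaluation).
#'
#' @param beat_index 1-based index of the beat among the record's peaks.
#' @param rr Interval sequence from [rr_intervals()].
#' @param local_mean,global_mean Trailing means from [dynamic_means()].
#' @return Named numeric vector of 4 ratios (see [rr_feature_names()]), or
#'   all-`NA` for the first/last beat.
#' @export
normalized_rr <- function(beat_index, rr, local_mean, global_mean) {
  n_beats <- length(rr) + 1L
  out <- stats::setNames(rep(NA_real_, 4L), rr_feature_names())
  if (beat_index <= 1L || beat_index >= n_beats) {
    return(out)
  }
  pre <- rr[beat_index - 1L]
  post <- rr[beat_index]
  lm <- local_mean[beat_index - 1L]
  gm <- global_mean[beat_index - 1L]
  out[] <- c(pre / lm, pre / gm, post / lm, post / gm)
  out
}

#' All-beat RR feature matrix for a record
#'
#' @param peaks Ascending R-peak sample indices.
#' @param fs Sampling rate in Hz.
#' @param local_w,global_w Trailing window lengths (see [dynamic_means()]).
#' @return `length(peaks) x 4` matrix; first and last rows are `NA`.
#' @export
rr_feature_matrix <- function(peaks, fs, local_w = 80L, global_w = 400L) {
  k <- length(peaks)
  out <- matrix(NA_real_, k, 4L, dimnames = list(NULL, rr_feature_names()))
  if (k < 3L) {
    return(out)
  }
  rr <- rr_intervals(peaks, fs)
  dm <- dynamic_means(rr, local_w, global_w)
  i <- 2:(k - 1L)
  pre <- rr[i - 1L]
  post <- rr[i]
  lm <- dm$local[i - 1L]
  gm <- dm$global[i - 1L]
  out[i, ] <- cbind(pre / lm, pre / gm, post / lm, post / gm)
  out
}

#' Attach RR features to beat segments
#'
#' Computes [rr_feature_matrix()] from the source record's full peak list
#' and attaches the rows matching each segment's center index. Segments
#' whose beat lacks a predecessor or successor carry `NA` features; drop
#' them with [drop_unavailable_rr()] before training or evaluation.
#'
#' @param segments A `beat_segments` object from one record.
#' @param record The [beat_record()] the segments came from (same rate).
#' @param local_w,global_w Trailing window lengths.
#' @return The segments with a `rr` matrix field.
#' @export
append_rr_features <- function(segments, record, local_w = 80L, global_w = 400L) {
  stopifnot(inherits(segments, "beat_segments"))
  validate_beat_record(record)
  if (!all(segments$record_id == record$record_id)) {
    stop("append_rr_features: segments and record ids disagree")
  }
  feat <- rr_feature_matrix(record$peaks, record$fs, local_w, global_w)
  pos <- match(segments$center_index, record$peaks)
  if (anyNA(pos)) stop("append_rr_features: segment centers missing from record peaks")
  segments$rr <- feat[pos, , drop = FALSE]
  segments
}

#' Drop beats with unavailable RR features
#'
#' @param segments A `beat_segments` object with RR features attached.
#' @return The segments restricted to beats with complete RR features.
#' @export
drop_unavailable_rr <- function(segments) {
  if (is.null(segments$rr)) stop("segments carry no RR features")
  subset_segments(segments, stats::complete.cases(segments$rr))
}
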