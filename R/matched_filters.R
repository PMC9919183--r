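#' First discrete difference of a beat window
#'
#' `out[i] = window[i+1] - window[i]`, the discrete stand-in for continuous
#' differentiation. The derivative of an `L`-sample window has `L - 1`
#' samples.
#'
#' @param window Numeric vector (length >= 2) or matrix (one window per
#'   row).
#' @return Vector of length `L - 1`, or matrix with `L - 1` columns.
#' @export
#' @examples
#' first_derivative(c(0, 1, 3, 6))
first_derivative <- function(window) {
  if (is.matrix(window)) {
    if (ncol(window) < 2L) stop("first_derivative: need at least 2 samples")
    window[, -1L, drop = FALSE] - window[, -ncol(window), drop = FALSE]
  } else {
    if (length(window) < 2L) stop("first_derivative: need at least 2 samples")
    diff(window)
  }
}

# Model-facing feature transform: raw windows -> feature windows of the
# original length. The derivative (length L-1) is front-padded with one
# repeated edge value so signal and derivative features share the 64-long
# input the correlator expects.
feature_windows <- function(windows, feature_kind) {
  switch(feature_kind,
    signal = windows,
    derivative = {
      d <- first_derivative(windows)
      cbind(d[, 1L, drop = FALSE], d)
    },
    stop("unknown feature_kind: ", feature_kind)
  )
}

central_crop_index <- function(L, nk) {
  if (nk > L) stop("kernel length NK (", nk, ") exceeds feature length (", L, ")")
  start <- (L - nk) %/% 2L # 0-based; 64->32 keeps [16, 48)
  seq.int(start + 1L, start + nk)
}

#' Extract matched-filter templates from training beats
#'
#' A template is the arithmetic mean of the feature windows of all training
#' beats in a group; groups are sub-classes, AAMI super-classes, or
#' record-by-sub-class pairs. Derivative templates are means of per-beat
#' first differences (identical, by linearity, to differencing the mean).
#' When `nk` is shorter than the feature window, the central `nk` samples
#' are kept (for 64-long features and `nk = 32`, samples 16..47, discarding
#' 16 from each edge, where most of the template energy away from the
#' R-peak carries little class information). Groups with no examples are
#' simply absent. No amplitude normalization is applied.
#'
#' @param segments Training `beat_segments`.
#' @param granularity One of `"sub_class"`, `"super_class"`,
#'   `"per_record_sub_class"`.
#' @param feature_kind `"signal"` or `"derivative"`.
#' @param nk Kernel length (32 or 64 in practice; any `nk <=` feature
#'   length is accepted).
#' @return An object of class `template_bank`: list with `labels`,
#'   `kernels` (`nk x n_templates` matrix, one column per template), `nk`,
#'   `granularity`, `feature_kind`, `group_sizes`.
#' @export
extract_templates <- function(segments,
                              granularity = c("sub_class", "super_class", "per_record_sub_class"),
                              feature_kind = c("derivative", "signal"),
                              nk = 32L) {
  granularity <- match.arg(granularity)
  feature_kind <- match.arg(feature_kind)
  if (n_beats(segments) == 0L) stop("extract_templates: no training segments")
  feats <- feature_windows(segments$windows, feature_kind)
  group <- switch(granularity,
    sub_class = segments$sub_label,
    super_class = segments$super_label,
    per_record_sub_class = paste(segments$record_id, segments$sub_label, sep = ":")
  )
  labels <- sort(unique(group))
  crop <- central_crop_index(ncol(feats), as.integer(nk))
  kernels <- vapply(
    labels,
    function(g) colMeans(feats[group == g, crop, drop = FALSE]),
    numeric(length(crop))
  )
  structure(
    list(
      labels = labels,
      kernels = matrix(kernels, nrow = length(crop), dimnames = list(NULL, labels)),
      nk = as.integer(nk), granularity = granularity,
      feature_kind = feature_kind,
      group_sizes = as.integer(table(group)[labels])
    ),
    class = "template_bank"
  )
}

#' @export
print.template_bank <- function(x, ...) {
  cat(sprintf(
    "<template_bank> %d templates of %d samples (%s, %s feature)\n",
    length(x$labels), x$nk, x$granularity, x$feature_kind
  ))
  cat("  labels:", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' Sliding cross-correlation with same-length zero padding
#'
#' `y[n] = sum_k x[n + k - 1 - floor((K - 1) / 2)] * h[k]` with `x` taken
#' as zero outside its support: stride-1 correlation (no kernel flip),
#' output length equal to input length. This is the primitive a correlator
#' kernel of the network computes per channel, and the classical
#' matched-filter receiver's correlation stage.
#'
#' @param x Numeric input of length `N`.
#' @param h Numeric template of length `K <= N`.
#' @param padding Only `"same"` is supported.
#' @return Numeric vector of length `N`.
#' @export
correlate <- function(x, h, padding = "same") {
  if (!identical(padding, "same")) stop("only padding = 'same' is supported")
  n <- length(x)
  k <- length(h)
  if (k > n) stop("correlate: template longer than input")
  pad_left <- (k - 1L) %/% 2L
  xp <- c(numeric(pad_left), x, numeric(k - 1L - pad_left))
  y <- numeric(n)
  for (j in seq_len(k)) {
    y <- y + h[j] * xp[j:(j + n - 1L)]
  }
  y
}

#' Classical matched-filter classification of one beat window
#'
#' Correlates the window with every template in the bank, samples each
#' correlator at its maximum over lags, and picks the label with the
#' largest peak (ties broken lexicographically by label). The window must
#' already be in the bank's feature kind.
#'
#' @param window Numeric feature window.
#' @param bank A `template_bank`.
#' @return List of class `mf_decision`: `best_label` and named `scores`.
#' @export
mf_classify <- function(window, bank) {
  stopifnot(inherits(bank, "template_bank"))
  scores <- vapply(
    seq_along(bank$labels),
    function(t) max(correlate(window, bank$kernels[, t])),
    numeric(1)
  )
  names(scores) <- bank$labels
  # which.max on the lexicographically ordered labels breaks ties low
  ord <- order(bank$labels)
  best <- names(scores)[ord][which.max(scores[ord])]
  structure(list(best_label = best, scores = scores), class = "mf_decision")
}

#' Matched-filter classification of a segment set
#'
#' Applies the bank's feature transform to raw windows, then
#' [mf_classify()] per beat.
#'
#' @param segments A `beat_segments` object (raw signal windows).
#' @param bank A `template_bank`.
#' @return Character vector of predicted labels.
#' @export
mf_classify_segments <- function(segments, bank) {
  feats <- feature_windows(segments$windows, bank$feature_kind)
  vapply(
    seq_len(nrow(feats)),
    function(i) mf_classify(feats[i, ], bank)$best_label,
    character(1)
  )
}

#' Persist / load a template bank as plain text
#'
#' A JSON header (`nk`, `granularity`, `feature_kind`, labels, group
#' sizes) plus a CSV of kernels, one column per template.
#'
#' @param bank A `template_bank`.
#' @param path Stem or `.json` path.
#' @return Header path invisibly (writer); a `template_bank` (reader).
#' @export
write_template_bank <- function(bank, path) {
  p <- fixture_paths(path)
  jsonlite::write_json(
    list(
      format = "mfbeat-bank-v1", nk = bank$nk, granularity = bank$granularity,
      feature_kind = bank$feature_kind, labels = bank$labels,
      group_sizes = bank$group_sizes
    ),
    p$header,
    auto_unbox = TRUE, digits = NA
  )
  k <- as.data.frame(bank$kernels)
  names(k) <- bank$labels
  utils::write.csv(k, paste0(sub("\\.json$", "", p$header), ".kernels.csv"),
    row.names = FALSE
  )
  invisible(p$header)
}

#' @rdname write_template_bank
#' @export
read_template_bank <- function(path) {
  p <- fixture_paths(path)
  hdr <- jsonlite::read_json(p$header, simplifyVector = TRUE)
  kern <- utils::read.csv(
    paste0(sub("\\.json$", "", p$header), ".kernels.csv"),
    check.names = FALSE
  )
  structure(
    list(
      labels = hdr$labels,
      kernels = matrix(as.matrix(kern),
        nrow = hdr$nk,
        dimnames = list(NULL, hdr$labels)
      ),
      nk = as.integer(hdr$nk), granularity = hdr$granularity,
      feature_kind = hdr$feature_kind,
      group_sizes = as.integer(hdr$group_sizes)
    ),
    class = "template_bank"
  )
}
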