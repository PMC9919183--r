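#' Architecture specification of the matched-filter CNN
#'
#' One wide correlator layer fused with an RR-interval branch. The beat
#' branch takes a 64-sample window (or its first derivative, front-padded
#' by one repeated edge value back to 64 samples; or both as two channels),
#' correlates it with `nf` kernels of length `nk` (stride 1, same padding,
#' per-kernel bias), batch-normalizes each channel, applies tanh, and
#' samples each channel's global maximum over time. The RR branch maps the
#' 4 normalized RR features, treated as a 4x1 sequence, through dense
#' layers of widths 32/16/8 (ReLU, applied along the last axis) and
#' flattens to 32 values. Both branches are concatenated and a dense
#' softmax head produces class probabilities.
#'
#' @param n_classes 3, 4 or 5 (N/SVEB/VEB, + F, + Q).
#' @param nk Correlator kernel length, 32 or 64.
#' @param nf Number of correlator kernels; defaults to the template counts
#'   of the inter-patient training set at sub-class granularity for the
#'   class scope (11, 12, 13 for 3, 4, 5 classes).
#' @param input_feature `"derivative"`, `"signal"` or `"both"` (two input
#'   channels with separate kernels per channel, summed as usual for a
#'   multi-channel convolution).
#' @param conv_trainable Logical; `FALSE` freezes the correlator kernels
#'   and biases at their initial (template) values.
#' @param conv_init `"mf_templates"` (kernels preloaded from a
#'   [extract_templates()] bank) or `"default"` (Glorot-uniform random).
#' @param class_weighting Logical; when `TRUE`, training weights class `c`
#'   by `N_total / (n_classes * N_c)`.
#' @param rr_branch_widths Dense widths of the RR branch.
#' @param window_len Beat-window length in samples.
#' @param seed Integer seed controlling weight initialization and batch
#'   shuffling.
#' @return An object of class `mf_model_spec`.
#' @export
mf_model_spec <- function(n_classes = 3L, nk = 32L, nf = NULL,
                          input_feature = c("derivative", "signal", "both"),
                          conv_trainable = TRUE,
                          conv_init = c("mf_templates", "default"),
                          class_weighting = FALSE,
                          rr_branch_widths = c(32L, 16L, 8L),
                          window_len = 64L,
                          seed = 1L) {
  input_feature <- match.arg(input_feature)
  conv_init <- match.arg(conv_init)
  n_classes <- as.integer(n_classes)
  nk <- as.integer(nk)
  if (!n_classes %in% 3:5) stop("n_classes must be 3, 4 or 5")
  if (!nk %in% c(32L, 64L)) stop("nk must be 32 or 64")
  if (is.null(nf)) nf <- c(`3` = 11L, `4` = 12L, `5` = 13L)[[as.character(n_classes)]]
  structure(
    list(
      n_classes = n_classes, nk = nk, nf = as.integer(nf),
      input_feature = input_feature, conv_trainable = isTRUE(conv_trainable),
      conv_init = conv_init, class_weighting = isTRUE(class_weighting),
      rr_branch_widths = as.integer(rr_branch_widths),
      window_len = as.integer(window_len), seed = as.integer(seed)
    ),
    class = "mf_model_spec"
  )
}

#' Closed-form parameter accounting of the architecture
#'
#' Counts every weight, bias and batch-normalization parameter of the
#' network described by `spec`, split into trainable and non-trainable.
#' Batch-normalization contributes 4 per channel (scale and shift
#' trainable; moving mean and variance never). Freezing the correlator
#' moves its weights and biases to the non-trainable total.
#'
#' @param spec An [mf_model_spec()].
#' @return List of class `param_count`: `total`, `trainable`,
#'   `non_trainable`, and a `layers` breakdown.
#' @export
#' @examples
#' count_params(mf_model_spec(3, nk = 32, conv_trainable = FALSE))
count_params <- function(spec) {
  stopifnot(inherits(spec, "mf_model_spec"))
  cin <- if (spec$input_feature == "both") 2L else 1L
  nf <- spec$nf
  conv <- nf * spec$nk * cin + nf
  bn <- 4L * nf
  widths <- spec$rr_branch_widths
  d_in <- c(1L, widths[-length(widths)])
  rr <- sum(d_in * widths + widths)
  concat_w <- nf + 4L * widths[length(widths)]
  softmax <- concat_w * spec$n_classes + spec$n_classes
  total <- conv + bn + rr + softmax
  trainable <- 2L * nf + rr + softmax + if (spec$conv_trainable) conv else 0L
  structure(
    list(
      total = total, trainable = trainable, non_trainable = total - trainable,
      layers = c(
        conv = conv, batch_norm = bn, rr_branch = rr, softmax = softmax
      ),
      concat_width = concat_w
    ),
    class = "param_count"
  )
}

#' @export
print.param_count <- function(x, ...) {
  cat("Total params:", x$total, "\n")
  cat("Trainable params:", x$trainable, "\n")
  cat("Non-trainable params:", x$non_trainable, "\n")
  cat(
    "  per layer:",
    paste(names(x$layers), x$layers, sep = "=", collapse = " "), "\n"
  )
  invisible(x)
}

model_class_labels <- function(n_classes) {
  c("N", "SVEB", "VEB", "F", "Q")[seq_len(n_classes)]
}

glorot_uniform <- function(fan_in, fan_out, dims) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -limit, limit), dim = dims)
}

#' Assemble the matched-filter CNN
#'
#' Builds the network of [mf_model_spec()], initializing the correlator
#' kernels from a template bank (`conv_init = "mf_templates"`) or randomly.
#' For the two-channel `"both"` input, supply a named list
#' `list(signal = , derivative = )` of banks with equal labels. Kernel
#' biases start at zero, batch-normalization at identity (moving mean 0,
#' variance 1), and dense layers Glorot-uniform under the spec seed.
#'
#' @param spec An [mf_model_spec()].
#' @param bank A `template_bank` (or list of two for `"both"`); required
#'   iff `conv_init = "mf_templates"`.
#' @return An object of class `mf_model`.
#' @export
build_model <- function(spec, bank = NULL) {
  stopifnot(inherits(spec, "mf_model_spec"))
  cin <- if (spec$input_feature == "both") 2L else 1L
  nf <- spec$nf
  nk <- spec$nk

  if (spec$conv_init == "mf_templates") {
    if (is.null(bank)) stop("conv_init = 'mf_templates' requires a template bank")
    banks <- if (cin == 2L) {
      if (!is.list(bank) || !all(c("signal", "derivative") %in% names(bank))) {
        stop("input_feature = 'both' needs list(signal = , derivative = ) banks")
      }
      list(bank$signal, bank$derivative)
    } else {
      if (inherits(bank, "template_bank") && bank$feature_kind != spec$input_feature) {
        stop(
          "bank feature_kind '", bank$feature_kind,
          "' does not match spec input_feature '", spec$input_feature, "'"
        )
      }
      list(bank)
    }
    for (b in banks) {
      if (b$nk != nk || ncol(b$kernels) != nf) {
        stop(
          "template bank mismatch: expected NK=", nk, ", NF=", nf,
          " but bank has NK=", b$nk, ", NF=", ncol(b$kernels)
        )
      }
    }
  } else if (!is.null(bank)) {
    stop("bank must be omitted when conv_init = 'default'")
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(spec$seed)

  conv_w <- if (spec$conv_init == "mf_templates") {
    w <- array(0, dim = c(nk, cin, nf))
    for (c in seq_len(cin)) w[, c, ] <- banks[[c]]$kernels
    w
  } else {
    glorot_uniform(nk * cin, nk * nf, c(nk, cin, nf))
  }
  widths <- spec$rr_branch_widths
  d_in <- c(1L, widths[-length(widths)])
  rr_layers <- lapply(seq_along(widths), function(i) {
    list(
      W = glorot_uniform(d_in[i], widths[i], c(d_in[i], widths[i])),
      b = numeric(widths[i])
    )
  })
  concat_w <- nf + 4L * widths[length(widths)]
  params <- list(
    conv_w = conv_w,
    conv_b = numeric(nf),
    bn_gamma = rep(1, nf),
    bn_beta = numeric(nf),
    rr = rr_layers,
    out_w = glorot_uniform(concat_w, spec$n_classes, c(concat_w, spec$n_classes)),
    out_b = numeric(spec$n_classes)
  )
  structure(
    list(
      spec = spec,
      class_labels = model_class_labels(spec$n_classes),
      params = params,
      bn_moving_mean = numeric(nf),
      bn_moving_var = rep(1, nf),
      bank_labels = if (spec$conv_init == "mf_templates") banks[[1L]]$labels else NULL,
      trained = FALSE
    ),
    class = "mf_model"
  )
}

#' @export
print.mf_model <- function(x, ...) {
  pc <- model_param_count(x)
  cat(sprintf(
    "<mf_model> %d classes, NK=%d, NF=%d, input=%s, conv %s (%s init)%s\n",
    x$spec$n_classes, x$spec$nk, x$spec$nf, x$spec$input_feature,
    if (x$spec$conv_trainable) "trainable" else "frozen", x$spec$conv_init,
    if (x$trained) ", trained" else ""
  ))
  cat(sprintf(
    "  params: %d total (%d trainable, %d non-trainable)\n",
    pc$total, pc$trainable, pc$non_trainable
  ))
  invisible(x)
}

#' Introspected parameter counts of a built model
#'
#' Sums the actual parameter arrays of an [build_model()] network —
#' independent of the closed form in [count_params()], which it must
#' match exactly.
#'
#' @param model An `mf_model`.
#' @return List with `total`, `trainable`, `non_trainable`.
#' @export
model_param_count <- function(model) {
  conv_n <- length(model$params$conv_w) + length(model$params$conv_b)
  bn_train <- length(model$params$bn_gamma) + length(model$params$bn_beta)
  bn_frozen <- length(model$bn_moving_mean) + length(model$bn_moving_var)
  rr_n <- sum(vapply(
    model$params$rr,
    function(l) length(l$W) + length(l$b), numeric(1)
  ))
  out_n <- length(model$params$out_w) + length(model$params$out_b)
  total <- conv_n + bn_train + bn_frozen + rr_n + out_n
  trainable <- bn_train + rr_n + out_n +
    if (model$spec$conv_trainable) conv_n else 0L
  list(total = total, trainable = trainable, non_trainable = total - trainable)
}

# raw windows -> (B x L x cin) feature channels as a list of matrices
model_input_channels <- function(model, windows) {
  switch(model$spec$input_feature,
    signal = list(windows),
    derivative = list(feature_windows(windows, "derivative")),
    both = list(windows, feature_windows(windows, "derivative"))
  )
}

# im2col for stride-1 same-padding correlation: returns (B*T) x (nk*cin),
# rows ordered beat-fastest within each output-time block.
conv_im2col <- function(channels, nk) {
  pad_left <- (nk - 1L) %/% 2L
  blocks <- lapply(channels, function(Xf) {
    B <- nrow(Xf)
    Tn <- ncol(Xf)
    Xp <- cbind(
      matrix(0, B, pad_left), Xf,
      matrix(0, B, nk - 1L - pad_left)
    )
    cols <- matrix(0, B * Tn, nk)
    for (j in seq_len(nk)) {
      cols[, j] <- as.vector(Xp[, j:(j + Tn - 1L), drop = FALSE])
    }
    cols
  })
  do.call(cbind, blocks)
}

bn_eps <- 1e-3 # framework-conventional epsilon
bn_momentum <- 0.99

# Full forward pass. X: B x L raw signal windows; R: B x 4 RR features.
# training = TRUE uses batch statistics (and returns them); otherwise the
# moving statistics. Returns probs plus caches for backprop when
# keep_cache = TRUE.
model_forward <- function(model, X, R, training = FALSE, keep_cache = FALSE,
                          xcol = NULL) {
  p <- model$params
  B <- nrow(X)
  Tn <- ncol(X)
  nf <- model$spec$nf
  if (is.null(xcol)) {
    xcol <- conv_im2col(model_input_channels(model, X), model$spec$nk)
  }
  wmat <- matrix(p$conv_w, nrow = dim(p$conv_w)[1L] * dim(p$conv_w)[2L])
  conv <- xcol %*% wmat
  conv <- sweep(conv, 2L, p$conv_b, `+`)

  if (training) {
    mu <- colMeans(conv)
    centered <- sweep(conv, 2L, mu)
    v <- colMeans(centered^2)
  } else {
    mu <- model$bn_moving_mean
    v <- model$bn_moving_var
    centered <- sweep(conv, 2L, mu)
  }
  inv_sd <- 1 / sqrt(v + bn_eps)
  xhat <- sweep(centered, 2L, inv_sd, `*`)
  bn_out <- sweep(sweep(xhat, 2L, p$bn_gamma, `*`), 2L, p$bn_beta, `+`)
  act <- tanh(bn_out)

  gmp <- matrix(0, B, nf)
  gmp_idx <- matrix(0L, B, nf)
  for (c in seq_len(nf)) {
    M <- matrix(act[, c], nrow = B) # B x T
    idx <- max.col(M, ties.method = "first")
    gmp_idx[, c] <- idx
    gmp[, c] <- M[cbind(seq_len(B), idx)]
  }

  rv <- matrix(as.vector(R), ncol = 1L) # (B*4) x 1, beat-fastest
  rr_pre <- vector("list", length(p$rr))
  h <- rv
  for (i in seq_along(p$rr)) {
    z <- sweep(h %*% p$rr[[i]]$W, 2L, p$rr[[i]]$b, `+`)
    rr_pre[[i]] <- z
    h <- pmax(z, 0)
  }
  rr_flat <- matrix(h, nrow = B) # B x (4 * last width)

  z_cat <- cbind(gmp, rr_flat)
  logits <- sweep(z_cat %*% p$out_w, 2L, p$out_b, `+`)
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)

  out <- list(probs = probs)
  if (training) {
    out$batch_mu <- mu
    out$batch_var <- v
  }
  if (keep_cache) {
    out$cache <- list(
      xcol = xcol, conv = conv, centered = centered, inv_sd = inv_sd,
      xhat = xhat, act = act, gmp = gmp, gmp_idx = gmp_idx,
      rv = rv, rr_pre = rr_pre, rr_flat = rr_flat, z_cat = z_cat,
      B = B, Tn = Tn
    )
  }
  out
}

#' Class probabilities for a segment set
#'
#' @param model A (typically trained) `mf_model`.
#' @param segments `beat_segments` with RR features and no missing rows
#'   (see [drop_unavailable_rr()]).
#' @return Matrix of class probabilities (one row per beat, columns named
#'   by class) with attribute `"label"` holding the argmax labels.
#' @export
predict_mf <- function(model, segments) {
  if (is.null(segments$rr)) stop("segments carry no RR features")
  if (anyNA(segments$rr)) {
    stop("segments contain unavailable RR features; drop_unavailable_rr() first")
  }
  pr <- model_forward(model, segments$windows, segments$rr,
    training = FALSE
  )$probs
  colnames(pr) <- model$class_labels
  attr(pr, "label") <- model$class_labels[max.col(pr, ties.method = "first")]
  pr
}
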