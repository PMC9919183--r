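#' Per-class and macro metrics from a confusion matrix
#'
#' Rows index truth, columns predictions. For each class a one-vs-rest
#' reduction gives TP/FP/FN, from which precision `TP / (TP + FP)`,
#' sensitivity (recall) `TP / (TP + FN)` and `F1 = 2 * PREC * SEN /
#' (PREC + SEN)` are computed. Undefined ratios (zero denominator) are
#' reported as 0 and flagged. Macro scores are unweighted means over
#' classes with non-zero support; accuracy is `trace / total`.
#'
#' @param confusion Square count matrix with identical row/column class
#'   names (or unnamed).
#' @return Object of class `eval_report`: `confusion`, `per_class`
#'   (data.frame with PREC/SEN/F1/support), `macro`, `accuracy`,
#'   `undefined` (logical flag matrix).
#' @export
confusion_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion))
  if (is.null(rownames(confusion))) {
    rownames(confusion) <- colnames(confusion) <- paste0("c", seq_len(nrow(confusion)))
  }
  classes <- rownames(confusion)
  total <- sum(confusion)
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  prec <- safe_div(tp, tp + fp)
  sen <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * prec * sen, prec + sen)
  undefined <- cbind(
    PREC = (tp + fp) == 0, SEN = (tp + fn) == 0,
    F1 = (prec + sen) == 0
  )
  support <- rowSums(confusion)
  macro_over <- support > 0
  if (!all(macro_over)) {
    warning(
      "classes with zero test support excluded from macro averages: ",
      paste(classes[!macro_over], collapse = ", ")
    )
  }
  structure(
    list(
      confusion = confusion,
      per_class = data.frame(
        class = classes, PREC = unname(prec), SEN = unname(sen),
        F1 = unname(f1), support = unname(support)
      ),
      macro = c(
        PREC = mean(prec[macro_over]), SEN = mean(sen[macro_over]),
        F1 = mean(f1[macro_over])
      ),
      accuracy = if (total > 0) sum(tp) / total else 0,
      undefined = undefined
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> accuracy %.4f | macro PREC %.4f SEN %.4f F1 %.4f\n",
    x$accuracy, x$macro["PREC"], x$macro["SEN"], x$macro["F1"]
  ))
  cat("confusion (rows = truth):\n")
  print(x$confusion)
  print(x$per_class, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Evaluate a model on labeled beat segments
#'
#' @param model A trained `mf_model`.
#' @param segments `beat_segments` with complete RR features; labels must
#'   come from the model's class set.
#' @return An `eval_report` (see [confusion_metrics()]).
#' @export
evaluate_model <- function(model, segments) {
  xy <- segments_xy(segments, model)
  pred <- attr(predict_mf(model, segments), "label")
  truth <- factor(segments$super_label, levels = model$class_labels)
  pred <- factor(pred, levels = model$class_labels)
  confusion_metrics(table(truth, pred))
}

#' Noise-robustness sweep
#'
#' Re-runs training/evaluation across a grid of additive-noise levels.
#' Noise is always applied to the raw signal windows, never to
#' derivatives; the model's input feature is recomputed from the noisy
#' windows. The noise variance at a grid point is `percent / 100` times
#' the mean squared amplitude of the clean windows of the set being
#' corrupted. In `"train_and_test"` mode the model is retrained on noisy
#' training/validation data at each grid point; in `"test_only"` mode one
#' clean model per seed is reused and only the test set is corrupted.
#' Each grid point draws its noise with seed `base_seed + index` for
#' reproducibility.
#'
#' @param spec An [mf_model_spec()] (its `conv_init` decides whether a
#'   bank is extracted from the training data).
#' @param data List with `beat_segments` elements `train`, `val`, `test`
#'   (complete RR features).
#' @param mode `"test_only"` or `"train_and_test"`.
#' @param grid Numeric vector of noise percentages in `[0, 100]`.
#' @param base_seed Base seed for noise realizations.
#' @param epochs,batch_size Passed to [train_mf()].
#' @return data.frame with columns `noise_percent`, `mode`, `seed`,
#'   `accuracy`, `macro_F1`.
#' @export
noise_sweep <- function(spec, data, mode = c("test_only", "train_and_test"),
                        grid = seq(0, 50, by = 10), base_seed = 1000L,
                        epochs = 100L, batch_size = 512L) {
  mode <- match.arg(mode)
  if (any(grid < 0 | grid > 100)) stop("noise grid must lie in [0, 100]")
  noisy <- function(segments, pct, seed) {
    if (pct == 0) {
      return(segments)
    }
    w <- segments$windows
    p_sig <- mean(w^2)
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_seed(old_seed), add = TRUE)
    set.seed(seed)
    segments$windows <- w + matrix(
      stats::rnorm(length(w), 0, sqrt(pct / 100 * p_sig)),
      nrow = nrow(w)
    )
    segments
  }
  fit <- function(train, val) {
    bank <- if (spec$conv_init == "mf_templates") {
      if (spec$input_feature == "both") {
        list(
          signal = extract_templates(train, "sub_class", "signal", spec$nk),
          derivative = extract_templates(train, "sub_class", "derivative", spec$nk)
        )
      } else {
        extract_templates(train, "sub_class", spec$input_feature, spec$nk)
      }
    } else {
      NULL
    }
    if (!is.null(bank)) {
      nb <- if (inherits(bank, "template_bank")) bank else bank$derivative
      spec$nf <- length(nb$labels)
    }
    train_mf(build_model(spec, bank), train, val,
      epochs = epochs, batch_size = batch_size
    )
  }
  base_model <- if (mode == "test_only") fit(data$train, data$val) else NULL
  rows <- lapply(seq_along(grid), function(i) {
    pct <- grid[i]
    seed_i <- base_seed + i
    if (mode == "train_and_test") {
      m <- fit(
        noisy(data$train, pct, seed_i), noisy(data$val, pct, seed_i + 500L)
      )
      test <- noisy(data$test, pct, seed_i + 1000L)
    } else {
      m <- base_model
      test <- noisy(data$test, pct, seed_i + 1000L)
    }
    rep <- evaluate_model(m, test)
    data.frame(
      noise_percent = pct, mode = mode, seed = seed_i,
      accuracy = rep$accuracy, macro_F1 = unname(rep$macro["F1"])
    )
  })
  do.call(rbind, rows)
}
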