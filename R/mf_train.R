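# Training: class-weighted categorical cross-entropy, Adam with
# reduce-on-plateau scheduling, early stopping on validation loss with
# best-weight restoration. Backpropagation is written out by hand; the
# network is small enough that plain matrix algebra on one CPU trains it
# in seconds to minutes.

#' Inverse-frequency class weights
#'
#' `w_c = N_total / (n_classes * N_c)` over the training labels, so that a
#' balanced set gets unit weights and minority classes are up-weighted in
#' proportion to their scarcity.
#'
#' @param labels Character vector of training labels.
#' @param class_labels Ordered class label set of the model head.
#' @return Named numeric vector of weights.
#' @export
#' @examples
#' class_weights(rep(c("N", "SVEB", "VEB"), c(90, 5, 5)), c("N", "SVEB", "VEB"))
class_weights <- function(labels, class_labels) {
  counts <- vapply(class_labels, function(cl) sum(labels == cl), numeric(1))
  if (any(counts == 0)) {
    stop(
      "class(es) absent from training data: ",
      paste(class_labels[counts == 0], collapse = ", ")
    )
  }
  stats::setNames(length(labels) / (length(class_labels) * counts), class_labels)
}

adam_state <- function(params) {
  lapply(params, function(p) {
    if (is.list(p)) {
      adam_state(p)
    } else {
      list(m = array(0, dim = if (is.null(dim(p))) length(p) else dim(p)), v = NULL)
    }
  })
}

segments_xy <- function(segments, model) {
  lab <- match(segments$super_label, model$class_labels)
  if (anyNA(lab)) {
    bad <- unique(segments$super_label[is.na(lab)])
    stop(
      "labels outside the model's class set: ", paste(bad, collapse = ", "),
      " (model classes: ", paste(model$class_labels, collapse = ", "), ")"
    )
  }
  list(X = segments$windows, R = segments$rr, y = lab)
}

weighted_ce <- function(probs, y, w) {
  py <- probs[cbind(seq_along(y), y)]
  sum(w * -log(pmax(py, 1e-12))) / length(y)
}

# Backward pass; returns gradients matching the trainable-parameter layout.
model_backward <- function(model, cache, y, w) {
  p <- model$params
  B <- cache$B
  nf <- model$spec$nf
  n_cls <- model$spec$n_classes

  probs <- cache$probs
  dlogits <- probs
  dlogits[cbind(seq_len(B), y)] <- dlogits[cbind(seq_len(B), y)] - 1
  dlogits <- dlogits * (w / B)

  g <- list()
  g$out_w <- t(cache$z_cat) %*% dlogits
  g$out_b <- colSums(dlogits)
  dz_cat <- dlogits %*% t(p$out_w)

  dgmp <- dz_cat[, seq_len(nf), drop = FALSE]
  drr_flat <- dz_cat[, -seq_len(nf), drop = FALSE]

  # RR branch backward (flatten is a reshape)
  dh <- matrix(as.vector(drr_flat), nrow = B * 4L)
  g$rr <- vector("list", length(p$rr))
  for (i in rev(seq_along(p$rr))) {
    dz <- dh * (cache$rr_pre[[i]] > 0)
    h_in <- if (i == 1L) cache$rv else pmax(cache$rr_pre[[i - 1L]], 0)
    g$rr[[i]] <- list(W = t(h_in) %*% dz, b = colSums(dz))
    if (i > 1L) dh <- dz %*% t(p$rr[[i]]$W)
  }

  # GMP backward: route each channel's gradient to its argmax time
  dact <- matrix(0, B * cache$Tn, nf)
  for (c in seq_len(nf)) {
    rows <- (cache$gmp_idx[, c] - 1L) * B + seq_len(B)
    dact[cbind(rows, c)] <- dgmp[, c]
  }
  dbn_out <- dact * (1 - cache$act^2)

  g$bn_gamma <- colSums(dbn_out * cache$xhat)
  g$bn_beta <- colSums(dbn_out)

  if (model$spec$conv_trainable) {
    n <- B * cache$Tn
    dxhat <- sweep(dbn_out, 2L, p$bn_gamma, `*`)
    dvar <- colSums(dxhat * cache$centered) * (-0.5) * cache$inv_sd^3
    dmu <- -colSums(dxhat) * cache$inv_sd -
      dvar * 2 * colMeans(cache$centered)
    dconv <- sweep(dxhat, 2L, cache$inv_sd, `*`) +
      sweep(cache$centered, 2L, 2 * dvar / n, `*`) +
      matrix(dmu / n, n, nf, byrow = TRUE)
    g$conv_w <- array(
      t(cache$xcol) %*% dconv,
      dim = dim(p$conv_w)
    )
    g$conv_b <- colSums(dconv)
  }
  g
}

adam_update <- function(param, grad, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-7) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  if (is.null(state$v)) state$v <- array(0, dim = dim(state$m))
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  param <- param - lr * mhat / (sqrt(vhat) + eps)
  list(param = param, state = state)
}

#' Train the matched-filter CNN
#'
#' Minimizes (optionally class-weighted) categorical cross-entropy with
#' Adam at an initial learning rate of 1e-3, halving on a validation-loss
#' plateau (patience 10, floor 1e-5), early-stopping after 20 stagnant
#' epochs and restoring the best validation weights. Defaults: up to 500
#' epochs, mini-batches of 512. Batch statistics update the
#' batch-normalization moving averages with momentum 0.99. Shuffling and
#' initialization are driven by the spec seed, so runs are reproducible.
#'
#' @param model An `mf_model` from [build_model()].
#' @param train,val `beat_segments` with complete RR features.
#' @param epochs,batch_size Training schedule (defaults 500 / 512).
#' @param lr Initial learning rate.
#' @param lr_factor,lr_patience,min_lr Reduce-on-plateau schedule.
#' @param es_patience Early-stopping patience on validation loss.
#' @param verbose Print one line per epoch.
#' @return The trained `mf_model` with a `history` data.frame attached
#'   (`epoch`, `loss`, `acc`, `val_loss`, `val_acc`, `lr`).
#' @export
train_mf <- function(model, train, val, epochs = 500L, batch_size = 512L,
                     lr = 1e-3, lr_factor = 0.5, lr_patience = 10L,
                     min_lr = 1e-5, es_patience = 20L, verbose = FALSE) {
  tr <- segments_xy(train, model)
  va <- segments_xy(val, model)
  if (anyNA(tr$R) || anyNA(va$R)) {
    stop("train_mf: RR features contain NA; drop_unavailable_rr() first")
  }
  cw <- if (model$spec$class_weighting) {
    class_weights(train$super_label, model$class_labels)
  } else {
    stats::setNames(rep(1, model$spec$n_classes), model$class_labels)
  }
  # presence check runs regardless of weighting: every head class must occur
  invisible(class_weights(train$super_label, model$class_labels))
  w_tr <- unname(cw[tr$y])

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(model$spec$seed + 1L)

  trainable <- c(
    if (model$spec$conv_trainable) c("conv_w", "conv_b"),
    "bn_gamma", "bn_beta", "rr", "out_w", "out_b"
  )
  opt <- adam_state(model$params[trainable])
  step <- 0L
  n_tr <- length(tr$y)
  # feature channels are fixed: precompute once, index per batch
  chans <- model_input_channels(model, tr$X)
  va_xcol <- conv_im2col(model_input_channels(model, va$X), model$spec$nk)

  history <- data.frame()
  best <- list(val_loss = Inf, params = NULL, moving = NULL, epoch = 0L)
  plateau_wait <- 0L
  es_wait <- 0L
  cur_lr <- lr

  for (epoch in seq_len(epochs)) {
    perm <- sample.int(n_tr)
    ep_loss <- 0
    ep_correct <- 0
    for (start in seq(1L, n_tr, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1L, n_tr)]
      bx <- lapply(chans, function(ch) ch[idx, , drop = FALSE])
      xcol <- conv_im2col(bx, model$spec$nk)
      fw <- model_forward(model, tr$X[idx, , drop = FALSE],
        tr$R[idx, , drop = FALSE],
        training = TRUE, keep_cache = TRUE, xcol = xcol
      )
      fw$cache$probs <- fw$probs
      # moving-statistics update
      model$bn_moving_mean <- bn_momentum * model$bn_moving_mean +
        (1 - bn_momentum) * fw$batch_mu
      model$bn_moving_var <- bn_momentum * model$bn_moving_var +
        (1 - bn_momentum) * fw$batch_var

      g <- model_backward(model, fw$cache, tr$y[idx], w_tr[idx])
      step <- step + 1L
      for (nm in trainable) {
        if (nm == "rr") {
          for (i in seq_along(model$params$rr)) {
            for (part in c("W", "b")) {
              u <- adam_update(
                model$params$rr[[i]][[part]], g$rr[[i]][[part]],
                opt$rr[[i]][[part]], cur_lr, step
              )
              model$params$rr[[i]][[part]] <- u$param
              opt$rr[[i]][[part]] <- u$state
            }
          }
        } else {
          u <- adam_update(model$params[[nm]], g[[nm]], opt[[nm]], cur_lr, step)
          model$params[[nm]] <- u$param
          opt[[nm]] <- u$state
        }
      }
      ep_loss <- ep_loss + weighted_ce(fw$probs, tr$y[idx], w_tr[idx]) * length(idx)
      ep_correct <- ep_correct +
        sum(max.col(fw$probs, ties.method = "first") == tr$y[idx])
    }
    va_fw <- model_forward(model, va$X, va$R, training = FALSE, xcol = va_xcol)
    val_loss <- weighted_ce(va_fw$probs, va$y, rep(1, length(va$y)))
    val_acc <- mean(max.col(va_fw$probs, ties.method = "first") == va$y)
    history <- rbind(history, data.frame(
      epoch = epoch, loss = ep_loss / n_tr, acc = ep_correct / n_tr,
      val_loss = val_loss, val_acc = val_acc, lr = cur_lr
    ))
    if (verbose) {
      message(sprintf(
        "epoch %3d loss %.4f acc %.4f val_loss %.4f val_acc %.4f lr %.2g",
        epoch, ep_loss / n_tr, ep_correct / n_tr, val_loss, val_acc, cur_lr
      ))
    }
    if (val_loss < best$val_loss - 1e-9) {
      best <- list(
        val_loss = val_loss, params = model$params,
        moving = list(model$bn_moving_mean, model$bn_moving_var),
        epoch = epoch
      )
      plateau_wait <- 0L
      es_wait <- 0L
    } else {
      plateau_wait <- plateau_wait + 1L
      es_wait <- es_wait + 1L
      if (plateau_wait >= lr_patience && cur_lr > min_lr) {
        cur_lr <- max(cur_lr * lr_factor, min_lr)
        plateau_wait <- 0L
      }
      if (es_wait >= es_patience) break
    }
  }
  if (!is.null(best$params)) {
    model$params <- best$params
    model$bn_moving_mean <- best$moving[[1L]]
    model$bn_moving_var <- best$moving[[2L]]
  }
  model$trained <- TRUE
  model$history <- history
  model$best_epoch <- best$epoch
  model
}
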