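# Plain-text (JSON) model persistence: spec, parameter arrays, batch-norm
# moving statistics, class labels. Arrays are stored as {dim, data} pairs
# at full precision; save/load round-trips to the last printed digit
# (~1e-15 relative error at worst).

pack_array <- function(a) {
  list(dim = if (is.null(dim(a))) length(a) else dim(a), data = as.vector(a))
}

unpack_array <- function(x) {
  d <- unlist(x$dim)
  v <- as.numeric(unlist(x$data))
  if (length(d) <= 1L) v else array(v, dim = d)
}

#' Save / load a model as JSON
#'
#' @param model An `mf_model`.
#' @param path JSON file path.
#' @return `path` invisibly (writer); an `mf_model` (reader).
#' @export
save_model <- function(model, path) {
  obj <- list(
    format = "mfbeat-model-v1",
    spec = unclass(model$spec),
    class_labels = model$class_labels,
    bank_labels = model$bank_labels,
    trained = model$trained,
    params = list(
      conv_w = pack_array(model$params$conv_w),
      conv_b = pack_array(model$params$conv_b),
      bn_gamma = pack_array(model$params$bn_gamma),
      bn_beta = pack_array(model$params$bn_beta),
      rr = stats::setNames(
        lapply(model$params$rr, function(l) {
          list(W = pack_array(l$W), b = pack_array(l$b))
        }),
        paste0("layer", seq_along(model$params$rr))
      ),
      out_w = pack_array(model$params$out_w),
      out_b = pack_array(model$params$out_b)
    ),
    bn_moving_mean = model$bn_moving_mean,
    bn_moving_var = model$bn_moving_var
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "mfbeat-model-v1")) {
    stop("not an mfbeat model file: ", path)
  }
  spec_vals <- obj$spec
  spec <- mf_model_spec(
    n_classes = spec_vals$n_classes, nk = spec_vals$nk, nf = spec_vals$nf,
    input_feature = spec_vals$input_feature,
    conv_trainable = spec_vals$conv_trainable, conv_init = spec_vals$conv_init,
    class_weighting = spec_vals$class_weighting,
    rr_branch_widths = spec_vals$rr_branch_widths,
    window_len = spec_vals$window_len, seed = spec_vals$seed
  )
  structure(
    list(
      spec = spec,
      class_labels = obj$class_labels,
      params = list(
        conv_w = unpack_array(obj$params$conv_w),
        conv_b = unpack_array(obj$params$conv_b),
        bn_gamma = unpack_array(obj$params$bn_gamma),
        bn_beta = unpack_array(obj$params$bn_beta),
        rr = unname(lapply(
          obj$params$rr[order(names(obj$params$rr))],
          function(l) list(W = unpack_array(l$W), b = unpack_array(l$b))
        )),
        out_w = unpack_array(obj$params$out_w),
        out_b = unpack_array(obj$params$out_b)
      ),
      bn_moving_mean = as.numeric(obj$bn_moving_mean),
      bn_moving_var = as.numeric(obj$bn_moving_var),
      bank_labels = obj$bank_labels,
      trained = isTRUE(obj$trained)
    ),
    class = "mf_model"
  )
}
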