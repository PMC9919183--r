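#' Beat morphology specification for the synthetic generator
#'
#' Describes one beat class as a sum of Gaussian deflections (stand-ins for
#' the P wave, QRS complex and T wave) plus its RR-interval dynamics. The
#' largest-amplitude component is treated as the QRS complex; the annotated
#' R-peak of every generated beat is the sample of maximum absolute QRS
#' deflection.
#'
#' @param class_symbol Single-character beat annotation symbol; must belong
#'   to [beat_symbol_whitelist()].
#' @param wave_params Matrix or data.frame with columns `amplitude`
#'   (dimensionless), `center` (seconds relative to the R-peak) and `width`
#'   (Gaussian sd, seconds, > 0). One row per deflection.
#' @param rr_mean Mean RR interval preceding a beat of this class, seconds.
#' @param rr_jitter_sd Standard deviation of Gaussian RR jitter, seconds.
#'
#' @return An object of class `beat_shape_spec`.
#' @export
beat_shape_spec <- function(class_symbol, wave_params, rr_mean, rr_jitter_sd = 0) {
  wave_params <- as.matrix(wave_params)
  colnames(wave_params) <- c("amplitude", "center", "width")
  if (!class_symbol %in% beat_symbol_whitelist()) {
    stop(
      "class_symbol '", class_symbol, "' is not an annotated beat symbol; ",
      "expected one of: ", paste(beat_symbol_whitelist(), collapse = " ")
    )
  }
  if (any(wave_params[, "width"] <= 0)) stop("wave widths must be > 0")
  if (rr_mean <= 0) stop("rr_mean must be > 0")
  if (rr_jitter_sd < 0) stop("rr_jitter_sd must be >= 0")
  structure(
    list(
      class_symbol = class_symbol, wave_params = wave_params,
      rr_mean = rr_mean, rr_jitter_sd = rr_jitter_sd
    ),
    class = "beat_shape_spec"
  )
}

#' Default three-class synthetic morphologies
#'
#' Three mutually distinguishable beat shapes emulating a normal beat
#' (`"N"`: P/QRS/T, narrow tall positive QRS, RR 0.8 s), an atrial premature
#' beat (`"A"`: early P fused toward QRS, shorter RR 0.6 s) and a premature
#' ventricular contraction (`"V"`: wide negative QRS, absent P, RR 0.55 s).
#' Amplitudes are in arbitrary units; the generator makes no claim of
#' physiological fidelity beyond distinct QRS width/polarity and
#' class-dependent RR dynamics.
#'
#' @param rr_jitter_sd RR jitter applied to every class, seconds.
#' @return List of three [beat_shape_spec()] objects named by symbol.
#' @export
default_beat_shapes <- function(rr_jitter_sd = 0.04) {
  wp <- function(...) matrix(c(...), ncol = 3, byrow = TRUE)
  list(
    N = beat_shape_spec(
      "N",
      wp(
        0.15, -0.20, 0.025, # P
        1.00, 0.00, 0.012, # QRS (narrow, positive)
        -0.15, 0.025, 0.010, # S dip
        0.30, 0.25, 0.045 # T
      ),
      rr_mean = 0.80, rr_jitter_sd = rr_jitter_sd
    ),
    A = beat_shape_spec(
      "A",
      wp(
        0.25, -0.10, 0.020, # early ectopic P close to QRS
        0.85, 0.00, 0.014, # QRS slightly wider
        0.25, 0.22, 0.040 # T
      ),
      rr_mean = 0.60, rr_jitter_sd = rr_jitter_sd
    ),
    V = beat_shape_spec(
      "V",
      wp(
        -1.10, 0.00, 0.040, # wide negative QRS, no P
        0.45, 0.30, 0.060 # large discordant T
      ),
      rr_mean = 0.55, rr_jitter_sd = rr_jitter_sd
    )
  )
}

#' Configuration of a synthetic ECG record
#'
#' @param fs Sampling rate in Hz. Default 360 Hz, the native rate of the
#'   ambulatory recordings the generator emulates.
#' @param duration Record duration in seconds.
#' @param class_mix Named numeric vector of per-class probabilities summing
#'   to 1 (names are beat symbols present in `shapes`).
#' @param shapes List of [beat_shape_spec()]; default [default_beat_shapes()].
#' @param noise_percent Additive white Gaussian noise power as a percentage
#'   of the clean signal power, in `[0, 100]`.
#' @param seed Integer RNG seed; generation is bit-reproducible given the
#'   seed.
#'
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(fs = 360, duration = 60,
                             class_mix = c(N = 0.8, A = 0.1, V = 0.1),
                             shapes = default_beat_shapes(),
                             noise_percent = 0, seed = 1L) {
  if (fs <= 0) stop("fs must be > 0")
  if (noise_percent < 0 || noise_percent > 100) {
    stop("noise_percent must be in [0, 100]")
  }
  if (abs(sum(class_mix) - 1) > 1e-9) {
    stop("class_mix probabilities must sum to 1 (got ", sum(class_mix), ")")
  }
  shape_syms <- vapply(shapes, function(s) s$class_symbol, character(1))
  if (!all(names(class_mix) %in% shape_syms)) {
    stop(
      "class_mix names missing from shapes: ",
      paste(setdiff(names(class_mix), shape_syms), collapse = ", ")
    )
  }
  names(shapes) <- shape_syms
  structure(
    list(
      fs = fs, duration = duration, class_mix = class_mix, shapes = shapes,
      noise_percent = noise_percent, seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

sum_of_gaussians <- function(t, wave_params) {
  out <- numeric(length(t))
  for (r in seq_len(nrow(wave_params))) {
    a <- wave_params[r, 1]
    mu <- wave_params[r, 2]
    s <- wave_params[r, 3]
    out <- out + a * exp(-0.5 * ((t - mu) / s)^2)
  }
  out
}

#' Synthesize an annotated ECG record
#'
#' Lays beats down sequentially: each beat's class is drawn from
#' `class_mix`, the gap to the previous peak from the incoming beat's
#' `rr_mean` plus Gaussian jitter (truncated at 0.2 s to keep peaks
#' ordered), and the beat waveform (sum of Gaussians) is added to the
#' signal centered on the peak. The annotated index is the sample of
#' maximum absolute QRS deflection. AWGN is then added at the configured
#' percentage of the clean signal power.
#'
#' @param config A [synthetic_config()].
#' @return A [beat_record()] with attribute `"clean_signal"` holding the
#'   noise-free signal (useful for verifying realized noise power).
#' @export
#' @examples
#' rec <- synthesize_record(synthetic_config(duration = 30, seed = 7))
#' rec
synthesize_record <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  fs <- config$fs
  n <- floor(config$duration * fs)
  min_rr <- min(vapply(
    config$shapes[names(config$class_mix)],
    function(s) s$rr_mean, numeric(1)
  ))
  if (config$duration < 2 * min_rr) {
    stop(
      "duration too short to hold one beat: need at least ",
      format(2 * min_rr), " s"
    )
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(config$seed)

  syms <- names(config$class_mix)
  # draw classes and peak times until the record is full
  t_peak <- numeric(0)
  classes <- character(0)
  t_cur <- min_rr # leave room for the first beat's waveform
  margin <- 0.4 # keep T waves inside the record
  repeat {
    cls <- sample(syms, 1L, prob = config$class_mix)
    shape <- config$shapes[[cls]]
    rr <- shape$rr_mean +
      if (shape$rr_jitter_sd > 0) stats::rnorm(1L, 0, shape$rr_jitter_sd) else 0
    rr <- max(rr, 0.2)
    t_next <- if (length(t_peak) == 0L) t_cur else t_peak[length(t_peak)] + rr
    if (t_next > config$duration - margin) break
    t_peak <- c(t_peak, t_next)
    classes <- c(classes, cls)
  }
  if (length(t_peak) == 0L) {
    stop(
      "duration too short to hold one beat: need at least ",
      format(min_rr + margin), " s"
    )
  }

  signal <- numeric(n)
  peaks <- integer(length(t_peak))
  t_axis <- (seq_len(n) - 1) / fs
  for (i in seq_along(t_peak)) {
    shape <- config$shapes[[classes[i]]]
    # restrict evaluation to a +-0.5 s neighbourhood for speed
    lo <- max(1L, floor((t_peak[i] - 0.5) * fs))
    hi <- min(n, ceiling((t_peak[i] + 0.5) * fs))
    idx <- lo:hi
    signal[idx] <- signal[idx] + sum_of_gaussians(t_axis[idx] - t_peak[i], shape$wave_params)
    # annotate at the argmax of the |QRS| component (largest |amplitude| wave)
    qrs_row <- which.max(abs(shape$wave_params[, 1]))
    qrs <- abs(sum_of_gaussians(
      t_axis[idx] - t_peak[i],
      shape$wave_params[qrs_row, , drop = FALSE]
    ))
    peaks[i] <- idx[which.max(qrs)] - 1L # 0-based
  }

  clean <- signal
  if (config$noise_percent > 0) {
    signal <- add_awgn(signal, config$noise_percent,
      seed = config$seed + 1L
    )
  }
  rec <- beat_record(
    record_id = sprintf("synth-%d", config$seed),
    fs = fs, signal = signal, peaks = peaks, symbols = classes
  )
  attr(rec, "clean_signal") <- clean
  rec
}

#' Add white Gaussian noise at a percentage of signal power
#'
#' The noise variance is `noise_percent / 100` times the mean squared
#' amplitude of the input, taken over the whole signal.
#'
#' @param signal Numeric vector (non-empty).
#' @param noise_percent Noise-to-signal power percentage in `[0, 100]`.
#' @param seed Optional integer seed for a reproducible realization.
#' @return Numeric vector, same length as `signal`.
#' @export
add_awgn <- function(signal, noise_percent, seed = NULL) {
  if (length(signal) == 0L) stop("add_awgn: empty signal")
  if (noise_percent < 0 || noise_percent > 100) {
    stop("noise_percent must be in [0, 100]")
  }
  if (noise_percent == 0) {
    return(signal)
  }
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_seed(old_seed), add = TRUE)
    set.seed(as.integer(seed))
  }
  p_sig <- mean(signal^2)
  signal + stats::rnorm(length(signal), 0, sqrt(noise_percent / 100 * p_sig))
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}
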