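# Anti-aliased rational resampling (polyphase-style: zero-stuff, windowed-
# sinc FIR low-pass, decimate). 360 -> 128 Hz reduces to the ratio 16/45.

fir_lowpass <- function(n_taps, cutoff) {
  # windowed-sinc low-pass; cutoff in cycles/sample (Nyquist = 0.5)
  m <- n_taps - 1L
  k <- seq(0L, m)
  x <- 2 * cutoff * (k - m / 2)
  h <- 2 * cutoff * ifelse(x == 0, 1, sin(pi * x) / (pi * x))
  w <- 0.54 - 0.46 * cos(2 * pi * k / m) # Hamming
  h * w
}

#' Rational-factor resampling with an anti-aliasing FIR filter
#'
#' Resamples `x` by `p/q`: zero-stuffs by `p`, applies a Hamming-windowed
#' sinc low-pass at `min(1/p, 1/q)` of the upsampled Nyquist, compensates
#' the filter group delay, and keeps every `q`-th sample. Matches the
#' standard polyphase resampler up to edge transients.
#'
#' @param x Numeric vector.
#' @param p,q Positive integers (up/down factors); reduced by their gcd.
#' @param taps_per_phase Half-width control of the FIR; total length is
#'   `2 * taps_per_phase * max(p, q) + 1`.
#' @return Numeric vector of length `ceiling(length(x) * p / q)`.
#' @export
resample_poly <- function(x, p, q, taps_per_phase = 10L) {
  g <- gcd_int(p, q)
  p <- as.integer(p / g)
  q <- as.integer(q / g)
  if (p == 1L && q == 1L) {
    return(x)
  }
  n_out <- ceiling(length(x) * p / q)
  up <- numeric(length(x) * p)
  up[seq(1L, length(up), by = p)] <- x * p # compensate zero-stuffing loss
  n_taps <- 2L * taps_per_phase * max(p, q) + 1L
  h <- fir_lowpass(n_taps, cutoff = min(1 / p, 1 / q) / 2)
  y <- fft_filter(up, h)
  delay <- (n_taps - 1L) / 2L
  y <- y[(delay + 1L):(delay + length(up))]
  y[seq(1L, by = q, length.out = n_out)]
}

gcd_int <- function(a, b) {
  while (b != 0L) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

# linear convolution via FFT, full length
fft_filter <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nfft <- stats::nextn(n, 2L)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - length(x)))) *
    stats::fft(c(h, numeric(nfft - length(h)))), inverse = TRUE)) / nfft
  y[seq_len(n)]
}

#' Downsample a beat_record to a target rate
#'
#' The signal is resampled with [resample_poly()]; annotated peak indices
#' are rescaled by `target_fs / fs` and rounded (half-to-even) onto the new
#' grid, then clipped into range. Upsampling is out of scope and errors.
#'
#' @param record A [beat_record()].
#' @param target_fs Target sampling rate in Hz, at most `record$fs`.
#' @return A [beat_record()] at `target_fs`.
#' @export
resample_record <- function(record, target_fs = 128) {
  validate_beat_record(record)
  if (target_fs > record$fs) {
    stop(
      "upsampling (", record$fs, " -> ", target_fs,
      " Hz) is out of scope; target_fs must be <= record fs"
    )
  }
  if (target_fs == record$fs) {
    return(record)
  }
  # rational approximation of the rate ratio on a 1e6 grid
  p <- as.integer(round(target_fs * 1e3))
  q <- as.integer(round(record$fs * 1e3))
  y <- resample_poly(record$signal, p, q)
  ratio <- target_fs / record$fs
  new_peaks <- as.integer(round(record$peaks * ratio)) # round half to even
  new_peaks <- pmin(pmax(new_peaks, 0L), length(y) - 1L)
  beat_record(
    record_id = record$record_id, fs = target_fs, signal = y,
    peaks = new_peaks, symbols = record$symbols
  )
}
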