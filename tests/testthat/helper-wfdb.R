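# Minimal WFDB *writer* used as an independent oracle for the reader
# tests: it emits header/signal/annotation bytes straight from the format
# definition, sharing no code with the package's reader.

write_wfdb_fixture <- function(dir, record = "t100", fs = 360,
                               leads = c("MLII", "V1"),
                               signals, # list of numeric vectors, equal length
                               ann_samples, ann_codes,
                               gain = 200, adczero = 1024,
                               with_aux = TRUE, with_skip = FALSE) {
  stopifnot(length(signals) == length(leads))
  n <- length(signals[[1L]])
  adc <- lapply(signals, function(x) {
    v <- as.integer(round(x * gain + adczero))
    pmin(pmax(v, 0L), 4095L)
  })

  hea <- c(
    sprintf("%s %d %g %d", record, length(leads), fs, n),
    vapply(seq_along(leads), function(k) {
      sprintf(
        "%s.dat 212 %g %d %d %d 0 0 %s",
        record, gain, 11L, adczero, adc[[k]][1L], leads[k]
      )
    }, character(1))
  )
  writeLines(hea, file.path(dir, paste0(record, ".hea")))

  # format 212: frames interleave the leads; 2 samples -> 3 bytes
  flat <- if (length(leads) == 2L) {
    as.vector(rbind(adc[[1L]], adc[[2L]]))
  } else {
    adc[[1L]]
  }
  if (length(flat) %% 2L == 1L) flat <- c(flat, 0L)
  s1 <- flat[seq(1L, length(flat), by = 2L)]
  s2 <- flat[seq(2L, length(flat), by = 2L)]
  bytes <- as.raw(as.vector(rbind(
    bitwAnd(s1, 0xFFL),
    bitwOr(bitwAnd(bitwShiftR(s1, 8L), 0x0FL), bitwShiftL(bitwAnd(bitwShiftR(s2, 8L), 0x0FL), 4L)),
    bitwAnd(s2, 0xFFL)
  )))
  writeBin(bytes, file.path(dir, paste0(record, ".dat")))

  # MIT annotation stream
  word <- function(code, interval) {
    c(bitwAnd(interval, 0xFFL), bitwOr(bitwShiftL(code, 2L), bitwAnd(bitwShiftR(interval, 8L), 0x03L)))
  }
  stream <- integer(0)
  t_prev <- 0L
  if (with_aux) { # AUX pseudo-annotation with a 3-byte payload (padded)
    stream <- c(stream, word(63L, 3L), utf8ToInt("(N"), 0L, 0L)
  }
  for (i in seq_along(ann_samples)) {
    gap <- ann_samples[i] - t_prev
    if (with_skip && i == 1L && gap > 0L) {
      # encode the first gap as SKIP (code 59) + 4-byte PDP-11 interval
      stream <- c(
        stream, word(59L, 0L),
        bitwAnd(bitwShiftR(gap, 16L), 0xFFL), bitwShiftR(gap, 24L),
        bitwAnd(gap, 0xFFL), bitwAnd(bitwShiftR(gap, 8L), 0xFFL)
      )
      stream <- c(stream, word(ann_codes[i], 0L))
    } else {
      stopifnot(gap <= 1023L)
      stream <- c(stream, word(ann_codes[i], gap))
    }
    t_prev <- ann_samples[i]
  }
  stream <- c(stream, word(0L, 0L)) # end of stream
  writeBin(as.raw(stream), file.path(dir, paste0(record, ".atr")))
  file.path(dir, record)
}
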