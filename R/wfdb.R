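# Minimal WFDB reader: header (.hea), signal (.dat, formats 212/16/80),
# and MIT-format annotations (.atr). Only what beat-by-beat segmentation
# needs: one lead's samples plus beat annotations. No WFDB writing.

# standard annotation-code -> symbol table (beat codes only)
wfdb_code_symbols <- function() {
  c(
    `1` = "N", `2` = "L", `3` = "R", `4` = "a", `5` = "V", `6` = "F",
    `7` = "J", `8` = "A", `9` = "S", `10` = "E", `11` = "j", `12` = "/",
    `13` = "Q", `34` = "e", `38` = "f"
  )
}

parse_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty WFDB header: ", hea_path)
  top <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(top) < 3L) stop("malformed WFDB header line: ", lines[1L])
  nsig <- as.integer(top[2L])
  fs <- as.numeric(sub("/.*", "", top[3L])) # strip counter frequency
  nsamp <- if (length(top) >= 4L) as.integer(top[4L]) else NA_integer_
  if (length(lines) < 1L + nsig) {
    stop("WFDB header declares ", nsig, " signals but lists fewer")
  }
  sig <- lapply(lines[1L + seq_len(nsig)], function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    fmt_field <- f[2L]
    fmt <- as.integer(sub("^([0-9]+).*", "\\1", fmt_field))
    gain_field <- if (length(f) >= 3L) f[3L] else "200"
    gain <- as.numeric(sub("^([-0-9.eE+]+).*", "\\1", gain_field))
    baseline <- if (grepl("\\(", gain_field)) {
      as.numeric(sub(".*\\((-?[0-9]+)\\).*", "\\1", gain_field))
    } else if (length(f) >= 5L) {
      as.numeric(f[5L]) # adczero
    } else {
      0
    }
    desc <- if (length(f) >= 9L) paste(f[9:length(f)], collapse = " ") else ""
    list(
      file = f[1L], format = fmt,
      gain = if (is.na(gain) || gain == 0) 200 else gain,
      baseline = if (is.na(baseline)) 0 else baseline,
      description = desc
    )
  })
  list(record = top[1L], nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

read_dat_212 <- function(raw, nsig) {
  n_pairs <- length(raw) %/% 3L
  b <- matrix(as.integer(raw[seq_len(3L * n_pairs)]), nrow = 3L)
  s1 <- b[1L, ] + bitwShiftL(bitwAnd(b[2L, ], 0x0FL), 8L)
  s2 <- b[3L, ] + bitwShiftL(bitwAnd(bitwShiftR(b[2L, ], 4L), 0x0FL), 8L)
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  flat <- as.vector(rbind(s1, s2))
  matrix(flat, nrow = nsig) # one column per frame
}

read_wfdb_signal <- function(dat_path, fmt, nsig) {
  raw <- readBin(dat_path, "raw", n = file.info(dat_path)$size)
  if (fmt == 212L) {
    read_dat_212(raw, nsig)
  } else if (fmt == 16L) {
    v <- readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L, signed = TRUE, endian = "little")
    matrix(v, nrow = nsig)
  } else if (fmt == 80L) {
    v <- as.integer(raw) - 128L
    matrix(v, nrow = nsig)
  } else {
    stop("unsupported WFDB signal format: ", fmt)
  }
}

read_wfdb_annotations <- function(atr_path) {
  raw <- as.integer(readBin(atr_path, "raw", n = file.info(atr_path)$size))
  n_words <- length(raw) %/% 2L
  time <- 0
  i <- 1L
  samples <- integer(0)
  codes <- integer(0)
  while (i + 1L <= 2L * n_words) {
    lo <- raw[i]
    hi <- raw[i + 1L]
    i <- i + 2L
    code <- bitwShiftR(hi, 2L)
    interval <- bitwShiftL(bitwAnd(hi, 0x03L), 8L) + lo
    if (code == 0L && interval == 0L) break
    if (code == 59L) { # SKIP: 4-byte interval, PDP-11 word order
      if (i + 3L > length(raw)) stop("truncated SKIP annotation in ", atr_path)
      w_hi <- raw[i] + bitwShiftL(raw[i + 1L], 8L)
      w_lo <- raw[i + 2L] + bitwShiftL(raw[i + 3L], 8L)
      i <- i + 4L
      time <- time + w_hi * 65536 + w_lo
    } else if (code %in% c(60L, 61L, 62L)) {
      # NUM / SUB / CHN modifiers: no time advance, ignored
    } else if (code == 63L) { # AUX: skip payload (padded to even length)
      skip <- interval + (interval %% 2L)
      i <- i + skip
    } else {
      time <- time + interval
      samples <- c(samples, as.integer(time))
      codes <- c(codes, code)
    }
  }
  list(sample = samples, code = codes)
}

#' Read one lead of a WFDB record with beat annotations
#'
#' Parses the `.hea` header, decodes the `.dat` signal (formats 212, 16 and
#' 80) for the requested lead, converts samples to physical units via the
#' per-signal gain and baseline, and attaches beat annotations from the
#' `.atr` file. Non-beat annotation codes (rhythm changes, signal-quality
#' marks, comments, ...) are dropped; only symbols in
#' [beat_symbol_whitelist()] are kept.
#'
#' @param path Record path without extension (e.g. `"mitdb/100"`).
#' @param lead_name Signal description to select (e.g. `"MLII"`).
#' @param annotator Annotation file extension, default `"atr"`.
#' @return A [beat_record()] in physical units.
#' @export
read_wfdb_record <- function(path, lead_name = "MLII", annotator = "atr") {
  hea_path <- paste0(path, ".hea")
  if (!file.exists(hea_path)) stop("WFDB header not found: ", hea_path)
  hdr <- parse_wfdb_header(hea_path)
  leads <- vapply(hdr$signals, function(s) s$description, character(1))
  k <- match(lead_name, leads)
  if (is.na(k)) {
    stop(
      "lead '", lead_name, "' not present in record '", hdr$record,
      "'; available leads: ", paste(leads, collapse = ", ")
    )
  }
  sig_meta <- hdr$signals[[k]]
  dat_path <- file.path(dirname(hea_path), sig_meta$file)
  if (!file.exists(dat_path)) stop("WFDB signal file not found: ", dat_path)
  fmts <- unique(vapply(hdr$signals, function(s) s$format, integer(1)))
  if (length(fmts) != 1L) stop("mixed-format WFDB records are unsupported")
  adc <- read_wfdb_signal(dat_path, fmts, hdr$nsig)
  x <- (adc[k, ] - sig_meta$baseline) / sig_meta$gain
  if (!is.na(hdr$nsamp) && hdr$nsamp <= length(x)) x <- x[seq_len(hdr$nsamp)]

  atr_path <- paste0(path, ".", annotator)
  if (!file.exists(atr_path)) {
    stop("WFDB annotation file not found: ", atr_path)
  }
  ann <- read_wfdb_annotations(atr_path)
  sym_map <- wfdb_code_symbols()
  sym <- sym_map[as.character(ann$code)]
  keep <- !is.na(sym) & sym %in% beat_symbol_whitelist() &
    ann$sample >= 0L & ann$sample < length(x)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message("read_wfdb_record: dropped ", n_dropped, " non-beat/out-of-range annotations")
  }
  beat_record(
    record_id = hdr$record, fs = hdr$fs, signal = x,
    peaks = ann$sample[keep], symbols = unname(sym[keep])
  )
}
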