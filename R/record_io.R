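#' Annotated beat symbols recognized by the package
#'
#' The single-character beat annotation symbols of the five-super-class
#' taxonomy handled here: normal and bundle-branch/escape beats (N, L, R,
#' e, j), supraventricular ectopics (A, a, J, S), ventricular ectopics
#' (V, E), fusion (F) and unknown/paced (Q, f, /). Anything outside this
#' whitelist is treated as a non-beat annotation and dropped on read.
#'
#' @return Character vector of 15 symbols.
#' @export
beat_symbol_whitelist <- function() {
  c(
    "N", "L", "R", "e", "j",
    "A", "a", "J", "S",
    "V", "E",
    "F",
    "Q", "f", "/"
  )
}

fixture_paths <- function(path) {
  stem <- sub("\\.json$", "", path)
  list(
    header = paste0(stem, ".json"),
    signal = paste0(stem, ".signal.csv"),
    ann = paste0(stem, ".ann.csv")
  )
}

#' Write a beat_record in the plain fixture dialect
#'
#' The dialect is three diff-friendly text files sharing a stem: a JSON
#' header `<stem>.json` (`record_id`, `fs`, sample and beat counts), a
#' signal table `<stem>.signal.csv` with columns `sample_index` (0-based)
#' and `value`, and an annotation table `<stem>.ann.csv` with columns
#' `peak_index` (0-based) and `symbol`.
#'
#' @param record A [beat_record()].
#' @param path Output stem or path to the `.json` header.
#' @return The header path, invisibly.
#' @export
write_fixture <- function(record, path) {
  validate_beat_record(record)
  p <- fixture_paths(path)
  jsonlite::write_json(
    list(
      format = "mfbeat-fixture-v1",
      record_id = record$record_id,
      fs = record$fs,
      n_samples = length(record$signal),
      n_beats = length(record$peaks)
    ),
    p$header,
    auto_unbox = TRUE, digits = NA
  )
  utils::write.csv(
    data.frame(
      sample_index = seq_along(record$signal) - 1L,
      value = record$signal
    ),
    p$signal,
    row.names = FALSE
  )
  utils::write.csv(
    data.frame(peak_index = record$peaks, symbol = record$symbols),
    p$ann,
    row.names = FALSE
  )
  invisible(p$header)
}

read_fixture_csv <- function(path, expected_cols) {
  if (!file.exists(path)) stop("fixture file missing: ", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = NA),
    error = function(e) stop("malformed fixture CSV '", path, "': ", conditionMessage(e))
  )
  if (!identical(names(df), expected_cols)) {
    stop(
      "malformed fixture CSV '", path, "': expected columns ",
      paste(expected_cols, collapse = ","), " but found ",
      paste(names(df), collapse = ",")
    )
  }
  df
}

#' Read a beat_record from the plain fixture dialect
#'
#' Inverse of [write_fixture()]. All [beat_record()] invariants are
#' enforced on read; malformed files raise an error naming the offending
#' file and field.
#'
#' @param path Fixture stem or path to the `.json` header.
#' @return A [beat_record()].
#' @export
read_fixture <- function(path) {
  p <- fixture_paths(path)
  if (!file.exists(p$header)) stop("fixture header missing: ", p$header)
  hdr <- tryCatch(
    jsonlite::read_json(p$header, simplifyVector = TRUE),
    error = function(e) stop("malformed fixture header '", p$header, "': ", conditionMessage(e))
  )
  for (field in c("record_id", "fs")) {
    if (is.null(hdr[[field]])) {
      stop("malformed fixture header '", p$header, "': missing field '", field, "'")
    }
  }
  sig <- read_fixture_csv(p$signal, c("sample_index", "value"))
  if (nrow(sig) == 0L) stop("fixture '", p$signal, "': empty signal")
  if (!identical(as.integer(sig$sample_index), seq_len(nrow(sig)) - 1L)) {
    stop("fixture '", p$signal, "': sample_index must run 0..n-1")
  }
  ann <- read_fixture_csv(p$ann, c("peak_index", "symbol"))
  if (!is.null(hdr$n_samples) && hdr$n_samples != nrow(sig)) {
    stop(
      "fixture '", p$header, "': header n_samples (", hdr$n_samples,
      ") disagrees with signal rows (", nrow(sig), ")"
    )
  }
  beat_record(
    record_id = hdr$record_id, fs = hdr$fs, signal = sig$value,
    peaks = ann$peak_index, symbols = as.character(ann$symbol)
  )
}
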