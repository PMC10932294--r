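#' Read an EEG trace from a two-column time/value text file
#'
#' Accepts whitespace- or tab-delimited text with two numeric columns
#' (time in seconds, signal value), with or without a header line. The
#' sampling rate is inferred from the median time step.
#'
#' @param path File path.
#' @return An [eeg_trace()].
#' @export
read_eeg_text <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(trimws(first),
                                                           "\\s+")[[1]][1])))
  tab <- utils::read.table(path, header = has_header)
  if (ncol(tab) < 2) abort("Expected two columns: time, value.")
  t <- as.numeric(tab[[1]])
  v <- as.numeric(tab[[2]])
  if (anyNA(t) || anyNA(v)) abort("Non-numeric entries in EEG text file.")
  dt <- median(diff(t))
  if (!is.finite(dt) || dt <= 0) abort("Time column must be increasing.")
  eeg_trace(v, fs = 1 / dt, start_s = t[1])
}

#' Write an EEG trace as two-column time/value text
#'
#' @param trace An [eeg_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eeg_text <- function(trace, path) {
  stopifnot(inherits(trace, "eeg_trace"))
  readr::write_tsv(tidy(trace), path)
  invisible(path)
}

#' Read one channel of a European Data Format (EDF) recording
#'
#' Minimal reader for uncompressed EDF: parses the fixed 256-byte header
#' plus per-signal header blocks, reads the interleaved 16-bit
#' little-endian data records of the requested channel and rescales the
#' digital values to physical units using the per-signal calibration
#' (physical and digital minima/maxima).
#'
#' @param path EDF file path.
#' @param channel Channel index (1-based) or label.
#' @return An [eeg_trace()] in physical units.
#' @export
read_edf <- function(path, channel = 1) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_field <- function(nbytes) trimws(rawToChar(readBin(con, "raw", nbytes)))
  version <- hdr_field(8)
  if (version != "0") abort("Not an EDF file (version field != '0').")
  hdr_field(80); hdr_field(80)           # patient, recording ids
  hdr_field(8); hdr_field(8)             # start date, time
  header_bytes <- as.integer(hdr_field(8))
  hdr_field(44)                          # reserved
  n_records <- as.integer(hdr_field(8))
  record_duration <- as.numeric(hdr_field(8))
  ns <- as.integer(hdr_field(4))
  if (is.na(ns) || ns < 1) abort("Malformed EDF header.")

  per_signal <- function(nbytes) {
    vapply(seq_len(ns), function(i) hdr_field(nbytes), character(1))
  }
  labels <- per_signal(16)
  per_signal(80); per_signal(8)          # transducer, physical dimension
  phys_min <- as.numeric(per_signal(8))
  phys_max <- as.numeric(per_signal(8))
  dig_min <- as.numeric(per_signal(8))
  dig_max <- as.numeric(per_signal(8))
  per_signal(80)                         # prefiltering
  samples_per_record <- as.integer(per_signal(8))
  per_signal(32)                         # reserved

  if (is.character(channel) && !channel %in% labels &&
      is.na(suppressWarnings(as.integer(channel)))) {
    abort(sprintf("Channel '%s' not found (labels: %s).", channel,
                  paste(labels, collapse = ", ")))
  }
  ch <- if (is.character(channel) && channel %in% labels) {
    match(channel, labels)
  } else {
    as.integer(channel)
  }
  if (is.na(ch) || ch < 1 || ch > ns) abort("Invalid channel index.")

  seek(con, header_bytes)
  out <- vector("list", n_records)
  for (rec in seq_len(n_records)) {
    for (sig in seq_len(ns)) {
      vals <- readBin(con, "integer", n = samples_per_record[sig],
                      size = 2, signed = TRUE, endian = "little")
      if (sig == ch) out[[rec]] <- vals
    }
  }
  digital <- unlist(out)
  gain <- (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
  physical <- phys_min[ch] + (digital - dig_min[ch]) * gain
  eeg_trace(physical, fs = samples_per_record[ch] / record_duration)
}
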