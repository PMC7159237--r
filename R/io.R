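# EDF/BDF: fixed-layout ASCII header (256 bytes + 256 per signal) followed
# by data records of little-endian integers (EDF: 16-bit, BDF: 24-bit).
# Events are carried in a Biosemi-style "Status" channel: the event code
# index at the event sample, 0 elsewhere.

pad_field <- function(x, width) {
  x <- substr(format(x, width = width), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to disk
#'
#' Formats: `"rds"` (the internal container, lossless), `"edf"` (16-bit)
#' or `"bdf"` (Biosemi 24-bit). EDF/BDF quantize each channel to its
#' per-channel physical range; events are encoded in an appended Status
#' channel and recovered by [read_recording()].
#'
#' @param rec An `fpvs_recording`.
#' @param path Output path.
#' @param format `"rds"`, `"edf"` or `"bdf"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("rds", "edf", "bdf")) {
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(rec, path)
    return(invisible(path))
  }
  n_bytes <- if (format == "bdf") 3L else 2L
  dig_max <- if (format == "bdf") 8388607 else 32767
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF/BDF export needs an integer fs")
  fs <- as.integer(round(fs))

  has_events <- nrow(rec$events) > 0
  codes <- unique(rec$events$code)
  data <- rec$data
  labels <- rec$labels
  if (has_events) {
    status <- numeric(ncol(data))
    status[rec$events$sample] <- match(rec$events$code, codes)
    data <- rbind(data, status)
    labels <- c(labels, "Status")
  }
  ns <- nrow(data)

  # pad to whole 1-s records
  n_rec <- ceiling(ncol(data) / fs)
  if (ncol(data) < n_rec * fs)
    data <- cbind(data, matrix(0, ns, n_rec * fs - ncol(data)))

  phys_min <- apply(data, 1, min)
  phys_max <- apply(data, 1, max)
  flat <- phys_max - phys_min < 1e-12
  phys_max[flat] <- phys_min[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))

  magic <- if (format == "bdf") c(as.raw(255), charToRaw(pad_field("BIOSEMI", 7)))
           else charToRaw(pad_field("0", 8))
  writeBin(magic, con)
  writeChar(pad_field("fpvstag export", 80), con, eos = NULL)
  writeChar(pad_field("", 80), con, eos = NULL)
  writeChar(pad_field("01.01.26", 8), con, eos = NULL)
  writeChar(pad_field("00.00.00", 8), con, eos = NULL)
  writeChar(pad_field(256 * (ns + 1L), 8), con, eos = NULL)
  writeChar(pad_field(if (format == "bdf") "24BIT" else "", 44), con, eos = NULL)
  writeChar(pad_field(n_rec, 8), con, eos = NULL)
  writeChar(pad_field("1", 8), con, eos = NULL)         # record duration (s)
  writeChar(pad_field(ns, 4), con, eos = NULL)
  for (l in labels) writeChar(pad_field(l, 16), con, eos = NULL)
  for (i in seq_len(ns)) writeChar(pad_field("", 80), con, eos = NULL)  # transducer
  for (i in seq_len(ns)) writeChar(pad_field("uV", 8), con, eos = NULL)
  for (v in phys_min) writeChar(pad_field(sprintf("%.6g", v), 8), con, eos = NULL)
  for (v in phys_max) writeChar(pad_field(sprintf("%.6g", v), 8), con, eos = NULL)
  for (i in seq_len(ns)) writeChar(pad_field(-dig_max - 1, 8), con, eos = NULL)
  for (i in seq_len(ns)) writeChar(pad_field(dig_max, 8), con, eos = NULL)
  for (i in seq_len(ns)) writeChar(pad_field("", 80), con, eos = NULL)  # prefilter
  for (i in seq_len(ns)) writeChar(pad_field(fs, 8), con, eos = NULL)
  for (i in seq_len(ns)) writeChar(pad_field("", 32), con, eos = NULL)  # reserved

  scale <- (phys_max - phys_min) / (2 * dig_max + 1)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (s in seq_len(ns)) {
      dig <- round((data[s, idx] - phys_min[s]) / scale[s]) - dig_max - 1
      dig <- pmin(pmax(dig, -dig_max - 1), dig_max)
      if (n_bytes == 2L) {
        writeBin(as.integer(dig), con, size = 2, endian = "little")
      } else {
        u <- as.integer(dig)
        u[u < 0] <- u[u < 0] + 16777216L
        bytes <- rbind(u %% 256L, (u %/% 256L) %% 256L, u %/% 65536L)
        writeBin(as.raw(bytes), con)
      }
    }
  }
  invisible(path)
}

read_ascii <- function(con, n) {
  trimws(readChar(con, n, useBytes = TRUE))
}

#' Read a recording from disk
#'
#' @param path File path.
#' @param format `"rds"`, `"edf"` or `"bdf"`; guessed from the extension
#'   when omitted.
#' @return An `fpvs_recording` (data in muV). A Status channel written by
#'   [write_recording()] is converted back to events.
#' @export
read_recording <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("rds", "edf", "bdf"))
      stop("cannot guess format from extension: ", path)
  }
  if (format == "rds") {
    rec <- readRDS(path)
    if (!inherits(rec, "fpvs_recording")) stop("not an fpvs_recording: ", path)
    return(rec)
  }
  n_bytes <- if (format == "bdf") 3L else 2L
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8)
  if (format == "bdf" &&
      !(magic[1] == as.raw(255) && rawToChar(magic[2:8]) == "BIOSEMI"))
    stop("malformed BDF header at byte offset 0: bad magic")
  readChar(con, 160, useBytes = TRUE)  # patient + recording id
  readChar(con, 16, useBytes = TRUE)   # date + time
  header_bytes <- as.integer(read_ascii(con, 8))
  read_ascii(con, 44)
  n_rec <- as.integer(read_ascii(con, 8))
  rec_dur <- as.numeric(read_ascii(con, 8))
  ns <- as.integer(read_ascii(con, 4))
  if (is.na(ns) || ns < 1) stop("malformed header at byte offset 252: bad signal count")
  labels <- vapply(seq_len(ns), function(i) read_ascii(con, 16), character(1))
  for (i in seq_len(ns)) readChar(con, 80, useBytes = TRUE)
  units <- vapply(seq_len(ns), function(i) read_ascii(con, 8), character(1))
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) read_ascii(con, 8), character(1)))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) read_ascii(con, 8), character(1)))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) read_ascii(con, 8), character(1)))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) read_ascii(con, 8), character(1)))
  for (i in seq_len(ns)) readChar(con, 80, useBytes = TRUE)
  nsamp <- as.integer(vapply(seq_len(ns), function(i) read_ascii(con, 8), character(1)))
  for (i in seq_len(ns)) readChar(con, 32, useBytes = TRUE)

  bad_units <- !(tolower(units) %in% c("uv", "µv", ""))
  if (any(bad_units))
    stop("unit mismatch: expected uV, got ", paste(unique(units[bad_units]), collapse = ", "))
  expected <- header_bytes + n_rec * sum(nsamp) * n_bytes
  if (sz < expected)
    stop(sprintf("truncated file: %d bytes, expected %d", sz, expected))
  if (length(unique(nsamp)) != 1)
    stop("mixed per-signal sampling rates are not supported")
  fs <- nsamp[1] / rec_dur

  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- matrix(0, ns, n_rec * nsamp[1])
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * nsamp[1] + 1L):(r * nsamp[1])
    for (s in seq_len(ns)) {
      if (n_bytes == 2L) {
        dig <- readBin(con, "integer", nsamp[s], size = 2, signed = TRUE,
                       endian = "little")
      } else {
        raw3 <- readBin(con, "raw", nsamp[s] * 3L)
        m <- matrix(as.integer(raw3), nrow = 3)
        dig <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
        dig[dig >= 8388608] <- dig[dig >= 8388608] - 16777216
      }
      data[s, idx] <- (dig - dig_min[s]) * scale[s] + phys_min[s]
    }
  }
  status <- which(labels == "Status")
  events <- data.frame(sample = integer(0), code = character(0))
  if (length(status) == 1L) {
    codes <- round(data[status, ])
    at <- which(codes > 0.5)
    events <- data.frame(sample = at, code = sprintf("EV%d", codes[at]),
                         stringsAsFactors = FALSE)
    data <- data[-status, , drop = FALSE]
    labels <- labels[-status]
  }
  recording(data, fs, labels, events)
}

#' Export a spectrum (or baseline-corrected values) as a delimited table
#'
#' Columns: bin index, frequency (Hz), then one column per channel (muV).
#'
#' @param spec An `fpvs_spectrum` or `fpvs_bc`.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_spectrum_table <- function(spec, path) {
  vals <- if (inherits(spec, "fpvs_bc")) spec$values else spec$amps
  df <- data.frame(bin = seq_len(ncol(vals)) - 1L,
                   freq_hz = (seq_len(ncol(vals)) - 1L) * spec$df)
  df <- cbind(df, as.data.frame(t(vals)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
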