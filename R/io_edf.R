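# Minimal EDF (European Data Format) writer/reader: 16-bit samples, one 1-s
# data record per second, physical dimension microvolts. Covers exactly what
# the pipeline exchanges; not a general-purpose EDF implementation.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too long: ", x, call. = FALSE)
  formatC(x, width = -width)
}

edf_num <- function(x, width = 8) {
  s <- formatC(signif(x, 6), format = "g", width = -1)
  if (nchar(s) > width) s <- formatC(x, digits = 4, format = "g")
  edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' 16-bit EDF with one 1-s data record per second and per-channel symmetric
#' physical scaling; the recording length must be a whole number of seconds.
#' Round-tripping through [read_edf()] preserves the data to within the
#' 16-bit quantization step (physical range / 65535 per channel).
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF export needs an integer sampling rate", call. = FALSE)
  n <- n_samples(rec)
  n_rec <- n %/% fs
  if (n_rec * fs != n) stop("recording must be a whole number of seconds", call. = FALSE)
  ns <- nrow(rec$data)

  phys_max <- apply(rec$data, 1, function(x) max(abs(x), 1))
  phys_max <- phys_max * 1.0001  # keep extremes strictly inside the range
  # quantize against the value as printed in the header, not the full double
  phys_max <- vapply(phys_max, function(p) as.numeric(edf_num(p)), 0)
  dig_min <- -32768; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad("1", 8), edf_pad(ns, 4),
    paste(vapply(rec$labels, edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(vapply(-phys_max, edf_num, ""), collapse = ""),
    paste(vapply(phys_max, edf_num, ""), collapse = ""),
    paste(rep(edf_pad(dig_min, 8), ns), collapse = ""),
    paste(rep(edf_pad(dig_max, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(fs, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = ""))
  writeChar(hdr, con, eos = NULL)

  # digital conversion per channel, then interleave records
  scale <- (dig_max - dig_min) / (2 * phys_max)
  dig <- round((rec$data + phys_max) * scale) + dig_min
  dig <- pmin(pmax(dig, dig_min), dig_max)
  block <- matrix(0L, nrow = fs * ns, ncol = n_rec)
  for (ch in seq_len(ns)) {
    block[((ch - 1) * fs + 1):(ch * fs), ] <- matrix(as.integer(dig[ch, ]),
                                                     nrow = fs)
  }
  writeBin(as.integer(block), con, size = 2, endian = "little")
  invisible(path)
}

#' Read an EDF file
#'
#' Reads a 16-bit EDF file written by [write_edf()] (or any EDF with a
#' constant number of samples per record per channel) and returns the
#' physically scaled channels in microvolts.
#'
#' @param path EDF file path.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(k) trimws(readChar(con, k, useBytes = TRUE))
  ver <- rd(8)
  if (!identical(ver, "0")) stop("not an EDF file: ", path, call. = FALSE)
  rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)  # transducer
  for (i in seq_len(ns)) rd(8)   # dimension
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)  # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)

  total <- sum(spr) * n_rec
  raw <- readBin(con, "integer", n = total, size = 2, signed = TRUE,
                 endian = "little")
  block <- matrix(raw, nrow = sum(spr), ncol = n_rec)
  data <- matrix(NA_real_, nrow = ns, ncol = 0)
  offsets <- cumsum(c(0, spr))
  data <- do.call(rbind, lapply(seq_len(ns), function(ch) {
    d <- as.numeric(block[(offsets[ch] + 1):offsets[ch + 1], ])
    (d - dig_min[ch]) * (phys_max[ch] - phys_min[ch]) /
      (dig_max[ch] - dig_min[ch]) + phys_min[ch]
  }))
  fs <- spr[1] / rec_dur
  eeg_recording(data, fs = fs, labels = labels)
}

#' Read a BrainVision recording (read-only dialect)
#'
#' Minimal reader for the BrainVision core format: an INI-style `.vhdr`
#' header naming a multiplexed binary `.eeg` data file in `INT_16` (with
#' per-channel resolution) or `IEEE_FLOAT_32` format. Only multiplexed
#' orientation is supported.
#'
#' @param vhdr_path Path to the `.vhdr` header file.
#' @return An [eeg_recording()] in microvolts.
#' @export
read_brainvision <- function(vhdr_path) {
  if (!file.exists(vhdr_path)) stop("no such file: ", vhdr_path, call. = FALSE)
  lines <- readLines(vhdr_path, warn = FALSE)
  kv <- function(key) {
    hit <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (length(hit) == 0) stop("BrainVision header lacks ", key, call. = FALSE)
    sub(paste0("^", key, "="), "", hit[1])
  }
  data_file <- file.path(dirname(vhdr_path), kv("DataFile"))
  orientation <- toupper(kv("Orientation"))
  if (orientation != "MULTIPLEXED") {
    stop("only MULTIPLEXED BrainVision data is supported", call. = FALSE)
  }
  ns <- as.integer(kv("NumberOfChannels"))
  fs <- 1e6 / as.numeric(kv("SamplingInterval"))
  fmt <- toupper(kv("BinaryFormat"))
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  if (length(ch_lines) < ns) stop("incomplete channel table", call. = FALSE)
  parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines[seq_len(ns)]), ",")
  labels <- vapply(parts, `[`, "", 1)
  resolution <- vapply(parts, function(p) {
    r <- suppressWarnings(as.numeric(p[3]))
    if (is.na(r)) 1 else r
  }, 0)

  n_bytes <- file.info(data_file)$size
  if (fmt == "INT_16") {
    raw <- readBin(data_file, "integer", n = n_bytes / 2, size = 2,
                   signed = TRUE, endian = "little")
    m <- matrix(as.numeric(raw), nrow = ns)
    m <- m * resolution
  } else if (fmt == "IEEE_FLOAT_32") {
    raw <- readBin(data_file, "numeric", n = n_bytes / 4, size = 4,
                   endian = "little")
    m <- matrix(raw, nrow = ns)
  } else {
    stop("unsupported BinaryFormat: ", fmt, call. = FALSE)
  }
  eeg_recording(m, fs = fs, labels = labels)
}

#' Read a recording from disk
#'
#' Dispatches on the file extension: `.edf` via [read_edf()], `.vhdr` via
#' [read_brainvision()]. Verifies that the required channels are present.
#'
#' @param path File path (`.edf` or `.vhdr`).
#' @param require_channels Channel labels that must be present (default
#'   Cz and CPz).
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, require_channels = c("Cz", "CPz")) {
  ext <- tolower(tools::file_ext(path))
  rec <- switch(ext,
                edf = read_edf(path),
                vhdr = read_brainvision(path),
                stop("unsupported recording format: .", ext, call. = FALSE))
  missing <- setdiff(require_channels, rec$labels)
  if (length(missing) > 0) {
    stop(sprintf("%s: required channel(s) missing: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  rec
}
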