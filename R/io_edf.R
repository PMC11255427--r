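# Minimal EDF (European Data Format) reader/writer.
#
# EDF stores a fixed-layout ASCII header (256 bytes + 256 per signal)
# followed by data records of little-endian 16-bit integers, scaled
# per channel between a physical and a digital range. The writer uses
# 1 s data records (so the sampling rate must be a whole number of Hz
# and the record an integer number of seconds) and a symmetric
# physical range auto-scaled per channel, which bounds the round-trip
# error by physical_range / 2^16 per sample.
#
# The recording-start Zeitgeber hour is carried in the EDF "recording
# identification" free-text field as "startzt=<hours>".

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7, width = -1)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

#' Write a signal record to an EDF file
#'
#' @param record a [signal_record()].
#' @param path output file path.
#' @details The sampling rate must be an integer number of Hz and the
#'   record an integer number of seconds (EDF data records of 1 s are
#'   used). Samples must be finite. Physical ranges are auto-scaled per
#'   channel, so `read_signal_record(write_signal_record(x))` reproduces
#'   the samples within 16-bit quantization of each channel's range.
#' @return `path`, invisibly.
#' @export
write_signal_record <- function(record, path) {
  stopifnot(inherits(record, "signal_record"))
  x <- record$samples
  if (anyNA(x) || any(!is.finite(x)))
    stop("write_signal_record: non-finite samples")
  fs <- record$fs
  if (fs != round(fs))
    stop("write_signal_record: EDF writer requires an integer sampling rate")
  n <- nrow(x)
  if (n %% fs != 0)
    stop("write_signal_record: record length must be a whole number of seconds")
  nrec <- n / fs
  ns <- ncol(x)

  amp <- apply(abs(x), 2, max)
  amp[amp == 0] <- 1
  dig <- matrix(0L, n, ns)
  for (j in seq_len(ns))
    dig[, j] <- as.integer(round(x[, j] / amp[j] * 32767))

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchar(s), eos = NULL)
  wr(edf_pad("0", 8))
  wr(edf_pad("psgpharm", 80))
  wr(edf_pad(sprintf("startzt=%.6f", record$start_zt), 80))
  wr(edf_pad("01.01.00", 8))
  wr(edf_pad("00.00.00", 8))
  wr(edf_num(256L * (ns + 1L), 8))
  wr(edf_pad("", 44))
  wr(edf_num(nrec, 8))
  wr(edf_num(1, 8))
  wr(edf_num(ns, 4))
  wr(paste(vapply(record$labels, edf_pad, "", width = 16), collapse = ""))
  wr(paste(rep(edf_pad("", 80), ns), collapse = ""))
  wr(paste(vapply(record$units, edf_pad, "", width = 8), collapse = ""))
  wr(paste(vapply(-amp, edf_num, "", width = 8), collapse = ""))
  wr(paste(vapply(amp, edf_num, "", width = 8), collapse = ""))
  wr(paste(rep(edf_num(-32767L, 8), ns), collapse = ""))
  wr(paste(rep(edf_num(32767L, 8), ns), collapse = ""))
  wr(paste(rep(edf_pad("", 80), ns), collapse = ""))
  wr(paste(rep(edf_num(as.integer(fs), 8), ns), collapse = ""))
  wr(paste(rep(edf_pad("", 32), ns), collapse = ""))

  # data records: per record, each signal's fs samples consecutively
  # (column-major flattening of the record's rows gives exactly that order)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.vector(dig[idx, , drop = FALSE]), con,
             size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf_header <- function(con) {
  rd <- function(nc) readChar(con, nc, useBytes = TRUE)
  num <- function(nc) as.numeric(trimws(rd(nc)))
  version <- trimws(rd(8))
  patient <- trimws(rd(80))
  recording <- trimws(rd(80))
  rd(8); rd(8)                       # start date / time, unused
  num(8)                             # header bytes
  rd(44)
  nrec <- num(8)
  rec_dur <- num(8)
  ns <- as.integer(num(4))
  fld <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  labels <- fld(16)
  fld(80)
  units <- fld(8)
  pmin <- as.numeric(fld(8))
  pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8))
  dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  fld(32)
  list(version = version, recording = recording, nrec = nrec,
       rec_dur = rec_dur, ns = ns, labels = labels, units = units,
       pmin = pmin, pmax = pmax, dmin = dmin, dmax = dmax, spr = spr)
}

#' Read an EDF file into a signal record
#'
#' @param path an EDF/EDF+ file.
#' @param channel_roles named character vector or list mapping channel
#'   labels present in the file to roles (`"EEG"`, `"EMG"`, `"OTHER"`).
#'   Channels not listed are given role `OTHER`.
#' @return A validated [signal_record()].
#' @export
read_signal_record <- function(path, channel_roles = NULL) {
  if (!file.exists(path))
    stop("read_signal_record: file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  if (any(h$spr <= 0)) stop("read_signal_record: zero-length channel")
  if (length(unique(h$spr / h$rec_dur)) != 1L)
    stop("read_signal_record: mismatched channel sampling rates")
  fs <- h$spr[1] / h$rec_dur
  n <- h$nrec * h$spr[1]
  samples <- matrix(0, n, h$ns)
  for (r in seq_len(h$nrec)) {
    for (j in seq_len(h$ns)) {
      d <- readBin(con, "integer", n = h$spr[j], size = 2L, signed = TRUE,
                   endian = "little")
      if (length(d) != h$spr[j])
        stop("read_signal_record: truncated data record ", r)
      # digital -> physical, per-channel linear map
      gain <- (h$pmax[j] - h$pmin[j]) / (h$dmax[j] - h$dmin[j])
      samples[((r - 1L) * h$spr[j] + 1L):(r * h$spr[j]), j] <-
        h$pmin[j] + (d - h$dmin[j]) * gain
    }
  }
  roles <- rep("OTHER", h$ns)
  if (!is.null(channel_roles)) {
    channel_roles <- unlist(channel_roles)
    unknown <- setdiff(names(channel_roles), h$labels)
    if (length(unknown))
      stop("read_signal_record: unknown channel label(s) in channel_roles: ",
           paste(unknown, collapse = ", "))
    roles[match(names(channel_roles), h$labels)] <- toupper(channel_roles)
  }
  start_zt <- 0
  m <- regmatches(h$recording,
                  regexec("startzt=([0-9.]+)", h$recording))[[1]]
  if (length(m) == 2L) start_zt <- as.numeric(m[2])
  signal_record(samples, h$labels, roles, fs, start_zt = start_zt,
                units = h$units)
}
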