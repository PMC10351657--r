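# Minimal EDF (European Data Format) reader/writer: fixed 256-byte ASCII
# header + 256 bytes per signal, then 1-s data records of 16-bit
# little-endian integers. Covers uniform-rate continuous recordings, which
# is all this package produces; EDF+ annotation streams are out of scope.

pad_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

num_field <- function(x, width) {
  s <- formatC(x, format = "g", digits = 6)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = width - 2)
  pad_field(s, width)
}

#' Write a recording to an EDF file
#'
#' Signals are scaled per channel to the 16-bit digital range with a
#' symmetric physical range, so the round-trip error is bounded by one
#' quantization step (`max|x| / 32767`). The sampling rate must be a whole
#' number (one data record per second); samples beyond the last whole second
#' are dropped with a warning.
#'
#' @param recording an [ieeg_recording()].
#' @param path output file path.
#' @param patient_id,recording_id free-text header fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, patient_id = "X",
                      recording_id = "synthetic") {
  stopifnot(inherits(recording, "ieeg_recording"))
  fs <- recording$fs_hz
  if (abs(fs - round(fs)) > 1e-9)
    stopf("EDF writer requires an integer sampling rate, got %g", fs)
  fs <- as.integer(round(fs))
  nch <- nrow(recording$samples)
  ntime <- ncol(recording$samples)
  nrec <- ntime %/% fs
  if (nrec < 1) stopf("recording shorter than one 1-s EDF record")
  if (nrec * fs < ntime)
    warning(sprintf("dropping %d trailing samples beyond the last whole second",
                    ntime - nrec * fs))
  pm <- apply(abs(recording$samples), 1, max)
  pm[pm == 0] <- 1
  pm <- signif(pm, 6)                      # header stores ~6 digits
  dig <- matrix(0L, nrow = nch, ncol = nrec * fs)
  for (i in seq_len(nch)) {
    d <- round(recording$samples[i, seq_len(nrec * fs)] / pm[i] * 32767)
    dig[i, ] <- as.integer(pmax(pmin(d, 32767), -32767))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field(patient_id, 80), pad_field(recording_id, 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + nch), 8), pad_field("", 44),
    pad_field(nrec, 8), pad_field("1", 8), pad_field(nch, 4),
    paste(vapply(recording$channel_labels, pad_field, "", width = 16), collapse = ""),
    paste(rep(pad_field("", 80), nch), collapse = ""),          # transducer
    paste(rep(pad_field("uV", 8), nch), collapse = ""),
    paste(vapply(-pm, num_field, "", width = 8), collapse = ""),  # phys min
    paste(vapply(pm, num_field, "", width = 8), collapse = ""),   # phys max
    paste(rep(pad_field("-32767", 8), nch), collapse = ""),
    paste(rep(pad_field("32767", 8), nch), collapse = ""),
    paste(rep(pad_field("", 80), nch), collapse = ""),          # prefilter
    paste(rep(pad_field(fs, 8), nch), collapse = ""),
    paste(rep(pad_field("", 32), nch), collapse = ""))
  writeChar(hdr, con, eos = NULL)
  # data records: per record, per channel, fs samples
  arr <- array(dig, dim = c(nch, fs, nrec))
  writeBin(as.integer(aperm(arr, c(2, 1, 3))), con, size = 2,
           endian = "little")
  invisible(path)
}

read_fields <- function(con, width, n = 1) {
  vapply(seq_len(n), function(i) trimws(readChar(con, width, useBytes = TRUE)), "")
}

#' Read an EDF file into a recording
#'
#' @param path EDF file path.
#' @return an [ieeg_recording()] with samples in physical units.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_fields(con, 8)
  if (version != "0") stopf("not an EDF file (version field '%s')", version)
  invisible(read_fields(con, 80, 2))       # patient, recording ids
  invisible(read_fields(con, 8, 2))        # date, time
  header_bytes <- as.integer(read_fields(con, 8))
  invisible(read_fields(con, 44))
  nrec <- as.integer(read_fields(con, 8))
  rec_dur <- as.numeric(read_fields(con, 8))
  nch <- as.integer(read_fields(con, 4))
  if (is.na(nch) || nch < 1 || is.na(nrec) || nrec < 1)
    stopf("malformed EDF header")
  labels <- read_fields(con, 16, nch)
  invisible(read_fields(con, 80, nch))
  invisible(read_fields(con, 8, nch))      # phys dim
  phys_min <- as.numeric(read_fields(con, 8, nch))
  phys_max <- as.numeric(read_fields(con, 8, nch))
  dig_min <- as.numeric(read_fields(con, 8, nch))
  dig_max <- as.numeric(read_fields(con, 8, nch))
  invisible(read_fields(con, 80, nch))
  spr <- as.integer(read_fields(con, 8, nch))
  if (length(unique(spr)) != 1)
    stopf("mixed per-channel sampling rates are not supported")
  seek(con, header_bytes)
  raw <- readBin(con, "integer", n = nrec * sum(spr), size = 2,
                 endian = "little", signed = TRUE)
  if (length(raw) < nrec * sum(spr)) stopf("truncated EDF data section")
  arr <- array(raw, dim = c(spr[1], nch, nrec))
  samples <- matrix(0, nrow = nch, ncol = nrec * spr[1])
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (i in seq_len(nch)) {
    d <- as.numeric(arr[, i, ])
    samples[i, ] <- (d - dig_min[i]) * scale[i] + phys_min[i]
  }
  ieeg_recording(samples, spr[1] / rec_dur, labels)
}
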