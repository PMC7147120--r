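# Minimal European Data Format (EDF) codec for multichannel EEG.
#
# EDF stores 16-bit integers scaled between per-channel physical and digital
# ranges, in fixed-width ASCII-headed data records. This writer uses 1-s
# records (so fs must be an integer), a symmetric physical range per channel
# and digital range -32767..32767, and pads the final partial record with
# zeros; the true sample count is kept in the 44-byte reserved header field
# (`NSAMP=<n>`) so a round trip restores the exact length.

edf_field <- function(x, width) {
  s <- format(x)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  formatC(s, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' @param rec a [multichannel_recording()]; `fs` must be a whole number.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_eeg()]
#' @export
write_eeg <- function(rec, path) {
  validate_recording(rec)
  if (rec$fs != round(rec$fs))
    stop("format error: EDF writer requires an integer sampling rate")
  nchan <- nrow(rec$data)
  n <- ncol(rec$data)
  spr <- as.integer(rec$fs)              # samples per 1-s record
  nrec <- as.integer(ceiling(n / spr))

  pmax <- apply(abs(rec$data), 1L, max)
  pmax[pmax == 0] <- 1
  dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8L),
    edf_field(rec$subject_id, 80L),
    edf_field(sprintf("cond=%s ord=%d", rec$condition,
                      rec$presentation_order), 80L),
    edf_field("01.01.20", 8L), edf_field("00.00.00", 8L),
    edf_field(256L * (nchan + 1L), 8L),
    edf_field(sprintf("NSAMP=%d", n), 44L),
    edf_field(nrec, 8L), edf_field(1L, 8L), edf_field(nchan, 4L))
  writeChar(hdr, con, eos = NULL)
  per_sig <- function(vals, width)
    writeChar(paste0(vapply(vals, edf_field, "", width = width),
                     collapse = ""), con, eos = NULL)
  per_sig(rec$channel_labels, 16L)
  per_sig(rep("", nchan), 80L)
  per_sig(rep("uV", nchan), 8L)
  per_sig(sprintf("%.6g", -pmax), 8L)
  per_sig(sprintf("%.6g", pmax), 8L)
  per_sig(rep(-dmax, nchan), 8L)
  per_sig(rep(dmax, nchan), 8L)
  per_sig(rep("", nchan), 80L)
  per_sig(rep(spr, nchan), 8L)
  per_sig(rep("", nchan), 32L)

  # header strings round-trip at 6 significant digits; quantize against the
  # values a reader will parse
  pmax_r <- as.numeric(sprintf("%.6g", pmax))
  padded <- matrix(0, nchan, nrec * spr)
  padded[, seq_len(n)] <- rec$data
  dig <- round(sweep(padded, 1L, dmax / pmax_r, `*`))
  dig[dig > dmax] <- dmax
  dig[dig < -dmax] <- -dmax
  # records: for each record, channels in turn, spr samples each
  idx <- seq_len(spr)
  for (r in seq_len(nrec)) {
    block <- t(dig[, (r - 1L) * spr + idx, drop = FALSE])
    writeBin(as.integer(block), con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256)
    stop("format error: not an EDF file (header truncated): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  ver <- rd(8L)
  subject_id <- rd(80L)
  recinfo <- rd(80L)
  rd(8L); rd(8L); rd(8L)
  reserved <- rd(44L)
  nrec <- as.integer(rd(8L))
  dur <- as.numeric(rd(8L))
  nchan <- as.integer(rd(4L))
  if (is.na(nchan) || nchan < 1L || is.na(nrec) || is.na(dur))
    stop("format error: malformed EDF header: ", path)
  rds <- function(width) vapply(seq_len(nchan), function(i) rd(width), "")
  labels <- rds(16L); rds(80L); rds(8L)
  pmin <- as.numeric(rds(8L)); pmax <- as.numeric(rds(8L))
  dmin <- as.numeric(rds(8L)); dmax <- as.numeric(rds(8L))
  rds(80L)
  spr <- as.integer(rds(8L))
  rds(32L)
  if (length(unique(spr)) != 1L)
    stop("validation error: channels disagree on samples per record")
  fs <- spr[1L] / dur

  total <- nrec * spr[1L]
  data <- matrix(0, nchan, total)
  raw <- readBin(con, "integer", n = nrec * nchan * spr[1L], size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) != nrec * nchan * spr[1L])
    stop("validation error: EDF data shorter than header promises: ", path)
  # raw layout: record-major, channel-major within record
  arr <- array(raw, dim = c(spr[1L], nchan, nrec))
  for (j in seq_len(nchan))
    data[j, ] <- as.numeric(arr[, j, ])
  scale <- (pmax - pmin) / (dmax - dmin)
  data <- sweep(sweep(data, 1L, dmin, `-`), 1L, scale, `*`) + pmin

  nsamp <- if (grepl("^NSAMP=\\d+$", reserved))
    as.integer(sub("^NSAMP=", "", reserved)) else total
  data <- data[, seq_len(min(nsamp, total)), drop = FALSE]

  cond <- if (grepl("cond=unaided", recinfo)) "unaided" else "aided"
  ord <- if (grepl("ord=2", recinfo)) 2L else 1L
  multichannel_recording(data, fs, labels, subject_id, cond, ord)
}
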