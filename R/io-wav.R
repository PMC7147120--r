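# Minimal RIFF/WAVE codec, PCM 16-bit only. Samples are exchanged as
# doubles in [-1, 1] and scaled by 32767, so the round-trip quantization
# error is bounded by 0.5/32767.

#' Read a WAV audio file
#'
#' Reads a PCM 16-bit WAV file. Stereo input is averaged to mono (the
#' stimulus is single-speaker, presented from one loudspeaker). Segment
#' boundaries default to one whole-file segment.
#'
#' @param path path to a WAV file.
#' @return An [audio_stimulus()].
#' @export
read_audio <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 44)
    stop("format error: not a WAV file (too short): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  readBin(con, "integer", 1L, size = 4L, endian = "little")
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    stop("format error: not a RIFF/WAVE file: ", path)
  fs <- NULL; nch <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    len <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2L, size = 2L, endian = "little")
      if (fmt[1L] != 1L)
        stop("format error: only PCM WAV is supported")
      nch <- fmt[2L]
      fs <- readBin(con, "integer", 1L, size = 4L, endian = "little")
      readBin(con, "integer", 1L, size = 4L, endian = "little")
      readBin(con, "integer", 1L, size = 2L, endian = "little")
      bits <- readBin(con, "integer", 1L, size = 2L, endian = "little")
      if (len > 16L) readBin(con, "raw", len - 16L)
    } else if (id == "data") {
      if (is.null(bits))
        stop("format error: WAV data chunk precedes fmt chunk")
      if (bits != 16L)
        stop("format error: only 16-bit PCM is supported (got ", bits, ")")
      samples <- readBin(con, "integer", n = len %/% 2L, size = 2L,
                         signed = TRUE, endian = "little")
      break
    } else {
      readBin(con, "raw", len + len %% 2L)
    }
  }
  if (is.null(fs) || is.null(samples))
    stop("format error: WAV fmt or data chunk missing: ", path)
  x <- samples / 32767
  if (nch > 1L) {
    m <- matrix(x, nrow = nch)
    x <- colMeans(m)
  }
  audio_stimulus(x, fs)
}

#' Write a waveform to a PCM 16-bit WAV file
#'
#' @param audio an [audio_stimulus()] or numeric vector in `[-1, 1]`
#'   (values outside are clipped with a warning).
#' @param path output path.
#' @param fs sampling rate, required when `audio` is a bare vector.
#' @return `path`, invisibly.
#' @export
write_audio <- function(audio, path, fs = NULL) {
  if (inherits(audio, "audio_stimulus")) {
    x <- audio$waveform
    fs <- audio$fs
  } else {
    x <- as.numeric(audio)
    if (is.null(fs)) stop("fs required when writing a bare vector")
  }
  if (length(x) && max(abs(x)) > 1) {
    warning("waveform clipped to [-1, 1] for 16-bit PCM")
    x <- pmin(1, pmax(-1, x))
  }
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_len <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_len, con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(c(1L, 1L), con, size = 2L, endian = "little")   # PCM, mono
  writeBin(as.integer(fs), con, size = 4L, endian = "little")
  writeBin(as.integer(fs) * 2L, con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")
  writeBin(16L, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_len, con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}
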