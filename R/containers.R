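#' Multichannel EEG recording
#'
#' Container for a scalp EEG recording: a channels x samples matrix of
#' microvolt values with a single sampling rate, ordered channel labels
#' (10-20 montage), and session metadata.
#'
#' @param data numeric matrix, channels x samples.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_labels character vector, one label per channel.
#' @param subject_id subject identifier string.
#' @param condition listening condition, `"aided"` or `"unaided"`.
#' @param presentation_order integer rank of the condition within the
#'   session (1 = heard first, 2 = heard second).
#'
#' @return An object of class `multichannel_recording`.
#' @export
multichannel_recording <- function(data, fs, channel_labels = NULL,
                                   subject_id = "S00",
                                   condition = c("aided", "unaided"),
                                   presentation_order = 1L) {
  if (!is.matrix(data)) data <- matrix(data, nrow = 1L)
  storage.mode(data) <- "double"
  condition <- match.arg(condition)
  if (is.null(channel_labels))
    channel_labels <- paste0("Ch", seq_len(nrow(data)))
  rec <- structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         subject_id = subject_id, condition = condition,
         presentation_order = as.integer(presentation_order)),
    class = "multichannel_recording")
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  stopifnot(is.matrix(rec$data))
  if (!is.numeric(rec$fs) || length(rec$fs) != 1L || rec$fs <= 0)
    stop("validation error: fs must be a positive scalar")
  if (nrow(rec$data) < 2L)
    stop("validation error: a recording needs at least 2 channels")
  if (length(rec$channel_labels) != nrow(rec$data))
    stop("validation error: channel count (", nrow(rec$data),
         ") disagrees with channel_labels length (",
         length(rec$channel_labels), ")")
  if (anyNA(rec$data))
    stop("validation error: recording contains missing samples")
  if (!rec$presentation_order %in% c(1L, 2L))
    stop("validation error: presentation_order must be 1 or 2")
  invisible(rec)
}

#' @export
print.multichannel_recording <- function(x, ...) {
  cat(sprintf(
    "<multichannel_recording> %s/%s: %d channels x %d samples @ %g Hz (%.1f s)\n",
    x$subject_id, x$condition, nrow(x$data), ncol(x$data), x$fs,
    ncol(x$data) / x$fs))
  invisible(x)
}

#' Audio stimulus waveform
#'
#' A mono waveform with its sampling rate and an ordered set of contiguous
#' segment boundaries (0-based sample indices, half-open intervals) that
#' tile the waveform; by default the whole file is one segment.
#'
#' @param waveform numeric vector of samples (arbitrary amplitude units).
#' @param fs sampling rate in Hz.
#' @param segment_starts 0-based start indices of the segments; the first
#'   must be 0 and starts must be strictly increasing.
#'
#' @return An object of class `audio_stimulus`.
#' @export
audio_stimulus <- function(waveform, fs, segment_starts = 0L) {
  waveform <- as.numeric(waveform)
  if (!is.numeric(fs) || fs <= 0) stop("validation error: fs must be > 0")
  segment_starts <- as.integer(segment_starts)
  if (length(segment_starts) == 0L || segment_starts[1L] != 0L ||
      is.unsorted(segment_starts, strictly = TRUE) ||
      any(segment_starts >= max(length(waveform), 1L)))
    stop("validation error: segment starts must begin at 0, increase, ",
         "and lie inside the waveform")
  structure(list(waveform = waveform, fs = fs,
                 segment_starts = segment_starts),
            class = "audio_stimulus")
}

#' @export
print.audio_stimulus <- function(x, ...) {
  cat(sprintf("<audio_stimulus> %d samples @ %g Hz (%.1f s), %d segment(s)\n",
              length(x$waveform), x$fs, length(x$waveform) / x$fs,
              length(x$segment_starts)))
  invisible(x)
}

#' Amplitude envelope time series
#'
#' A single time series holding the stimulus amplitude envelope at a given
#' sampling rate. A raw (Hilbert-magnitude) envelope is nonnegative; a
#' band-filtered envelope may be signed because band-pass filtering removes
#' the DC component.
#'
#' @param samples numeric vector of envelope samples.
#' @param fs sampling rate in Hz.
#' @param band a [band_spec()] describing the filtering applied, or the
#'   string `"raw"` for an unfiltered envelope.
#'
#' @return An object of class `envelope`.
#' @export
envelope <- function(samples, fs, band = "raw") {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || fs <= 0) stop("validation error: fs must be > 0")
  if (identical(band, "raw") && length(samples) && min(samples) < 0)
    stop("validation error: a raw envelope must be nonnegative")
  structure(list(samples = samples, fs = fs, band = band),
            class = "envelope")
}

#' @export
print.envelope <- function(x, ...) {
  bname <- if (identical(x$band, "raw")) "raw" else x$band$name
  cat(sprintf("<envelope> %d samples @ %g Hz (%s)\n",
              length(x$samples), x$fs, bname))
  invisible(x)
}

# Coerce an envelope or plain vector to a numeric vector.
env_samples <- function(x) {
  if (inherits(x, "envelope")) x$samples else as.numeric(x)
}
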