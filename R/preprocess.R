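# Band-specific zero-phase FIR preprocessing shared by the EEG and the
# stimulus envelope: Hamming-window band-pass at the native rate, one
# forward pass compensated for the group delay, then downsampling to the
# processing rate (64 Hz). EEG is average-referenced first. The envelope
# and the EEG traverse the identical filter/resample code path.

#' Design a Hamming-window band-pass FIR kernel
#'
#' The tap count follows the Hamming-window design rule
#' `length = round(3.3 / min(tbw_lo, tbw_hi) * fs)`, bumped to the next odd
#' integer when even, so the kernel has an exact integer group delay of
#' `(length - 1) / 2` samples. The -6 dB cutoffs are placed half a
#' transition bandwidth outside the passband corners, i.e. at
#' `f_lo - tbw_lo/2` and `f_hi + tbw_hi/2`. The reported `order` equals the
#' tap count (the convention used when quoting, e.g., "order 6759" for the
#' 1-4 Hz band at 2048 Hz).
#'
#' @param band a [band_spec()].
#' @param fs design sampling rate in Hz; must exceed twice the upper
#'   cutoff `f_hi + tbw_hi/2`.
#' @return An object of class `filter_kernel` with fields `coefficients`,
#'   `order`, `design_fs`, `band`.
#' @examples
#' design_fir(canonical_bands("delta")[[1]], 2048)$order  # 6759
#' @export
design_fir <- function(band, fs) {
  stopifnot(inherits(band, "band_spec"))
  hi_cut <- band$f_hi + band$tbw_hi / 2
  lo_cut <- band$f_lo - band$tbw_lo / 2
  if (fs <= 2 * hi_cut)
    stop("design error: fs = ", fs, " Hz too low for band ", band$name,
         " (upper cutoff ", hi_cut, " Hz)")
  if (lo_cut <= 0)
    stop("design error: lower transition extends to or below 0 Hz")
  len <- round(3.3 / min(band$tbw_lo, band$tbw_hi) * fs)
  if (len %% 2L == 0L) len <- len + 1L
  h <- signal::fir1(len - 1L, c(lo_cut, hi_cut) / (fs / 2),
                    type = "pass", window = signal::hamming(len))
  # null the DC component exactly (a band-pass must reject constants; the
  # windowed design leaves a small residual at 0 Hz). Subtracting the tap
  # mean preserves symmetry and perturbs the passband negligibly.
  h <- h - mean(h)
  structure(list(coefficients = as.numeric(h), order = as.integer(len),
                 design_fs = fs, band = band),
            class = "filter_kernel")
}

#' @export
print.filter_kernel <- function(x, ...) {
  cat(sprintf("<filter_kernel> %s band (%g-%g Hz), %d taps @ %g Hz\n",
              x$band$name, x$band$f_lo, x$band$f_hi, x$order, x$design_fs))
  invisible(x)
}

#' Magnitude response of a filter kernel
#'
#' Evaluates the kernel's frequency response at the requested frequencies
#' by direct evaluation of the transfer function on the unit circle.
#'
#' @param kernel a `filter_kernel`.
#' @param freqs frequencies in Hz.
#' @return Numeric vector of magnitude gains (linear scale).
#' @export
fir_response <- function(kernel, freqs) {
  h <- kernel$coefficients
  w <- 2 * pi * freqs / kernel$design_fs
  vapply(w, function(wi)
    Mod(sum(h * exp(-1i * wi * (seq_along(h) - 1L)))), 0)
}

#' Export filter taps as CSV
#'
#' One tap per line with its index, for cross-implementation checks.
#'
#' @param kernel a `filter_kernel`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_kernel_csv <- function(kernel, path) {
  write.csv(data.frame(index = seq_along(kernel$coefficients) - 1L,
                       coefficient = kernel$coefficients),
            path, row.names = FALSE)
  invisible(path)
}

# Linear convolution via FFT with 5-smooth padding; returns the full
# length n + m - 1 sequence. `H`/`nf` allow reusing a precomputed padded
# kernel spectrum across many signals of the same length.
fft_conv <- function(x, h, H = NULL, nf = NULL) {
  n <- length(x); m <- length(h)
  if (is.null(nf)) nf <- nextn(n + m - 1L, c(2, 3, 5))
  if (is.null(H)) H <- fft(c(h, numeric(nf - m)))
  y <- Re(fft(fft(c(x, numeric(nf - n))) * H, inverse = TRUE)) / nf
  y[seq_len(n + m - 1L)]
}

#' Apply a FIR kernel with zero-phase (delay-compensated) semantics
#'
#' The signal is convolved once forward with the kernel (zero-padded
#' edges), then shifted left by the group delay `(length - 1) / 2` samples,
#' so a symmetric kernel introduces no net phase shift. Output length
#' equals input length; the first and last `(length - 1) / 2` samples are
#' affected by edge padding.
#'
#' @param kernel a `filter_kernel` from [design_fir()].
#' @param x numeric signal vector, longer than the kernel.
#' @return Filtered signal, same length as `x`.
#' @export
apply_zero_phase <- function(kernel, x) {
  h <- kernel$coefficients
  n <- length(x)
  if (n <= length(h))
    stop("signal (", n, " samples) must be longer than the kernel (",
         length(h), " taps)")
  gd <- (length(h) - 1L) %/% 2L
  fft_conv(x, h)[gd + seq_len(n)]
}

#' Re-reference a recording to the common average
#'
#' Subtracts the per-sample mean across all channels from every channel,
#' so each column (time point) of the result has zero mean.
#'
#' @param rec a [multichannel_recording()] with at least 2 channels.
#' @return The re-referenced recording.
#' @export
average_reference <- function(rec) {
  validate_recording(rec)
  rec$data <- sweep(rec$data, 2L, colMeans(rec$data), `-`)
  rec
}

#' Resample a band-limited signal
#'
#' Anti-alias low-pass (Hamming-window FIR, cutoff at `0.45 * fs_out` with
#' a `0.1 * fs_out` transition band) followed by interpolation onto the
#' output grid `t_j = j / fs_out`. When `fs_in` is an integer multiple of
#' `fs_out` the grid points coincide with input samples and the
#' interpolation is exact sample selection. The band filters upstream
#' already confine content well below `fs_out / 2`; the anti-alias stage is
#' defense in depth.
#'
#' @param x numeric signal vector.
#' @param fs_in input sampling rate in Hz.
#' @param fs_out output sampling rate in Hz, at most `fs_in`.
#' @return Signal of length `round(length(x) * fs_out / fs_in)`.
#' @export
resample_to <- function(x, fs_in, fs_out = 64) {
  if (fs_out > fs_in)
    stop("resampling error: fs_out (", fs_out, ") exceeds fs_in (", fs_in, ")")
  n <- length(x)
  n_out <- round(n * fs_out / fs_in)
  if (fs_out == fs_in) return(x)
  lp <- anti_alias_kernel(fs_in, fs_out)
  if (n <= length(lp$coefficients)) {
    # short signal: skip the FIR stage (content assumed already band-limited)
    xf <- x
  } else {
    # edge-replication padding: a low-pass passes DC, so extending with the
    # boundary values avoids the downward edge bias of zero padding and
    # keeps constants exactly constant
    gd <- (length(lp$coefficients) - 1L) %/% 2L
    xp <- c(rep(x[1L], gd), x, rep(x[n], gd))
    xf <- apply_zero_phase(lp, xp)[gd + seq_len(n)]
  }
  t_out <- (seq_len(n_out) - 1L) / fs_out
  approx(x = (seq_len(n) - 1L) / fs_in, y = xf, xout = t_out,
         rule = 2L)$y
}

anti_alias_kernel <- function(fs_in, fs_out) {
  cutoff <- 0.45 * fs_out
  tbw <- 0.1 * fs_out
  len <- round(3.3 / tbw * fs_in)
  if (len %% 2L == 0L) len <- len + 1L
  h <- signal::fir1(len - 1L, cutoff / (fs_in / 2), type = "low",
                    window = signal::hamming(len))
  h <- h / sum(h)   # exact unit DC gain: constants resample to constants
  structure(list(coefficients = as.numeric(h), order = as.integer(len),
                 design_fs = fs_in,
                 band = band_spec("wide", 1e-6, cutoff, 1e-6, tbw)),
            class = "filter_kernel")
}

# Analytic signal via the frequency-domain method: zero the negative
# frequencies, double the positive ones, keep DC (and Nyquist for even n).
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  w <- numeric(n)
  if (n %% 2L == 0L) {
    w[1L] <- 1
    w[2:(n / 2)] <- 2
    w[n / 2 + 1L] <- 1
  } else {
    w[1L] <- 1
    w[2:((n + 1L) / 2)] <- 2
  }
  fft(X * w, inverse = TRUE) / n
}

#' Extract the temporal amplitude envelope of a stimulus
#'
#' Computes the magnitude of the analytic signal (the original waveform as
#' real part, its Hilbert transform as imaginary part), yielding the
#' nonnegative temporal envelope at the audio rate.
#'
#' @param audio an [audio_stimulus()] (mono) or numeric vector.
#' @param fs sampling rate, required when `audio` is a bare vector.
#' @return An [envelope()] at the audio sampling rate, band `"raw"`.
#' @export
extract_envelope <- function(audio, fs = NULL) {
  if (inherits(audio, "audio_stimulus")) {
    x <- audio$waveform
    fs <- audio$fs
  } else {
    x <- as.numeric(audio)
    if (is.null(fs)) stop("fs required when passing a bare vector")
  }
  if (length(x) == 0L) stop("validation error: empty waveform")
  envelope(Mod(analytic_signal(x)), fs, band = "raw")
}

#' Band-specific preprocessing to the 64 Hz analysis rate
#'
#' Applies the full preprocessing chain for one frequency band. For an EEG
#' recording: common-average reference, Hamming-window band-pass designed
#' at the native rate, one-pass delay-compensated filtering per channel,
#' then resampling to `target_fs`. For an envelope: identical filtering and
#' resampling (no referencing), so stimulus and EEG traverse the same
#' filter specification, as the decoding model assumes.
#'
#' @param x a [multichannel_recording()] or an [envelope()].
#' @param band a [band_spec()].
#' @param target_fs output sampling rate in Hz (default 64).
#' @return An object of the same class as `x`, at `target_fs`, with the
#'   band recorded.
#' @export
preprocess_band <- function(x, band, target_fs = 64) {
  UseMethod("preprocess_band")
}

#' @export
preprocess_band.multichannel_recording <- function(x, band, target_fs = 64) {
  x <- average_reference(x)
  fr <- band_filter_resampler(band, x$fs, target_fs, ncol(x$data))
  filtered <- t(apply(x$data, 1L, fr))
  multichannel_recording(filtered, target_fs, x$channel_labels,
                         x$subject_id, x$condition, x$presentation_order)
}

#' @export
preprocess_band.envelope <- function(x, band, target_fs = 64) {
  fr <- band_filter_resampler(band, x$fs, target_fs, length(x$samples))
  envelope(fr(x$samples), target_fs, band = band)
}

# One-pass filter+resample closure for signals of a fixed length: the band
# kernel and the anti-alias kernel are combined into a single linear-phase
# kernel whose padded spectrum is computed once and reused across
# channels; delay-compensated filtering is followed by interpolation onto
# the output grid.
band_filter_resampler <- function(band, fs_in, target_fs, n) {
  h <- design_fir(band, fs_in)$coefficients
  if (target_fs < fs_in) {
    aa <- anti_alias_kernel(fs_in, target_fs)$coefficients
    h <- fft_conv(h, aa)                      # odd + odd - 1 = odd length
  } else if (target_fs > fs_in) {
    stop("resampling error: target_fs exceeds the native rate")
  }
  if (n <= length(h))
    stop("signal (", n, " samples) must be longer than the combined ",
         "filter (", length(h), " taps)")
  gd <- (length(h) - 1L) %/% 2L
  nf <- nextn(n + length(h) - 1L, c(2, 3, 5))
  H <- fft(c(h, numeric(nf - length(h))))
  n_out <- round(n * target_fs / fs_in)
  t_in <- (seq_len(n) - 1L) / fs_in
  t_out <- (seq_len(n_out) - 1L) / target_fs
  function(x) {
    xf <- fft_conv(x, h, H = H, nf = nf)[gd + seq_len(n)]
    if (target_fs == fs_in) return(xf)
    approx(t_in, xf, xout = t_out, rule = 2L)$y
  }
}

#' Drop mastoid channels from a recording
#'
#' The decoder operates on the scalp montage; mastoid electrodes
#' (labels `M1`, `M2`, `A1`, `A2`, `TP9`, `TP10`) contribute to the
#' common-average reference but are excluded from decoding by default.
#'
#' @param rec a [multichannel_recording()].
#' @param mastoid_labels labels treated as mastoids.
#' @return The recording restricted to scalp channels.
#' @export
drop_mastoids <- function(rec,
                          mastoid_labels = c("M1", "M2", "A1", "A2",
                                             "TP9", "TP10")) {
  keep <- !(rec$channel_labels %in% mastoid_labels)
  if (sum(keep) < 2L) return(rec)
  rec$data <- rec$data[keep, , drop = FALSE]
  rec$channel_labels <- rec$channel_labels[keep]
  rec
}
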