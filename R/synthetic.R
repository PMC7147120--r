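# Forward-model synthetic data with known ground truth. The generator
# uses exactly the components the analysis assumes — a speech-like
# envelope, per-channel linear convolution with a causal cortical response
# kernel, additive 1/f background noise at a configurable SNR — so decoder
# misfit on synthetic data isolates implementation error rather than model
# mismatch.

#' Generate a speech-like temporal envelope
#'
#' Builds a nonnegative envelope as a jittered pulse train at the syllable
#' rate (inter-pulse intervals gamma-distributed with mean `1 /
#' syllable_rate`), convolved with a gamma-shaped burst (~50 ms rise,
#' ~150 ms decay), and modulated by a slow sentence-rate (~0.5 Hz)
#' amplitude fluctuation. The modulation spectrum peaks near the syllable
#' rate (around 4 Hz, the dominant modulation of running English speech).
#'
#' @param duration length in seconds.
#' @param fs sampling rate in Hz.
#' @param syllable_rate mean pulse rate in Hz.
#' @param seed integer seed; identical seeds give identical output.
#' @return An [envelope()] (band `"raw"`, max-normalized to 1).
#' @export
gen_envelope <- function(duration, fs, syllable_rate = 4, seed = 1L) {
  stopifnot(duration > 0, fs > 0)
  set.seed(seed)
  n <- round(duration * fs)
  # renewal pulse process: gamma ISI, shape 16 => CV = 0.25 around 1/rate
  shape <- 16
  n_pulses <- ceiling(duration * syllable_rate * 1.3) + 8L
  isi <- rgamma(n_pulses, shape = shape, rate = shape * syllable_rate)
  times <- cumsum(isi)
  times <- times[times < duration]
  amps <- rlnorm(length(times), meanlog = 0, sdlog = 0.3)
  train <- numeric(n)
  idx <- pmin(n, floor(times * fs) + 1L)
  train[idx] <- train[idx] + amps
  # syllabic burst: g(t) = t * exp(-t / 0.05), ~50 ms rise, ~150 ms tail
  tk <- seq(0, 0.4, by = 1 / fs)
  burst <- tk * exp(-tk / 0.05)
  burst <- burst / max(burst)
  env <- fft_conv(train, burst)[seq_len(n)]
  # sentence-rate modulation
  tt <- (seq_len(n) - 1L) / fs
  phase <- runif(1L, 0, 2 * pi)
  env <- env * (1 + 0.4 * sin(2 * pi * 0.5 * tt + phase))
  env[env < 0] <- 0
  envelope(env / max(env), fs, band = "raw")
}

#' Smoothed modulation spectrum of an envelope
#'
#' Welch-style smoothed periodogram of the mean-removed envelope,
#' restricted to a frequency range; used to locate the dominant modulation
#' frequency.
#'
#' @param env an [envelope()] or numeric vector.
#' @param fs sampling rate (taken from `env` when an envelope).
#' @param f_range frequency range in Hz to retain.
#' @return data.frame with `freq` (Hz) and `power`.
#' @export
modulation_spectrum <- function(env, fs = NULL, f_range = c(1, 20)) {
  if (is.null(fs)) fs <- if (inherits(env, "envelope")) env$fs else 64
  x <- env_samples(env)
  sp <- stats::spec.pgram(stats::ts(x - mean(x), frequency = fs),
                          spans = c(11, 11), plot = FALSE, detrend = FALSE)
  keep <- sp$freq >= f_range[1L] & sp$freq <= f_range[2L]
  data.frame(freq = sp$freq[keep], power = sp$spec[keep])
}

#' Generate a ground-truth cortical response kernel
#'
#' Per-channel impulse response of the simulated cortex to the envelope: a
#' difference-of-Gaussians temporal profile (positive peak near 100 ms,
#' negative peak near 200 ms — the canonical auditory cortical response
#' morphology) scaled by a smooth frontocentral topography with small
#' seeded channel-to-channel variation. Support is 0-400 ms (causal: the
#' brain lags the stimulus) and total energy is normalized to 1.
#'
#' @param n_channels number of EEG channels.
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @return An object of class `forward_kernel`: `h` (channels x
#'   lag-samples), `topography`, `fs`, `lag_times` (seconds).
#' @export
gen_kernel <- function(n_channels = 32L, fs = 2048, seed = 1L) {
  set.seed(seed)
  tk <- seq(0, 0.4, by = 1 / fs)
  profile <- exp(-(tk - 0.10)^2 / (2 * 0.02^2)) -
    0.7 * exp(-(tk - 0.20)^2 / (2 * 0.035^2))
  ch <- seq_len(n_channels)
  center <- (n_channels + 1) / 2
  topo <- 0.15 + exp(-((ch - center) / (0.35 * n_channels))^2)
  topo <- topo * (1 + 0.1 * rnorm(n_channels))
  topo <- abs(topo)
  h <- outer(topo, profile)
  nrm <- sqrt(sum(h^2))
  h <- h / nrm
  # the kernel is rank-1 (shared temporal profile, per-channel gain);
  # keeping the factors lets the forward model convolve once
  structure(list(h = h, topography = topo / nrm, profile = profile,
                 fs = fs, lag_times = tk),
            class = "forward_kernel")
}

# 1/f ("pink") background noise, synthesized directly in the frequency
# domain: Hermitian-symmetric Gaussian spectrum with amplitudes scaled by
# f^(-alpha/2), one inverse FFT; unit variance.
pink_noise <- function(n, alpha = 1) {
  nf <- nextn(n, c(2, 3, 5))
  half <- nf %/% 2L
  # positive-frequency bins 1..half (bin `half` is Nyquist for even nf)
  re <- rnorm(half); im <- rnorm(half)
  amp <- seq_len(half)^(-alpha / 2)
  pos <- (re + 1i * im) * amp
  pos[half] <- complex(real = re[half] * amp[half], imaginary = 0)
  W <- c(0, pos, Conj(rev(pos[seq_len(half - 1L)])))
  x <- Re(fft(W, inverse = TRUE))[seq_len(n)]
  (x - mean(x)) / sd(x)
}

#' Simulate EEG as a forward model of an envelope
#'
#' Each channel is the convolution of the envelope with that channel's
#' response kernel, plus 1/f (pink) noise scaled per channel so that
#' `10 * log10(signal power / noise power)` equals `snr_db`.
#'
#' @param env an [envelope()] at the kernel's sampling rate.
#' @param kernel a `forward_kernel` from [gen_kernel()].
#' @param snr_db per-channel signal-to-noise ratio in dB.
#' @param seed integer seed.
#' @param noise `"pink"` (default) or `"white"`.
#' @param subject_id,condition,presentation_order recording metadata.
#' @return A [multichannel_recording()] at the kernel's rate with labels
#'   `C01..Cnn`.
#' @export
gen_eeg <- function(env, kernel, snr_db, seed = 1L, noise = c("pink", "white"),
                    subject_id = "sim", condition = "aided",
                    presentation_order = 1L) {
  noise <- match.arg(noise)
  stopifnot(inherits(kernel, "forward_kernel"))
  x <- env_samples(env)
  if (inherits(env, "envelope") && env$fs != kernel$fs)
    stop("envelope must be at the kernel sampling rate (", kernel$fs, " Hz)")
  set.seed(seed)
  n <- length(x)
  N <- nrow(kernel$h)
  xc <- x - mean(x)
  rank1 <- !is.null(kernel$profile) &&
    isTRUE(all.equal(kernel$h, outer(kernel$topography, kernel$profile),
                     tolerance = 1e-10))
  base <- if (rank1) fft_conv(xc, kernel$profile)[seq_len(n)] else NULL
  data <- matrix(0, N, n)
  for (j in seq_len(N)) {
    s <- if (rank1) kernel$topography[j] * base else
      fft_conv(xc, kernel$h[j, ])[seq_len(n)]
    ps <- mean(s^2)
    if (ps == 0) stop("zero-energy signal; cannot set an SNR")
    nz <- if (noise == "pink") pink_noise(n) else rnorm(n)
    data[j, ] <- s + nz * sqrt(ps / 10^(snr_db / 10))
  }
  multichannel_recording(data, kernel$fs,
                         channel_labels = sprintf("C%02d", seq_len(N)),
                         subject_id = subject_id, condition = condition,
                         presentation_order = presentation_order)
}

#' Cohort specification for simulation
#'
#' @param n_subjects number of simulated subjects.
#' @param duration recording length in seconds (default 1500 s = 25 min,
#'   presented as 8 contiguous segments).
#' @param snr_aided,snr_unaided per-channel EEG SNR in dB for the two
#'   conditions.
#' @param n_channels simulated channel count.
#' @param fs simulation sampling rate in Hz.
#' @param n_segments stimulus segment count.
#' @param behavior parameters of the behavioral model: expected proportion
#'   correct is `plogis((snr_db - mid) / scale)` and observed scores are
#'   beta-distributed around it with concentration `kappa`.
#' @param seed master seed; per-subject seeds are derived from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 17L, duration = 1500,
                        snr_aided = -10, snr_unaided = -10,
                        n_channels = 32L, fs = 2048, n_segments = 8L,
                        behavior = list(mid = -30, scale = 8, kappa = 60),
                        seed = 1L) {
  stopifnot(n_subjects >= 1L, duration >= 60)
  structure(list(n_subjects = as.integer(n_subjects), duration = duration,
                 snr_aided = snr_aided, snr_unaided = snr_unaided,
                 n_channels = as.integer(n_channels), fs = fs,
                 n_segments = as.integer(n_segments), behavior = behavior,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

behavior_expected <- function(snr_db, behavior) {
  plogis((snr_db - behavior$mid) / behavior$scale)
}

behavior_draw <- function(snr_db, behavior) {
  p <- behavior_expected(snr_db, behavior)
  rbeta(1L, p * behavior$kappa, (1 - p) * behavior$kappa)
}

# deterministic per-subject sub-seed, kept below 2^31
subseed <- function(seed, i, salt = 0L) {
  (as.integer(seed) * 1009L + i * 7919L + salt * 104729L) %% 2000000000L
}

#' Simulate a full aided/unaided cohort
#'
#' Per subject: one shared speech-like envelope (split into
#' `n_segments` contiguous segments), a subject-specific response kernel,
#' two EEG recordings at the aided and unaided SNRs, a balanced randomized
#' presentation order, and behavioral scores (BKB-sentence and
#' multiple-choice proportions) drawn from the logistic-beta behavior
#' model. With `out_dir` set, recordings are written as EDF and the
#' stimulus as WAV (the envelope amplitude-modulating a 1 kHz carrier, so
#' [extract_envelope()] on the file recovers the ground truth).
#'
#' @param spec a [cohort_spec()].
#' @param out_dir optional directory for EDF/WAV/CSV fixtures.
#' @param audio_fs sampling rate for written WAV stimuli.
#' @return A list of class `cohort` with one entry per subject
#'   (`envelope`, `kernel`, `aided`, `unaided`, `behavior`) and a
#'   `behavior` data.frame attribute.
#' @export
gen_cohort <- function(spec, out_dir = NULL, audio_fs = 8000) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  # balanced order: half the subjects hear aided first, shuffled
  set.seed(spec$seed)
  n <- spec$n_subjects
  aided_first <- sample(rep(c(TRUE, FALSE), length.out = n))
  subjects <- vector("list", n)
  beh_rows <- vector("list", n)
  for (i in seq_len(n)) {
    sid <- sprintf("S%02d", i)
    env <- gen_envelope(spec$duration, spec$fs,
                        seed = subseed(spec$seed, i, 1L))
    kern <- gen_kernel(spec$n_channels, spec$fs,
                       seed = subseed(spec$seed, i, 2L))
    ord_a <- if (aided_first[i]) 1L else 2L
    aided <- gen_eeg(env, kern, spec$snr_aided,
                     seed = subseed(spec$seed, i, 3L),
                     subject_id = sid, condition = "aided",
                     presentation_order = ord_a)
    unaided <- gen_eeg(env, kern, spec$snr_unaided,
                       seed = subseed(spec$seed, i, 4L),
                       subject_id = sid, condition = "unaided",
                       presentation_order = 3L - ord_a)
    set.seed(subseed(spec$seed, i, 5L))
    beh <- data.frame(
      subject_id = sid,
      bkb_aided = behavior_draw(spec$snr_aided, spec$behavior),
      bkb_unaided = behavior_draw(spec$snr_unaided, spec$behavior),
      mcq_aided = behavior_draw(spec$snr_aided + 5, spec$behavior),
      mcq_unaided = behavior_draw(spec$snr_unaided + 5, spec$behavior),
      aided_first = aided_first[i])
    if (!is.null(out_dir)) {
      write_eeg(aided, file.path(out_dir, paste0(sid, "_aided.edf")))
      write_eeg(unaided, file.path(out_dir, paste0(sid, "_unaided.edf")))
      # envelope is already low-passed by construction; interpolate onto
      # the audio grid and modulate a carrier below the audio Nyquist
      n_env <- length(env$samples)
      wav_env <- approx((seq_len(n_env) - 1L) / spec$fs, env$samples,
                        xout = (seq_len(round(n_env / spec$fs * audio_fs))
                                - 1L) / audio_fs, rule = 2L)$y
      f_car <- min(1000, audio_fs / 4)
      carrier <- sin(2 * pi * f_car * (seq_along(wav_env) - 1L) / audio_fs)
      write_audio(0.9 * wav_env / max(wav_env) * carrier,
                  file.path(out_dir, paste0(sid, "_stimulus.wav")),
                  fs = audio_fs)
    }
    segb <- floor(seq(0, length(env$samples), length.out = spec$n_segments + 1L))
    env$segment_starts <- segb[-length(segb)]
    subjects[[i]] <- list(subject_id = sid, envelope = env, kernel = kern,
                          aided = aided, unaided = unaided, behavior = beh)
    beh_rows[[i]] <- beh
  }
  beh_tab <- do.call(rbind, beh_rows)
  if (!is.null(out_dir))
    write.csv(beh_tab, file.path(out_dir, "behavior.csv"),
              row.names = FALSE)
  structure(subjects, class = "cohort", behavior = beh_tab)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects, %d channels, %.0f s @ %g Hz\n",
              length(x), nrow(x[[1L]]$kernel$h),
              length(x[[1L]]$envelope$samples) / x[[1L]]$envelope$fs,
              x[[1L]]$envelope$fs))
  invisible(x)
}
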