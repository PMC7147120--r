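delta <- canonical_bands("delta")[[1]]
theta <- canonical_bands("theta")[[1]]
wide  <- canonical_bands("wide")[[1]]

test_that("FIR design reproduces the canonical tap counts at 2048 Hz", {
  expect_identical(design_fir(delta, 2048)$order, 6759L)
  expect_identical(design_fir(theta, 2048)$order, 3379L)
  expect_identical(design_fir(wide, 2048)$order, 6759L)
  # the rule scales with fs and always lands on an odd length
  k512 <- design_fir(delta, 512)
  expect_identical(k512$order, 1691L)
  expect_identical(k512$order %% 2L, 1L)
})

test_that("designed kernels are symmetric (linear phase)", {
  for (b in list(delta, theta, wide)) {
    h <- design_fir(b, 512)$coefficients
    expect_lt(max(abs(h - rev(h))) / max(abs(h)), 1e-12)
  }
})

test_that("FIR design rejects an inadequate sampling rate", {
  expect_error(design_fir(wide, 40), "design error")
})

test_that("magnitude response: passband flat, stopband suppressed", {
  kd <- design_fir(delta, 2048)
  kt <- design_fir(theta, 2048)
  kw <- design_fir(wide, 2048)
  db <- function(k, f) 20 * log10(fir_response(k, f))
  # passband interior within 1 dB
  expect_gt(min(db(kd, seq(2, 3.5, by = 0.25))), -1)
  expect_gt(min(db(kt, seq(5.5, 7.5, by = 0.25))), -1)
  expect_gt(min(db(kw, seq(4, 19, by = 1))), -1)
  # stopband one transition bandwidth beyond each edge; the theta low
  # edge sits on a window sidelobe (cutoff near DC), hence the looser
  # bound there, recovering the deep floor half a bandwidth further out
  expect_lt(db(kd, 8), -40)       # 4 + 2·tbw_hi/... beyond upper corner
  expect_lt(db(kd, 0), -100)      # exact DC null
  expect_lt(db(kt, 10), -40)
  expect_lt(db(kt, 2), -35)
  expect_lt(db(kt, 1), -50)
  expect_lt(db(kw, 25), -40)
  expect_lt(db(kw, 0), -100)
})

test_that("zero-phase filtering compensates the group delay exactly", {
  k <- design_fir(delta, 512)
  x <- numeric(4000); x[1500] <- 1
  y <- apply_zero_phase(k, x)
  expect_identical(which.max(abs(y)), 1500L)
  expect_error(apply_zero_phase(k, numeric(100)), "longer than")
})

test_that("band-pass output: DC rejected, passband tone preserved", {
  k <- design_fir(delta, 512)
  n <- 6000
  ctr <- 2000:4000
  dc <- apply_zero_phase(k, rep(1, n))
  expect_lt(max(abs(dc[ctr])), 1e-3)
  tone <- sin(2 * pi * 2.5 * (0:(n - 1)) / 512)
  out <- apply_zero_phase(k, tone)
  expect_equal(max(abs(out[ctr])), fir_response(k, 2.5), tolerance = 0.005)
  expect_equal(max(abs(out[ctr])), 1, tolerance = 0.02)
})

test_that("filtered band-limited noise peaks in cross-correlation at lag 0", {
  set.seed(8)
  k <- design_fir(theta, 512)
  x <- rnorm(12000)
  y <- apply_zero_phase(k, x)
  xb <- apply_zero_phase(k, y)  # band-limited input vs its filtered output
  cc <- ccf(y[3000:9000], xb[3000:9000], lag.max = 40, plot = FALSE)
  expect_equal(as.numeric(cc$lag)[which.max(cc$acf)], 0)
})

test_that("average referencing zeroes the per-sample channel mean", {
  v <- rnorm(100)
  two <- multichannel_recording(rbind(v, -v), 64)
  expect_equal(average_reference(two)$data, rbind(v, -v))
  same <- multichannel_recording(rbind(v, v, v), 64)
  expect_true(all(average_reference(same)$data == 0))
  rec <- multichannel_recording(matrix(rnorm(400), 4), 64)
  expect_lt(max(abs(colMeans(average_reference(rec)$data))), 1e-12)
})

test_that("resampling honors the length rule and preserves tones", {
  expect_length(resample_to(rnorm(2048), 2048, 64), 64L)
  t_in <- (0:(2048 * 8 - 1)) / 2048
  y <- resample_to(sin(2 * pi * 5 * t_in), 2048, 64)
  ref <- sin(2 * pi * 5 * (seq_along(y) - 1) / 64)
  ctr <- 40:(length(y) - 40)
  expect_gt(cor(y[ctr], ref[ctr]), 0.999)
  # constants survive exactly (edge-replication padding, unit DC gain)
  expect_equal(resample_to(rep(2, 500), 500, 100), rep(2, 100))
  expect_equal(resample_to(rep(3, 2048 * 5), 2048, 64), rep(3, 320))
  expect_error(resample_to(rnorm(100), 64, 128), "exceeds")
})

test_that("Hilbert envelope recovers tone amplitude and AM modulators", {
  fs <- 8000
  tt <- (0:(2 * fs - 1)) / fs
  tone <- extract_envelope(0.5 * sin(2 * pi * 1000 * tt), fs)
  ctr <- 400:(length(tt) - 400)
  expect_true(all(tone$samples >= 0))
  expect_equal(max(abs(tone$samples[ctr] - 0.5)) / 0.5, 0,
               tolerance = 0.01)
  mod <- 1 + 0.5 * sin(2 * pi * 4 * tt)
  am <- extract_envelope(mod * sin(2 * pi * 1000 * tt), fs)
  expect_gt(cor(am$samples[ctr], mod[ctr]), 0.99)
  zero <- extract_envelope(audio_stimulus(numeric(100), fs))
  expect_true(all(zero$samples == 0))
  expect_error(extract_envelope(numeric(0), fs), "empty")
})

test_that("preprocess_band length arithmetic holds from the audio rate", {
  env <- envelope(abs(rnorm(44100 * 60)), 44100)
  out <- preprocess_band(env, delta)
  expect_length(out$samples, 60L * 64L)
  expect_equal(out$fs, 64)
})

test_that("band-filtered white noise concentrates power in the band", {
  set.seed(5)
  env <- envelope(abs(rnorm(2048 * 120)), 2048)
  out <- preprocess_band(env, delta)
  # exclude the filter-delay edge transients (~2 s per side), which are
  # flagged but not dropped by the pipeline
  x <- out$samples[(64 * 3):(length(out$samples) - 64 * 3)]
  sp <- spec.pgram(ts(x - mean(x), frequency = 64), plot = FALSE, taper = 0)
  inband <- sp$freq >= 0.5 & sp$freq <= 5
  expect_gt(sum(sp$spec[inband]) / sum(sp$spec), 0.95)
})

test_that("symmetric filtering commutes exactly with time reversal", {
  set.seed(6)
  k <- design_fir(delta, 512)
  x <- abs(rnorm(512 * 20))
  expect_equal(apply_zero_phase(k, rev(x)),
               rev(apply_zero_phase(k, x)), tolerance = 1e-9)
})

test_that("the full pipeline commutes with reversal up to grid alignment", {
  # the 64 Hz output grid is anchored at the first sample, so reversing
  # the input shifts the grid by one output sample when the duration is a
  # whole number of output periods; compare at the best of the two shifts
  set.seed(6)
  x <- abs(rnorm(2048 * 30 + 1))   # duration = whole output periods
  a <- preprocess_band(envelope(rev(x), 2048), delta)$samples
  b <- rev(preprocess_band(envelope(x, 2048), delta)$samples)
  ctr <- 200:(length(a) - 200)
  d0 <- max(abs(a[ctr] - b[ctr]))
  d1 <- max(abs(a[ctr] - b[ctr - 1L]))
  expect_lt(min(d0, d1) / stats::sd(b[ctr]), 0.02)
})

test_that("EEG and envelope pipelines share one code path", {
  set.seed(7)
  v <- rnorm(2048 * 20)
  rec <- multichannel_recording(rbind(v, -v), 2048)  # avg-ref invariant
  eeg_out <- preprocess_band(rec, theta)$data[1, ]
  env_out <- preprocess_band(structure(list(samples = v, fs = 2048,
                                            band = "raw"),
                                       class = "envelope"), theta)$samples
  expect_equal(eeg_out, env_out, tolerance = 1e-12)
})

test_that("mastoid channels are dropped for decoding but not referencing", {
  rec <- multichannel_recording(matrix(rnorm(5 * 50), 5), 64,
                                c("Fz", "Cz", "Pz", "M1", "M2"))
  kept <- drop_mastoids(rec)
  expect_identical(kept$channel_labels, c("Fz", "Cz", "Pz"))
  expect_identical(nrow(kept$data), 3L)
})

test_that("filter kernels export as readable CSV tap lists", {
  k <- design_fir(theta, 512)
  p <- tempfile(fileext = ".csv")
  write_kernel_csv(k, p)
  tab <- read.csv(p)
  expect_identical(nrow(tab), k$order)
  expect_equal(tab$coefficient, k$coefficients, tolerance = 1e-12)
})
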