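# Independent oracles and small fixture builders used across test files.

# Exact two-sided signed-rank p by direct enumeration of every sign
# pattern (kept independent of the package's implementation: builds the
# pattern list with expand.grid and recomputes ranks per pattern).
brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  grid <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W <- apply(grid, 1, function(s) sum(r[s == 1]))
  min(1, 2 * min(mean(W <= v), mean(W >= v)))
}

# Benjamini-Yekutieli adjusted p-values straight from the definition:
# for each i, min over j >= rank(i) of p_(j) * m * c(m) / j, uncapped.
brute_by <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m), function(i)
    min(ps[i:m] * m * cm / (i:m)), 0)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Ridge solution via the augmented least-squares system [X; sqrt(l)*I].
augmented_ridge <- function(X, y, lambda) {
  p <- ncol(X)
  Xa <- rbind(X, sqrt(lambda) * diag(p))
  ya <- c(y, numeric(p))
  qr.solve(Xa, ya)
}

# Minimal evaluation_result for exercising detect_response directly.
fake_eval <- function(pooled, kind = "forward") {
  structure(list(pooled_r = pooled, lambda_opt = 1, mean_r = mean(pooled),
                 sd_r = stats::sd(pooled), per_fold_r = list(pooled),
                 band = "delta", condition = "aided",
                 envelope_kind = kind),
            class = "evaluation_result")
}

# EEG recording at 64 Hz whose channels carry lagged copies of a target
# series plus noise; for decoder tests that skip the filtering front end.
lagged_recording <- function(target, lags_used = c(3, 6, 10),
                             noise_sd = 0.1, seed = 99) {
  set.seed(seed)
  n <- length(target)
  dat <- t(vapply(lags_used, function(k)
    c(numeric(k), target[seq_len(n - k)]) + rnorm(n, 0, noise_sd),
    numeric(n)))
  multichannel_recording(dat, 64)
}

# Stereo 16-bit PCM WAV writer (the package itself only writes mono).
write_stereo_wav <- function(left, right, fs, path) {
  inter <- as.integer(round(as.vector(rbind(left, right)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_len <- 2L * length(inter)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_len, con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(c(1L, 2L), con, size = 2L, endian = "little")
  writeBin(as.integer(fs), con, size = 4L, endian = "little")
  writeBin(as.integer(fs) * 4L, con, size = 4L, endian = "little")
  writeBin(4L, con, size = 2L, endian = "little")
  writeBin(16L, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_len, con, size = 4L, endian = "little")
  writeBin(inter, con, size = 2L, endian = "little")
  invisible(path)
}
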