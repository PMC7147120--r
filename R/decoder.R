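# Backward decoder: the stimulus envelope y(t) is modeled as a linear
# combination of the EEG channels at a window of delays,
#   y(t) = sum_j sum_k beta[j,k] * x_j(t + tau_k),
# estimated by ridge regression beta = (X'X + lambda I)^{-1} X'y on the
# lagged design matrix X.

#' Decoder lag specification
#'
#' Converts a lag window in seconds into integer sample lags at the
#' analysis rate, `k = round(tau * fs)` for `tau` from `tau_min` to
#' `tau_max`. At the canonical window (-100 ms to +400 ms) and 64 Hz this
#' yields lags -6..26, i.e. 33 lags.
#'
#' @param tau_min,tau_max lag window in seconds (EEG delay relative to the
#'   stimulus).
#' @param fs analysis sampling rate in Hz.
#' @return An object of class `lag_spec` with `lag_samples`, `k_min`,
#'   `k_max`, `n_lags`, `fs`.
#' @export
lag_spec <- function(tau_min = -0.100, tau_max = 0.400, fs = 64) {
  stopifnot(tau_min < tau_max, fs > 0)
  k_min <- as.integer(round(tau_min * fs))
  k_max <- as.integer(round(tau_max * fs))
  structure(list(tau_min = tau_min, tau_max = tau_max, fs = fs,
                 k_min = k_min, k_max = k_max,
                 lag_samples = seq.int(k_min, k_max),
                 n_lags = k_max - k_min + 1L),
            class = "lag_spec")
}

#' Build the lagged spatiotemporal design matrix
#'
#' Row `t`, column `(j, k)` holds channel `j` at sample `t + k` (zero when
#' the shifted index falls outside the recording). Columns are
#' channel-major: channel varies slowest, lag fastest, giving `N * T`
#' columns for `N` channels and `T` lags.
#'
#' @param eeg a [multichannel_recording()] at the lag spec's rate, or a
#'   channels x samples matrix.
#' @param lags a [lag_spec()].
#' @param rows optional integer vector of rows (time indices) to build;
#'   defaults to all samples. Lagged values are always drawn from the full
#'   recording, so a row subset sees its true neighbours.
#' @return A list of class `lagged_design` with `X` (rows x N*T),
#'   `valid_rows` (logical: all lags in range), `rows`, `lags`,
#'   `n_channels`.
#' @export
build_lag_matrix <- function(eeg, lags, rows = NULL) {
  dat <- if (inherits(eeg, "multichannel_recording")) {
    if (!isTRUE(all.equal(eeg$fs, lags$fs)))
      stop("recording rate (", eeg$fs, ") must match lag spec rate (",
           lags$fs, ")")
    eeg$data
  } else as.matrix(eeg)
  n <- ncol(dat)
  N <- nrow(dat)
  T_ <- lags$n_lags
  if (n <= T_)
    stop("recording (", n, " samples) shorter than the lag span (", T_, ")")
  if (is.null(rows)) rows <- seq_len(n)
  X <- matrix(0, length(rows), N * T_)
  for (j in seq_len(N)) {
    ch <- dat[j, ]
    for (ki in seq_len(T_)) {
      idx <- rows + lags$lag_samples[ki]
      ok <- idx >= 1L & idx <= n
      col <- (j - 1L) * T_ + ki
      X[ok, col] <- ch[idx[ok]]
    }
  }
  valid <- rows + lags$k_min >= 1L & rows + lags$k_max <= n
  structure(list(X = X, valid_rows = valid, rows = rows, lags = lags,
                 n_channels = N),
            class = "lagged_design")
}

design_X <- function(X) if (inherits(X, "lagged_design")) X$X else as.matrix(X)

#' Fit the ridge-regression backward decoder
#'
#' Solves the normal equations `(X'X + lambda I) beta = X'y` after
#' mean-centering the columns of `X` and `y` (the intercept is restored at
#' prediction time; band-passed signals are near zero-mean, so centering is
#' a numerically safe normalization that leaves the model unchanged). A
#' single `lambda` is shared across all channel-lag columns; no column
#' scaling is applied.
#'
#' @param X a `lagged_design` from [build_lag_matrix()] or a numeric
#'   matrix.
#' @param y response (envelope at the analysis rate): an [envelope()] or
#'   numeric vector, one value per row of `X`.
#' @param lambda ridge penalty, a scalar `>= 0`.
#' @return An object of class `decoder_weights`: `beta` (length N*T),
#'   `lambda`, `x_center`, `y_center`, plus `n_channels`/`lags` when known
#'   (then `coef_matrix` reshapes `beta` to channels x lags).
#' @export
fit_ridge <- function(X, y, lambda) {
  stopifnot(length(lambda) == 1L, lambda >= 0)
  Xm <- design_X(X)
  yv <- env_samples(y)
  if (length(yv) != nrow(Xm))
    stop("y length (", length(yv), ") must equal X row count (",
         nrow(Xm), ")")
  xc <- colMeans(Xm)
  yc <- mean(yv)
  Xc <- sweep(Xm, 2L, xc, `-`)
  G <- crossprod(Xc)
  diag(G) <- diag(G) + lambda
  b <- tryCatch(
    solve(G, crossprod(Xc, yv - yc)),
    error = function(e)
      stop("solver error: X'X + lambda*I is singular",
           if (lambda == 0) " (collinear columns; use lambda > 0)" else "",
           call. = FALSE))
  structure(list(beta = as.numeric(b), lambda = lambda, x_center = xc,
                 y_center = yc,
                 n_channels = if (inherits(X, "lagged_design"))
                   X$n_channels else NA_integer_,
                 lags = if (inherits(X, "lagged_design")) X$lags else NULL),
            class = "decoder_weights")
}

#' Reshape decoder weights to a channels x lags matrix
#'
#' @param w a `decoder_weights` fit on a `lagged_design`.
#' @return Matrix with one row per channel, one column per lag.
#' @export
coef_matrix <- function(w) {
  stopifnot(inherits(w, "decoder_weights"))
  if (is.na(w$n_channels) || is.null(w$lags))
    stop("weights were not fit on a lagged_design; lag layout unknown")
  matrix(w$beta, nrow = w$n_channels, ncol = w$lags$n_lags, byrow = TRUE,
         dimnames = list(NULL, paste0("lag", w$lags$lag_samples)))
}

#' Reconstruct the envelope from EEG with fitted decoder weights
#'
#' Computes `y_hat = X beta` in centered coordinates and restores the
#' training intercept, so a zero decoder predicts the training-mean
#' envelope.
#'
#' @param X a `lagged_design` or matrix with columns matching `beta`.
#' @param w a `decoder_weights` from [fit_ridge()].
#' @return An [envelope()] at the lag spec's rate (band `"reconstructed"`),
#'   same length as the rows of `X`.
#' @export
predict_envelope <- function(X, w) {
  Xm <- design_X(X)
  if (ncol(Xm) != length(w$beta))
    stop("shape mismatch: X has ", ncol(Xm), " columns but beta has ",
         length(w$beta))
  yhat <- as.numeric(Xm %*% w$beta) - sum(w$x_center * w$beta) + w$y_center
  fs <- if (inherits(X, "lagged_design")) X$lags$fs else 64
  structure(list(samples = yhat, fs = fs, band = "reconstructed"),
            class = "envelope")
}

#' Per-segment Pearson correlations between two envelopes
#'
#' Splits both series into non-overlapping windows of `segment_length`
#' seconds (the trailing partial window is dropped) and returns the Pearson
#' correlation within each window. A zero-variance window yields `r = 0`
#' with a warning, so pooled distributions keep a fixed cardinality.
#'
#' @param y_hat,y [envelope()] objects or numeric vectors of equal length.
#' @param segment_length window length in seconds.
#' @param fs sampling rate in Hz, taken from `y_hat` when it is an
#'   envelope.
#' @return Numeric vector of per-segment correlations.
#' @export
segment_correlations <- function(y_hat, y, segment_length = 10, fs = NULL) {
  if (is.null(fs))
    fs <- if (inherits(y_hat, "envelope")) y_hat$fs else 64
  a <- env_samples(y_hat)
  b <- env_samples(y)
  if (length(a) != length(b))
    stop("envelopes must have equal length (", length(a), " vs ",
         length(b), ")")
  seg <- floor(segment_length * fs)
  n_seg <- length(a) %/% seg
  if (n_seg == 0L)
    stop("signal shorter than one segment (", seg, " samples)")
  vapply(seq_len(n_seg), function(s) {
    idx <- (s - 1L) * seg + seq_len(seg)
    sa <- a[idx]; sb <- b[idx]
    if (var(sa) == 0 || var(sb) == 0) {
      warning("zero-variance segment ", s, "; correlation recorded as 0")
      return(0)
    }
    cor(sa, sb)
  }, 0)
}
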