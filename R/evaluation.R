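# Five-fold cross-validated evaluation of the backward decoder with a
# regularization sweep, and the chance-level (time-reversed envelope)
# companion run. The per-fold Gram matrices are assembled from per-block
# cross-products (test blocks partition the recording, so the training
# Gram matrix is the total minus the fold's own block), and one symmetric
# eigen-decomposition per fold serves the entire lambda grid.

#' Contiguous cross-validation folds
#'
#' Partitions `n_samples` time points into `n_folds` contiguous, disjoint
#' test blocks whose sizes differ by at most one sample; the training set
#' of each fold is the complement.
#'
#' @param n_samples number of time samples.
#' @param n_folds number of folds.
#' @param min_test minimum test-block length in samples.
#' @return A list of `n_folds` lists with integer vectors `train`, `test`.
#' @export
make_folds <- function(n_samples, n_folds = 5L, min_test = 2L) {
  stopifnot(n_folds >= 2L)
  if (n_samples < n_folds * min_test)
    stop("recording too short: ", n_samples, " samples for ", n_folds,
         " folds")
  bounds <- floor(n_samples * (0:n_folds) / n_folds)
  lapply(seq_len(n_folds), function(f) {
    test <- (bounds[f] + 1L):bounds[f + 1L]
    list(train = setdiff(seq_len(n_samples), test), test = test)
  })
}

# Shared engine: evaluates one recording against one or more envelopes
# (which reuse the same design-matrix cross-products). Returns one
# (lambda x fold x segment) tensor per envelope.
cv_engine <- function(eeg, envs, cfg) {
  stopifnot(inherits(eeg, "multichannel_recording"))
  if (eeg$fs != cfg$target_fs)
    stop("recording must be at the analysis rate (", cfg$target_fs, " Hz)")
  if (cfg$scalp_only) eeg <- drop_mastoids(eeg)
  lags <- lag_spec(cfg$lag_window[1L], cfg$lag_window[2L], cfg$target_fs)
  n <- ncol(eeg$data)
  ys <- lapply(envs, function(e) {
    v <- env_samples(e)
    if (length(v) != n)
      stop("envelope length (", length(v),
           ") must match recording length (", n, ")")
    v
  })
  folds <- make_folds(n, cfg$n_folds,
                      min_test = floor(cfg$segment_length * cfg$target_fs))
  L <- length(cfg$lambda_grid)
  seg <- floor(cfg$segment_length * cfg$target_fs)
  segs_per_fold <- vapply(folds, function(f)
    as.integer(length(f$test) %/% seg), 0L)
  p <- NULL

  # pass 1: per-block cross-products
  C_tot <- NULL; s_tot <- NULL
  d_tot <- lapply(ys, function(.) NULL)
  block_stats <- vector("list", cfg$n_folds)
  for (f in seq_len(cfg$n_folds)) {
    ld <- build_lag_matrix(eeg, lags, rows = folds[[f]]$test)
    Xb <- ld$X
    use <- if (cfg$valid_rows_only) ld$valid_rows else
      rep(TRUE, nrow(Xb))
    Xu <- Xb[use, , drop = FALSE]
    Cb <- crossprod(Xu)
    sb <- colSums(Xu)
    db <- lapply(ys, function(y) crossprod(Xu, y[folds[[f]]$test][use]))
    tb <- vapply(ys, function(y) sum(y[folds[[f]]$test][use]), 0)
    nb <- sum(use)
    block_stats[[f]] <- list(C = Cb, s = sb, d = db, t = tb, n = nb)
    C_tot <- if (is.null(C_tot)) Cb else C_tot + Cb
    s_tot <- if (is.null(s_tot)) sb else s_tot + sb
    d_tot <- Map(function(a, b) if (is.null(a)) b else a + b, d_tot, db)
    p <- ncol(Xb)
  }
  t_tot <- Reduce(`+`, lapply(block_stats, `[[`, "t"))
  n_tot <- sum(vapply(block_stats, `[[`, 0, "n"))

  tensors <- lapply(ys, function(.)
    array(NA_real_, dim = c(L, cfg$n_folds, max(segs_per_fold))))

  # pass 2: per-fold solve + test prediction
  for (f in seq_len(cfg$n_folds)) {
    bs <- block_stats[[f]]
    n_tr <- n_tot - bs$n
    s_tr <- s_tot - bs$s
    G <- (C_tot - bs$C) - tcrossprod(s_tr) / n_tr
    eg <- eigen(G, symmetric = TRUE)
    vals <- pmax(eg$values, 0)
    Xb <- build_lag_matrix(eeg, lags, rows = folds[[f]]$test)$X
    mu <- s_tr / n_tr
    for (ei in seq_along(ys)) {
      y <- ys[[ei]]
      t_tr <- t_tot[ei] - bs$t[ei]
      ybar <- t_tr / n_tr
      xty <- (d_tot[[ei]] - bs$d[[ei]]) - s_tr * (t_tr / n_tr)
      vt_xty <- as.numeric(crossprod(eg$vectors, xty))
      B <- eg$vectors %*% (matrix(vt_xty, p, L) /
                             outer(vals, cfg$lambda_grid, `+`))
      Yhat <- Xb %*% B
      Yhat <- sweep(Yhat, 2L, as.numeric(crossprod(mu, B)), `-`) + ybar
      y_te <- y[folds[[f]]$test]
      for (l in seq_len(L)) {
        r <- segment_correlations(Yhat[, l], y_te,
                                  segment_length = cfg$segment_length,
                                  fs = cfg$target_fs)
        tensors[[ei]][l, f, seq_along(r)] <- r
      }
    }
  }
  lapply(tensors, function(tn) {
    attr(tn, "lambda_grid") <- cfg$lambda_grid
    attr(tn, "segs_per_fold") <- segs_per_fold
    tn
  })
}

#' Cross-validated correlation tensor for a regularization sweep
#'
#' For every ridge parameter in the grid and every fold: fits the decoder
#' on the training blocks, reconstructs the envelope on the held-out test
#' block, and scores per-segment Pearson correlations. Dimensions are
#' `(lambda, fold, segment)`; folds with fewer segments are NA-padded.
#'
#' @param eeg a [multichannel_recording()] at the analysis rate.
#' @param env an [envelope()] (or numeric vector) at the analysis rate,
#'   same length as the recording.
#' @param cfg an [analysis_config()].
#' @return A 3-D array with attributes `lambda_grid` and `segs_per_fold`.
#' @export
cross_validate <- function(eeg, env, cfg = analysis_config()) {
  cv_engine(eeg, list(env), cfg)[[1L]]
}

#' Select the optimal regularization and pool test correlations
#'
#' The optimal `lambda` maximizes the grand mean correlation across all
#' folds and segments; ties break toward the smaller `lambda`. The pooled
#' distribution is the tensor slice at the optimum, flattened across folds
#' and segments.
#'
#' @param tensor a correlation tensor from [cross_validate()].
#' @param grid the lambda grid (defaults to the tensor's
#'   `lambda_grid` attribute).
#' @param band,condition,envelope_kind metadata carried into the result.
#' @return An object of class `evaluation_result`: `pooled_r`,
#'   `lambda_opt`, `mean_r`, `sd_r`, `per_fold_r`, `band`, `condition`,
#'   `envelope_kind`.
#' @export
select_lambda <- function(tensor, grid = attr(tensor, "lambda_grid"),
                          band = NA_character_, condition = NA_character_,
                          envelope_kind = "forward") {
  stopifnot(length(dim(tensor)) == 3L, dim(tensor)[1L] == length(grid))
  grand <- apply(tensor, 1L, mean, na.rm = TRUE)
  if (all(is.nan(grand))) stop("all-NaN correlation tensor")
  best <- which.max(grand)  # first maximum = smallest lambda on ties
  per_fold <- lapply(seq_len(dim(tensor)[2L]), function(f) {
    r <- tensor[best, f, ]
    r[!is.na(r)]
  })
  pooled <- unlist(per_fold, use.names = FALSE)
  structure(list(pooled_r = pooled, lambda_opt = grid[best],
                 lambda_index = best, mean_r = mean(pooled),
                 sd_r = sd(pooled), per_fold_r = per_fold, band = band,
                 condition = condition, envelope_kind = envelope_kind),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(
    "<evaluation_result> %s: mean r = %.4f (sd %.4f), n = %d segments, lambda* = %.3g\n",
    x$envelope_kind, x$mean_r, x$sd_r, length(x$pooled_r), x$lambda_opt))
  invisible(x)
}

#' Chance-level evaluation with the time-reversed envelope
#'
#' Runs the identical pipeline — same folds, same lambda grid, independent
#' lambda optimization — with the envelope reversed in time at the
#' analysis rate, yielding the empirical chance distribution of segment
#' correlations.
#'
#' @inheritParams cross_validate
#' @return An `evaluation_result` with `envelope_kind = "time_reversed"`.
#' @export
evaluate_null <- function(eeg, env, cfg = analysis_config()) {
  rev_env <- env
  if (inherits(env, "envelope")) rev_env$samples <- rev(env$samples)
  else rev_env <- rev(env_samples(env))
  tensor <- cross_validate(eeg, rev_env, cfg)
  select_lambda(tensor, cfg$lambda_grid,
                band = env_band_name(env), condition = eeg$condition,
                envelope_kind = "time_reversed")
}

env_band_name <- function(env) {
  if (inherits(env, "envelope") && inherits(env$band, "band_spec"))
    env$band$name else NA_character_
}

#' Forward and chance-level evaluation of one subject
#'
#' Evaluates the forward envelope and its time-reversal in one pass
#' (sharing the design-matrix cross-products and per-fold
#' eigen-decompositions, which dominate the cost) and tests the paired
#' difference.
#'
#' @inheritParams cross_validate
#' @return A `subject_detection` (see [detect_response()]).
#' @export
evaluate_subject <- function(eeg, env, cfg = analysis_config()) {
  rev_env <- rev(env_samples(env))
  tensors <- cv_engine(eeg, list(env_samples(env), rev_env), cfg)
  fwd <- select_lambda(tensors[[1L]], cfg$lambda_grid,
                       band = env_band_name(env), condition = eeg$condition,
                       envelope_kind = "forward")
  nul <- select_lambda(tensors[[2L]], cfg$lambda_grid,
                       band = env_band_name(env), condition = eeg$condition,
                       envelope_kind = "time_reversed")
  detect_response(fwd, nul, cfg$alpha)
}

#' Detect an above-chance cortical response
#'
#' Two-sided Wilcoxon signed-rank test between the forward and
#' chance-level pooled correlation distributions, paired by segment index
#' (forward segment i and null segment i score the same temporal window of
#' EEG). The response is significant when `p < alpha` and the forward
#' median exceeds the null median.
#'
#' @param fwd,null `evaluation_result` objects with equal pooled
#'   cardinality.
#' @param alpha significance level.
#' @return An object of class `subject_detection`: `forward`, `null`,
#'   `p_value`, `significant`.
#' @export
detect_response <- function(fwd, null, alpha = 0.05) {
  stopifnot(inherits(fwd, "evaluation_result"),
            inherits(null, "evaluation_result"))
  if (length(fwd$pooled_r) != length(null$pooled_r))
    stop("forward and null pooled distributions must have equal cardinality")
  d <- fwd$pooled_r - null$pooled_r
  p <- if (all(d == 0)) 1 else
    suppressWarnings(wilcox.test(fwd$pooled_r, null$pooled_r,
                                 paired = TRUE, exact = FALSE)$p.value)
  structure(list(forward = fwd, null = null, p_value = p,
                 significant = (p < alpha) &&
                   (median(fwd$pooled_r) > median(null$pooled_r)),
                 alpha = alpha),
            class = "subject_detection")
}

#' @export
print.subject_detection <- function(x, ...) {
  cat(sprintf(
    "<subject_detection> forward r = %.4f vs null r = %.4f, p = %.3g (%s)\n",
    x$forward$mean_r, x$null$mean_r, x$p_value,
    if (x$significant) "significant" else "not significant"))
  invisible(x)
}
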