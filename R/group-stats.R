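# Group-level nonparametric statistics across subjects, conditions and
# bands. Reconstruction correlations are non-normally distributed, so all
# comparisons are rank- or sign-based; families of tests are adjusted with
# the Benjamini-Yekutieli procedure, deliberately left uncapped so
# adjusted p-values may exceed 1.

stats_report <- function(test_name, statistic, raw_p, n, notes = "") {
  structure(list(test_name = test_name, statistic = statistic,
                 raw_p = raw_p, adjusted_p = NA_real_, n = n,
                 notes = notes),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat(sprintf("<stats_report> %s: statistic = %.4g, p = %.4g (n = %d)%s\n",
              x$test_name, x$statistic, x$raw_p, x$n,
              if (!is.na(x$adjusted_p))
                sprintf(", BY-adjusted p = %.4g", x$adjusted_p) else ""))
  if (nzchar(x$notes)) cat("  ", x$notes, "\n")
  invisible(x)
}

# Two-sided signed-rank p-value for a vector of differences. Zeros are
# dropped. For n <= 16 the exact sign-flip permutation null conditional on
# the observed magnitudes (midranks) is enumerated, which stays exact in
# the presence of tied magnitudes; beyond that, wilcox.test handles it
# (exact when tie-free, normal approximation otherwise).
signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(list(statistic = 0, p = 1, n = 0L))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 16L) {
    # all 2^n sign assignments of the midranks
    signs <- matrix(bitwAnd(rep(0:(2^n - 1L), each = n),
                            rep(2^(seq_len(n) - 1L), 2^n)) > 0,
                    nrow = n)
    W <- as.numeric(crossprod(r, signs))
    p <- min(1, 2 * min(mean(W <= v), mean(W >= v)))
  } else {
    p <- suppressWarnings(wilcox.test(d)$p.value)
  }
  list(statistic = v, p = p, n = n)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on subject-paired values; zero differences
#' are dropped per the standard convention, and all-tied input yields
#' `p = 1`. For 16 or fewer nonzero differences the p-value is computed
#' from the exact sign-flip permutation null conditional on the observed
#' magnitudes (valid under tied magnitudes); larger samples use the
#' standard `wilcox.test` machinery.
#'
#' @param a,b numeric vectors of equal length (>= 5 pairs), paired by
#'   subject.
#' @return A `stats_report`.
#' @export
paired_wilcoxon <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 5L)
  sr <- signed_rank_p(a - b)
  stats_report("wilcoxon_signed_rank", statistic = sr$statistic,
               raw_p = sr$p, n = length(a),
               notes = if (sr$n == 0L) "all pairs tied" else "")
}

#' Signed-rank test of aided/unaided ratios against 1
#'
#' Tests whether per-subject `aided/unaided` ratios differ from unity via
#' a two-sided Wilcoxon signed-rank test on `ratio - 1`. Subjects with a
#' zero unaided value are excluded with a warning.
#'
#' @param aided,unaided numeric vectors paired by subject.
#' @return A `stats_report` (the `n` reflects subjects actually tested).
#' @export
ratio_test <- function(aided, unaided) {
  stopifnot(length(aided) == length(unaided))
  bad <- unaided == 0
  if (any(bad)) {
    warning(sum(bad), " subject(s) with zero unaided value excluded")
    aided <- aided[!bad]; unaided <- unaided[!bad]
  }
  r <- aided / unaided
  sr <- signed_rank_p(r - 1)
  stats_report("ratio_vs_unity", statistic = sr$statistic, raw_p = sr$p,
               n = length(r),
               notes = if (sr$n == 0L) "all ratios exactly 1" else "")
}

#' Rank-based comparison of dispersion between two groups
#'
#' Kruskal-Wallis H test applied to absolute deviations from each group's
#' own median (a rank-based Brown-Forsythe analogue): the deviation
#' transform removes location differences, so the H test responds to
#' spread. `raw = TRUE` applies Kruskal-Wallis to the raw values instead
#' (a location test).
#'
#' @param a,b numeric vectors (>= 3 values each).
#' @param raw apply the test to raw values rather than deviations.
#' @return A `stats_report` with the H statistic and chi-square p-value.
#' @export
kruskal_variance <- function(a, b, raw = FALSE) {
  stopifnot(length(a) >= 3L, length(b) >= 3L)
  xa <- if (raw) a else abs(a - median(a))
  xb <- if (raw) b else abs(b - median(b))
  vals <- c(xa, xb)
  if (length(unique(vals)) == 1L)
    return(stats_report("kruskal_wallis_dispersion", statistic = 0,
                        raw_p = 1, n = length(vals),
                        notes = "degenerate: all values equal"))
  g <- factor(rep(c("a", "b"), c(length(xa), length(xb))))
  kt <- kruskal.test(vals, g)
  stats_report(if (raw) "kruskal_wallis_raw" else
                 "kruskal_wallis_dispersion",
               statistic = unname(kt$statistic), raw_p = kt$p.value,
               n = length(vals))
}

#' Uncapped Benjamini-Yekutieli adjustment
#'
#' Step-up false-discovery-rate adjustment valid under arbitrary
#' dependence: for sorted p-values, `adjusted_(i) = min over j >= i of
#' p_(j) * m * c(m) / j` with `c(m) = sum(1/(1:m))`. Unlike the common
#' convention, adjusted values are NOT capped at 1, so they can exceed 1;
#' each adjusted value is never below its raw value.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order (possibly > 1).
#' @export
by_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  stopifnot(all(p_values >= 0 & p_values <= 1))
  m <- length(p_values)
  cm <- sum(1 / seq_len(m))
  o <- order(p_values)
  ps <- p_values[o]
  scaled <- ps * m * cm / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Bisquare robust linear regression
#'
#' Iteratively reweighted least squares with Tukey bisquare weights
#' (tuning constant 4.685 on a MAD-based scale), as implemented by
#' `MASS::rlm`. The slope p-value comes from the robust t statistic on
#' `n - 2` degrees of freedom. A numerically exact linear relation (robust
#' scale ~ 0) falls back to ordinary least squares.
#'
#' @param x,y numeric vectors (n >= 4); `x` must have nonzero variance.
#' @return A list: `slope`, `intercept`, `p` (slope test), `r`
#'   (descriptive Pearson correlation), `n`.
#' @export
robust_regress <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4L)
  if (var(x) == 0) stop("zero variance in x; slope undefined")
  n <- length(x)
  ols <- lm(y ~ x)
  res_scale <- mad(ols$residuals)
  if (res_scale <= 1e-10 * max(mad(y), abs(mean(y)), 1)) {
    # numerically exact linear relation
    cf <- coef(ols)
    return(list(slope = unname(cf[2L]), intercept = unname(cf[1L]),
                p = 0, r = cor(x, y), n = n))
  }
  fit <- tryCatch(
    suppressWarnings(MASS::rlm(y ~ x, psi = MASS::psi.bisquare, c = 4.685,
                               scale.est = "MAD", maxit = 50)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) fit <- ols
  cf <- coef(fit)
  tval <- summary(fit)$coefficients[2L, 3L]  # slope t value (lm and rlm)
  list(slope = unname(cf[2L]), intercept = unname(cf[1L]),
       p = 2 * pt(-abs(tval), df = n - 2),
       r = cor(x, y), n = n)
}

#' Exact sign test for presentation-order effects
#'
#' Exact binomial sign test on `sign(first - second)` with ties dropped:
#' did the condition heard first yield systematically different values
#' than the condition heard second?
#'
#' @param first,second numeric vectors paired by subject: the value from
#'   the condition presented first resp. second.
#' @return A `stats_report` (statistic = number of positive differences).
#' @export
order_effect_sign_test <- function(first, second) {
  stopifnot(length(first) == length(second))
  d <- first - second
  d <- d[d != 0]
  if (length(d) == 0L)
    return(stats_report("order_sign_test", statistic = 0, raw_p = 1,
                        n = 0L, notes = "all ties"))
  k <- sum(d > 0)
  bt <- binom.test(k, length(d), p = 0.5)
  stats_report("order_sign_test", statistic = k, raw_p = bt$p.value,
               n = length(d))
}

#' Cross-band association of decoder performance
#'
#' For each condition (and for aided/unaided ratios), fits the pairwise
#' associations between per-subject mean reconstruction correlations
#' across bands (delta-wide, theta-wide, delta-theta) with
#' [robust_regress()], and adjusts the slope p-values of all nine tests as
#' one Benjamini-Yekutieli family. Subjects missing any band are dropped
#' with a warning.
#'
#' @param records data.frame with columns `subject_id`, `band`
#'   (delta/theta/wide), `condition` (aided/unaided), `mean_r`.
#' @return data.frame: `comparison`, `pair`, `pearson_r`, `slope`,
#'   `raw_p`, `adjusted_p`, `n`.
#' @export
band_cross_correlation <- function(records) {
  need <- c("subject_id", "band", "condition", "mean_r")
  stopifnot(all(need %in% names(records)))
  subs <- sort(unique(records$subject_id))
  get_vec <- function(band, cond) {
    sel <- records$band == band & records$condition == cond
    v <- setNames(records$mean_r[sel], records$subject_id[sel])
    unname(v[as.character(subs)])
  }
  tab <- list()
  for (cond in c("aided", "unaided"))
    for (b in c("delta", "theta", "wide"))
      tab[[paste(b, cond, sep = ".")]] <- get_vec(b, cond)
  complete <- Reduce(`&`, lapply(tab, function(v) !is.na(v)))
  if (any(!complete))
    warning(sum(!complete), " subject(s) missing a band/condition dropped")
  tab <- lapply(tab, `[`, complete)
  pairs <- list(c("delta", "wide"), c("theta", "wide"), c("delta", "theta"))
  rows <- list()
  for (cond in c("aided", "unaided")) {
    for (pr in pairs) {
      f <- robust_regress(tab[[paste(pr[1L], cond, sep = ".")]],
                          tab[[paste(pr[2L], cond, sep = ".")]])
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = cond, pair = paste(pr, collapse = "-"),
        pearson_r = f$r, slope = f$slope, raw_p = f$p, n = f$n)
    }
  }
  ratio <- lapply(c(delta = "delta", theta = "theta", wide = "wide"),
                  function(b) tab[[paste0(b, ".aided")]] /
                    tab[[paste0(b, ".unaided")]])
  for (pr in pairs) {
    f <- robust_regress(ratio[[pr[1L]]], ratio[[pr[2L]]])
    rows[[length(rows) + 1L]] <- data.frame(
      comparison = "ratio", pair = paste(pr, collapse = "-"),
      pearson_r = f$r, slope = f$slope, raw_p = f$p, n = f$n)
  }
  out <- do.call(rbind, rows)
  out$adjusted_p <- by_adjust(out$raw_p)
  out
}

#' Apply a BY family adjustment to a list of stats reports
#'
#' @param reports list of `stats_report` objects forming one adjustment
#'   family (typically the tests of one figure/table).
#' @return The list with `adjusted_p` filled in.
#' @export
adjust_family <- function(reports) {
  adj <- by_adjust(vapply(reports, `[[`, 0, "raw_p"))
  Map(function(r, a) { r$adjusted_p <- a; r }, reports, adj)
}
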