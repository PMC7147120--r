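test_that("paired signed-rank test matches exact enumeration for n <= 8", {
  set.seed(51)
  for (n in 5:8) {
    for (rep in 1:5) {
      a <- rnorm(n); b <- rnorm(n)
      expect_equal(paired_wilcoxon(a, b)$raw_p, brute_signed_rank_p(a - b),
                   tolerance = 1e-12)
    }
  }
  # reversed sequence example: enumeration over all 2^6 sign patterns
  a <- 1:6; b <- 6:1
  expect_equal(paired_wilcoxon(a, b)$raw_p, brute_signed_rank_p(a - b),
               tolerance = 1e-12)
})

test_that("signed-rank edge cases: ties, all-positive shifts", {
  a <- rnorm(8)
  expect_equal(paired_wilcoxon(a, a)$raw_p, 1)
  # n = 16 uniform shift: exact all-positive tail despite tied magnitudes
  a16 <- rnorm(16)
  expect_equal(paired_wilcoxon(a16 + 1, a16)$raw_p, 2 / 2^16,
               tolerance = 1e-12)
  # beyond the enumeration limit the standard machinery takes over
  a20 <- rnorm(20); b20 <- rnorm(20)
  expect_equal(paired_wilcoxon(a20, b20)$raw_p,
               wilcox.test(a20, b20, paired = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("ratio test compares aided/unaided ratios against unity", {
  u <- abs(rnorm(10)) + 0.5
  expect_equal(ratio_test(u, u)$raw_p, 1)
  expect_equal(ratio_test(2 * u, u)$raw_p, 2 / 2^10, tolerance = 1e-12)
  expect_warning(r <- ratio_test(c(1, 1, 1, 1, 1, 1), c(1, 0, 1, 1, 2, 1)),
                 "excluded")
  expect_identical(r$n, 5L)
})

test_that("ratio test holds its size under a log-symmetric null", {
  set.seed(52)
  rej <- mean(replicate(500, {
    ratios <- exp(rnorm(16, 0, 0.3))
    ratio_test(ratios, rep(1, 16))$raw_p < 0.05
  }))
  expect_gt(rej, 0.01)
  expect_lt(rej, 0.10)
})

test_that("rank dispersion test ignores location and detects spread", {
  x <- rnorm(17)
  expect_equal(kruskal_variance(x, x)$statistic, 0, tolerance = 1e-12)

  set.seed(53)
  loc_rej <- mean(replicate(300, {
    kruskal_variance(rnorm(17), rnorm(17) + 2)$raw_p < 0.05
  }))
  expect_lt(loc_rej, 0.12)   # location shifts do not trigger it

  pow <- mean(replicate(100, {
    kruskal_variance(rnorm(17), 10 * rnorm(17))$raw_p < 0.05
  }))
  expect_gt(pow, 0.9)        # ten-fold spread difference is caught

  # literal reading: raw-value Kruskal-Wallis responds to location
  raw_rej <- mean(replicate(200, {
    kruskal_variance(rnorm(10), rnorm(10) + 2, raw = TRUE)$raw_p < 0.05
  }))
  expect_gt(raw_rej, 0.9)
})

test_that("uncapped BY adjustment follows the step-up definition", {
  expect_equal(by_adjust(0.2), 0.2)                       # m = 1 unchanged
  expect_equal(by_adjust(c(0.01, 0.02, 0.03)),
               c(0.055, 0.055, 0.055), tolerance = 1e-12)
  over <- by_adjust(c(0.9, 0.95))
  expect_true(all(over > 1))                              # never capped
  # step-up minimum: min(0.9*3, 0.95*1.5) applies to both positions
  expect_equal(over, c(1.425, 1.425), tolerance = 1e-12)
  expect_length(by_adjust(numeric(0)), 0L)

  set.seed(54)
  for (rep in 1:20) {
    p <- runif(sample(1:8, 1))
    adj <- by_adjust(p)
    expect_equal(adj, brute_by(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(!is.unsorted(adj[order(p)]))              # monotone
    # capping recovers the standard implementation
    expect_equal(pmin(adj, 1), p.adjust(p, method = "BY"),
                 tolerance = 1e-12)
  }
})

test_that("bisquare regression resists outliers and finds exact lines", {
  fit <- robust_regress(1:10, 2 * (1:10) + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-8)
  expect_equal(fit$intercept, 1, tolerance = 1e-8)

  set.seed(55)
  x <- rnorm(15)
  y <- 1 + 0.5 * x + rnorm(15, 0, 0.05)
  y[15] <- y[15] + 8                         # one gross outlier
  rob <- robust_regress(x, y)
  clean <- coef(lm(y[-15] ~ x[-15]))[2]
  expect_equal(rob$slope, unname(clean), tolerance = 0.05)

  expect_error(robust_regress(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("bisquare slope test holds its size under independence", {
  set.seed(56)
  rej <- mean(replicate(300, {
    robust_regress(rnorm(20), rnorm(20))$p < 0.05
  }))
  expect_gt(rej, 0.01)
  expect_lt(rej, 0.12)
})

test_that("sign test reproduces exact binomial tails", {
  first <- c(rep(1, 8), rep(-1, 8)); second <- rep(0, 16)
  expect_equal(order_effect_sign_test(first, second)$raw_p, 1)
  expect_equal(order_effect_sign_test(rep(1, 16), rep(0, 16))$raw_p,
               2 / 2^16, tolerance = 1e-12)
  p12 <- order_effect_sign_test(c(rep(1, 12), rep(-1, 4)), rep(0, 16))
  expect_equal(p12$raw_p, 2 * sum(choose(16, 12:16)) / 2^16,
               tolerance = 1e-12)
  expect_equal(p12$raw_p, 0.0768, tolerance = 1e-3)
  allties <- order_effect_sign_test(rep(1, 6), rep(1, 6))
  expect_equal(allties$raw_p, 1)
  expect_identical(allties$n, 0L)
})

test_that("band cross-correlation forms one nine-test BY family", {
  set.seed(57)
  subs <- sprintf("S%02d", 1:12)
  base <- expand.grid(subject_id = subs,
                      band = c("delta", "theta", "wide"),
                      condition = c("aided", "unaided"),
                      stringsAsFactors = FALSE)
  base$mean_r <- rnorm(nrow(base), 0.15, 0.05)
  # make wide an exact duplicate of delta within each condition
  for (cond in c("aided", "unaided")) {
    d <- base$band == "delta" & base$condition == cond
    w <- base$band == "wide" & base$condition == cond
    base$mean_r[w] <- base$mean_r[d]
  }
  out <- band_cross_correlation(base)
  expect_identical(nrow(out), 9L)
  dw <- out[out$pair == "delta-wide" & out$comparison == "aided", ]
  expect_equal(dw$pearson_r, 1, tolerance = 1e-12)
  expect_true(all(out$adjusted_p >= out$raw_p))

  # dropping one subject shrinks n but nothing else breaks
  smaller <- band_cross_correlation(base[base$subject_id != "S01", ])
  expect_identical(nrow(smaller), 9L)
  expect_true(all(smaller$n == 11))

  # a subject with a missing band is dropped with a warning
  expect_warning(dropped <- band_cross_correlation(base[-1, ]), "dropped")
  expect_true(all(dropped$n == 11))
})

test_that("independent bands rarely reach adjusted significance", {
  set.seed(58)
  hits <- replicate(60, {
    tab <- expand.grid(subject_id = sprintf("S%02d", 1:12),
                       band = c("delta", "theta", "wide"),
                       condition = c("aided", "unaided"),
                       stringsAsFactors = FALSE)
    tab$mean_r <- rnorm(nrow(tab), 0.15, 0.05)
    mean(band_cross_correlation(tab)$adjusted_p < 0.05)
  })
  expect_lte(mean(hits), 0.05)
})

test_that("family adjustment decorates stats reports in place", {
  reports <- list(paired_wilcoxon(rnorm(8), rnorm(8)),
                  order_effect_sign_test(rnorm(8), rnorm(8)))
  adj <- adjust_family(reports)
  expect_equal(vapply(adj, `[[`, 0, "adjusted_p"),
               by_adjust(vapply(reports, `[[`, 0, "raw_p")),
               tolerance = 1e-12)
})
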