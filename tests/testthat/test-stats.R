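test_that("signed-rank z matches the exact enumeration oracle for small n", {
  a <- c(1.3, 0.9, 2.1, 1.7, 2.6, 0.4, 1.1, 1.9, 0.2, 1.5)
  b <- c(0.8, 1.0, 1.2, 1.1, 1.9, 0.6, 0.5, 1.2, 0.4, 0.9)
  res <- wilcoxon_signed_rank(a, b)

  # brute force: exact null distribution of W over all sign assignments
  d <- a - b
  r <- rank(abs(d))
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_null <- signs %*% r
  p_exact <- mean(abs(W_null - n * (n + 1) / 4) >= abs(res$W - n * (n + 1) / 4))
  expect_lt(abs(res$p - p_exact), 0.03)  # normal approximation error
  expect_equal(res$W, sum(r[d > 0]))
  # direction and symmetry
  expect_gt(res$z, 0)
  expect_equal(wilcoxon_signed_rank(b, a)$z, -res$z)
  expect_warning(w0 <- wilcoxon_signed_rank(a, a), "zero")
  expect_equal(w0$z, 0)
  # agreement with the standard implementation's statistic
  expect_equal(res$W, unname(suppressWarnings(wilcox.test(a, b, paired = TRUE))$statistic))
})

test_that("effect sizes reproduce the printed statistic pairs", {
  expect_equal(effect_size_r(4.108, 22), 0.619, tolerance = 2e-3)
  expect_equal(effect_size_r(2.642, 22), 0.398, tolerance = 2e-3)
  expect_equal(effect_size_r(3.945, 22), 0.595, tolerance = 2e-3)
  expect_equal(effect_size_r(-3.457, 22), -0.521, tolerance = 2e-3)
  expect_equal(effect_size_r(0, 100), 0)
  expect_equal(cohens_d_paired(7.938, 22), 1.692, tolerance = 2e-3)
  expect_equal(cohens_d_paired(-3.765, 22), -0.803, tolerance = 2e-3)
  expect_equal(cohens_d_paired(0, 10), 0)
})

test_that("eta squared is the bounded sum-of-squares ratio", {
  expect_equal(eta_squared(0, 10), 0)
  expect_equal(eta_squared(10, 10), 1)
  expect_equal(eta_squared(0.16, 10), 0.016)
  expect_error(eta_squared(2, 0), "ss_total")
  expect_error(eta_squared(11, 10), "ss_effect")
})

test_that("BCa interval behaves on constants, skewed data and seeds", {
  x <- withr::with_seed(4, rexp(80))
  expect_warning(ci_const <- bca_bootstrap_ci(function(v) 1, x, n_boot = 200,
                                              seed = 1),
                 "degenerate")
  expect_equal(unname(ci_const[1:2]), c(1, 1))

  ci1 <- bca_bootstrap_ci(mean, x, n_boot = 2000, seed = 9)
  ci2 <- bca_bootstrap_ci(mean, x, n_boot = 2000, seed = 9)
  expect_identical(ci1, ci2)
  expect_true(ci1[1] < mean(x) && mean(x) < ci1[2])
  expect_equal(attr(ci1, "type"), "bca")
  # skewed data: BCa shifts the interval relative to percentile
  expect_error(bca_bootstrap_ci(mean, x, n_boot = 50), "n_boot")
})

test_that("median percentile CI uses resampled medians", {
  expect_equal(as.numeric(median_percentile_ci(rep(3, 10), n_boot = 500, seed = 1)),
               c(3, 3))
  x <- withr::with_seed(8, rexp(60))
  ci <- median_percentile_ci(x, seed = 2)
  expect_true(ci[1] <= median(x) && median(x) <= ci[2])
  expect_identical(ci, median_percentile_ci(x, seed = 2))
})

test_that("the ranked GLME recovers an uncertainty effect with correct coding", {
  tabs <- lapply(1:6, function(p) {
    tab <- make_table(n = 60, seed = 30 + p)
    gt <- ground_truth(tab)$trials
    data.frame(participant = paste0("p", p), condition = gt$condition,
               rt = tab$rt, d = abs(gt$d))
  })
  df <- do.call(rbind, tabs)
  fit <- ranked_glme(df, response = "rt", predictor = "d")
  co <- fit$coefficients
  # condition coding: 3 dummies with No-Adapt-See as the reference
  expect_equal(sum(grepl("^condition", rownames(co))), 3L)
  expect_false(any(grepl("NoAdaptSee", rownames(co))))
  # longer RTs at smaller |d|: negative ranked-|d| fixed effect
  expect_lt(co["x", "t"], -4)
  expect_true(is.finite(fit$AIC) && is.finite(fit$BIC))
  expect_error(ranked_glme(df[df$participant == "p1", ], "rt", "d"),
               "participants")
})

test_that("the ranked GLME type-I error is consistent with its nominal level", {
  # shuffled predictors: |t| < 2.58 in about 99% of fits
  n_rep <- 60
  exceed <- withr::with_seed(17, {
    sum(vapply(seq_len(n_rep), function(i) {
      df <- do.call(rbind, lapply(1:4, function(p) {
        data.frame(participant = paste0("p", p), condition = "NoAdaptSee",
                   y = rnorm(40), x = rnorm(40))
      }))
      fit <- ranked_glme(df, response = "y", predictor = "x")
      abs(fit$coefficients["x", "t"]) > 2.58
    }, logical(1)))
  })
  # exact binomial upper band for a 1% rate at n_rep fits
  expect_lte(exceed, qbinom(0.999, n_rep, 0.01) + 1)
})
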