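test_that("psychometric probability follows the lapse-scaled Gaussian CDF", {
  expect_equal(psychometric_prob(0.1, mu = 0.1, sigma = 0.04), 0.5)
  expect_equal(psychometric_prob(-50, mu = 0, sigma = 0.05, lambda = 0.3), 0.15)
  expect_equal(psychometric_prob(0.05, 0, 0.05), pnorm(1), tolerance = 1e-12)
  expect_error(psychometric_prob(0, 0, -1), "sigma")

  # non-decreasing and point-symmetric about (mu, 1/2)
  s <- seq(-0.3, 0.3, length.out = 101)
  p <- psychometric_prob(s, 0.03, 0.05, 0.1)
  expect_true(all(diff(p) >= 0))
  expect_equal(p + psychometric_prob(2 * 0.03 - s, 0.03, 0.05, 0.1),
               rep(1, length(s)))
})

test_that("grid MLE equals a brute-force scan and beats no continuous refit", {
  tab <- make_table(n = 60, seed = 12, conditions = "NoAdaptSee")
  grid <- psychometric_grid(n_points = 15, mu_range = c(-0.15, 0.15),
                            sigma_range = c(0.01, 0.2))
  fit <- fit_psychometric(tab, grid)

  # brute force over the full 3-d grid
  sub <- tab
  r <- as.integer(sub$choice == 1)
  best <- -Inf
  for (l in grid$lambda) for (m in grid$mu) for (sg in grid$sigma) {
    p <- psychometric_prob(sub$s, m, sg, l)
    ll <- sum(log(ifelse(r == 1, p, 1 - p)))
    if (ll > best) best <- ll
  }
  expect_equal(fit$logLik, best, tolerance = 1e-10)

  # a continuous optimizer from the grid optimum can only match or improve,
  # and stays within about one grid step of the grid solution
  nll <- function(par) {
    p <- psychometric_prob(sub$s, par[1], exp(par[2]), plogis(par[3]) * 0.3)
    -sum(log(ifelse(r == 1, p, 1 - p)))
  }
  cont <- optim(c(fit$params$mu, log(fit$params$sigma),
                  qlogis(min(max(fit$lambda / 0.3, 1e-6), 1 - 1e-6))), nll)
  expect_gte(-cont$value, fit$logLik - 1e-6)
  mu_step <- diff(grid$mu)[1]
  sigma_step <- diff(log(grid$sigma))[1]
  expect_lt(abs(cont$par[1] - fit$params$mu), 1.5 * mu_step)
  expect_lt(abs(cont$par[2] - log(fit$params$sigma)), 1.5 * sigma_step)
})

test_that("noise-free step data pin mu at the step and flag the sigma boundary", {
  df <- data.frame(participant_id = "p", condition = "NoAdaptSee",
                   s = seq(-0.3, 0.3, length.out = 60),
                   choice = ifelse(seq(-0.3, 0.3, length.out = 60) > 0, 1, -1),
                   confidence = 1, rt = 0.5)
  fit <- fit_psychometric(trial_table(df),
                          psychometric_grid(n_points = 41))
  expect_lt(abs(fit$params$mu), 0.011)
  expect_equal(fit$params$sigma, min(fit$grid$sigma))
  expect_true("NoAdaptSee:sigma" %in% fit$boundary)
})

test_that("default grids follow the two experiments' protocols", {
  g2 <- psychometric_grid("exp2")
  expect_equal(lengths(g2), c(mu = 201L, sigma = 201L, lambda = 201L))
  expect_equal(range(g2$mu), c(-0.2, 0.2))
  expect_equal(range(g2$sigma), c(1e-4, 0.2))
  g1 <- psychometric_grid("exp1")
  expect_equal(length(g1$mu), 101L)
  expect_equal(range(g1$sigma), c(0.001, 0.5))
})

test_that("bias is read off binned curve extrema with tie averaging", {
  curve <- data.frame(condition = "AdaptSee", bin = 1:5,
                      center = c(-0.2, -0.1, 0, 0.1, 0.2),
                      mean = c(0.9, 0.7, 0.5, 0.7, 0.9),
                      sem = 0, n = 11)
  expect_equal(bias_from_binned_curve(curve, "min_confidence")[["AdaptSee"]], 0)
  tied <- curve
  tied$mean <- c(0.9, 0.5, 0.7, 0.5, 0.9)
  expect_equal(bias_from_binned_curve(tied, "min_confidence")[["AdaptSee"]], 0)
  rtc <- curve
  rtc$mean <- c(0.4, 0.5, 0.8, 0.5, 0.4)
  expect_equal(bias_from_binned_curve(rtc, "max_rt")[["AdaptSee"]], 0)
  expect_error(bias_from_binned_curve(curve[0, ]), "empty")
})

test_that("RT-curve bias lands within a bin width of the uncertainty minimum", {
  obs <- ground_truth_observer("insightful", mu_adapt = -0.06)
  stim <- simulate_stimuli(4000, seed = 8, conditions = "AdaptSee")
  tab <- simulate_trials(obs, stim, seed = 8)
  b <- bias_from_binned_curve(bin_curve(tab, "rt"), "max_rt")
  expect_lt(abs(b[["AdaptSee"]] - (-0.06)), 0.6 / 11)
})

test_that("compensation index normalizes the Believe shift by the See bias", {
  expect_equal(mae_compensation_index(c(AdaptSee = -0.05, AdaptBelieve = 0)), 1)
  expect_equal(mae_compensation_index(c(AdaptSee = -0.05, AdaptBelieve = -0.05)), 0)
  expect_equal(mae_compensation_index(c(AdaptSee = -0.05, AdaptBelieve = 0.025)), 1.5)
  expect_error(mae_compensation_index(c(AdaptSee = 0, AdaptBelieve = 0.1)),
               "undefined")
})
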