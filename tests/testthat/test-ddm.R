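test_that("driftless symmetric diffusion matches the closed-form first passage", {
  p0 <- ddm_params(drift_gain = 0, bound = 1.5, t_nd = 0)
  sim <- simulate_ddm(p0, rep(0, 8000), dt = 2e-4, seed = 2, max_t = 30)
  expect_true(all(!sim$censored))
  p_up <- mean(sim$choice == 1)
  expect_lt(abs(p_up - 0.5), 3 * sqrt(0.25 / 8000))
  # E[T] = B^2 for unit noise, symmetric bounds, central start
  expect_lt(abs(mean(sim$rt) - 1.5^2), 0.12)
})

test_that("Fokker-Planck propagation conserves probability and matches the series", {
  for (pars in list(c(drift = 1.2, B = 1.2, z = 0.3),
                    c(drift = -0.8, B = 1.5, z = 0),
                    c(drift = 0, B = 1, z = -0.4))) {
    fp <- insightobs:::fp_first_passage_cpp(pars[["drift"]], pars[["B"]],
                                            pars[["z"]], 0.01, 5e-4, 3)
    total <- fp$survivor_mass + sum(fp$g_up + fp$g_low) * 5e-4
    expect_lt(abs(total - 1), 1e-3)

    params <- ddm_params(drift_gain = 1, bound = pars[["B"]], t_nd = 0,
                         z = pars[["z"]])
    tt <- seq(0.1, 2.5, by = 0.1)
    up <- insightobs:::ddm_choice_density(tt, pars[["drift"]], params, 1)
    lo <- insightobs:::ddm_choice_density(tt, pars[["drift"]], params, -1)
    expect_lt(max(abs(up - approx(fp$t, fp$g_up, tt)$y)), 5e-3)
    expect_lt(max(abs(lo - approx(fp$t, fp$g_low, tt)$y)), 5e-3)
  }
})

test_that("the analytic likelihood agrees with an Euler simulation histogram", {
  params <- ddm_params(drift_gain = 8, bound = 1.3, t_nd = 0, z = 0.2)
  s <- 0.12
  sim <- simulate_ddm(params, rep(s, 40000), dt = 1e-4, seed = 6, max_t = 20)
  drift <- insightobs:::ddm_drift(s, params)
  breaks <- seq(0, 4, by = 0.2)
  for (ch in c(-1, 1)) {
    rt <- sim$rt[sim$choice == ch]
    emp <- hist(rt[rt < 4], breaks = breaks, plot = FALSE)$counts / nrow(sim) / 0.2
    mids <- breaks[-1] - 0.1
    ana <- insightobs:::ddm_choice_density(mids, drift, params, ch)
    expect_lt(max(abs(emp - ana)), 0.12)  # binning + Euler discretization error
  }
  # both likelihood routes agree on real trial data
  tab <- data.frame(s = rep(s, 300), choice = sim$choice[1:300],
                    rt = pmin(sim$rt[1:300], 2.9))
  expect_equal(ddm_likelihood(tab, params, method = "analytic"),
               ddm_likelihood(tab, params, method = "fp"), tolerance = 5e-3)
})

test_that("the likelihood is robust to RTs below the nondecision time", {
  params <- ddm_params(drift_gain = 5, bound = 1.2, t_nd = 0.5)
  tab <- data.frame(s = 0.1, choice = 1, rt = 0.3)  # rt < t_nd
  ll <- ddm_likelihood(tab, params)
  expect_true(is.finite(ll))
  expect_equal(ll, log(1e-10))
  expect_error(ddm_likelihood(data.frame(s = 0, choice = 1, rt = 3.5), params),
               "trim")
})

test_that("nondecision time is recovered from unbiased trials", {
  truth <- ddm_params(drift_gain = 9, bound = 1.3, t_nd = 0.4)
  st <- withr::with_seed(5, runif(1000, -0.3, 0.3))
  sim <- simulate_ddm(truth, st, dt = 5e-4, seed = 5)
  tab <- data.frame(condition = "NoAdaptSee", s = st, choice = sim$choice,
                    rt = sim$rt)[!sim$censored, ]
  fit <- fit_ddm(tab, "base", seed = 2, n_gen = 40)
  expect_lt(abs(fit$param_table$t_nd - 0.4), 0.05)
  expect_lt(abs(fit$param_table$bound - 1.3), 0.25)
})

test_that("adding a free starting point does not help symmetric data", {
  truth <- ddm_params(drift_gain = 8, bound = 1.3, t_nd = 0.3)
  st <- withr::with_seed(7, runif(400, -0.3, 0.3))
  sim <- simulate_ddm(truth, st, dt = 5e-4, seed = 7)
  tab <- data.frame(condition = "NoAdaptSee", s = st, choice = sim$choice,
                    rt = sim$rt)[!sim$censored, ]
  base <- fit_ddm(tab, "base", seed = 3, n_gen = 40)
  zfree <- fit_ddm(tab, "starting_point", seed = 3, n_gen = 40)
  expect_gt(zfree$BIC, base$BIC - 2)
  expect_lt(abs(zfree$param_table$z), 0.12)
})

test_that("conditional response functions expose the bias signatures", {
  zmod <- ddm_params(drift_gain = 8, bound = 1.5, t_nd = 0.3, z = 0.45)
  dmod <- ddm_params(drift_gain = 8, bound = 1.5, t_nd = 0.3, drift_bias = 0.15)
  n <- 20000
  for (m in list(zmod, dmod)) {
    sim <- simulate_ddm(m, rep(0, n), dt = 5e-4, seed = 9)
    tab <- data.frame(condition = "AdaptBelieve", s = 0, choice = sim$choice,
                      rt = sim$rt)[!sim$censored, ]
    crf <- conditional_response_function(tab)
    expect_equal(nrow(crf), 5L)
    if (identical(m, zmod)) {
      # starting-point bias: strongest in the fastest quantile, decaying
      expect_gt(crf$prop_clockwise[1], 0.8)
      expect_gt(crf$prop_clockwise[1] - crf$prop_clockwise[5], 0.25)
      expect_true(all(diff(crf$prop_clockwise) < 0.05))
    } else {
      # drift-rate bias: persists across quantiles
      expect_true(all(crf$prop_clockwise > 0.6))
      expect_lt(crf$prop_clockwise[1] - crf$prop_clockwise[5], 0.25)
    }
  }
  # unbiased diffusion: all quantile bins near one half
  sim <- simulate_ddm(ddm_params(drift_gain = 8, bound = 1.5, t_nd = 0.3),
                      rep(0, n), dt = 5e-4, seed = 9)
  tab <- data.frame(condition = "NoAdaptSee", s = 0, choice = sim$choice,
                    rt = sim$rt)[!sim$censored, ]
  crf <- conditional_response_function(tab)
  expect_true(all(abs(crf$prop_clockwise - 0.5) < 0.03))
})
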