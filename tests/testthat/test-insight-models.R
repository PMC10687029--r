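default_spec <- function(...) {
  bayes_observer_spec("mu_likelihood", mu_encoding = c(0, -0.1),
                      sigma_encoding = 0.05, ...)
}

test_that("the decision variable is symmetric, monotone and never NaN", {
  spec <- default_spec(mu_likelihood = 0.07)
  # at x = -mu_likelihood the category integrals cancel
  expect_equal(decision_variable(-0.07, spec, "AdaptBelieve"), 0,
               tolerance = 1e-10)
  x <- seq(-0.6, 0.6, length.out = 201)
  d <- decision_variable(x, spec, "AdaptBelieve")
  expect_true(all(is.finite(d)))
  expect_true(all(diff(d) > 0))
  # extreme measurements keep d finite and strongly signed
  dx <- decision_variable(c(-50, 50), spec, "AdaptBelieve")
  expect_true(all(is.finite(dx)) && dx[1] < -1e3 && dx[2] > 1e3)
  # a tilted prior adds its log odds at the symmetry point
  tilted <- bayes_observer_spec("prior", mu_encoding = c(0, -0.1),
                                sigma_encoding = 0.05, prior = 0.6)
  expect_equal(decision_variable(0, tilted, "AdaptSee"), qlogis(0.6),
               tolerance = 1e-10)
})

test_that("closed form matches the double-integral oracle across a grid", {
  for (mu_l in c(-0.05, 0, 0.1)) {
    for (sg in c(0.02, 0.08)) {
      spec <- bayes_observer_spec("mu_likelihood", mu_encoding = c(0, -0.1),
                                  sigma_encoding = sg, mu_likelihood = mu_l)
      x <- c(-0.21, -0.07, 0.013, 0.11, 0.19)
      d1 <- decision_variable(x, spec, "AdaptBelieve")
      d2 <- decision_variable_oracle(x, spec, "AdaptBelieve", sigma_A = 1e-6)
      expect_equal(d1, d2, tolerance = 1e-4)
    }
  }
})

test_that("offset uncertainty shrinks the evidence toward zero", {
  spec <- default_spec()
  x <- c(-0.15, -0.05, 0.05, 0.15)
  d0 <- decision_variable_oracle(x, spec, "AdaptSee", sigma_A = 1e-6)
  d1 <- decision_variable_oracle(x, spec, "AdaptSee", sigma_A = 0.05)
  expect_true(all(abs(d1) < abs(d0)))
  expect_equal(sign(d1), sign(d0))
  # the symmetry point stays at zero for any sigma_A
  expect_equal(decision_variable_oracle(0, spec, "AdaptSee", 0.05), 0,
               tolerance = 1e-8)
})

test_that("respond thresholds choice and confidence as specified", {
  spec <- default_spec(k_confidence = 0.85)
  r <- respond(0, spec, "NoAdaptSee")
  expect_equal(r$choice, -1L)           # strict inequality at d = k_choice
  expect_equal(r$confidence_value, 0.5)
  expect_equal(r$q, 0L)

  r <- respond(2, spec, "NoAdaptSee")
  expect_equal(r$confidence_value, plogis(2), tolerance = 1e-12)
  expect_equal(r$q, 1L)

  late <- bayes_observer_spec("k_choice", mu_encoding = c(0, -0.1),
                              sigma_encoding = 0.05, k_choice = -2)
  expect_equal(respond(-1, late, "AdaptBelieve")$choice, 1L)

  # confidence is strictly increasing in |d|
  conf <- respond(c(-3, -1, 0, 1, 3), spec, "NoAdaptSee")$confidence_value
  expect_true(all(diff(conf[3:5]) > 0) && conf[1] > conf[2])

  # the k_choice_confidence variant shifts the confidence computation too
  kc <- bayes_observer_spec("k_choice_confidence", mu_encoding = c(0, -0.1),
                            sigma_encoding = 0.05, k_choice = 1.5,
                            k_confidence = 0.7)
  expect_equal(respond(1.5, kc, "AdaptBelieve")$confidence_value, 0.5)
})

test_that("sampled response probabilities behave and match quadrature", {
  spec <- default_spec()
  p <- predict_response_probs(0.05, spec, "NoAdaptSee", n_samples = 500, seed = 2)
  expect_equal(sum(p), 1, tolerance = 3 / 500)

  # deterministic limit: the saturated outcome is clipped to 1 - 1/n
  tight <- bayes_observer_spec("mu_likelihood", mu_encoding = c(0, 0),
                               sigma_encoding = 1e-8)
  p <- predict_response_probs(0.2, tight, "NoAdaptSee", n_samples = 500, seed = 2)
  expect_equal(unname(p[["p1q1"]]), 1 - 1 / 500)
  expect_equal(unname(p[["m1q0"]]), 1 / 500)

  # marginal clockwise probability vs deterministic quadrature over x
  marg_quad <- function(s, spec, cond) {
    cut <- insightobs:::invert_decision_variable(0, spec, cond)
    1 - pnorm(cut, mean = s - insightobs:::mu_encoding_for(spec, cond),
              sd = spec$sigma_encoding[[cond]])
  }
  for (s in c(-0.1, 0, 0.08)) {
    p <- predict_response_probs(s, spec, "AdaptSee", n_samples = 2000, seed = 5)
    pq <- marg_quad(s, spec, "AdaptSee")
    mc_se <- sqrt(pq * (1 - pq) / 2000)
    expect_lt(abs((p[["p1q0"]] + p[["p1q1"]]) - pq), 3 * mc_se + 1e-3)
  }
})

test_that("joint log likelihood: clipping arithmetic, order invariance, fast path", {
  tab <- make_table(n = 30, seed = 4)
  spec <- ground_truth(tab)$observer$spec
  expect_equal(joint_loglikelihood(tab, spec, n_samples = 300, seed = 9),
               joint_loglikelihood(tab, spec, n_samples = 300, seed = 9,
                                   method = "naive"))
  shuffled <- tab[sample(nrow(tab)), ]
  expect_equal(joint_loglikelihood(tab, spec, seed = 9),
               joint_loglikelihood(shuffled, spec, seed = 9), tolerance = 1e-10)

  # single saturated trial: LL = log(1 - 1/n_samples)
  one <- trial_table(data.frame(participant_id = "p", condition = "NoAdaptSee",
                                s = 0.25, choice = 1, confidence = 1, rt = 0.5))
  tight <- bayes_observer_spec("mu_likelihood", mu_encoding = c(0, 0),
                               sigma_encoding = 1e-8)
  expect_equal(joint_loglikelihood(one, tight, n_samples = 500, seed = 1),
               log(1 - 1 / 500))

  # the generating parameters beat a perturbed spec on large data
  big <- make_table(n = 4000, seed = 13, conditions = c("AdaptSee", "AdaptBelieve"))
  truth_spec <- ground_truth(big)$observer$spec
  worse <- truth_spec
  worse$mu_likelihood[["AdaptBelieve"]] <- 0.15
  expect_gt(joint_loglikelihood(big, truth_spec, seed = 2),
            joint_loglikelihood(big, worse, seed = 2))
})

test_that("insight signature holds at the level of predicted curves", {
  # increasing mu_likelihood shifts choice PSE and confidence minimum in
  # tandem; increasing k_choice shifts the choice PSE only
  s_grid <- seq(-0.25, 0.25, length.out = 41)
  curve <- function(spec, cond) {
    probs <- vapply(s_grid, function(s) {
      p <- predict_response_probs(s, spec, cond, n_samples = 4000, seed = 3)
      c(p[["p1q0"]] + p[["p1q1"]], p[["m1q1"]] + p[["p1q1"]])
    }, numeric(2))
    list(pse = approx(probs[1, ], s_grid, xout = 0.5, ties = "ordered")$y,
         conf_min = s_grid[which.min(probs[2, ])])
  }
  base <- default_spec()
  ins <- default_spec(mu_likelihood = c(0, 0, 0, -0.1))
  late <- bayes_observer_spec("k_choice", mu_encoding = c(0, -0.1),
                              sigma_encoding = 0.05,
                              k_choice = c(0, 0, 0, 3.76))
  b <- curve(base, "AdaptBelieve")
  i <- curve(ins, "AdaptBelieve")
  l <- curve(late, "AdaptBelieve")
  step <- diff(s_grid)[1]
  # a negative mu_likelihood (matching the negative encoding offset) moves
  # the choice PSE and the confidence minimum rightward, in tandem
  expect_gt(i$pse - b$pse, 0.06)
  expect_gt(i$conf_min - b$conf_min, 0.06)
  expect_lt(abs((i$pse - b$pse) - (i$conf_min - b$conf_min)), 4 * step)
  # a positive k_choice moves the choice PSE only
  expect_gt(l$pse - b$pse, 0.06)
  expect_lt(abs(l$conf_min - b$conf_min), 4 * step)
})

test_that("prior shifts d by a constant while mu_likelihood scales with noise", {
  x <- c(-0.05, 0, 0.05)
  for (sg in c(0.03, 0.1)) {
    neutral <- bayes_observer_spec("prior", mu_encoding = c(0, 0),
                                   sigma_encoding = sg, prior = 0.5)
    tilted <- bayes_observer_spec("prior", mu_encoding = c(0, 0),
                                  sigma_encoding = sg, prior = 0.58)
    delta <- decision_variable(x, tilted, "AdaptBelieve") -
      decision_variable(x, neutral, "AdaptBelieve")
    expect_equal(delta, rep(qlogis(0.58), 3), tolerance = 1e-9)
  }
  # the mu_likelihood-induced d shift at fixed x grows as sigma shrinks
  shift_at <- function(sg) {
    a <- bayes_observer_spec("mu_likelihood", mu_encoding = c(0, 0),
                             sigma_encoding = sg, mu_likelihood = 0.05)
    b <- bayes_observer_spec("mu_likelihood", mu_encoding = c(0, 0),
                             sigma_encoding = sg)
    decision_variable(0.02, b, "AdaptSee") - decision_variable(0.02, a, "AdaptSee")
  }
  expect_gt(abs(shift_at(0.03)), abs(shift_at(0.1)))
})

test_that("information criteria and trivial model comparisons", {
  expect_equal(information_criteria(0, 0, 10), c(AIC = 0, BIC = 0))
  expect_equal(information_criteria(-100, 9, 484),
               c(AIC = 218, BIC = 200 + 9 * log(484)))
  ic <- data.frame(participant = rep(c("a", "b"), each = 2),
                   variant = rep(c("m1", "m2"), 2),
                   AIC = c(10, 12, 20, 21), BIC = c(11, 13, 21, 22))
  cmp <- compare_models(ic, reference = "m1", n_boot = 500, seed = 1)
  ref_row <- cmp[cmp$variant == "m1", ]
  expect_equal(unlist(ref_row[, -1]), c(sum_dAIC = 0, dAIC_lo = 0, dAIC_hi = 0,
                                        sum_dBIC = 0, dBIC_lo = 0, dBIC_hi = 0))
  expect_equal(cmp$sum_dAIC[cmp$variant == "m2"], 3)
  # identical ICs across variants: delta 0 regardless of resampling
  ic$AIC <- 5; ic$BIC <- 6
  cmp <- compare_models(ic, reference = "m1", n_boot = 500, seed = 1)
  expect_true(all(cmp$sum_dAIC == 0 & cmp$dAIC_lo == 0 & cmp$dAIC_hi == 0))
  ic$participant[1] <- "c"
  expect_error(compare_models(ic, reference = "m1", n_boot = 200), "match")
})

test_that("model fitting recovers an insightful observer and flags boundaries", {
  tab <- make_table(n = 121, seed = 21, conditions = c("AdaptSee", "AdaptBelieve"))
  fit <- fit_bayes_model(tab, "mu_likelihood", mu_encoding = c(0, -0.1),
                         n_starts = 6, seed = 3,
                         conditions = c("AdaptSee", "AdaptBelieve"))
  expect_lt(abs(fit$spec$mu_likelihood[["AdaptBelieve"]] - (-0.1)), 0.04)
  expect_lt(abs(fit$spec$mu_likelihood[["AdaptSee"]]), 0.04)
  expect_equal(fit$n_params, 6L)
  expect_equal(fit$AIC, -2 * fit$logLik + 12)
  truth_ll <- joint_loglikelihood(tab, ground_truth(tab)$observer$spec, seed = 3)
  expect_gte(fit$logLik, truth_ll - 1e-6)
})
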