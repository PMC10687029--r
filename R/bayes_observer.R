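#' Bayesian observer model specification
#'
#' Defines one member of the Bayesian choice-plus-confidence observer
#' family. Every variant shares the early encoding stage: the stimulus `s`
#' is encoded as a noisy internal measurement `x ~ Normal(s - A, sigma)`,
#' where `A` is an adaptation-induced offset (mean `mu_encoding`, fixed to
#' one value for No-Adapt and one for Adapt conditions). The intermediate
#' stage converts `x` into the decision variable `d`, the log-posterior
#' ratio of the two motion categories; an insightful observer subtracts an
#' assumed offset `mu_likelihood` inside the likelihood, and a prior
#' variant tilts the category prior. The late stage thresholds `d` at
#' `k_choice` for the binary choice and thresholds the posterior
#' probability of the chosen option at `k_confidence` for the binary
#' confidence report.
#'
#' @param variant one of `"mu_likelihood"`, `"prior"`,
#'   `"mu_likelihood+prior"`, `"k_choice"`, `"mu_likelihood+k_choice"`,
#'   `"k_choice_confidence"`. Controls which parameter families are free
#'   (non-neutral); neutral values are `mu_likelihood = 0`, `prior = 0.5`,
#'   `k_choice = 0`.
#' @param mu_encoding length-2 named numeric `c(NoAdapt = , Adapt = )`,
#'   fixed encoding offsets in task units.
#' @param sigma_encoding,mu_likelihood,prior,k_choice,k_confidence numeric
#'   of length 1 or 4 (one value per main condition, recycled).
#' @param category_bounds named numeric `s21, s22, s11, s12`.
#' @param conditions condition labels the per-condition parameters refer to.
#' @return An object of class `bayes_observer_spec`.
#' @export
bayes_observer_spec <- function(variant = c("mu_likelihood", "prior",
                                            "mu_likelihood+prior", "k_choice",
                                            "mu_likelihood+k_choice",
                                            "k_choice_confidence"),
                                mu_encoding = c(NoAdapt = 0, Adapt = 0),
                                sigma_encoding = 0.05,
                                mu_likelihood = 0,
                                prior = 0.5,
                                k_choice = 0,
                                k_confidence = 0.7,
                                category_bounds = c(s21 = -0.3, s22 = 0, s11 = 0, s12 = 0.3),
                                conditions = main_conditions()) {
  variant <- match.arg(variant)
  n <- length(conditions)
  expand <- function(v, name) {
    if (length(v) == 1L) v <- rep(v, n)
    if (length(v) != n) stop(name, " must have length 1 or ", n, call. = FALSE)
    stats::setNames(as.numeric(v), conditions)
  }
  spec <- structure(list(
    variant = variant,
    mu_encoding = c(NoAdapt = unname(mu_encoding[1]), Adapt = unname(mu_encoding[2])),
    sigma_encoding = expand(sigma_encoding, "sigma_encoding"),
    mu_likelihood = expand(mu_likelihood, "mu_likelihood"),
    prior = expand(prior, "prior"),
    k_choice = expand(k_choice, "k_choice"),
    k_confidence = expand(k_confidence, "k_confidence"),
    category_bounds = category_bounds,
    conditions = conditions
  ), class = "bayes_observer_spec")
  if (any(spec$sigma_encoding <= 0)) stop("sigma_encoding must be > 0", call. = FALSE)
  if (any(spec$k_confidence < 0.5 | spec$k_confidence > 1)) {
    stop("k_confidence must lie in [0.5, 1)", call. = FALSE)
  }
  if (any(spec$prior <= 0 | spec$prior >= 1)) stop("prior must lie in (0, 1)", call. = FALSE)
  spec
}

#' @export
print.bayes_observer_spec <- function(x, ...) {
  cat(sprintf("<bayes_observer_spec> variant '%s'\n", x$variant))
  cat(sprintf("  mu_encoding: NoAdapt %.4g, Adapt %.4g\n",
              x$mu_encoding[["NoAdapt"]], x$mu_encoding[["Adapt"]]))
  m <- rbind(sigma_encoding = x$sigma_encoding,
             mu_likelihood = x$mu_likelihood,
             prior = x$prior,
             k_choice = x$k_choice,
             k_confidence = x$k_confidence)
  print(round(m, 4))
  invisible(x)
}

# Which parameter families are free for a given variant (besides sigma and
# k_confidence, free in all variants).
variant_free_families <- function(variant) {
  base <- c("sigma_encoding", "k_confidence")
  extra <- switch(variant,
                  "mu_likelihood" = "mu_likelihood",
                  "prior" = "prior",
                  "mu_likelihood+prior" = c("mu_likelihood", "prior"),
                  "k_choice" = "k_choice",
                  "mu_likelihood+k_choice" = c("mu_likelihood", "k_choice"),
                  "k_choice_confidence" = "k_choice")
  c(base, extra)
}

# mu_encoding value applying to one condition label.
mu_encoding_for <- function(spec, condition) {
  unname(spec$mu_encoding[[if (is_adapt_condition(condition)) "Adapt" else "NoAdapt"]])
}

#' Decision variable of the Bayesian observer
#'
#' The log-posterior ratio of the clockwise versus counterclockwise motion
#' category given an internal measurement `x`:
#' \deqn{d = \log\frac{p(C=1)}{1-p(C=1)}
#'   + \log\frac{\Phi(s_{12}-\mu_L-x) - \Phi(s_{11}-\mu_L-x)}
#'              {\Phi(s_{22}-\mu_L-x) - \Phi(s_{21}-\mu_L-x)}}
#' with all normal CDFs zero-mean with the condition's encoding noise
#' `sigma`, and `mu_L` the observer's assumed encoding offset
#' (`mu_likelihood`; 0 for a naive observer). Evaluated in log space with
#' tail mirroring so the CDF differences never underflow to 0/0; the result
#' is finite and strictly increasing in `x`.
#'
#' @param x internal measurement(s), task units.
#' @param spec a [bayes_observer_spec()].
#' @param condition a single condition label.
#' @return Numeric vector of log-odds `d`, same length as `x`.
#' @export
decision_variable <- function(x, spec, condition) {
  sigma <- unname(spec$sigma_encoding[[condition]])
  mu_l <- unname(spec$mu_likelihood[[condition]])
  p1 <- unname(spec$prior[[condition]])
  cb <- spec$category_bounds
  log_num <- log_pnorm_diff((cb[["s11"]] - mu_l - x) / sigma,
                            (cb[["s12"]] - mu_l - x) / sigma)
  log_den <- log_pnorm_diff((cb[["s21"]] - mu_l - x) / sigma,
                            (cb[["s22"]] - mu_l - x) / sigma)
  width_term <- log((cb[["s22"]] - cb[["s21"]]) / (cb[["s12"]] - cb[["s11"]]))
  stats::qlogis(p1) + width_term + log_num - log_den
}

#' Numeric double-integral oracle for the decision variable
#'
#' Evaluates the full generative model in which the observer is uncertain
#' about the offset `A ~ Normal(mu_likelihood, sigma_A)`: each category
#' likelihood is the double integral over the category's stimulus interval
#' and over `A`, computed by nested adaptive quadrature (the `A` integral
#' after standardising `A = mu + sigma_A u`). As `sigma_A -> 0` this
#' converges to [decision_variable()].
#'
#' @inheritParams decision_variable
#' @param sigma_A offset uncertainty, >= 0 (values below 1e-12 use the
#'   delta-function limit directly).
#' @return Numeric vector of log-odds `d`.
#' @export
decision_variable_oracle <- function(x, spec, condition, sigma_A = 1e-6) {
  if (sigma_A < 0) stop("sigma_A must be >= 0", call. = FALSE)
  sigma <- unname(spec$sigma_encoding[[condition]])
  mu_l <- unname(spec$mu_likelihood[[condition]])
  p1 <- unname(spec$prior[[condition]])
  cb <- spec$category_bounds
  cat_lik <- function(xi, lo, hi) {
    if (sigma_A < 1e-12) {
      inner <- function(s) stats::dnorm(xi, mean = s - mu_l, sd = sigma)
      val <- stats::integrate(inner, lo, hi, rel.tol = 1e-10)
      return(val$value / (hi - lo))
    }
    outer_fun <- function(u) {
      vapply(u, function(ui) {
        a <- mu_l + sigma_A * ui
        inner <- function(s) stats::dnorm(xi, mean = s - a, sd = sigma)
        stats::integrate(inner, lo, hi, rel.tol = 1e-10)$value
      }, numeric(1)) * stats::dnorm(u)
    }
    val <- stats::integrate(outer_fun, -10, 10, rel.tol = 1e-8)
    if (val$message != "OK") stop("quadrature did not converge: ", val$message, call. = FALSE)
    val$value / (hi - lo)
  }
  vapply(x, function(xi) {
    num <- cat_lik(xi, cb[["s11"]], cb[["s12"]])
    den <- cat_lik(xi, cb[["s21"]], cb[["s22"]])
    stats::qlogis(p1) + log(num) - log(den)
  }, numeric(1))
}

#' Map a decision variable to choice and confidence
#'
#' The choice is clockwise (+1) iff `d > k_choice` (strict). The confidence
#' value is the posterior probability of the chosen option,
#' `1 / (1 + exp(-|d|))`; the `k_choice_confidence` variant additionally
#' shifts the confidence computation by the choice criterion, using
#' `|d - k_choice|`. The binary confidence report is high (1) iff the
#' confidence value exceeds `k_confidence` (strict).
#'
#' @param d log-odds decision variable(s).
#' @inheritParams decision_variable
#' @return A data.frame with columns `choice` (-1/+1), `confidence_value`
#'   and `q` (0/1).
#' @export
respond <- function(d, spec, condition) {
  k_choice <- unname(spec$k_choice[[condition]])
  k_conf <- unname(spec$k_confidence[[condition]])
  choice <- ifelse(d > k_choice, 1L, -1L)
  conf_arg <- if (spec$variant == "k_choice_confidence") abs(d - k_choice) else abs(d)
  confidence_value <- stats::plogis(conf_arg)
  q <- as.integer(confidence_value > k_conf)
  data.frame(choice = choice, confidence_value = confidence_value, q = q)
}

# Solve d(x) = target for x (d is strictly increasing).
invert_decision_variable <- function(target, spec, condition) {
  cb <- spec$category_bounds
  prior_term <- stats::qlogis(unname(spec$prior[[condition]])) +
    log((cb[["s22"]] - cb[["s21"]]) / (cb[["s12"]] - cb[["s11"]]))
  invert_d_cpp(target, unname(spec$sigma_encoding[[condition]]),
               unname(spec$mu_likelihood[[condition]]), prior_term,
               cb[["s11"]], cb[["s12"]], cb[["s21"]], cb[["s22"]])
}

# The four joint (choice, confidence) outcomes in fixed order.
outcome_labels <- function() c("m1q0", "m1q1", "p1q0", "p1q1")

outcome_index <- function(choice, q) {
  # (-1,0)->1, (-1,1)->2, (+1,0)->3, (+1,1)->4
  1L + as.integer(q) + 2L * as.integer(choice == 1)
}

# Measurement-space cut points partitioning x into intervals of constant
# (choice, q) outcome, plus the outcome index of each interval.
outcome_regions <- function(spec, condition) {
  k_choice <- unname(spec$k_choice[[condition]])
  k_conf <- unname(spec$k_confidence[[condition]])
  t_conf <- stats::qlogis(k_conf)  # |.| threshold in log-odds units
  targets <- if (spec$variant == "k_choice_confidence") {
    c(k_choice - t_conf, k_choice, k_choice + t_conf)
  } else {
    c(-t_conf, k_choice, t_conf)
  }
  # order 3 values without generic dispatch (hot path)
  if (targets[1] > targets[2]) targets[1:2] <- targets[2:1]
  if (targets[2] > targets[3]) targets[2:3] <- targets[3:2]
  if (targets[1] > targets[2]) targets[1:2] <- targets[2:1]
  targets <- targets[c(TRUE, targets[2] > targets[1], targets[3] > targets[2])]
  cb <- spec$category_bounds
  sigma <- unname(spec$sigma_encoding[[condition]])
  mu_l <- unname(spec$mu_likelihood[[condition]])
  prior_term <- stats::qlogis(unname(spec$prior[[condition]])) +
    log((cb[["s22"]] - cb[["s21"]]) / (cb[["s12"]] - cb[["s11"]]))
  cuts <- numeric(length(targets))
  for (i in seq_along(targets)) {
    cuts[i] <- invert_d_cpp(targets[i], sigma, mu_l, prior_term,
                            cb[["s11"]], cb[["s12"]], cb[["s21"]], cb[["s22"]])
  }
  # region outcomes follow from threshold logic directly in d space
  n_t <- length(targets)
  d_reps <- c(targets[1] - 1,
              if (n_t > 1) (targets[-n_t] + targets[-1]) / 2,
              targets[n_t] + 1)
  choice <- ifelse(d_reps > k_choice, 1L, -1L)
  conf_arg <- if (spec$variant == "k_choice_confidence") {
    abs(d_reps - k_choice)
  } else {
    abs(d_reps)
  }
  q <- as.integer(stats::plogis(conf_arg) > k_conf)
  list(cuts = cuts, outcome = outcome_index(choice, q))
}

#' Predicted response probabilities by sampling
#'
#' Approximates the marginal probability of each joint (choice, confidence)
#' outcome at stimulus `s` by simulating `n_samples` internal measurements
#' `x ~ Normal(s - mu_encoding, sigma_encoding)` and mapping each through
#' [respond()]. Outcome probabilities of exactly 0 or 1 are clipped to
#' `1/n_samples` and `1 - 1/n_samples` respectively.
#'
#' @param s stimulus value (scalar).
#' @inheritParams decision_variable
#' @param n_samples number of measurement samples (default 500).
#' @param seed integer seed (common random numbers across calls).
#' @return Named numeric of length 4 over outcomes `m1q0` (choice -1, low),
#'   `m1q1`, `p1q0`, `p1q1` (choice +1, high).
#' @export
predict_response_probs <- function(s, spec, condition, n_samples = 500L, seed = 1L) {
  stopifnot(n_samples >= 1)
  z <- with_seed(substream_seed(seed, paste0("probs_", condition)),
                 stats::rnorm(n_samples))
  x <- s - mu_encoding_for(spec, condition) + spec$sigma_encoding[[condition]] * z
  resp <- respond(decision_variable(x, spec, condition), spec, condition)
  idx <- outcome_index(resp$choice, resp$q)
  p <- tabulate(idx, nbins = 4L) / n_samples
  p <- clip_probs(p, n_samples)
  stats::setNames(p, outcome_labels())
}

# Replace extreme outcome probabilities (0 or 1) as specified.
clip_probs <- function(p, n_samples) {
  p[p == 0] <- 1 / n_samples
  p[p == 1] <- 1 - 1 / n_samples
  p
}

# Fast per-trial outcome probabilities using the interval structure of the
# decision rule: d(x) is strictly increasing, so each outcome occupies a
# contiguous x-interval delimited by at most 3 cuts. Z is a fixed matrix of
# standard-normal draws (n_trials x n_samples), giving common random
# numbers across likelihood evaluations.
outcome_probs_matrix <- function(s, spec, condition, Z, sorted = FALSE) {
  regions <- outcome_regions(spec, condition)
  mu_shift <- s - mu_encoding_for(spec, condition)
  sigma <- unname(spec$sigma_encoding[[condition]])
  n_samples <- ncol(Z)
  if (sorted) {
    # rows of Z pre-sorted once per fit: counting is a binary search
    thr <- vapply(regions$cuts, function(cut) (cut - mu_shift) / sigma,
                  numeric(nrow(Z)))
    if (is.null(dim(thr))) thr <- matrix(thr, nrow = 1)
    counts_below <- count_below_sorted_cpp(Z, thr)
  } else {
    counts_below <- vapply(regions$cuts, function(cut) {
      as.numeric(count_below_cpp(Z, (cut - mu_shift) / sigma))
    }, numeric(nrow(Z)))
    if (is.null(dim(counts_below))) counts_below <- matrix(counts_below, nrow = 1)
  }
  n_regions <- length(regions$cuts) + 1L
  P <- matrix(0, nrow(Z), 4L)
  prev <- 0
  for (r in seq_len(n_regions)) {
    cnt <- if (r <= length(regions$cuts)) counts_below[, r] else n_samples
    P[, regions$outcome[r]] <- P[, regions$outcome[r]] + (cnt - prev)
    prev <- cnt
  }
  P <- P / n_samples
  P[P == 0] <- 1 / n_samples
  P[P == 1] <- 1 - 1 / n_samples
  P
}

#' Joint choice-confidence log likelihood
#'
#' Sum over trials of the log predicted probability of the observed
#' (choice, confidence) outcome under a [bayes_observer_spec()], with the
#' sampling approximation and extreme-value clipping of
#' [predict_response_probs()]. Deterministic given `seed` (the same
#' standard-normal draws are reused for every parameter value, de-noising
#' optimization).
#'
#' @param table a [trial_table()].
#' @inheritParams predict_response_probs
#' @param method `"fast"` exploits the interval structure of the decision
#'   rule; `"naive"` maps every sample through [respond()]. Identical
#'   results up to measure-zero ties.
#' @return Scalar log likelihood.
#' @export
joint_loglikelihood <- function(table, spec, n_samples = 500L, seed = 1L,
                                method = c("fast", "naive")) {
  method <- match.arg(method)
  ll <- 0
  for (cond in intersect(spec$conditions, unique(table$condition))) {
    rows <- table$condition == cond
    s <- table$s[rows]
    Z <- condition_draws(s, n_samples, seed, cond)
    obs <- outcome_index(table$choice[rows], table$confidence[rows])
    P <- if (method == "fast") {
      outcome_probs_matrix(s, spec, cond, Z)
    } else {
      naive_probs_matrix(s, spec, cond, Z)
    }
    ll <- ll + sum(log(P[cbind(seq_along(obs), obs)]))
  }
  ll
}

# Standard-normal draw matrix for one condition's trials. Rows are keyed
# by the trial's stimulus value (not its position), so the likelihood is
# invariant to trial order and identical stimuli reuse identical draws.
condition_draws <- function(s, n_samples, seed, condition) {
  keys <- paste0("probs_", condition, "_", formatC(s, digits = 15, format = "g"))
  t(vapply(keys, function(k) {
    with_seed(substream_seed(seed, k), stats::rnorm(n_samples))
  }, numeric(n_samples), USE.NAMES = FALSE))
}

naive_probs_matrix <- function(s, spec, condition, Z) {
  sigma <- unname(spec$sigma_encoding[[condition]])
  mu_shift <- s - mu_encoding_for(spec, condition)
  n_samples <- ncol(Z)
  P <- matrix(0, length(s), 4L)
  for (i in seq_along(s)) {
    x <- mu_shift[i] + sigma * Z[i, ]
    resp <- respond(decision_variable(x, spec, condition), spec, condition)
    P[i, ] <- tabulate(outcome_index(resp$choice, resp$q), nbins = 4L) / n_samples
  }
  P[P == 0] <- 1 / n_samples
  P[P == 1] <- 1 - 1 / n_samples
  P
}
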