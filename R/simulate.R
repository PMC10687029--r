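#' Ground-truth observer for synthetic experiments
#'
#' Bundles a generative encoding stage (per-condition encoding offset
#' `mu_A`, offset spread `sigma_A`, encoding noise) with a response policy
#' describing how the observer handles a known distortion:
#' \describe{
#'   \item{naive}{ignores the offset everywhere (`mu_likelihood = 0`,
#'     `k_choice = 0`): the motion after-effect is uncorrected.}
#'   \item{insightful}{compensates at the inference stage: in
#'     Adapt-Believe, `mu_likelihood` is set to the true encoding offset,
#'     shifting the decision variable and hence choice and confidence
#'     curves in tandem.}
#'   \item{late-compensation}{compensates at the response stage only: in
#'     Adapt-Believe, `k_choice` is set to the decision-variable value that
#'     nulls the choice bias, shifting the choice curve while leaving the
#'     confidence minimum at the distorted location.}
#' }
#'
#' @param policy response policy, see Details.
#' @param mu_adapt true encoding offset in Adapt conditions (task units;
#'   negative values produce the clockwise motion after-effect's leftward
#'   psychometric shift). No-Adapt conditions have offset 0.
#' @param sigma_A trial-to-trial spread of the offset (default 0: the
#'   delta-function regime the fitted models assume; set > 0 for the
#'   full-model robustness regime).
#' @param sigma_encoding encoding noise, length 1 or 4.
#' @param k_confidence confidence threshold(s) in (0.5, 1).
#' @param prior category prior(s) p(C = 1).
#' @param category_bounds category boundaries, see [trial_table()].
#' @return An object of class `ground_truth_observer` containing the
#'   response-policy [bayes_observer_spec()] and the generative fields.
#' @export
ground_truth_observer <- function(policy = c("insightful", "late-compensation", "naive"),
                                  mu_adapt = -0.1,
                                  sigma_A = 0,
                                  sigma_encoding = 0.05,
                                  k_confidence = 0.7,
                                  prior = 0.5,
                                  category_bounds = c(s21 = -0.3, s22 = 0, s11 = 0, s12 = 0.3)) {
  policy <- match.arg(policy)
  conditions <- main_conditions()
  mu_l <- stats::setNames(rep(0, 4), conditions)
  k_choice <- stats::setNames(rep(0, 4), conditions)
  variant <- "mu_likelihood"
  if (policy == "insightful") {
    mu_l[["AdaptBelieve"]] <- mu_adapt
  } else if (policy == "late-compensation") {
    variant <- "k_choice"
    # criterion value that nulls the choice bias: d at the measurement the
    # (naive) observer receives when the physical stimulus is at the
    # would-be neutral point
    naive <- bayes_observer_spec(variant = "mu_likelihood",
                                 mu_encoding = c(NoAdapt = 0, Adapt = mu_adapt),
                                 sigma_encoding = sigma_encoding,
                                 k_confidence = k_confidence, prior = prior,
                                 category_bounds = category_bounds)
    k_choice[["AdaptBelieve"]] <- decision_variable(-mu_adapt, naive, "AdaptBelieve")
  }
  spec <- bayes_observer_spec(variant = variant,
                              mu_encoding = c(NoAdapt = 0, Adapt = mu_adapt),
                              sigma_encoding = sigma_encoding,
                              mu_likelihood = mu_l,
                              k_choice = k_choice,
                              k_confidence = k_confidence,
                              prior = prior,
                              category_bounds = category_bounds)
  mu_A <- ifelse(is_adapt_condition(conditions), mu_adapt, 0)
  structure(list(policy = policy, spec = spec,
                 mu_A = stats::setNames(mu_A, conditions),
                 sigma_A = sigma_A),
            class = "ground_truth_observer")
}

#' @export
print.ground_truth_observer <- function(x, ...) {
  cat(sprintf("<ground_truth_observer> policy '%s', mu_adapt = %.4g, sigma_A = %.4g\n",
              x$policy, x$mu_A[["AdaptSee"]], x$sigma_A))
  print(x$spec)
  invisible(x)
}

#' Generative response-time model
#'
#' The experiments analyse response times through decision uncertainty
#' (smaller `|d|`, longer RT) but do not prescribe a generative RT model;
#' this one produces RTs monotone decreasing in `|d|`:
#' `rt = (t0 + beta * softplus(center - |d|)) * exp(noise)`, with
#' `softplus(x) = log(1 + exp(x))` and lognormal multiplicative noise.
#' A `"ddm"` mode instead draws first-passage times from a
#' drift-diffusion process (see [ddm_params()]) for cross-module coherence.
#'
#' @param mode `"uncertainty-linear"` or `"ddm"`.
#' @param t0 intercept / nondecision time, seconds.
#' @param beta seconds per softplus log-odds unit.
#' @param center softplus center in `|d|` units.
#' @param sdlog lognormal noise SD (log scale).
#' @param ddm a [ddm_params()] object, required for `"ddm"` mode.
#' @return An object of class `rt_model`.
#' @export
rt_model <- function(mode = c("uncertainty-linear", "ddm"),
                     t0 = 0.3, beta = 0.15, center = 3, sdlog = 0.2,
                     ddm = NULL) {
  mode <- match.arg(mode)
  if (mode == "ddm" && is.null(ddm)) stop("ddm mode requires a ddm_params object",
                                          call. = FALSE)
  structure(list(mode = mode, t0 = t0, beta = beta, center = center,
                 sdlog = sdlog, ddm = ddm), class = "rt_model")
}

#' Generative pupil-dilation model
#'
#' Pupil area is modelled as a baseline plus an uncertainty-scaled,
#' gamma-shaped dilation impulse response locked to stimulus onset (peak
#' about 1 s after onset, matching the sluggish pupil response), plus white
#' noise. The dilation amplitude is `gain * plogis(-|d|)`, so greater
#' decision uncertainty (smaller `|d|`) produces larger dilations by
#' construction.
#'
#' @param baseline baseline pupil area, arbitrary units.
#' @param shape,scale gamma kernel shape and scale (s); the kernel peaks at
#'   `(shape - 1) * scale` after `latency`.
#' @param latency kernel onset latency after the stimulus, seconds.
#' @param gain dilation amplitude per unit of uncertainty, arbitrary units.
#' @param noise_sd additive white-noise SD, arbitrary units.
#' @param rate sampling rate, Hz (default 1000).
#' @return An object of class `pupil_model`.
#' @export
pupil_model <- function(baseline = 1000, shape = 3, scale = 0.5, latency = 0.2,
                        gain = 150, noise_sd = 5, rate = 1000) {
  stopifnot(rate > 0, shape > 0, scale > 0, noise_sd >= 0)
  structure(list(baseline = baseline, shape = shape, scale = scale,
                 latency = latency, gain = gain, noise_sd = noise_sd,
                 rate = rate), class = "pupil_model")
}

#' Simulate stimulus sequences
#'
#' Draws i.i.d. uniform stimulus speeds per condition. With
#' `include_zero = TRUE` the draw closest to zero is replaced by exactly 0,
#' matching designs that use an odd trial count to include a static test
#' stimulus.
#'
#' @param n_per_condition trials per condition (default 121).
#' @param bounds stimulus range (default `c(-0.3, 0.3)`).
#' @param seed integer seed; identical seeds give identical sequences.
#' @param conditions condition labels.
#' @param include_zero force exactly one zero stimulus per condition.
#' @return Named list of numeric stimulus vectors, one per condition.
#' @export
simulate_stimuli <- function(n_per_condition = 121L, bounds = c(-0.3, 0.3),
                             seed = 1L, conditions = main_conditions(),
                             include_zero = FALSE) {
  if (n_per_condition < 1) stop("n_per_condition must be >= 1", call. = FALSE)
  if (length(bounds) != 2 || bounds[1] >= bounds[2]) {
    stop("bounds must be an increasing length-2 range", call. = FALSE)
  }
  with_seed(substream_seed(seed, "stimuli"), {
    out <- lapply(conditions, function(cond) {
      s <- stats::runif(n_per_condition, bounds[1], bounds[2])
      if (include_zero) s[which.min(abs(s))] <- 0
      s
    })
    stats::setNames(out, conditions)
  })
}

#' Simulate a synthetic experiment from a ground-truth observer
#'
#' Runs the generative model forward per trial: draws the offset
#' `A ~ Normal(mu_A, sigma_A)` and the measurement
#' `x ~ Normal(s - A, sigma_encoding)`, computes the decision variable `d`
#' under the observer's policy, thresholds it into choice and confidence,
#' and draws a response time from the RT model given `|d|`.
#'
#' @param observer a [ground_truth_observer()].
#' @param stimuli named list of stimulus vectors per condition, e.g. from
#'   [simulate_stimuli()].
#' @param rtm an [rt_model()].
#' @param seed integer seed.
#' @param participant_id participant label.
#' @return A [trial_table()] with a `ground_truth` attribute (list with
#'   per-trial `d`, `x`, `A` and the observer), readable via
#'   [ground_truth()].
#' @export
simulate_trials <- function(observer, stimuli, rtm = rt_model(), seed = 1L,
                            participant_id = "sim01") {
  spec <- observer$spec
  rows <- list()
  gt <- list()
  for (cond in names(stimuli)) {
    s <- stimuli[[cond]]
    n <- length(s)
    draws <- with_seed(substream_seed(seed, paste0("trials_", cond)), {
      list(A = stats::rnorm(n, observer$mu_A[[cond]], observer$sigma_A),
           x_noise = stats::rnorm(n),
           rt_noise = stats::rnorm(n))
    })
    x <- s - draws$A + spec$sigma_encoding[[cond]] * draws$x_noise
    d <- decision_variable(x, spec, cond)
    resp <- respond(d, spec, cond)
    rt <- generate_rt(abs(d), s, rtm, draws$rt_noise,
                      substream_seed(seed, paste0("rt_", cond)))
    rows[[cond]] <- data.frame(
      participant_id = participant_id, condition = cond, s = s,
      choice = resp$choice, confidence = resp$q, rt = rt,
      stringsAsFactors = FALSE
    )
    gt[[cond]] <- data.frame(condition = cond, s = s, A = draws$A, x = x, d = d)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  bounds <- range(unlist(stimuli))
  bounds <- c(min(bounds[1], spec$category_bounds[["s21"]]),
              max(bounds[2], spec$category_bounds[["s12"]]))
  table <- trial_table(df, s_bounds = bounds,
                       category_bounds = spec$category_bounds)
  truth <- do.call(rbind, gt)
  rownames(truth) <- NULL
  attr(table, "ground_truth") <- list(observer = observer, trials = truth)
  table
}

generate_rt <- function(abs_d, s, rtm, noise, seed) {
  if (rtm$mode == "uncertainty-linear") {
    mean_rt <- rtm$t0 + rtm$beta * log1p(exp(rtm$center - abs_d))
    mean_rt * exp(rtm$sdlog * noise)
  } else {
    sim <- simulate_ddm(rtm$ddm, s, seed = seed)
    rt <- sim$rt
    rt[sim$censored] <- NA_real_
    rt
  }
}

#' Ground truth of a simulated trial table
#' @param table a table produced by [simulate_trials()].
#' @return List with the generating observer and per-trial latent values
#'   (`A`, `x`, `d`), or `NULL` for empirical tables.
#' @export
ground_truth <- function(table) attr(table, "ground_truth")

#' Simulate pupil-area time series
#'
#' Generates one pupil trace per trial: baseline plus an
#' uncertainty-scaled gamma dilation kernel locked to stimulus onset plus
#' Gaussian white noise (see [pupil_model()]).
#'
#' @param d_values per-trial decision variables (their absolute value
#'   drives uncertainty).
#' @param model a [pupil_model()].
#' @param events optional data.frame with one row per trial and columns
#'   `fixation_onset`, `adaptor_onset`, `stimulus_onset`, `response_time`,
#'   `trial_end` (seconds from trial start). Defaults to fixation at 0 s,
#'   adaptor at 1 s, stimulus at 4 s, response 1 s later, end 4 s after
#'   stimulus onset.
#' @param seed integer seed.
#' @param condition optional per-trial condition labels stored alongside.
#' @return An object of class `pupil_series`: sampling `rate`, `events`
#'   (with condition and trial columns) and `trials`, a list of numeric
#'   area vectors sampled from time 0 at `rate`.
#' @export
simulate_pupil <- function(d_values, model = pupil_model(), events = NULL,
                           seed = 1L, condition = NULL) {
  n <- length(d_values)
  if (any(!is.finite(d_values))) stop("d values must be finite", call. = FALSE)
  if (is.null(events)) {
    events <- data.frame(
      fixation_onset = rep(0, n), adaptor_onset = 1,
      stimulus_onset = 4, response_time = 5, trial_end = 8
    )
  }
  events$trial <- seq_len(n)
  events$condition <- if (is.null(condition)) NA_character_ else as.character(condition)
  uncertainty <- stats::plogis(-abs(d_values))
  trials <- with_seed(substream_seed(seed, "pupil"), {
    lapply(seq_len(n), function(i) {
      t <- seq(0, events$trial_end[i], by = 1 / model$rate)
      lag <- t - events$stimulus_onset[i] - model$latency
      kernel <- numeric(length(t))
      pos <- lag > 0
      kernel[pos] <- stats::dgamma(lag[pos], shape = model$shape, scale = model$scale)
      peak <- stats::dgamma((model$shape - 1) * model$scale,
                            shape = model$shape, scale = model$scale)
      kernel <- kernel / peak
      model$baseline + model$gain * uncertainty[i] * kernel +
        stats::rnorm(length(t), 0, model$noise_sd)
    })
  })
  structure(list(rate = model$rate, events = events, trials = trials),
            class = "pupil_series")
}

#' @export
print.pupil_series <- function(x, ...) {
  cat(sprintf("<pupil_series> %d trial(s) at %g Hz\n", length(x$trials), x$rate))
  invisible(x)
}
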