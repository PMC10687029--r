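#' Drift-diffusion model parameters
#'
#' One condition's parameter set for a Wiener diffusion process with
#' symmetric absorbing bounds at `+-bound`, unit diffusion noise, and a
#' drift that grows linearly with the absolute stimulus speed toward the
#' stimulus side: `drift(s) = drift_gain * (s + drift_bias)`, so the
#' drift-rate bias acts as an additive fraction of the gain. The process
#' starts at `z * bound` (signed fraction of the bound) and the response
#' time is the first-passage time plus the nondecision time. The upper
#' bound maps to the clockwise (+1) choice.
#'
#' @param drift_gain drift per unit stimulus, in \[0, 20\].
#' @param bound decision bound, in \[1, 3\] (evidence units).
#' @param t_nd nondecision time, seconds, in \[0, 2\].
#' @param z starting-point bias as a signed fraction of the bound, in
#'   \[-1, 1\].
#' @param drift_bias drift-rate bias, in \[-1, 1\].
#' @return An object of class `ddm_params`.
#' @export
ddm_params <- function(drift_gain = 8, bound = 1.2, t_nd = 0.3, z = 0,
                       drift_bias = 0) {
  stopifnot(drift_gain >= 0, drift_gain <= 20, bound >= 1, bound <= 3,
            t_nd >= 0, t_nd <= 2, abs(z) <= 1, abs(drift_bias) <= 1)
  structure(list(drift_gain = drift_gain, bound = bound, t_nd = t_nd,
                 z = z, drift_bias = drift_bias, noise = 1),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf(
    "<ddm_params> gain %.3g, bound %.3g, t_nd %.3g s, z %.3g, drift_bias %.3g\n",
    x$drift_gain, x$bound, x$t_nd, x$z, x$drift_bias))
  invisible(x)
}

ddm_drift <- function(s, params) params$drift_gain * (s + params$drift_bias)

#' Simulate a drift-diffusion process
#'
#' Euler-Maruyama forward simulation: `dnu = drift dt + sqrt(dt) eta`,
#' `eta ~ Normal(0, 1)`, absorbed at `+-bound`; the response time is the
#' first-passage time plus `t_nd`. Decision times beyond `max_t` are
#' censored (RT `NA`, flagged), matching the 3 s trimming rule used before
#' fitting.
#'
#' @param params a [ddm_params()].
#' @param stimuli stimulus values, one per trial.
#' @param dt Euler step, seconds.
#' @param seed integer seed.
#' @param max_t censoring horizon for the decision time, seconds.
#' @return data.frame with `s`, `choice` (-1/+1, NA if censored), `rt`
#'   and `censored`.
#' @export
simulate_ddm <- function(params, stimuli, dt = 5e-4, seed = 1L, max_t = 3) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  sim <- with_seed(substream_seed(seed, "ddm"), {
    simulate_ddm_cpp(ddm_drift(stimuli, params), params$bound, params$z,
                     params$t_nd, dt, max_t)
  })
  data.frame(s = stimuli, choice = sim$choice, rt = sim$rt,
             censored = sim$censored)
}

# Drift-free part of the Navarro-Fuss first-passage density at the lower
# bound of a unit-noise, unit-separation Wiener process started at
# fraction w, on normalized time tt. Selects the small- or large-time
# series per element so the truncation error stays below err.
wfpt_series0 <- function(tt, w, err = 1e-10) {
  # number of terms needed by each series
  ks <- rep(2, length(tt))
  cond <- 2 * sqrt(2 * pi * tt) * err < 1
  ks[cond] <- 2 + sqrt(-2 * tt[cond] * log(2 * sqrt(2 * pi * tt[cond]) * err))
  ks <- pmax(ks, sqrt(tt) + 1)
  kl <- 1 / (pi * sqrt(pmax(tt, 1e-300)))
  cond <- pi * tt * err < 1
  kl[cond] <- pmax(sqrt(-2 * log(pi * tt[cond] * err) / (pi^2 * tt[cond])),
                   1 / (pi * sqrt(tt[cond])))
  use_small <- ks < kl
  f <- numeric(length(tt))
  if (any(use_small)) {
    tts <- tt[use_small]
    K <- ceiling(max(ks[use_small]))
    kk <- seq(-floor((K - 1) / 2), ceiling((K - 1) / 2))
    terms <- vapply(kk, function(k) {
      (w + 2 * k) * exp(-(w + 2 * k)^2 / (2 * tts))
    }, numeric(length(tts)))
    ssum <- if (is.null(dim(terms))) sum(terms) else rowSums(terms)
    f[use_small] <- ssum / sqrt(2 * pi * tts^3)
  }
  if (any(!use_small)) {
    ttl <- tt[!use_small]
    K <- ceiling(max(kl[!use_small]))
    kk <- seq_len(max(K, 1))
    terms <- vapply(kk, function(k) {
      k * exp(-k^2 * pi^2 * ttl / 2) * sin(k * pi * w)
    }, numeric(length(ttl)))
    lsum <- if (is.null(dim(terms))) sum(terms) else rowSums(terms)
    f[!use_small] <- pi * lsum
  }
  pmax(f, 0)
}

# First-passage density at the lower bound of [0, a] with drift v (may
# vary per element), start fraction w. The drift enters only through the
# exponential factor, so the series part is shared across trials.
wfpt_lower_density <- function(t, v, a, w, err = 1e-10) {
  out <- numeric(length(t))
  ok <- is.finite(t) & t > 0
  if (!any(ok)) return(out)
  tt <- t[ok] / a^2
  vv <- if (length(v) == 1L) v else v[ok]
  out[ok] <- wfpt_series0(tt, w, err) * exp(-vv * a * w - vv^2 * t[ok] / 2) / a^2
  out
}

# First-passage density at the chosen bound given our +-B parameterization;
# vectorized over trials (t and drift).
ddm_choice_density <- function(t, drift, params, choice) {
  a <- 2 * params$bound
  w <- (1 + params$z) / 2
  if (choice > 0) {
    wfpt_lower_density(t, -drift, a, 1 - w)  # upper bound by reflection
  } else {
    wfpt_lower_density(t, drift, a, w)
  }
}

#' Drift-diffusion log likelihood
#'
#' Per-trial likelihood is the first-passage density at the chosen bound
#' evaluated at `rt - t_nd`. Two routes are available: the exact
#' constant-drift first-passage series (`"analytic"`), and numeric
#' propagation of the Fokker-Planck density on a discretized grid
#' (`"fp"`, defaults `dnu = 0.01`, `dt = 0.0005`) with linear
#' interpolation of the bound flux at each trial's decision time.
#' Densities are floored at a small constant so response times faster than
#' the nondecision time never yield `-Inf` (robust likelihood).
#'
#' @param table data.frame with columns `s`, `choice` (-1/+1) and `rt`
#'   (seconds); all RTs must be <= `max_rt`.
#' @param params a [ddm_params()].
#' @param method `"analytic"` or `"fp"`.
#' @param dnu,dt Fokker-Planck grid steps.
#' @param floor density floor.
#' @param max_rt trimming bound, seconds.
#' @return Scalar log likelihood.
#' @export
ddm_likelihood <- function(table, params, method = c("analytic", "fp"),
                           dnu = 0.01, dt = 5e-4, floor = 1e-10, max_rt = 3) {
  method <- match.arg(method)
  rt <- table$rt
  if (anyNA(rt)) stop("missing RTs; drop censored/missing trials first", call. = FALSE)
  if (any(rt > max_rt)) {
    stop("trials with RT > ", max_rt, " s present; trim before fitting",
         call. = FALSE)
  }
  tdec <- rt - params$t_nd
  drift <- ddm_drift(table$s, params)
  dens <- numeric(nrow(table))
  if (method == "analytic") {
    for (ch in c(-1, 1)) {
      rows <- which(table$choice == ch)
      if (!length(rows)) next
      dens[rows] <- ddm_choice_density(tdec[rows], drift[rows], params, ch)
    }
  } else {
    for (g in split(seq_len(nrow(table)), drift)) {
      fp <- fp_first_passage_cpp(drift[g[1]], params$bound, params$z,
                                 dnu, dt, max_rt)
      up <- stats::approx(fp$t, fp$g_up, xout = tdec[g], yleft = 0, yright = 0)$y
      lo <- stats::approx(fp$t, fp$g_low, xout = tdec[g], yleft = 0, yright = 0)$y
      dens[g] <- ifelse(table$choice[g] > 0, up, lo)
    }
  }
  sum(log(pmax(dens, floor)))
}

# Differential evolution (DE/rand/1/bin) for box-constrained minimization.
de_optimize <- function(fn, lower, upper, n_pop = NULL, n_gen = 60,
                        f_weight = 0.8, cr = 0.9, seed = 1L) {
  d <- length(lower)
  if (is.null(n_pop)) n_pop <- max(20L, 8L * d)
  with_seed(substream_seed(seed, "de"), {
    pop <- sapply(seq_len(d), function(j) stats::runif(n_pop, lower[j], upper[j]))
    if (d == 1) pop <- matrix(pop, ncol = 1)
    vals <- apply(pop, 1, fn)
    history <- numeric(n_gen)
    for (gen in seq_len(n_gen)) {
      for (i in seq_len(n_pop)) {
        r <- sample(setdiff(seq_len(n_pop), i), 3)
        mutant <- pop[r[1], ] + f_weight * (pop[r[2], ] - pop[r[3], ])
        mutant <- pmin(pmax(mutant, lower), upper)
        cross <- stats::runif(d) < cr
        cross[sample.int(d, 1)] <- TRUE
        trial <- ifelse(cross, mutant, pop[i, ])
        v <- fn(trial)
        if (v <= vals[i]) {
          pop[i, ] <- trial
          vals[i] <- v
        }
      }
      history[gen] <- min(vals)
    }
    best <- which.min(vals)
    list(par = pop[best, ], value = vals[best], history = history)
  })
}

ddm_variant_fields <- function(variant) {
  switch(variant,
         base = c("drift_gain", "bound", "t_nd"),
         starting_point = c("drift_gain", "bound", "t_nd", "z"),
         drift_bias = c("drift_gain", "bound", "t_nd", "drift_bias"),
         both = c("drift_gain", "bound", "t_nd", "z", "drift_bias"))
}

ddm_field_bounds <- function() {
  list(drift_gain = c(0, 20), bound = c(1, 3), t_nd = c(0, 2),
       z = c(-1, 1), drift_bias = c(-1, 1))
}

#' Fit drift-diffusion model variants
#'
#' Fits one of four variants per condition by global stochastic
#' optimization (differential evolution) of the exact first-passage log
#' likelihood within the standard parameter ranges (drift gain \[0, 20\],
#' bound \[1, 3\], nondecision time \[0, 2\], biases \[-1, 1\]; unit
#' noise). Trials with RT above `max_rt` (default 3 s) or missing RT are
#' removed before fitting.
#'
#' @param table a [trial_table()] or data.frame with `condition`, `s`,
#'   `choice`, `rt`.
#' @param variant `"base"`, `"starting_point"` (adds the starting-point
#'   bias z), `"drift_bias"`, or `"both"`.
#' @param seed integer seed.
#' @param n_gen,n_pop differential-evolution generations and population.
#' @param max_rt RT trimming bound, seconds.
#' @return An object of class `ddm_fit`: per-condition parameter
#'   data.frame, total `logLik`, `n_params`, `n_trials`, `AIC`, `BIC` and
#'   optimizer traces.
#' @export
fit_ddm <- function(table, variant = c("base", "starting_point", "drift_bias", "both"),
                    seed = 1L, n_gen = 60L, n_pop = NULL, max_rt = 3) {
  variant <- match.arg(variant)
  fields <- ddm_variant_fields(variant)
  bounds <- ddm_field_bounds()[fields]
  keep <- !is.na(table$rt) & table$rt <= max_rt
  n_trimmed <- sum(!keep)
  table <- table[keep, , drop = FALSE]
  conditions <- unique(table$condition)
  params <- list()
  trace <- list()
  total_ll <- 0
  for (cond in conditions) {
    sub <- table[table$condition == cond, c("s", "choice", "rt")]
    if (nrow(sub) < 5) stop("condition ", cond, " has too few trials", call. = FALSE)
    obj <- function(par) {
      p <- as.list(par)
      names(p) <- fields
      full <- do.call(ddm_params, p)
      -ddm_likelihood(sub, full, method = "analytic", max_rt = max_rt)
    }
    res <- de_optimize(obj, vapply(bounds, `[`, numeric(1), 1),
                       vapply(bounds, `[`, numeric(1), 2),
                       n_pop = n_pop, n_gen = n_gen,
                       seed = substream_seed(seed, paste0("ddm_", cond)))
    if (!is.finite(res$value)) {
      stop("optimizer failed to converge for condition ", cond, call. = FALSE)
    }
    p <- as.list(res$par)
    names(p) <- fields
    params[[cond]] <- do.call(ddm_params, p)
    trace[[cond]] <- res$history
    total_ll <- total_ll - res$value
  }
  n_params <- length(fields) * length(conditions)
  ic <- information_criteria(total_ll, n_params, nrow(table))
  param_df <- do.call(rbind, lapply(conditions, function(cond) {
    p <- params[[cond]]
    data.frame(condition = cond, drift_gain = p$drift_gain, bound = p$bound,
               t_nd = p$t_nd, z = p$z, drift_bias = p$drift_bias,
               stringsAsFactors = FALSE)
  }))
  structure(list(variant = variant, params = params, param_table = param_df,
                 logLik = total_ll, n_params = n_params, n_trials = nrow(table),
                 n_trimmed = n_trimmed, AIC = ic[["AIC"]], BIC = ic[["BIC"]],
                 trace = trace),
            class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf("<ddm_fit> variant '%s': LL = %.2f, k = %d, n = %d (%d trimmed)\n",
              x$variant, x$logLik, x$n_params, x$n_trials, x$n_trimmed))
  cat(sprintf("  AIC = %.2f, BIC = %.2f\n", x$AIC, x$BIC))
  print(transform(x$param_table,
                  drift_gain = round(drift_gain, 3), bound = round(bound, 3),
                  t_nd = round(t_nd, 3), z = round(z, 3),
                  drift_bias = round(drift_bias, 3)))
  invisible(x)
}

#' Conditional response function
#'
#' Splits each condition's trials into RT-quantile bins (default 5,
#' equal-count over sorted RT) and reports the proportion of clockwise
#' choices per bin. Starting-point biases express themselves mostly in the
#' fastest bins (fast-decaying bias across quantiles); drift-rate biases
#' persist across quantiles.
#'
#' @param table a [trial_table()] or data.frame with `condition`,
#'   `choice`, `rt`.
#' @param n_bins number of RT-quantile bins (default 5).
#' @return A data.frame of class `crf` with columns `condition`, `bin`,
#'   `rt_mean`, `prop_clockwise`, `sem`, `n`.
#' @export
conditional_response_function <- function(table, n_bins = 5L) {
  keep <- !is.na(table$rt)
  table <- table[keep, , drop = FALSE]
  out <- lapply(unique(table$condition), function(cond) {
    sub <- table[table$condition == cond, ]
    if (nrow(sub) < n_bins) {
      stop("condition ", cond, " has fewer than ", n_bins, " trials", call. = FALSE)
    }
    ord <- order(sub$rt)
    n <- nrow(sub)
    edges <- round(seq(0, n, length.out = n_bins + 1))
    bin <- rep(seq_len(n_bins), times = diff(edges))
    up <- as.numeric(sub$choice[ord] == 1)
    data.frame(
      condition = cond,
      bin = seq_len(n_bins),
      rt_mean = as.numeric(tapply(sub$rt[ord], bin, mean)),
      prop_clockwise = as.numeric(tapply(up, bin, mean)),
      sem = as.numeric(tapply(up, bin, function(v) {
        if (length(v) < 2) return(0)
        stats::sd(v) / sqrt(length(v))
      })),
      n = as.integer(table(bin)),
      stringsAsFactors = FALSE
    )
  })
  structure(do.call(rbind, out), class = c("crf", "data.frame"))
}
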