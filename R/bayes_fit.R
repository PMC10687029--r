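# Maximum-likelihood fitting of the Bayesian observer variants and
# AIC/BIC model comparison.

# Hard bounds, plausible (start-sampling) ranges and scale of each free
# parameter family. sigma is optimized in log space.
bayes_param_ranges <- function() {
  list(
    sigma_encoding = list(lo = log(0.001), hi = log(0.15),
                          plo = log(0.001), phi = log(0.15), log = TRUE),
    mu_likelihood = list(lo = -3, hi = 6.5, plo = -3, phi = 6.5, log = FALSE),
    prior = list(lo = 0.4, hi = 0.6, plo = 0.4001, phi = 0.5999, log = FALSE),
    k_choice = list(lo = -5, hi = 5, plo = -5, phi = 5, log = FALSE),
    k_confidence = list(lo = 0.5, hi = 0.99999, plo = 0.50001, phi = 0.99999,
                        log = FALSE)
  )
}

# Box constraint via a logistic transform to the real line.
to_raw <- function(value, rng) {
  v <- pmin(pmax(value, rng$lo + 1e-10), rng$hi - 1e-10)
  stats::qlogis((v - rng$lo) / (rng$hi - rng$lo))
}

from_raw <- function(raw, rng) {
  rng$lo + (rng$hi - rng$lo) * stats::plogis(raw)
}

#' Fit a Bayesian observer variant by multi-start maximum likelihood
#'
#' Jointly fits the variant's free parameters to the choice and confidence
#' data by maximizing the sampled [joint_loglikelihood()]. The two
#' `mu_encoding` values are fixed (conventionally to the psychometric-curve
#' biases of the No-Adapt-See and Adapt-See conditions). All free
#' parameters are condition-specific, so the joint optimum decomposes into
#' independent per-condition optimizations; each runs `n_starts`
#' Nelder-Mead searches from seeded uniform draws within the plausible
#' ranges, on logistic-transformed (box-bounded) parameters, with common
#' random numbers across evaluations. The best start per condition is kept.
#'
#' @param table a [trial_table()].
#' @param variant model variant, see [bayes_observer_spec()].
#' @param mu_encoding length-2 numeric `c(NoAdapt, Adapt)`, fixed.
#' @param n_starts number of optimizer starts per condition (default 14).
#' @param n_samples measurement samples per trial for the likelihood.
#' @param seed integer seed controlling both the likelihood draws and the
#'   start points.
#' @param maxit Nelder-Mead iteration cap per start.
#' @param conditions conditions to fit (default: the main conditions
#'   present in the table).
#' @return An object of class `insight_fit`: the fitted
#'   [bayes_observer_spec()], `logLik`, `n_params`, `n_trials`, `AIC`,
#'   `BIC`, per-condition optimizer traces and boundary flags.
#' @export
fit_bayes_model <- function(table, variant, mu_encoding, n_starts = 14L,
                            n_samples = 500L, seed = 1L, maxit = 400L,
                            conditions = NULL) {
  if (is.null(conditions)) {
    conditions <- intersect(main_conditions(), unique(table$condition))
  }
  if (length(mu_encoding) != 2) stop("mu_encoding must have length 2 (NoAdapt, Adapt)",
                                     call. = FALSE)
  warn_if_nonuniform(table)
  families <- variant_free_families(variant)
  ranges <- bayes_param_ranges()[families]
  meta <- trial_meta(table)
  template <- bayes_observer_spec(variant = variant,
                                  mu_encoding = mu_encoding,
                                  category_bounds = meta$category_bounds,
                                  conditions = conditions)
  fitted <- template
  total_ll <- 0
  n_trials <- 0
  trace <- list()
  boundary <- character(0)
  for (cond in conditions) {
    rows <- table$condition == cond
    if (!any(rows)) stop("no trials for condition ", cond, call. = FALSE)
    s <- table$s[rows]
    obs <- outcome_index(table$choice[rows], table$confidence[rows])
    Z <- condition_draws(s, n_samples, seed, cond)
    Zs <- t(apply(Z, 1, sort))  # row-sorted: counting becomes binary search
    obs_cells <- cbind(seq_along(obs), obs)
    objective <- function(raw) {
      spec <- template
      for (j in seq_along(families)) {
        val <- from_raw(raw[j], ranges[[j]])
        if (isTRUE(ranges[[j]]$log)) val <- exp(val)
        spec[[families[j]]][[cond]] <- val
      }
      P <- outcome_probs_matrix(s, spec, cond, Zs, sorted = TRUE)
      -sum(log(P[obs_cells]))
    }
    # The clipped sampling likelihood is exactly flat far from the
    # informative region, which defeats purely local searches; a seeded
    # Latin-hypercube probe of the box supplies one additional informed
    # start alongside the protocol's uniform starts.
    probes <- with_seed(substream_seed(seed, paste0("probe_", cond)), {
      n_probe <- 96L
      vapply(ranges, function(rng) {
        u <- (sample.int(n_probe) - stats::runif(n_probe)) / n_probe
        rng$plo + u * (rng$phi - rng$plo)
      }, numeric(96L))
    })
    probe_vals <- apply(probes, 1, function(p) {
      objective(vapply(seq_along(families),
                       function(j) to_raw(p[j], ranges[[j]]), numeric(1)))
    })
    starts <- with_seed(substream_seed(seed, paste0("starts_", cond)), {
      vapply(ranges, function(rng) stats::runif(n_starts, rng$plo, rng$phi),
             numeric(n_starts))
    })
    if (n_starts == 1L) starts <- matrix(starts, nrow = 1)
    starts <- rbind(starts,
                    probes[which.min(probe_vals), , drop = FALSE],
                    moment_start(s, table$choice[rows], table$confidence[rows],
                                 template, cond, families, ranges))
    best <- NULL
    start_values <- numeric(nrow(starts))
    for (k in seq_len(nrow(starts))) {
      raw0 <- vapply(seq_along(families),
                     function(j) to_raw(starts[k, j], ranges[[j]]), numeric(1))
      res <- tryCatch({
        r <- stats::optim(raw0, objective, method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = 1e-7))
        for (round in 1:2) {  # restart: re-inflates the simplex
          r2 <- stats::optim(r$par, objective, method = "Nelder-Mead",
                             control = list(maxit = maxit, reltol = 1e-7))
          if (r$value - r2$value < 0.005) { r <- r2; break }
          r <- r2
        }
        r
      }, error = function(e) NULL)
      start_values[k] <- if (is.null(res)) NA_real_ else res$value
      if (!is.null(res) && (is.null(best) || res$value < best$value)) {
        best <- res
        best$start <- k
      }
    }
    if (is.null(best)) {
      stop("all optimizer starts failed for condition ", cond, call. = FALSE)
    }
    for (j in seq_along(families)) {
      val <- from_raw(best$par[j], ranges[[j]])
      span <- ranges[[j]]$hi - ranges[[j]]$lo
      if (min(val - ranges[[j]]$lo, ranges[[j]]$hi - val) < 1e-3 * span) {
        boundary <- c(boundary, paste0(cond, ":", families[j]))
      }
      if (isTRUE(ranges[[j]]$log)) val <- exp(val)
      fitted[[families[j]]][[cond]] <- val
    }
    total_ll <- total_ll - best$value
    n_trials <- n_trials + length(s)
    trace[[cond]] <- list(best_start = best$start, neg_ll = start_values,
                          convergence = best$convergence)
  }
  n_params <- length(families) * length(conditions)
  ic <- information_criteria(total_ll, n_params, n_trials)
  structure(list(
    spec = fitted, variant = variant, logLik = total_ll,
    n_params = n_params, n_trials = n_trials,
    AIC = ic[["AIC"]], BIC = ic[["BIC"]],
    trace = trace, boundary = boundary,
    n_samples = n_samples, n_starts = n_starts, seed = seed
  ), class = "insight_fit")
}

# Data-driven start: a probit fit of the choice curve provides the
# encoding-noise scale and the location of the decision cut in measurement
# space; the observed high-confidence rate places the confidence
# threshold. Expressed in whichever parameter family the variant frees.
moment_start <- function(s, choice, confidence, template, cond, families,
                         ranges) {
  clamp <- function(v, rng, eps = 1e-4) {
    span <- rng$phi - rng$plo
    min(max(v, rng$plo + eps * span), rng$phi - eps * span)
  }
  mu_enc <- mu_encoding_for(template, cond)
  fit <- tryCatch(
    suppressWarnings(stats::glm(I(choice == 1) ~ s,
                                family = stats::binomial("probit"))),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(stats::coef(fit)[2]) ||
      stats::coef(fit)[2] <= 0) {
    sigma0 <- 0.05
    cut <- 0
  } else {
    sigma0 <- min(max(1 / stats::coef(fit)[2], 0.0015), 0.14)
    cut <- -stats::coef(fit)[1] / stats::coef(fit)[2] - mu_enc
  }
  probe_spec <- template
  probe_spec$sigma_encoding[[cond]] <- sigma0
  start <- numeric(length(families))
  names(start) <- families
  for (j in seq_along(families)) {
    fam <- families[j]
    val <- switch(fam,
      sigma_encoding = log(sigma0),
      # hybrid variants attribute the whole cut to mu_likelihood
      mu_likelihood = cut,
      k_choice = if ("mu_likelihood" %in% families) 0 else
        decision_variable(cut, probe_spec, cond),
      prior = if ("mu_likelihood" %in% families) 0.5 else
        stats::plogis(-decision_variable(cut, probe_spec, cond)),
      k_confidence = {
        shift <- if ("mu_likelihood" %in% families) cut else 0
        probe_spec$mu_likelihood[[cond]] <- shift
        x_hat <- s - mu_enc
        d_hat <- decision_variable(x_hat, probe_spec, cond)
        if (template$variant == "k_choice_confidence") {
          d_hat <- d_hat - decision_variable(cut, probe_spec, cond)
        }
        q_rate <- mean(confidence == 1)
        stats::plogis(stats::quantile(abs(d_hat), probs = 1 - q_rate,
                                      names = FALSE))
      })
    start[j] <- clamp(val, ranges[[j]])
  }
  start
}

warn_if_nonuniform <- function(table) {
  meta <- trial_meta(table)
  s <- table$s
  if (length(s) >= 50) {
    ks <- suppressWarnings(
      stats::ks.test(s, "punif", meta$s_bounds[1], meta$s_bounds[2])
    )
    if (ks$p.value < 1e-4) {
      warning("stimulus values look non-uniform over the declared bounds; ",
              "the observer models assume a uniform stimulus distribution",
              call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.insight_fit <- function(x, ...) {
  cat(sprintf("<insight_fit> variant '%s': LL* = %.2f, k = %d, n = %d\n",
              x$variant, x$logLik, x$n_params, x$n_trials))
  cat(sprintf("  AIC = %.2f, BIC = %.2f\n", x$AIC, x$BIC))
  if (length(x$boundary)) {
    cat("  boundary hits:", paste(x$boundary, collapse = ", "), "\n")
  }
  print(x$spec)
  invisible(x)
}

#' Information criteria
#'
#' `AIC = -2 LL* + 2 k` and `BIC = -2 LL* + k log(n)` for a maximized log
#' likelihood `LL*` with `k` free parameters and `n` trials.
#'
#' @param LL maximized log likelihood.
#' @param k number of free parameters.
#' @param n number of trials (>= 1).
#' @return Named numeric `c(AIC, BIC)`.
#' @export
information_criteria <- function(LL, k, n) {
  stopifnot(n >= 1)
  c(AIC = -2 * LL + 2 * k, BIC = -2 * LL + k * log(n))
}

#' Compare fitted model variants across a cohort
#'
#' For each variant, subtracts the reference variant's AIC and BIC per
#' participant, sums the differences across participants, and attaches
#' percentile confidence intervals from resampling participants with
#' replacement (default 1e6 resamples). Negative summed differences favour
#' the variant over the reference.
#'
#' @param ic_table data.frame with columns `participant`, `variant`, `AIC`,
#'   `BIC`; every participant must appear under every variant.
#' @param reference variant label used as the reference.
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return A data.frame of class `model_comparison` with the summed
#'   differences and their bootstrap CIs per variant.
#' @export
compare_models <- function(ic_table, reference, n_boot = 1e6, seed = 1L,
                           conf = 0.95) {
  variants <- unique(ic_table$variant)
  if (!reference %in% variants) stop("reference variant not present", call. = FALSE)
  participants <- unique(ic_table$participant)
  wide <- function(metric) {
    m <- matrix(NA_real_, length(participants), length(variants),
                dimnames = list(participants, variants))
    for (i in seq_len(nrow(ic_table))) {
      m[as.character(ic_table$participant[i]), as.character(ic_table$variant[i])] <-
        ic_table[[metric]][i]
    }
    if (anyNA(m)) stop("participants do not match across variants", call. = FALSE)
    m - m[, reference]
  }
  dA <- wide("AIC")
  dB <- wide("BIC")
  n <- length(participants)
  alpha <- (1 - conf) / 2
  boot_ci <- function(d) {
    sums <- with_seed(substream_seed(seed, "compare_models"), {
      out <- matrix(NA_real_, n_boot, ncol(d))
      chunk <- 100000L
      done <- 0L
      while (done < n_boot) {
        b <- min(chunk, n_boot - done)
        idx <- sample.int(n, n * b, replace = TRUE)
        for (v in seq_len(ncol(d))) {
          out[done + seq_len(b), v] <- .colSums(d[idx, v], n, b)
        }
        done <- done + b
      }
      out
    })
    t(apply(sums, 2, stats::quantile, probs = c(alpha, 1 - alpha), names = FALSE))
  }
  ciA <- boot_ci(dA)
  ciB <- boot_ci(dB)
  structure(data.frame(
    variant = variants,
    sum_dAIC = colSums(dA),
    dAIC_lo = ciA[, 1], dAIC_hi = ciA[, 2],
    sum_dBIC = colSums(dB),
    dBIC_lo = ciB[, 1], dBIC_hi = ciB[, 2],
    row.names = NULL, stringsAsFactors = FALSE
  ), reference = reference, class = c("model_comparison", "data.frame"))
}
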