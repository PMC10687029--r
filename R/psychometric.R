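#' Psychometric response probability
#'
#' Gaussian-CDF psychometric curve with a symmetric lapse:
#' `p(r = 1 | s) = lambda/2 + (1 - lambda) * Phi(s; mu, sigma)`, where
#' `r = 1` is a clockwise response, `mu` is the bias (point of subjective
#' equality) and `sigma` the inverse slope.
#'
#' @param s stimulus value(s).
#' @param mu bias (PSE), stimulus units.
#' @param sigma inverse slope, stimulus units, > 0.
#' @param lambda lapse rate in \[0, 0.3\].
#' @return Probability of a clockwise response, in
#'   `[lambda/2, 1 - lambda/2]`.
#' @export
psychometric_prob <- function(s, mu, sigma, lambda = 0) {
  if (any(sigma <= 0)) stop("sigma must be > 0", call. = FALSE)
  if (any(lambda < 0 | lambda > 0.3)) stop("lambda must lie in [0, 0.3]", call. = FALSE)
  lambda / 2 + (1 - lambda) * stats::pnorm(s, mean = mu, sd = sigma)
}

#' Parameter grids for the psychometric grid search
#'
#' Presets follow the two experiments' estimation protocols: `"exp2"` uses
#' 201 values per parameter with mu linear on \[-0.2, 0.2\], sigma
#' logarithmic on \[1e-4, 0.2\] and lambda linear on \[0, 0.3\]; `"exp1"`
#' uses 101 values with mu on \[-0.3, 0.5\] and sigma logarithmic on
#' \[0.001, 0.5\]. Both endpoints of the log sigma grid are included.
#'
#' @param preset `"exp2"` (default) or `"exp1"`.
#' @param n_points optional override of the number of grid values.
#' @param mu_range,sigma_range,lambda_range optional range overrides.
#' @return List of grids `mu`, `sigma`, `lambda` with a `preset` attribute.
#' @export
psychometric_grid <- function(preset = c("exp2", "exp1"), n_points = NULL,
                              mu_range = NULL, sigma_range = NULL,
                              lambda_range = NULL) {
  preset <- match.arg(preset)
  defaults <- if (preset == "exp2") {
    list(n = 201L, mu = c(-0.2, 0.2), sigma = c(1e-4, 0.2), lambda = c(0, 0.3))
  } else {
    list(n = 101L, mu = c(-0.3, 0.5), sigma = c(0.001, 0.5), lambda = c(0, 0.3))
  }
  n <- n_points %||% defaults$n
  mu_range <- mu_range %||% defaults$mu
  sigma_range <- sigma_range %||% defaults$sigma
  lambda_range <- lambda_range %||% defaults$lambda
  structure(list(
    mu = seq(mu_range[1], mu_range[2], length.out = n),
    sigma = exp(seq(log(sigma_range[1]), log(sigma_range[2]), length.out = n)),
    lambda = seq(lambda_range[1], lambda_range[2], length.out = n)
  ), preset = preset)
}

#' Fit psychometric curves by exhaustive grid-search MLE
#'
#' Joint maximum-likelihood estimation of condition-specific bias `mu` and
#' inverse slope `sigma` with a single lapse rate `lambda` shared across
#' conditions: for each `lambda` grid value, four independent
#' two-dimensional (mu, sigma) searches maximize the per-condition
#' Bernoulli log likelihood; the `lambda` with the greatest total log
#' likelihood wins. Grid ties are broken deterministically towards the
#' smallest `sigma`, then the smallest `|mu|`. Parameters landing on grid
#' boundaries are flagged.
#'
#' @param table a [trial_table()]; choices are the binary responses
#'   (+1 = clockwise).
#' @param grid a [psychometric_grid()].
#' @return An object of class `psychometric_fit`: a `params` data.frame
#'   (condition, mu, sigma), the shared `lambda`, `logLik`, the grid, and
#'   `boundary` flags.
#' @export
fit_psychometric <- function(table, grid = psychometric_grid("exp2")) {
  conditions <- unique(table$condition)
  mu_order <- order(abs(grid$mu), grid$mu)  # tie-break: smallest |mu| first
  scans <- lapply(conditions, function(cond) {
    rows <- table$condition == cond
    s <- table$s[rows]
    r <- as.integer(table$choice[rows] == 1)
    if (length(unique(s)) < 2) {
      stop("condition ", cond, " needs >= 2 distinct stimulus values", call. = FALSE)
    }
    psy_grid_scan(s, r, grid$mu[mu_order], grid$sigma, grid$lambda)
  })
  total_ll <- Reduce(`+`, lapply(scans, `[[`, "logLik"))
  l_best <- which.max(total_ll)  # earliest (smallest lambda) on ties
  params <- do.call(rbind, lapply(seq_along(conditions), function(i) {
    data.frame(
      condition = conditions[i],
      mu = grid$mu[mu_order[scans[[i]]$mu_index[l_best]]],
      sigma = grid$sigma[scans[[i]]$sigma_index[l_best]],
      stringsAsFactors = FALSE
    )
  }))
  boundary <- character(0)
  for (i in seq_len(nrow(params))) {
    if (params$mu[i] %in% range(grid$mu)) {
      boundary <- c(boundary, paste0(params$condition[i], ":mu"))
    }
    if (params$sigma[i] %in% range(grid$sigma)) {
      boundary <- c(boundary, paste0(params$condition[i], ":sigma"))
    }
  }
  lambda <- grid$lambda[l_best]
  if (lambda %in% range(grid$lambda)) boundary <- c(boundary, "lambda")
  structure(list(
    params = params, lambda = lambda, logLik = total_ll[l_best],
    lambda_profile = total_ll, grid = grid, boundary = boundary,
    n_trials = nrow(table)
  ), class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit> LL = %.2f, shared lambda = %.4g (n = %d)\n",
              x$logLik, x$lambda, x$n_trials))
  print(transform(x$params, mu = round(mu, 4), sigma = round(sigma, 4)))
  if (length(x$boundary)) cat("  boundary hits:", paste(x$boundary, collapse = ", "), "\n")
  invisible(x)
}

#' Bias estimate from a binned confidence or RT curve
#'
#' Estimates the psychometric bias as the center of the bin attaining the
#' minimum confidence (confidence curves dip at the subjective neutral
#' point) or the maximum response time. Tied extrema return the mean of
#' the tied bin centers.
#'
#' @param curve a [bin_curve()] result (one or more conditions).
#' @param mode `"min_confidence"` or `"max_rt"`.
#' @return Named numeric, one bias estimate per condition.
#' @export
bias_from_binned_curve <- function(curve, mode = c("min_confidence", "max_rt")) {
  mode <- match.arg(mode)
  if (nrow(curve) == 0) stop("empty curve", call. = FALSE)
  conditions <- unique(curve$condition)
  out <- vapply(conditions, function(cond) {
    rows <- curve[curve$condition == cond, ]
    if (nrow(rows) < 2) stop("need >= 2 bins per condition", call. = FALSE)
    target <- if (mode == "min_confidence") min(rows$mean) else max(rows$mean)
    tied <- abs(rows$mean - target) < 1e-12
    mean(rows$center[tied])
  }, numeric(1))
  stats::setNames(out, conditions)
}

#' Motion after-effect compensation index
#'
#' The shift of the Adapt-Believe bias relative to Adapt-See, normalized
#' by the Adapt-See bias magnitude:
#' `(mu_AdaptBelieve - mu_AdaptSee) / |mu_AdaptSee|`. 0 means no
#' compensation, 1 exact compensation, > 1 overcompensation.
#'
#' @param fit a `psychometric_fit`, or a named numeric containing
#'   `AdaptSee` and `AdaptBelieve` bias values.
#' @return The dimensionless compensation index.
#' @export
mae_compensation_index <- function(fit) {
  mu <- if (inherits(fit, "psychometric_fit")) {
    stats::setNames(fit$params$mu, fit$params$condition)
  } else {
    fit
  }
  if (!all(c("AdaptSee", "AdaptBelieve") %in% names(mu))) {
    stop("need AdaptSee and AdaptBelieve biases", call. = FALSE)
  }
  if (mu[["AdaptSee"]] == 0) {
    stop("compensation index undefined: mu_AdaptSee is 0", call. = FALSE)
  }
  unname((mu[["AdaptBelieve"]] - mu[["AdaptSee"]]) / abs(mu[["AdaptSee"]]))
}
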