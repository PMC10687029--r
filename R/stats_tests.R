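#' Wilcoxon signed-rank test (normal approximation)
#'
#' Paired two-sided signed-rank test returning the z statistic used for
#' effect-size computation. Zero differences are discarded; tied absolute
#' differences receive mid-ranks and the variance carries the usual tie
#' correction. If every difference is zero the test is degenerate and
#' `z = 0`, `p = 1` is returned with a warning.
#'
#' @param a,b equal-length paired measurements (one value per
#'   participant).
#' @return List with `z`, `p` (two-sided), `n` (non-zero pairs) and the
#'   signed-rank sum `W`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length", call. = FALSE)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences are zero; degenerate test")
    return(list(z = 0, p = 1, n = 0L, W = 0))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) {
    warning("zero variance; degenerate test")
    return(list(z = 0, p = 1, n = n, W = W))
  }
  z <- (W - mu) / sqrt(sigma2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)), n = n, W = W)
}

#' Effect size for the signed-rank test
#'
#' `r = z / sqrt(2 N)`, with `N` the number of participants.
#'
#' @param z signed-rank z statistic.
#' @param n number of participants.
#' @return Effect size r.
#' @export
effect_size_r <- function(z, n) {
  stopifnot(n >= 1)
  z / sqrt(2 * n)
}

#' Paired Cohen's d from a t statistic
#'
#' `d = t / sqrt(N)` for a paired-samples t statistic with `N`
#' participants.
#'
#' @param t paired t statistic.
#' @param n number of participants (>= 2).
#' @return Cohen's d.
#' @export
cohens_d_paired <- function(t, n) {
  stopifnot(n >= 2)
  t / sqrt(n)
}

#' Eta squared
#'
#' `eta^2 = SS_effect / SS_total`.
#'
#' @param ss_effect effect sum of squares.
#' @param ss_total total sum of squares, > 0.
#' @return The ratio.
#' @export
eta_squared <- function(ss_effect, ss_total) {
  if (ss_total <= 0) stop("ss_total must be > 0", call. = FALSE)
  if (ss_effect < 0 || ss_effect > ss_total) {
    stop("ss_effect must lie in [0, ss_total]", call. = FALSE)
  }
  ss_effect / ss_total
}

#' BCa bootstrap confidence interval
#'
#' Bias-corrected and accelerated interval for a statistic of a sample
#' (bias correction from the bootstrap distribution, acceleration from the
#' jackknife), with defaults alpha = 0.05 and 100000 resamples. Degenerate
#' bootstrap distributions fall back to the percentile interval with a
#' warning.
#'
#' @param statistic function of one argument (the resampled data).
#' @param data vector or data.frame (rows are resampled).
#' @param n_boot number of resamples (>= 100).
#' @param alpha significance level (CI level is `1 - alpha`).
#' @param seed integer seed.
#' @return Numeric `c(lower, upper)` with attributes `point` (the
#'   statistic of the original data) and `type` (`"bca"` or
#'   `"percentile"`).
#' @export
bca_bootstrap_ci <- function(statistic, data, n_boot = 1e5, alpha = 0.05,
                             seed = 1L) {
  if (n_boot < 100) stop("n_boot must be >= 100", call. = FALSE)
  index_stat <- function(d, i) {
    statistic(if (is.data.frame(d)) d[i, , drop = FALSE] else d[i])
  }
  res <- with_seed(substream_seed(seed, "bca"), {
    boot::boot(data, index_stat, R = n_boot)
  })
  ci <- tryCatch({
    b <- boot::boot.ci(res, conf = 1 - alpha, type = "bca")
    c(b$bca[4], b$bca[5])
  }, error = function(e) NULL)
  type <- "bca"
  if (is.null(ci) || anyNA(ci)) {
    warning("degenerate bootstrap distribution; falling back to percentile")
    ci <- unname(stats::quantile(res$t[, 1], c(alpha / 2, 1 - alpha / 2)))
    type <- "percentile"
  }
  structure(ci, point = res$t0, type = type)
}

#' Percentile bootstrap interval for the median
#'
#' Resamples with replacement (default 5000 iterations) and returns the
#' 2.5th and 97.5th percentiles of the distribution of medians.
#'
#' @param values numeric vector (>= 2 values).
#' @param n_boot number of resamples.
#' @param seed integer seed.
#' @param probs percentile pair.
#' @return Numeric `c(lower, upper)` with attribute `point`.
#' @export
median_percentile_ci <- function(values, n_boot = 5000, seed = 1L,
                                 probs = c(0.025, 0.975)) {
  if (length(values) < 2) stop("need >= 2 values", call. = FALSE)
  meds <- with_seed(substream_seed(seed, "median_ci"), {
    n <- length(values)
    vapply(seq_len(n_boot),
           function(i) stats::median(sample(values, n, replace = TRUE)),
           numeric(1))
  })
  structure(unname(stats::quantile(meds, probs)), point = stats::median(values))
}

#' Ranked mixed-effects regression
#'
#' Fits the trial-level mixed-effects specification used for response
#' times and pupil measures: the response is modelled with fixed effects
#' for the intercept, the ranked predictor (typically `|s|` or `|d|`;
#' mid-ranks, ranked across all trials) and condition (dummy-coded with
#' No-Adapt-See as the reference), plus random intercepts and slopes for
#' all of these per participant. Optionally includes ranked RT as a
#' further covariate. Estimated by maximum likelihood (so AIC/BIC are
#' comparable across fixed-effect sets) via `lme4::lmer`; singular
#' random-effects structures are flagged, never silently simplified.
#'
#' @param data data.frame with columns `participant`, `condition`, the
#'   response, the predictor and optionally `rt`.
#' @param response,predictor column names.
#' @param include_rt include ranked `rt` as a covariate.
#' @param rank_predictor rank-transform the predictor (default TRUE).
#' @return List of class `ranked_glme`: `coefficients` (estimate, se, t
#'   per fixed effect), `AIC`, `BIC`, `adj_r2`, `singular`, and the lme4
#'   `model`.
#' @export
ranked_glme <- function(data, response, predictor, include_rt = FALSE,
                        rank_predictor = TRUE) {
  if (length(unique(data$participant)) < 2) {
    stop("need >= 2 participants", call. = FALSE)
  }
  df <- data.frame(
    y = data[[response]],
    x = if (rank_predictor) rank(data[[predictor]]) else data[[predictor]],
    condition = factor(data$condition,
                       levels = intersect(c(main_conditions(), all_conditions()),
                                          unique(data$condition))),
    participant = factor(data$participant)
  )
  terms <- "x"
  if (include_rt) {
    df$rt_rank <- rank(data$rt)
    terms <- c("rt_rank", "x")
  }
  if (nlevels(df$condition) > 1) terms <- c(terms, "condition")
  fixed <- paste(terms, collapse = " + ")
  form <- stats::as.formula(
    paste0("y ~ 1 + ", fixed, " + (1 + ", fixed, " | participant)"))
  model <- lme4::lmer(form, data = df, REML = FALSE,
                      control = lme4::lmerControl(calc.derivs = FALSE,
                                                  check.conv.singular = "ignore"))
  singular <- lme4::isSingular(model)
  co <- as.data.frame(summary(model)$coefficients)
  names(co) <- c("estimate", "se", "t")
  n <- nrow(df)
  p <- nrow(co)
  r2 <- stats::cor(stats::fitted(model), df$y)^2
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  structure(list(coefficients = as.matrix(co),
                 AIC = stats::AIC(model), BIC = stats::BIC(model),
                 adj_r2 = adj_r2, singular = singular, model = model),
            class = "ranked_glme")
}

#' @export
print.ranked_glme <- function(x, ...) {
  cat("<ranked_glme>", if (x$singular) "(singular fit)" else "", "\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  AIC %.1f, BIC %.1f, adj R^2 %.3f\n", x$AIC, x$BIC, x$adj_r2))
  invisible(x)
}
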