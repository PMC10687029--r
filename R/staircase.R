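#' Entropy-minimizing adaptive staircase
#'
#' Maintains a posterior over psychometric parameters (bias mu, noise
#' sigma, lapse lambda) on a fixed grid, updates it after each binary
#' response, and proposes the next stimulus as the candidate minimizing the
#' expected entropy of the updated posterior, averaged over the two
#' possible responses weighted by their predictive probabilities.
#'
#' `staircase_posterior()` builds the (uniform) starting posterior on the
#' default grids: mu linear, 51 points on \[-0.5, 0.5\]; sigma logarithmic,
#' 25 points on \[0.001, 0.5\]; lambda linear, 25 points on \[0, 0.3\].
#'
#' @param mu,sigma,lambda parameter grids.
#' @return An object of class `staircase_posterior` with the grids and the
#'   normalized probability array `w` (dim mu x sigma x lambda).
#' @export
staircase_posterior <- function(mu = seq(-0.5, 0.5, length.out = 51),
                                sigma = exp(seq(log(0.001), log(0.5), length.out = 25)),
                                lambda = seq(0, 0.3, length.out = 25)) {
  w <- array(1, dim = c(length(mu), length(sigma), length(lambda)))
  structure(list(mu = mu, sigma = sigma, lambda = lambda, w = w / sum(w)),
            class = "staircase_posterior")
}

# P(response = 1 | s) over the whole grid, as an array matching post$w.
staircase_pred_grid <- function(post, s) {
  phi <- stats::pnorm(outer(s - post$mu, post$sigma, "/"))  # note: (s-mu)/sigma
  p <- outer(phi, 1 - post$lambda)
  sweep(p, 3, post$lambda / 2, "+")
}

#' @rdname staircase_posterior
#' @param post a `staircase_posterior`.
#' @param stimulus stimulus shown.
#' @param response observed binary response (0/1 or -1/+1; positive =
#'   clockwise = 1).
#' @return `staircase_update()` returns the updated posterior.
#' @export
staircase_update <- function(post, stimulus, response) {
  r <- as.integer(response > 0)
  p1 <- staircase_pred_grid(post, stimulus)
  lik <- if (r == 1L) p1 else 1 - p1
  w <- post$w * lik
  total <- sum(w)
  if (total <= 0) stop("posterior update produced zero mass", call. = FALSE)
  post$w <- w / total
  post
}

#' @rdname staircase_posterior
#' @param candidates candidate stimulus values.
#' @return `adaptive_staircase_next()` returns a list with `stimulus` (the
#'   entropy-minimizing candidate; deterministic first-candidate
#'   tie-break) and `expected_entropy` (one value per candidate).
#' @export
adaptive_staircase_next <- function(post, candidates) {
  if (abs(sum(post$w) - 1) > 1e-8) stop("posterior is not normalized", call. = FALSE)
  entropy <- function(w) {
    w <- w[w > 0]
    -sum(w * log(w))
  }
  eh <- vapply(candidates, function(s) {
    p1_grid <- staircase_pred_grid(post, s)
    w1 <- post$w * p1_grid
    w0 <- post$w - w1  # post * (1 - p1)
    p1 <- sum(w1)
    p0 <- 1 - p1
    h1 <- if (p1 > 0) entropy(w1 / p1) else 0
    h0 <- if (p0 > 0) entropy(w0 / p0) else 0
    p1 * h1 + p0 * h0
  }, numeric(1))
  best <- which(eh <= min(eh) + 1e-12)[1]
  list(stimulus = candidates[best], expected_entropy = eh)
}

#' @rdname staircase_posterior
#' @return `staircase_estimates()` returns the posterior means of mu,
#'   sigma and lambda.
#' @export
staircase_estimates <- function(post) {
  c(mu = sum(apply(post$w, 1, sum) * post$mu),
    sigma = sum(apply(post$w, 2, sum) * post$sigma),
    lambda = sum(apply(post$w, 3, sum) * post$lambda))
}

#' Run an adaptive staircase against a simulated observer
#'
#' Simulates a full staircase: at each trial the entropy-minimizing
#' stimulus is selected, a binary response is drawn from the
#' Gaussian-CDF-plus-lapse psychometric observer with parameters `truth`,
#' and the posterior is updated.
#'
#' @param n_trials number of trials.
#' @param truth named numeric `c(mu, sigma, lambda)` of the simulated
#'   observer.
#' @param candidates candidate stimulus grid (default 41 points spanning
#'   the mu grid).
#' @param post starting posterior (default [staircase_posterior()]).
#' @param seed integer seed.
#' @return List with the final posterior, posterior-mean `estimates`, and
#'   the per-trial `stimuli` and `responses`.
#' @export
run_staircase <- function(n_trials, truth, candidates = seq(-0.5, 0.5, length.out = 41),
                          post = staircase_posterior(), seed = 1L) {
  stimuli <- numeric(n_trials)
  responses <- integer(n_trials)
  with_seed(substream_seed(seed, "staircase"), {
    for (i in seq_len(n_trials)) {
      s <- adaptive_staircase_next(post, candidates)$stimulus
      p1 <- psychometric_prob(s, truth[["mu"]], truth[["sigma"]], truth[["lambda"]])
      r <- stats::rbinom(1, 1, p1)
      post <- staircase_update(post, s, r)
      stimuli[i] <- s
      responses[i] <- r
    }
  })
  list(posterior = post, estimates = staircase_estimates(post),
       stimuli = stimuli, responses = responses)
}
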