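# Internal utilities shared across modules.

# Derive a deterministic 31-bit sub-seed from a master seed and a stage name,
# so pipeline stages can be re-run independently with one global seed.
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% 2147483647
  as.integer((abs(seed) * 2654435761 + h) %% 2147483647 + 1)
}

# Run an expression with a local RNG state (does not disturb the caller's).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# log(exp(la) - exp(lb)) for la > lb, computed stably.
log_diff_exp <- function(la, lb) {
  la + log1p(-exp(lb - la))
}

# Numerically stable log(pnorm(b) - pnorm(a)) for b > a (standard normal).
# Mirrors into the lower tail when both endpoints are positive.
log_pnorm_diff <- function(a, b) {
  flip <- a > 0
  if (any(flip)) {
    tmp <- a[flip]
    a[flip] <- -b[flip]
    b[flip] <- -tmp
  }
  log_diff_exp(stats::pnorm(b, log.p = TRUE), stats::pnorm(a, log.p = TRUE))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
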