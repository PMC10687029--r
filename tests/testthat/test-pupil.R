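make_series <- function(n_trials = 4, rate = 100, noise = 2, gain = 120,
                        d = NULL, seed = 3) {
  if (is.null(d)) d <- rep(c(0.5, 3), length.out = n_trials)
  simulate_pupil(d, pupil_model(rate = rate, noise_sd = noise, gain = gain),
                 seed = seed)
}

test_that("artifact removal bridges injected spikes and leaves the rest alone", {
  ser <- make_series(n_trials = 3, noise = 1)
  clean0 <- remove_artifacts(ser)
  # clean input: nothing flagged
  expect_true(all(!unlist(clean0$mask)))
  expect_equal(clean0$trials, ser$trials)

  spiked <- ser
  spiked$trials[[2]][300] <- spiked$trials[[2]][300] + 400
  cleaned <- remove_artifacts(spiked)
  expect_true(any(cleaned$mask[[2]]))
  expect_false(any(cleaned$mask[[1]]))
  # hand-computed bridge for the flagged segment
  seg <- range(which(cleaned$mask[[2]]))
  pad <- round(0.02 * ser$rate)
  pre <- mean(spiked$trials[[2]][(seg[1] - pad):(seg[1] - 1)])
  post <- mean(spiked$trials[[2]][(seg[2] + 1):(seg[2] + pad)])
  k <- seq_len(seg[2] - seg[1] + 1)
  want <- pre + (post - pre) * k / (seg[2] - seg[1] + 2)
  expect_equal(cleaned$trials[[2]][seg[1]:seg[2]], want)
  # untouched outside the segment
  outside <- setdiff(seq_along(ser$trials[[2]]), seg[1]:seg[2])
  expect_equal(cleaned$trials[[2]][outside], spiked$trials[[2]][outside])

  # constant series: no removal
  const <- ser
  const$trials <- lapply(const$trials, function(a) rep(500, length(a)))
  expect_true(all(!unlist(remove_artifacts(const)$mask)))
})

test_that("the band-pass keeps passband sinusoids and rejects DC and 50 Hz", {
  # the 0.01 Hz high-pass edge has a ~100 s time constant, so DC removal
  # needs a long trace before the middle of the series settles near zero
  rate <- 200
  t <- seq(0, 400, by = 1 / rate)
  ser <- structure(list(rate = rate, trials = list(), events = NULL),
                   class = "pupil_series")
  ser$trials <- list(rep(3, length(t)),
                     sin(2 * pi * 1 * t),
                     sin(2 * pi * 50 * t))
  out <- bandpass_filter(ser)
  mid <- seq(round(length(t) * 0.4), round(length(t) * 0.6))
  expect_lt(max(abs(out$trials[[1]][mid])), 0.15)           # DC removed
  amp1 <- diff(range(out$trials[[2]][mid])) / 2
  expect_gt(amp1, 0.95)                                      # 1 Hz preserved
  expect_lt(abs(amp1 - 1), 0.05)
  amp50 <- diff(range(out$trials[[3]][mid])) / 2
  expect_lt(amp50, 0.1)                                      # 50 Hz attenuated >90%
  expect_error(bandpass_filter(structure(list(rate = 15, trials = list(1:10)),
                                         class = "pupil_series")),
               "sampling rate")
})

test_that("normalization subtracts baselines and scales by the participant max", {
  ser <- make_series(n_trials = 2, noise = 0, gain = 100, d = c(0, 3))
  norm <- normalize_pupil(ser)
  # baseline window (last 400 ms of fixation) is centred on zero afterwards
  rate <- ser$rate
  b_idx <- which(seq_along(norm$trials[[1]]) - 1 >= 0.6 * rate &
                   seq_along(norm$trials[[1]]) - 1 < 1 * rate)
  expect_equal(mean(norm$trials[[1]][b_idx]), 0, tolerance = 1e-10)
  expect_equal(max(unlist(norm$trials)), 1)
  # peak ordering is preserved (monotone transform)
  raw_peaks <- vapply(ser$trials, max, numeric(1))
  new_peaks <- vapply(norm$trials, max, numeric(1))
  expect_equal(order(raw_peaks), order(new_peaks))

  flat <- ser
  flat$trials <- lapply(flat$trials, function(a) rep(200, length(a)))
  expect_error(normalize_pupil(flat), "maximum")
})

test_that("window averages use the configured decision-locked windows", {
  cfg <- preprocess_config()
  expect_equal(cfg$stim_window, c(2, 2.5))
  expect_equal(cfg$resp_window, c(0.5, 1))
  expect_equal(cfg$mad_multiplier, 16)
  ser <- make_series(n_trials = 1, noise = 0)
  ser$trials[[1]][] <- 0.3
  expect_equal(window_average(ser, "stimulus"), 0.3)
  expect_equal(window_average(ser, "response"), 0.3)
  expect_error(window_average(ser, "stimulus", window = c(10, 11)), "window")
})

test_that("moving-window regression flags degenerate windows instead of failing", {
  withr::with_seed(2, {
    pupil <- matrix(rnorm(60 * 30), 60, 30)
    predictors <- data.frame(participant = rep(c("a", "b", "c"), each = 20),
                             condition = "NoAdaptSee",
                             x = 0)  # zero-variance predictor
    mw <- moving_window_regression(pupil, rate = 100, predictors)
    expect_true(all(mw$singular | is.na(mw$t) | mw$effect != "x" |
                      !mw$significant))
  })
})
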