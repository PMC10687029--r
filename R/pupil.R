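#' Pupil preprocessing configuration
#'
#' Defaults follow the standard pupillometry pipeline used here: artifact
#' segments are samples whose dilation speed exceeds
#' `median + 16 * MAD` of the pooled speeds; removed segments are bridged
#' using 20 ms of context each side; traces are filtered with a zero-phase
#' order-2 Butterworth band-pass (0.01-10 Hz, applied as a high-pass then
#' a low-pass step); each trial is baseline-corrected by the mean of the
#' last 400 ms of fixation; decision-locked windows are 2000-2500 ms after
#' stimulus onset and 500-1000 ms after response; moving-window analyses
#' use 200 ms windows stepped by 20 ms.
#'
#' @param mad_multiplier speed-threshold multiplier (default 16).
#' @param interp_pad interpolation context, seconds (default 0.02).
#' @param filter_order Butterworth order (default 2).
#' @param passband band-pass edges, Hz.
#' @param baseline_window baseline duration before adaptor onset, seconds.
#' @param stim_window stimulus-locked window, seconds after stimulus onset.
#' @param resp_window response-locked window, seconds after response.
#' @param moving_width,moving_step moving-window width and step, seconds.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(mad_multiplier = 16, interp_pad = 0.02,
                              filter_order = 2, passband = c(0.01, 10),
                              baseline_window = 0.4,
                              stim_window = c(2, 2.5),
                              resp_window = c(0.5, 1),
                              moving_width = 0.2, moving_step = 0.02) {
  stopifnot(mad_multiplier > 0, interp_pad > 0, filter_order >= 1,
            length(passband) == 2, passband[1] > 0, passband[1] < passband[2],
            baseline_window > 0, moving_width > 0, moving_step > 0)
  structure(list(mad_multiplier = mad_multiplier, interp_pad = interp_pad,
                 filter_order = filter_order, passband = passband,
                 baseline_window = baseline_window, stim_window = stim_window,
                 resp_window = resp_window, moving_width = moving_width,
                 moving_step = moving_step),
            class = "preprocess_config")
}

#' Remove dilation-speed artifacts
#'
#' Flags samples belonging to segments where the absolute dilation speed
#' (forward difference divided by the sample interval) exceeds
#' `median(speed) + mad_multiplier * MAD(speed)`, pooling speeds across
#' trials for the threshold. Flagged segments closer than the
#' interpolation pad are merged, then each segment is replaced by a linear
#' bridge between the mean area over the pad before and after the segment.
#' Samples outside flagged segments are never modified.
#'
#' @param series a `pupil_series` (see [simulate_pupil()]).
#' @param config a [preprocess_config()].
#' @return The series with cleaned trials and a `mask` element (list of
#'   logical vectors, `TRUE` where samples were replaced).
#' @export
remove_artifacts <- function(series, config = preprocess_config()) {
  rate <- series$rate
  speeds <- lapply(series$trials, function(a) abs(diff(a)) * rate)
  pooled <- unlist(speeds)
  threshold <- stats::median(pooled) + config$mad_multiplier * stats::mad(pooled)
  pad <- max(1L, round(config$interp_pad * rate))
  cleaned <- vector("list", length(series$trials))
  mask <- vector("list", length(series$trials))
  for (i in seq_along(series$trials)) {
    a <- series$trials[[i]]
    n <- length(a)
    if (n < 2) stop("trial ", i, " has fewer than 2 samples", call. = FALSE)
    bad <- logical(n)
    over <- which(speeds[[i]] > threshold)
    bad[over] <- TRUE
    bad[pmin(over + 1L, n)] <- TRUE
    if (any(bad)) {
      # merge segments separated by less than the pad
      runs <- rle(bad)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      gap <- which(!runs$values & runs$lengths < pad)
      gap <- gap[gap > 1 & gap < length(runs$values)]
      for (g in gap) bad[starts[g]:ends[g]] <- TRUE
      if (all(bad)) stop("all samples flagged as artifacts in trial ", i, call. = FALSE)
      runs <- rle(bad)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (seg in which(runs$values)) {
        s0 <- starts[seg]; s1 <- ends[seg]
        pre_idx <- max(1L, s0 - pad):(s0 - 1L)
        post_idx <- (s1 + 1L):min(n, s1 + pad)
        pre <- if (s0 > 1) mean(a[pre_idx]) else NA
        post <- if (s1 < n) mean(a[post_idx]) else NA
        if (is.na(pre)) pre <- post
        if (is.na(post)) post <- pre
        k <- seq_len(s1 - s0 + 1L)
        a[s0:s1] <- pre + (post - pre) * k / (s1 - s0 + 2L)
      }
    }
    cleaned[[i]] <- a
    mask[[i]] <- bad
  }
  series$trials <- cleaned
  series$mask <- mask
  series
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies the band-pass in two steps per trial, high-pass then low-pass,
#' each as a forward-backward (zero-phase) Butterworth filter of the
#' configured order.
#'
#' @inheritParams remove_artifacts
#' @return The series with filtered trials.
#' @export
bandpass_filter <- function(series, config = preprocess_config()) {
  rate <- series$rate
  nyq <- rate / 2
  if (config$passband[2] >= nyq) {
    stop("sampling rate must exceed twice the upper cutoff", call. = FALSE)
  }
  hp <- signal::butter(config$filter_order, config$passband[1] / nyq, type = "high")
  lp <- signal::butter(config$filter_order, config$passband[2] / nyq, type = "low")
  min_len <- 3 * (2 * config$filter_order + 1)
  series$trials <- lapply(series$trials, function(a) {
    if (length(a) < min_len) {
      stop("trial shorter than the filter warm-up (", min_len, " samples)",
           call. = FALSE)
    }
    as.numeric(signal::filtfilt(lp, signal::filtfilt(hp, a)))
  })
  series
}

#' Baseline-subtract and normalize pupil traces
#'
#' Subtracts each trial's baseline (mean area over the last
#' `baseline_window` seconds of fixation, i.e. just before adaptor onset)
#' and divides every trial by the participant's maximum baseline-corrected
#' value across all conditions.
#'
#' @inheritParams remove_artifacts
#' @return The series with normalized trials and a `norm_max` element.
#' @export
normalize_pupil <- function(series, config = preprocess_config()) {
  rate <- series$rate
  corrected <- lapply(seq_along(series$trials), function(i) {
    a <- series$trials[[i]]
    b1 <- series$events$adaptor_onset[i]
    b0 <- b1 - config$baseline_window
    idx <- which(seq_along(a) - 1 >= b0 * rate & seq_along(a) - 1 < b1 * rate)
    if (length(idx) == 0) stop("baseline window outside trial ", i, call. = FALSE)
    a - mean(a[idx])
  })
  norm_max <- max(unlist(corrected))
  if (norm_max <= 0) stop("participant maximum is not positive", call. = FALSE)
  series$trials <- lapply(corrected, function(a) a / norm_max)
  series$norm_max <- norm_max
  series
}

#' Windowed pupil average
#'
#' Mean pupil value per trial within an event-locked window.
#'
#' @inheritParams remove_artifacts
#' @param lock `"stimulus"` or `"response"`.
#' @param window window in seconds relative to the locking event; defaults
#'   to the configured stimulus (2000-2500 ms) or response (500-1000 ms)
#'   window.
#' @return Numeric vector, one mean per trial.
#' @export
window_average <- function(series, lock = c("stimulus", "response"),
                           window = NULL, config = preprocess_config()) {
  lock <- match.arg(lock)
  if (is.null(window)) {
    window <- if (lock == "stimulus") config$stim_window else config$resp_window
  }
  onset <- if (lock == "stimulus") series$events$stimulus_onset else series$events$response_time
  rate <- series$rate
  vapply(seq_along(series$trials), function(i) {
    a <- series$trials[[i]]
    t0 <- onset[i] + window[1]
    t1 <- onset[i] + window[2]
    idx <- which(seq_along(a) - 1 >= t0 * rate & seq_along(a) - 1 < t1 * rate)
    if (length(idx) == 0 || t1 * rate > length(a)) {
      stop("window exceeds trial ", i, " span", call. = FALSE)
    }
    mean(a[idx])
  }, numeric(1))
}

#' Moving-window mixed-effects uncertainty regression
#'
#' Steps a window of `moving_width` seconds by `moving_step` across
#' event-locked pupil traces; in each window, the per-trial mean pupil
#' value is regressed on a ranked predictor (typically ranked `|d|` or
#' ranked `|s|`) plus condition dummies, with random intercepts and slopes
#' per participant (the ranked mixed-effects specification; see
#' [ranked_glme()]). Emits the fixed-effect t statistics per window and a
#' significance flag at p < 0.01 (normal approximation). Singular or
#' failed fits are flagged per window, not fatal.
#'
#' @param pupil matrix of event-locked pupil values, trials in rows,
#'   samples in columns starting at the locking event.
#' @param rate sampling rate of the matrix, Hz.
#' @param predictors data.frame with one row per trial: `participant`,
#'   `condition`, `x` (the raw predictor, ranked internally), optional
#'   `rt` if `include_rt`.
#' @param config a [preprocess_config()].
#' @param include_rt include ranked RT as a covariate.
#' @return data.frame of class `moving_window_fit`: one row per window and
#'   fixed effect with `window_center` (s), `effect`, `estimate`, `t`,
#'   `significant`, `singular`.
#' @export
moving_window_regression <- function(pupil, rate, predictors,
                                     config = preprocess_config(),
                                     include_rt = FALSE) {
  stopifnot(nrow(pupil) == nrow(predictors))
  width <- round(config$moving_width * rate)
  step <- max(1L, round(config$moving_step * rate))
  starts <- seq(1L, ncol(pupil) - width + 1L, by = step)
  crit <- stats::qnorm(1 - 0.01 / 2)
  out <- list()
  for (st in starts) {
    y <- rowMeans(pupil[, st:(st + width - 1L), drop = FALSE])
    df <- data.frame(participant = predictors$participant,
                     condition = predictors$condition,
                     x = predictors$x, y = y)
    if (include_rt) df$rt <- predictors$rt
    fit <- try(ranked_glme(df, response = "y", predictor = "x",
                           include_rt = include_rt), silent = TRUE)
    center <- (st - 1 + width / 2) / rate
    if (inherits(fit, "try-error")) {
      out[[length(out) + 1L]] <- data.frame(
        window_center = center, effect = "x", estimate = NA_real_,
        t = NA_real_, significant = FALSE, singular = TRUE)
      next
    }
    co <- fit$coefficients
    out[[length(out) + 1L]] <- data.frame(
      window_center = center, effect = rownames(co),
      estimate = co[, "estimate"], t = co[, "t"],
      significant = abs(co[, "t"]) > crit,
      singular = fit$singular, row.names = NULL)
  }
  structure(do.call(rbind, out), class = c("moving_window_fit", "data.frame"))
}

#' Event-locked pupil matrix
#'
#' Extracts a trials-by-samples matrix locked to an event, for
#' [moving_window_regression()].
#'
#' @inheritParams window_average
#' @param duration seconds after the locking event to extract.
#' @return Numeric matrix, one row per trial.
#' @export
pupil_epoch_matrix <- function(series, lock = c("stimulus", "response"),
                               duration = 2.5) {
  lock <- match.arg(lock)
  onset <- if (lock == "stimulus") series$events$stimulus_onset else series$events$response_time
  rate <- series$rate
  n_samp <- round(duration * rate)
  mat <- t(vapply(seq_along(series$trials), function(i) {
    a <- series$trials[[i]]
    i0 <- round(onset[i] * rate) + 1L
    if (i0 + n_samp - 1L > length(a)) {
      stop("epoch exceeds trial ", i, " span", call. = FALSE)
    }
    a[i0:(i0 + n_samp - 1L)]
  }, numeric(n_samp)))
  mat
}
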