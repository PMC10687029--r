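#' Pipeline configuration
#'
#' Collects every tunable of the simulation-to-analysis pipeline with the
#' study's standard values: 121 trials per condition on stimulus bounds
#' \[-0.3, 0.3\], 500 measurement samples and 14 optimizer starts for the
#' Bayesian model fits, the default psychometric grids, the DDM grid
#' (dnu = 0.01, dt = 0.0005), and the pupil preprocessing defaults.
#'
#' @param seed master seed; stage seeds are derived substreams.
#' @param trials_per_condition trials per condition.
#' @param s_bounds stimulus bounds.
#' @param n_samples,n_starts Bayesian model-fitting settings.
#' @param bayes_variants model variants to fit.
#' @param observer the generating [ground_truth_observer()].
#' @param ddm_variant DDM variant for the fitting stage.
#' @param ddm_grid list with `dnu` and `dt`.
#' @param pupil a [preprocess_config()].
#' @param pupil_rate sampling rate for simulated pupil traces, Hz.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, trials_per_condition = 121L,
                       s_bounds = c(-0.3, 0.3), n_samples = 500L,
                       n_starts = 14L,
                       bayes_variants = c("mu_likelihood", "k_choice"),
                       observer = ground_truth_observer("insightful"),
                       ddm_variant = "base",
                       ddm_grid = list(dnu = 0.01, dt = 5e-4),
                       pupil = preprocess_config(),
                       pupil_rate = 100) {
  structure(list(seed = as.integer(seed),
                 trials_per_condition = as.integer(trials_per_condition),
                 s_bounds = s_bounds, n_samples = as.integer(n_samples),
                 n_starts = as.integer(n_starts),
                 bayes_variants = bayes_variants, observer = observer,
                 ddm_variant = ddm_variant, ddm_grid = ddm_grid,
                 pupil = pupil, pupil_rate = pupil_rate),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Reads the plain-text key/value file written by [run_pipeline()] (or
#' authored by hand) holding seeds, stimulus bounds, trial counts and
#' fitting settings, and rebuilds a [run_config()]. Observer fields not
#' present fall back to the defaults.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  obs_fields <- raw$observer
  observer <- ground_truth_observer()
  if (!is.null(obs_fields$mu_encoding)) {
    observer <- ground_truth_observer(mu_adapt = obs_fields$mu_encoding[[2]])
  }
  run_config(
    seed = raw$seed %||% 1L,
    trials_per_condition = raw$trials_per_condition %||% 121L,
    s_bounds = unlist(raw$s_bounds) %||% c(-0.3, 0.3),
    n_samples = raw$n_samples %||% 500L,
    n_starts = raw$n_starts %||% 14L,
    bayes_variants = unlist(raw$bayes_variants) %||%
      c("mu_likelihood", "k_choice"),
    observer = observer,
    ddm_variant = raw$ddm_variant %||% "base",
    pupil_rate = raw$pupil_rate %||% 100
  )
}

config_hash <- function(config) {
  substream_seed(1L, paste(utils::capture.output(utils::str(config)), collapse = "\n"))
}

write_stamped <- function(df, path, hash) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %d", hash), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full synthetic pipeline
#'
#' Executes the requested stages in order -- simulate, fit_psychometric,
#' fit_bayes, compare_models, fit_ddm, preprocess_pupil, pupil_regression
#' -- writing each stage's outputs as delimited text into `out_dir`
#' together with the resolved configuration (YAML) and a log. Each output
#' file carries the configuration hash; identical configurations give
#' byte-identical numeric outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param stages ordered subset of the stage names above.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("insightrun"),
                         stages = c("simulate", "fit_psychometric", "fit_bayes",
                                    "compare_models", "fit_ddm",
                                    "preprocess_pupil", "pupil_regression")) {
  known <- c("simulate", "fit_psychometric", "fit_bayes", "compare_models",
             "fit_ddm", "preprocess_pupil", "pupil_regression")
  stages <- match.arg(stages, known, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  log_path <- file.path(out_dir, "pipeline.log")
  logline <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), sprintf(...)),
        file = log_path, append = TRUE)
  }
  cfg_dump <- config
  cfg_dump$observer <- unclass(cfg_dump$observer$spec)[
    c("variant", "mu_encoding", "sigma_encoding", "mu_likelihood", "prior",
      "k_choice", "k_confidence")]
  yaml::write_yaml(lapply(cfg_dump, function(x) if (is.list(x)) lapply(x, as.vector) else as.vector(x)),
                   file.path(out_dir, "config.yaml"))
  logline("config hash %d; stages: %s", hash, paste(stages, collapse = ", "))
  results <- list()
  run_stage <- function(name, fn) {
    t0 <- Sys.time()
    res <- tryCatch(fn(), error = function(e) {
      logline("stage %s FAILED: %s", name, conditionMessage(e))
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
    logline("stage %s done in %.1f s", name,
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }
  table <- NULL
  for (stage in stages) {
    if (stage == "simulate") {
      results$table <- run_stage(stage, function() {
        stimuli <- simulate_stimuli(config$trials_per_condition, config$s_bounds,
                                    seed = config$seed, include_zero = TRUE)
        tab <- simulate_trials(config$observer, stimuli, seed = config$seed)
        write_trial_table(tab, file.path(out_dir, "trials.csv"))
        truth <- ground_truth(tab)$trials
        write_stamped(truth, file.path(out_dir, "ground_truth.csv"), hash)
        tab
      })
    }
    table <- results$table %||% table
    if (stage == "fit_psychometric") {
      results$psychometric <- run_stage(stage, function() {
        fit <- fit_psychometric(table)
        out <- fit$params
        out$lambda <- fit$lambda
        write_stamped(out, file.path(out_dir, "psychometric.csv"), hash)
        curve <- bin_curve(table, "choice_clockwise")
        write_stamped(curve, file.path(out_dir, "choice_curve.csv"), hash)
        fit
      })
    }
    if (stage == "fit_bayes") {
      results$bayes <- run_stage(stage, function() {
        mu_enc <- bayes_mu_encoding(results$psychometric, config$observer)
        fits <- lapply(config$bayes_variants, function(v) {
          fit_bayes_model(table, v, mu_enc, n_starts = config$n_starts,
                          n_samples = config$n_samples, seed = config$seed)
        })
        names(fits) <- config$bayes_variants
        params <- do.call(rbind, lapply(names(fits), function(v) {
          sp <- fits[[v]]$spec
          data.frame(variant = v, condition = sp$conditions,
                     sigma_encoding = sp$sigma_encoding,
                     mu_likelihood = sp$mu_likelihood, prior = sp$prior,
                     k_choice = sp$k_choice, k_confidence = sp$k_confidence,
                     logLik = fits[[v]]$logLik, AIC = fits[[v]]$AIC,
                     BIC = fits[[v]]$BIC, row.names = NULL)
        }))
        write_stamped(params, file.path(out_dir, "bayes_fits.csv"), hash)
        fits
      })
    }
    if (stage == "compare_models") {
      results$comparison <- run_stage(stage, function() {
        fits <- results$bayes
        if (is.null(fits) || length(fits) < 2) {
          stop("compare_models needs >= 2 fitted variants")
        }
        ic <- do.call(rbind, lapply(names(fits), function(v) {
          data.frame(participant = "sim01", variant = v,
                     AIC = fits[[v]]$AIC, BIC = fits[[v]]$BIC)
        }))
        cmp <- compare_models(ic, reference = names(fits)[1], n_boot = 1000,
                              seed = config$seed)
        write_stamped(as.data.frame(cmp), file.path(out_dir, "model_comparison.csv"),
                      hash)
        cmp
      })
    }
    if (stage == "fit_ddm") {
      results$ddm <- run_stage(stage, function() {
        fit <- fit_ddm(table, config$ddm_variant, seed = config$seed)
        out <- fit$param_table
        out$logLik <- fit$logLik
        out$AIC <- fit$AIC
        out$BIC <- fit$BIC
        write_stamped(out, file.path(out_dir, "ddm_fit.csv"), hash)
        crf <- conditional_response_function(table)
        write_stamped(crf, file.path(out_dir, "crf.csv"), hash)
        fit
      })
    }
    if (stage == "preprocess_pupil") {
      results$pupil <- run_stage(stage, function() {
        truth <- ground_truth(table)$trials
        model <- pupil_model(rate = config$pupil_rate)
        series <- simulate_pupil(truth$d, model, seed = config$seed,
                                 condition = truth$condition)
        series <- normalize_pupil(bandpass_filter(remove_artifacts(series,
                                                                   config$pupil),
                                                  config$pupil), config$pupil)
        wa <- window_average(series, "stimulus", config = config$pupil)
        out <- data.frame(trial = seq_along(wa), condition = truth$condition,
                          abs_d = abs(truth$d), pupil_stim_window = wa)
        write_stamped(out, file.path(out_dir, "pupil_windows.csv"), hash)
        list(series = series, windows = out)
      })
    }
    if (stage == "pupil_regression") {
      results$pupil_regression <- run_stage(stage, function() {
        if (is.null(results$pupil)) stop("pupil_regression needs preprocess_pupil")
        win <- results$pupil$windows
        # single simulated participant: a fixed-effect rank regression of
        # the windowed pupil on ranked |d|
        fit <- stats::lm(pupil_stim_window ~ rank(abs_d) + condition, data = win)
        co <- summary(fit)$coefficients
        out <- data.frame(effect = rownames(co), estimate = co[, 1],
                          t = co[, 3], row.names = NULL)
        write_stamped(out, file.path(out_dir, "pupil_regression.csv"), hash)
        out
      })
    }
  }
  invisible(results)
}

# mu_encoding values for the Bayes fits: taken from the psychometric fit
# (No-Adapt-See and Adapt-See biases) when available, otherwise from the
# generating observer.
bayes_mu_encoding <- function(psy_fit, observer) {
  if (!is.null(psy_fit)) {
    mu <- stats::setNames(psy_fit$params$mu, psy_fit$params$condition)
    if (all(c("NoAdaptSee", "AdaptSee") %in% names(mu))) {
      return(c(NoAdapt = unname(mu[["NoAdaptSee"]]), Adapt = unname(mu[["AdaptSee"]])))
    }
  }
  c(NoAdapt = unname(observer$spec$mu_encoding[["NoAdapt"]]),
    Adapt = unname(observer$spec$mu_encoding[["Adapt"]]))
}
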