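# insightobs

Bayesian observer modelling of **perceptual insight**: can an observer
discount a known internal perceptual distortion — such as a motion
after-effect (MAE), where a static spiral appears to rotate opposite to a
previously viewed adaptor — and if so, at which stage of processing?

The package implements, as tested reusable components, the computational
pipeline of a psychophysics study on this question:

* a **synthetic-experiment generator**: a ground-truth Bayesian observer
  (encoding offset, encoding noise, response policy) that produces
  choices, binary confidence reports, response times, and pupil-area
  traces for the 2×2 task design (No-Adapt/Adapt × See/Believe, 121
  trials/condition, stimulus speeds uniform on [−0.3, 0.3]), plus the
  entropy-minimizing adaptive staircase used for stimulus placement;
* **psychometric curve fitting** by exhaustive grid-search MLE of the
  Gaussian-CDF-plus-lapse model, `p(r=1|s) = λ/2 + (1−λ)Φ(s; μ, σ)`,
  with condition-specific (μ, σ) and one shared lapse λ, and the MAE
  compensation index `(μ_AB − μ_AS)/|μ_AS|`;
* the **Bayesian observer family**: the decision variable
  `d = logit p(C=1) + log[(Φ(s₁₂−μ_L−x) − Φ(s₁₁−μ_L−x)) /
  (Φ(s₂₂−μ_L−x) − Φ(s₂₁−μ_L−x))]`, thresholded into choice
  (`d > k_choice`) and confidence (posterior of the chosen option vs.
  `k_confidence`), six variants differing in which compensation
  parameters are free (μ_likelihood, category prior, k_choice, hybrids),
  sampling-based joint choice–confidence likelihoods with extreme-value
  clipping, multi-start fitting, and AIC/BIC model comparison with
  participant-level bootstrap CIs;
* **drift-diffusion variants** (base, starting-point bias, drift-rate
  bias, both) with Euler simulation, Fokker–Planck *and* exact
  first-passage likelihoods, differential-evolution fitting, and
  conditional response functions (choice bias across 5 RT quantiles);
* **pupillometry preprocessing** (speed-based artifact removal at
  median + 16·MAD, zero-phase order-2 Butterworth band-pass 0.01–10 Hz,
  baseline and participant-max normalization) and moving-window ranked
  mixed-effects regressions of pupil area on decision uncertainty |d|;
* the **nonparametric statistics** used throughout: signed-rank z with
  effect size r = z/√(2N), paired Cohen's d = t/√N, BCa and percentile
  bootstrap intervals, η², and the ranked GLME specifications.

Everything is buildable and testable from the synthetic-data module
alone; no external downloads are required.

## Worked example

Simulate an insightful observer (encoding offset −0.1 in the Adapt
conditions, compensated at the inference stage in Adapt-Believe), fit
psychometric curves, and fit the perceptual-insight observer model:

```r
library(insightobs)

observer <- ground_truth_observer("insightful")
stimuli  <- simulate_stimuli(121, seed = 7, include_zero = TRUE)
trials   <- simulate_trials(observer, stimuli, seed = 7)

fit <- fit_psychometric(trials)
fit
#> <psychometric_fit> LL = -53.30, shared lambda = 0 (n = 484)
#>        condition     mu  sigma
#> 1     NoAdaptSee  0.018 0.0437
#> 2 NoAdaptBelieve  0.016 0.0390
#> 3       AdaptSee -0.082 0.0454
#> 4   AdaptBelieve  0.004 0.0348

mae_compensation_index(fit)
#> [1] 1.049
```

The Adapt-See curve shows the MAE as a negative bias (≈ −0.08, true
offset −0.1), Adapt-Believe returns to ≈ 0: a compensation index of
1.049 means essentially exact compensation (0 = none, 1 = exact,
> 1 = overcompensation). Fitting the insight model with the encoding
offsets fixed to the two See-condition biases recovers where the
compensation happened:

```r
bayes <- fit_bayes_model(trials, "mu_likelihood",
                         mu_encoding = c(fit$params$mu[1], fit$params$mu[3]),
                         n_starts = 14, seed = 7)
round(bayes$spec$mu_likelihood, 3)
#>     NoAdaptSee NoAdaptBelieve       AdaptSee   AdaptBelieve
#>         -0.003         -0.001          0.015         -0.088
```

Only Adapt-Believe carries a non-zero assumed offset (−0.088 vs. a true
−0.1): the fitted observer compensates by shifting its likelihood, not
its response criterion. `compare_models()` formalizes this across a
cohort, and `fit_ddm()` / `conditional_response_function()` ask the same
question of the response-time data. `run_pipeline()` chains every stage
(simulate → psychometric → observer models → comparison → DDM → pupil)
into a reproducible artifact directory.

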