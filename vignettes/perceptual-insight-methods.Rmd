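---
title: "Modelling perceptual insight: methods and design notes"
author: "insightobs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling perceptual insight: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insightobs)
```

# The scientific problem

When a visual adaptor induces a motion after-effect (MAE), a subsequently
viewed static spiral appears to rotate in the opposite direction: the
stimulus speed `s` is encoded as an internal measurement `x` that is both
noisy and *offset*. A nulling design measures the illusion as the bias
(point of subjective equality, PSE) of a psychometric curve: the stimulus
speed that cancels the illusory motion. The question this package
addresses computationally is *where* in the processing hierarchy an
observer can compensate for such a known internal distortion when asked to
report not what they *see* but what they *believe* is physically present:

* at an **intermediate inference stage**, by incorporating knowledge of
  the offset into the likelihood used to form the perceptual decision
  variable (perceptual insight), or
* at a **late response stage**, by shifting the criterion applied to an
  unchanged decision variable (response bias).

The two accounts are behaviourally dissociable: inference-level
compensation shifts the choice psychometric curve *and* the confidence
curve (whose minimum sits at the subjective neutral point) in tandem,
whereas a criterion shift moves the choice curve alone. The same logic
extends to response times, pupil dilation (both driven by decision
uncertainty) and to drift-diffusion decompositions of the choice process.

# The observer model

The task is a 2-by-2 design (No-Adapt/Adapt crossed with See/Believe)
with binary direction choices and binary confidence, 121 trials per
condition with `s` uniform on [-0.3, 0.3] (arbitrary task units; the
conversion to degrees of visual angle per second is the temporal/spatial
frequency ratio exposed by `spiral_velocity()`).

**Encoding.** On each trial `x ~ Normal(s - A, sigma_encoding)`, where
the offset `A` has mean `mu_encoding` (0 for No-Adapt; negative for
Adapt, producing the leftward MAE shift) and spread `sigma_A`. The
fitted model family assumes `sigma_A ~ 0` (a delta function); the full
model with `sigma_A > 0` is retained as a numeric-quadrature oracle
(`decision_variable_oracle()`), and the closed form is required to agree
with it to 1e-4 relative as `sigma_A -> 0`.

**Inference.** The decision variable is the log-posterior ratio of the
clockwise versus counterclockwise category. With category intervals
`[s11, s12]` and `[s21, s22]` (defaults 0..0.3 and -0.3..0) and an
assumed offset `mu_likelihood`,

$$d(x) = \mathrm{logit}\, p(C=1) + \log \frac{\Phi(s_{12} - \mu_L - x) -
\Phi(s_{11} - \mu_L - x)}{\Phi(s_{22} - \mu_L - x) - \Phi(s_{21} - \mu_L
- x)},$$

all CDFs with scale `sigma_encoding`. Because the CDF differences
underflow for extreme `x`, `decision_variable()` works throughout in log
space with tail mirroring (`log` CDFs combined via `log1p`), so `d` is
finite and strictly increasing everywhere.

**Response.** Choice is clockwise iff `d > k_choice` (strict). The
confidence value is the posterior probability of the chosen option,
`1/(1 + exp(-|d|))`, thresholded at `k_confidence` in (0.5, 1); the
`k_choice_confidence` variant computes confidence from `|d - k_choice|`,
letting a late criterion move the confidence curve too. The printed
source formula for confidence (`1/(1+e^{|d|})`) is bounded above by 0.5
and cannot be compared against a threshold in (0.5, 1); we use the
posterior-of-the-chosen-option form, which is the quantity the
architecture describes.

**Variants.** Six model variants share fixed `mu_encoding` (one No-Adapt
and one Adapt value, conventionally taken from the psychometric fits of
the two See conditions) and free per-condition `sigma_encoding` and
`k_confidence`, and differ in which compensation parameters are free:
`mu_likelihood`, `prior`, both, `k_choice`, `mu_likelihood + k_choice`,
or `k_choice_confidence`. Neutral values are 0 (offsets and criteria)
and 0.5 (prior).

# Fitting

**Psychometric curves** (`fit_psychometric()`) use the exhaustive
grid-search MLE protocol: for each shared lapse `lambda` on its grid,
four independent two-dimensional (mu, sigma) scans maximize the
Bernoulli likelihood per condition; the best `lambda` overall wins.
Default grids are 201 points per parameter (mu linear -0.2..0.2, sigma
logarithmic 1e-4..0.2, lambda linear 0..0.3), with a 101-point variant
for the staircase experiment's wider ranges. The scan is exact (it *is*
the estimator), implemented in C++ for the ~10^9 likelihood terms of a
default fit. Grid ties break deterministically toward smaller sigma,
then smaller |mu|. In recovery tests, "within two grid steps" refers to
the grid actually used by the fit; recovery experiments use 51-point
grids matched to their sample sizes (at 484 trials/condition the
Fisher-information SE of the bias is about 0.005 task units, so steps of
the 201-point grid are far below the statistical resolution of any
realistic sample).

**Observer models** (`fit_bayes_model()`) are fitted jointly to choice
and confidence by maximizing the sampled likelihood: 500 measurement
samples per trial (common random numbers, keyed by condition and
stimulus value so the likelihood is trial-order invariant), predicted
outcome probabilities clipped at `1/n_samples` and `1 - 1/n_samples`
before the log. Because `d` is strictly increasing in `x`, each joint
(choice, confidence) outcome occupies a contiguous interval of `x`; the
implementation inverts the decision rule's three thresholds once per
evaluation and counts pre-sorted samples by binary search, which is
exactly the naive per-sample computation (asserted in the tests) but
orders of magnitude faster. Every free parameter is condition-specific,
so the joint optimum decomposes into per-condition 3-4 parameter
problems. The optimizer protocol is multi-start Nelder-Mead on
logistic-transformed (box-bounded) parameters: 14 uniform seeded starts
within the plausible ranges by default, each with simplex-restart
rounds. Two initialization details matter because the clipped sampled
likelihood is *exactly flat* far from the informative region (every
predicted probability saturates and is clipped): a seeded Latin
hypercube probe of the parameter box contributes its best point as an
extra start, and a data-driven "moment" start is added, built from a
probit fit of the condition's choice curve (giving the noise scale and
the decision-cut location, attributed to whichever compensation
parameter the variant frees) and the observed high-confidence rate
(placing `k_confidence`). Parameter ranges follow the standard protocol:
`log sigma` in [log 0.001, log 0.15], `mu_likelihood` in [-3, 6.5],
`k_confidence` in [0.5, 0.99999], `k_choice` in [-5, 5] (the printed
"plausible" [-10, 10] exceeds its own hard bounds; the hard bounds are
used), prior in [0.4, 0.6] (the printed plausible range is inconsistent
with a probability near 0.5; starts are drawn in [0.4001, 0.5999]).

**Model comparison** (`compare_models()`) sums per-participant AIC/BIC
differences against a reference variant and attaches percentile CIs from
resampling participants with replacement (default 1e6 resamples). A
caveat discovered with the full model family: when data are generated
exactly by the `mu_likelihood` observer in a regime where `d(x)` is
close to linear over the stimulus range (small `sigma_encoding` relative
to the category width), the `k_choice_confidence` variant is a
near-reparameterization of the generating model - a shift of `d` is then
almost exactly a shift of `x` - and the two are separated by only
hundredths of a log-likelihood unit per hundred trials. Real data, which
neither variant generates exactly, do not sit on this knife edge. The
decisive and robust contrast is insight versus pure late compensation
(`k_choice`), which differs by tens of AIC units per simulated observer.

# Drift-diffusion module

`simulate_ddm()` is an Euler-Maruyama simulation of a unit-noise Wiener
process with symmetric bounds at +-`bound`, start `z * bound`, drift
`drift_gain * (s + drift_bias)` (the drift-rate bias as an additive
fraction of the gain; the original implementation's exact coupling is
not printed, so this choice is isolated in one internal function), and
nondecision time added to the first-passage time. Decision times beyond
3 s are censored, matching the trimming rule applied before fitting.

`ddm_likelihood()` offers two routes that the tests hold to agreement:
numeric Fokker-Planck propagation (Crank-Nicolson on the printed grid,
`dnu = 0.01`, `dt = 0.0005`, with second-order one-sided flux estimates
at the absorbing bounds; probability conservation is verified to 1e-3)
and the exact constant-drift first-passage series (small/large-time
forms selected per trial for a 1e-10 truncation bound). Fitting
(`fit_ddm()`) uses the series route inside an in-package differential
evolution optimizer (no DE package is available to the package's
dependencies) within the standard ranges: gain [0, 20], bound [1, 3],
nondecision time [0, 2], biases [-1, 1]. Densities are floored at 1e-10
so response times faster than the nondecision time never produce
`-Inf` (robust likelihood). `conditional_response_function()` bins
trials into 5 RT quantiles per condition; starting-point biases decay
across quantiles while drift-rate biases persist.

# Pupillometry module

Preprocessing follows the standard pipeline with all constants exposed
in `preprocess_config()`: artifact segments where the absolute dilation
speed (forward differences, pooled across trials) exceeds
`median + 16 * MAD`, merged when closer than 20 ms and replaced by a
linear bridge between 20 ms context means; a zero-phase order-2
Butterworth band-pass (0.01-10 Hz) applied as a high-pass then a
low-pass step per trial; baseline subtraction of the last 400 ms of
fixation; division by the participant's maximum across conditions
(taken after filtering, following the order of the processing
description). Decision-locked windows default to 2000-2500 ms
post-stimulus and 500-1000 ms post-response; the moving-window analysis
uses 200 ms windows stepped by 20 ms, fitting in each window the ranked
mixed-effects specification (fixed effects: intercept, ranked
predictor, condition dummies with No-Adapt-See reference; random
intercepts and slopes for all of these per participant; maximum
likelihood so information criteria are comparable across fixed-effect
sets). Significance flags use the normal approximation at p < 0.01;
singular windows are flagged, never silently simplified.

# The synthetic-data generator

`ground_truth_observer()` + `simulate_trials()` generate complete
synthetic experiments from a known observer, so every downstream stage
has a parameter-recovery surface. Defaults define the emulated study
conditions and are fixed once:

* `mu_adapt = -0.1` task units: an encoding offset producing an
  Adapt-See PSE of about -0.1, the magnitude regime of the empirical
  psychometric shifts (the true value in task units is not printed, so
  this is a one-time choice, not calibrated to data).
* `sigma_encoding = 0.05`: consistent with the steep empirical
  psychometric curves (inverse slopes of a few hundredths).
* `sigma_A = 0` by default (the delta-function regime the fitted models
  assume); a positive value reproduces the full-model robustness
  analysis.
* `k_confidence = 0.7`: a mid-range confidence criterion giving mixed
  high/low confidence reports.
* Response policies: *naive* (no compensation), *insightful*
  (`mu_likelihood` equal to the true offset in Adapt-Believe), and
  *late-compensation* (`k_choice` set to the decision-variable value
  that nulls the choice bias, leaving confidence uncorrected).

Response times are not given a generative model by the source analyses,
which only use the monotone uncertainty-RT relation; the generator's
default is `rt = (t0 + beta * softplus(center - |d|)) * lognormal
noise`, monotone decreasing in `|d|`, with a DDM mode for cross-module
coherence. Pupil traces are likewise generated from an invented but
structurally faithful model: baseline plus a gamma-shaped dilation
kernel peaking about 1 s after stimulus onset whose amplitude is
`gain * plogis(-|d|)`, plus white noise. Passing tests therefore show
that the analysis stages recover what these generators encode - encoding
offsets, policy signatures, uncertainty coupling - not that real pupil
or RT data follow these exact functional forms; real data add
luminance responses, blinks, autocorrelated noise and individual
differences that the generator deliberately omits.

The entropy-minimizing staircase (`adaptive_staircase_next()`)
maintains a posterior over (mu, sigma, lambda) on the standard grids
(51 linear points -0.5..0.5; 25 log points 0.001..0.5; 25 linear points
0..0.3) and proposes the candidate stimulus minimizing expected
posterior entropy, averaged over the two responses weighted by their
predictive probabilities; ties resolve to the first candidate.

# Statistics

`wilcoxon_signed_rank()` implements the normal-approximation z (zeros
discarded, mid-ranks with tie-corrected variance) because the base
implementation does not expose z; an exact-enumeration oracle backs it
in the tests. Effect sizes are `r = z / sqrt(2N)` and, for paired t
statistics, `d = t / sqrt(N)` - the latter is not printed as a formula
but reproduces every printed (t, d) pair to three decimals. BCa
intervals delegate to the `boot` package (alpha = 0.05, 1e5 resamples
by default) with a percentile fallback for degenerate bootstrap
distributions; median CIs use 5000 percentile resamples. The ANOVA
effect size is classic `eta^2 = SS_effect / SS_total` as printed.

# Problem sizes, tolerances and determinism

Everything is seed-deterministic: one master seed per run, with named
substreams per stage (and per stimulus value for likelihood draws), so
stages can be re-run independently and byte-identical outputs are
reproducible (`run_pipeline()` writes the resolved configuration and
stamps outputs with its hash). Validation experiments use the study's
own scales - 121 trials/condition for recovery, 22 simulated observers
for cohort comparison, 300 trials/condition for diffusion fits, 1e5
trials for conditional-response-function signatures - with optimizer
budgets (starts, generations, probe sizes) chosen per experiment and
reported alongside. Simulation-based checks assert statistical
properties with explicit bands: recovery medians against stated
tolerances, type-I rates against exact binomial bounds for their
nominal level, and coverage within binomial error of 95%.

# Known limitations

* The sampled likelihood is a step function of the parameters; the
  multi-start protocol with probe and moment initialization is robust in
  the tested regimes but, like any derivative-free method on a
  plateau-ridden surface, cannot certify global optimality.
* The `k_choice_confidence` near-degeneracy described above limits what
  cohort model comparison can claim on exactly-generated data in
  near-linear regimes.
* The pupil and RT generators are structural stand-ins; analyses of
  real recordings should revisit the preprocessing constants (sampling
  rate, windows) through `preprocess_config()`.
* Staircase-generated (non-uniform) stimulus sets violate the observer
  model's uniform-stimulus assumption; `fit_bayes_model()` warns but
  does not refuse.
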