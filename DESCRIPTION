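Package: insightobs
Title: Bayesian Observer Modelling of Perceptual Insight
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for quantifying perceptual insight: the incorporation of
    knowledge about an internal encoding distortion (such as a motion
    after-effect) into perceptual inference. Provides a synthetic-experiment
    generator with a known ground-truth Bayesian observer, grid-search
    maximum-likelihood psychometric curve fitting with a shared lapse rate,
    a family of Bayesian choice-plus-confidence observer models fitted by
    multi-start sampling-based maximum likelihood and compared by AIC/BIC
    with participant-level bootstrap, drift-diffusion model variants with
    starting-point and drift-rate biases (Fokker-Planck and exact
    first-passage likelihoods, conditional response functions), pupillometry
    preprocessing (artifact removal, zero-phase Butterworth filtering,
    baseline normalization) with moving-window mixed-effects uncertainty
    regressions, and the nonparametric statistics used throughout
    (signed-rank effect sizes, BCa and percentile bootstrap intervals,
    ranked generalized linear mixed-effects models).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    signal,
    lme4,
    boot,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
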