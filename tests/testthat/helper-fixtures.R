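# Shared fixtures: small synthetic experiments built in code.

make_table <- function(n = 24, policy = "insightful", seed = 1,
                       conditions = main_conditions(), ...) {
  obs <- ground_truth_observer(policy, ...)
  stimuli <- simulate_stimuli(n, seed = seed, conditions = conditions)
  simulate_trials(obs, stimuli, seed = seed)
}

tiny_df <- function(n = 6) {
  data.frame(
    participant_id = "p1",
    condition = rep(main_conditions(), length.out = n),
    s = seq(-0.25, 0.25, length.out = n),
    choice = rep(c(-1, 1), length.out = n),
    confidence = rep(c(0, 1), length.out = n),
    rt = seq(0.4, 1.2, length.out = n)
  )
}

# Probit GLM estimate of the point of subjective equality, used as a
# quick model-free choice-curve bias estimate in property tests.
pse_probit <- function(table, condition) {
  sub <- table[table$condition == condition, ]
  fit <- suppressWarnings(
    stats::glm(I(choice == 1) ~ s, family = stats::binomial("probit"), data = sub))
  unname(-stats::coef(fit)[1] / stats::coef(fit)[2])
}
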