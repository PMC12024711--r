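# shared fixture builders; everything is generated in code at test time

as_rewards <- function(m) {
  colnames(m) <- TREATMENTS
  structure(m, class = c("reward_matrix", "matrix"))
}

# cohort with treatment assigned independently of covariates
independent_cohort <- function(n, probs = c(0.5, 0.3, 0.2), seed = 1) {
  set.seed(seed)
  data.frame(
    x1 = rnorm(n), x2 = rnorm(n),
    treatment = factor(sample(TREATMENTS, n, replace = TRUE, prob = probs),
                       levels = TREATMENTS),
    death = rbinom(n, 1, 0.2)
  )
}

# spec with flat 10% mortality under OBS everywhere and a single-leaf
# planted policy; useful for constant-risk checks
flat_risk_spec <- function(n = 100, seed = 1) {
  synthetic_spec(
    n_patients = n,
    propensity = list(AE = c("(Intercept)" = 0),
                      SPLENECTOMY = c("(Intercept)" = 0)),
    outcome_base = c("(Intercept)" = stats::qlogis(0.1)),
    planted_policy = policy_tree(traumapolicy:::tree_leaf("OBS")),
    leaf_offsets = matrix(c(0, 0.5, 1), 1,
                          dimnames = list(NULL, TREATMENTS)),
    seed = seed
  )
}

# oracle reward matrix (true risks) from a synthetic cohort
oracle_rewards <- function(cohort) {
  as_rewards(cbind(cohort$p_obs, cohort$p_ae, cohort$p_splen))
}

oracle_nuisances <- function(cohort, clip = c(0.01, 0.99)) {
  manual_nuisances(
    mu = cbind(cohort$p_obs, cohort$p_ae, cohort$p_splen),
    e = cbind(cohort$e_obs, cohort$e_ae, cohort$e_splen),
    clip_bounds = clip
  )
}
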