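---
title: "Doubly robust policy trees for blunt splenic trauma: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Doubly robust policy trees for blunt splenic trauma: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traumapolicy)
```

## The problem

Blunt splenic trauma admits three managements: observation, splenic
angioembolization (AE) and splenectomy. Which one minimizes in-hospital
mortality depends on the patient — injury grade, hemodynamic status (shock
index, the heart rate divided by the systolic blood pressure), early
transfusion need, comorbidity. Registry data record only the outcome of the
treatment each patient actually received, under strongly confounded
assignment: sicker patients are operated on, so splenectomy's raw mortality
(about 20%) says little about what splenectomy *causes*.

`traumapolicy` implements the two-stage prescriptive approach for this
problem:

1. **Counterfactual (reward) estimation.** For every patient and every arm
   $t$, an augmented inverse-propensity-weighted (AIPW) mortality score
   $$\Gamma_i(t) = \hat\mu_t(x_i) +
     \frac{\mathbf 1\{T_i = t\}\,(Y_i - \hat\mu_t(x_i))}{\hat e_t(x_i)},$$
   built from a per-arm outcome model $\hat\mu_t$ and a three-class
   propensity model $\hat e_t$, both cross-fitted so no patient is scored
   by a model that saw them. The score is doubly robust: its mean is
   consistent for the counterfactual mortality if *either* nuisance model
   is correct.
2. **Interpretable policy learning.** An axis-aligned binary tree whose
   leaves prescribe one arm, fit to minimize
   $\frac1n\sum_i \Gamma_i(\pi(x_i)) + \mathrm{cp}\cdot(\text{splits})$
   subject to a minimum leaf size and a maximum depth. Branch semantics are
   fixed: a patient goes left when the split feature is strictly below the
   threshold, right at or above it.

The full protocol (`run_pipeline()`): stratify at admission SBP 70 mmHg,
split each stratum 50/50 into training and testing halves stratified
jointly on treatment and outcome, estimate nuisances independently within
each half, tune the tree's depth and complexity penalty by grid search, and
report the held-out doubly-robust mortality under the learned policy next
to the observed mortality of the same rows.

## The synthetic cohort generator

Real trauma-registry extracts are access-restricted, so validation rests on
a generator (`default_preset()`, `generate_cohort()`) that emulates a
registry-like cohort and — crucially — knows the right answer:

* **Covariates.** Vitals and demographics are truncated normals/lognormals
  placed at registry-like medians and IQRs (age median 38, SBP median 124
  mmHg with ~2.5% below 70, heart rate median 95, GCS mostly 15, BMI median
  26.8); splenic grade is drawn so grades 4–5 cover about 25% of patients;
  comorbidity and concomitant-injury flags are Bernoulli at registry-like
  marginals. Joint dependence beyond a heart-rate/SBP coupling (shock) and
  the clinical drivers below is deliberately not modeled.
* **Confounded assignment.** A softmax propensity model loading on splenic
  grade, shock index, early pRBC transfusion and intubation produces a mix
  near 84% observation / 3% AE / 13% splenectomy. Because the same
  variables drive mortality, naive comparisons are visibly biased (raw
  splenectomy mortality ~21% against ~6% under observation), which is what
  the doubly-robust machinery must undo.
* **Planted optimal policy.** Per-arm mortality risks share one covariate
  logit; each arm adds an offset that depends only on the leaf of a planted
  depth-2 tree (shock index at 1.5, grade at 4, early pRBC), with the
  planted arm's offset strictly smallest. The argmin of the true risks
  therefore *equals* the planted prescription everywhere by construction,
  and oracle risk/propensity columns ride along in the generated table for
  tests. Offsets (0.75–1.5 logits between best and worst arm in the stable
  region, 0.6–1.4 in shocked regions) were chosen once as clinically
  plausible effect sizes: modest differences for stable low-grade patients
  (where management is genuinely debated) and large penalties for
  under-treating hemorrhagic shock.
* One integer seed drives every draw; identical (spec, seed) reproduce the
  table bit for bit.

What passing tests on this generator do **not** show: robustness to
unmeasured confounding, informative missingness, center-level clustering,
or covariate distributions unlike the planted ones. The generator exists to
verify the estimator and optimizer, not to claim external validity.

## Numerical and design choices

**Arm order and ties.** Everything uses the fixed order OBS, AE,
SPLENECTOMY; when two arms tie inside a leaf the less invasive one wins.
Rewards are mortality scores and are always minimized.

**Tree search.** The optimizer is a local search: a greedy grow pass that
enumerates *every* axis-aligned boundary (thresholds at midpoints of
adjacent observed values) at each node, exact bottom-up pruning under the
complexity penalty, then coordinate-descent refinement that can collapse
any internal node or replace a small, shallow subtree by its exactly
enumerated optimum. The penalized objective never increases across accepted
moves. Randomized restarts (feature subsampling in the grow pass) guard
against local optima; `exhaustive_policy_tree()` provides the exact optimum
at depth ≤ 2 on small inputs and the test suite requires the local search
to attain it in at least 95% of seeded replicates. Against that reference
the local search matched 20/20 replicates at n = 400.

**Honest tuning.** Depth (3–8) and cp (0, 1e-4, 1e-3, 1e-2) are chosen on
an internal validation split of the training half whose rewards are built
from nuisances fit *only* on that split. This matters: when training and
validation rewards share one set of nuisance fits, their errors are
correlated and the grid search reliably selects deep trees that chase those
shared errors (we observed selected trees with *negative* training
objectives — impossible for a true mortality rate). With honest validation
the selected trees are shallow and stable.

**Weight truncation.** `fit_nuisances()` clips propensities into
[0.01, 0.99] by default (inverse weights at most 100). The pipeline default
is deliberately tighter, [0.10, 0.90]: with an arm received by ~3% of
patients, a handful of surviving AE patients otherwise carry reward entries
of magnitude ~1/ê, and a split search that examines every (feature,
threshold) pair will find and isolate them. Truncation at 10 trades a
small, known attenuation bias for the variance reduction that makes tree
learning stable; on the default preset it moves planted-policy agreement
from roughly 50% (untruncated) to above 90%. Both bounds are configuration
fields, not constants.

**Nuisance models.** The default family mirrors the protocol's random
forests (ranger probability forests, 300 trees, minimum node sizes 25 for
outcome and 50 for propensity models — large nodes keep the predicted
probabilities calibrated for the rare AE arm). A logistic family (per-arm
`glm`, multinomial logit) is provided for fast, well-specified tests.
Cross-fitting uses 5 folds stratified on (treatment, outcome); 3% of 5,000
rows still leaves ≥ 2 rows per arm per fold, and arms sparser than
2 × k_folds rows are rejected with an explicit error.

**Splits and strata.** The 50/50 train/test split is stratified jointly on
(treatment, death) with largest-remainder allocation, so both halves carry
every arm and both outcomes whenever counts permit; singleton cells go to
training with a warning. A stratum smaller than max(4 × min_leaf, 80) rows
is skipped with a warning rather than fit badly — the SBP < 70 stratum of a
small cohort triggers this.

**Missing values.** The generator can optionally blank SBP (the one
variable with documented gaps in registry descriptives). Training imputes
column medians for the split search only; at prescription time a missing
value follows the majority training branch recorded at each node. Leaf
report cells for arms no patient received are `NA`, never 0.

**Quartiles.** All medians/IQRs use linear interpolation (R type-7
quantiles), stated here because published tables rarely name their
convention; printed medians are not treated as exactly reproducible.

## Problem sizes used in validation

The test suite and acceptance script run the generator at n = 20,000 for
estimator consistency and end-to-end recovery (10,000 per half), n = 12,000
across 20 seeds for the direction-of-effect check, and n = 400 across 20
replicates for the exhaustive-oracle comparison. Sizes were chosen for
power: at n = 12,000 the held-out policy-value standard error (~0.4
percentage points) is several times smaller than the mortality reduction
being detected, so the direction of the effect is stable across seeds;
smaller cohorts leave the comparison underpowered rather than wrong.

## Known limitations

* Rewards outside [0, 1] are legitimate AIPW outputs and are not clamped;
  single-patient reward entries are not interpretable as probabilities.
* The tree optimizer is a heuristic beyond depth 2; optimality is verified
  only against the exhaustive oracle at small depth.
* The generator's treatment-effect heterogeneity is exactly tree-structured;
  real heterogeneity is not, and a depth-limited tree can only approximate
  it.
* Confidence intervals for policy values are naive (mean ± se of selected
  rewards); no bootstrap is performed by default.
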