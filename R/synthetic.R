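#' Synthetic trauma-cohort generator
#'
#' Simulates registry-like cohorts of adult blunt splenic trauma patients:
#' admission vitals, splenic injury grade, early transfusion, comorbidity and
#' concomitant-injury flags; a covariate-dependent three-arm treatment
#' assignment (observation / angioembolization / splenectomy) through a
#' softmax propensity model; and Bernoulli in-hospital mortality whose
#' per-arm risks are constructed so that the risk-minimizing treatment is a
#' known, planted, depth-2 policy tree. Oracle risk and propensity columns
#' are stored alongside the data, giving every downstream stage (reward
#' estimation, tree learning, policy evaluation) a cheap ground truth.
#'
#' @name synthetic-cohort
NULL

#' Create a synthetic cohort specification
#'
#' Rarely called directly; [default_preset()] returns the documented default.
#' Linear predictors are named coefficient vectors over cohort columns plus
#' an `"(Intercept)"` entry; the mortality logit for arm t is
#' `base + offset[leaf(x), t]` where `leaf(x)` is the planted tree's leaf and
#' each leaf's prescribed arm has the strictly smallest offset, so
#' `argmin_t p_t(x)` equals the planted prescription everywhere by
#' construction.
#'
#' @param n_patients default cohort size.
#' @param propensity named list with elements `AE` and `SPLENECTOMY`, each a
#'   named coefficient vector on the multinomial-logit scale relative to the
#'   OBS baseline.
#' @param outcome_base named coefficient vector for the shared mortality
#'   logit.
#' @param planted_policy `policy_tree` giving the optimal arm per region.
#' @param leaf_offsets matrix (one row per planted-tree leaf, in preorder
#'   leaf order; columns OBS/AE/SPLENECTOMY) of per-arm logit offsets.
#' @param sbp_missing_rate optional fraction of sbp values set missing
#'   (default 0; complete data).
#' @param seed integer seed governing all randomness for this spec.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_patients, propensity, outcome_base,
                           planted_policy, leaf_offsets,
                           sbp_missing_rate = 0, seed = 1L) {
  stopifnot(n_patients >= 0, inherits(planted_policy, "policy_tree"),
            is.matrix(leaf_offsets),
            identical(colnames(leaf_offsets), TREATMENTS),
            sbp_missing_rate >= 0, sbp_missing_rate < 1)
  leaves <- tree_leaves(planted_policy)
  if (nrow(leaf_offsets) != nrow(leaves)) {
    stopf("leaf_offsets must have one row per planted-policy leaf")
  }
  # planted arm must carry the strictly smallest offset in its leaf
  for (k in seq_len(nrow(leaves))) {
    off <- leaf_offsets[k, ]
    if (TREATMENTS[which.min(off)] != leaves$arm[k] ||
        sum(off == min(off)) != 1L) {
      stopf("leaf %d: planted arm %s is not the unique offset minimizer",
            k, leaves$arm[k])
    }
  }
  structure(
    list(n_patients = as.integer(n_patients), propensity = propensity,
         outcome_base = outcome_base, planted_policy = planted_policy,
         leaf_offsets = leaf_offsets,
         sbp_missing_rate = sbp_missing_rate, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# evaluate a named linear predictor on cohort columns
linpred <- function(coefs, data) {
  lp <- rep(unname(coefs["(Intercept)"] %||% 0), nrow(data))
  if (is.na(lp[1L])) lp <- rep(0, nrow(data))
  for (nm in setdiff(names(coefs), "(Intercept)")) {
    if (!nm %in% names(data)) {
      stopf("linear predictor references unknown covariate '%s'", nm)
    }
    lp <- lp + coefs[[nm]] * data[[nm]]
  }
  lp
}

#' True assignment propensities under a spec
#'
#' Softmax over the three arm linear predictors (OBS is the baseline with
#' predictor 0). Rows sum to 1 and lie strictly inside (0, 1).
#'
#' @param spec `synthetic_spec`.
#' @param data cohort rows with the covariates the spec references.
#' @return n x 3 matrix, columns `TREATMENTS`.
#' @export
true_propensities <- function(spec, data) {
  eta <- cbind(OBS = rep(0, nrow(data)),
               AE = linpred(spec$propensity$AE, data),
               SPLENECTOMY = linpred(spec$propensity$SPLENECTOMY, data))
  m <- exp(eta - apply(eta, 1L, max))
  m / rowSums(m)
}

#' True per-arm mortality risks under a spec
#'
#' @inheritParams true_propensities
#' @return n x 3 matrix of mortality probabilities, columns `TREATMENTS`.
#' @export
true_risks <- function(spec, data) {
  base <- linpred(spec$outcome_base, data)
  r <- route_rows(spec$planted_policy, data)
  all_leaf_ids <- tree_leaves(spec$planted_policy)$leaf_id
  leaf_row <- match(r, all_leaf_ids)      # row index into leaf_offsets
  p <- matrix(NA_real_, nrow(data), 3L, dimnames = list(NULL, TREATMENTS))
  for (j in 1:3) p[, j] <- stats::plogis(base + spec$leaf_offsets[leaf_row, j])
  p
}

draw_covariates <- function(spec, n) {
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  z_sbp <- stats::rnorm(n)
  sbp <- clamp(124 + 27 * z_sbp, 40, 220)
  hr <- clamp(95 - 9 * z_sbp + 21 * stats::rnorm(n), 30, 200)
  age <- clamp(exp(stats::rnorm(n, log(38), 0.55)), 18, 89)
  female <- stats::rbinom(n, 1, 0.336)
  rr <- clamp(19 + 4.5 * stats::rnorm(n), 8, 50)
  gcs_levels <- c(15, 14, 13, 12, 10, 8, 6, 3)
  gcs_probs <- c(0.66, 0.09, 0.05, 0.04, 0.04, 0.04, 0.04, 0.04)
  gcs <- sample(gcs_levels, n, replace = TRUE, prob = gcs_probs)
  bmi <- clamp(exp(stats::rnorm(n, log(26.8), 0.218)), 14, 60)
  spleen_grade <- sample(1:5, n, replace = TRUE,
                         prob = c(0.32, 0.222, 0.206, 0.174, 0.078))
  shock_index <- hr / sbp
  intubated <- stats::rbinom(n, 1, stats::plogis(
    -3.15 + 0.28 * (15 - gcs) + 0.02 * (124 - sbp)))
  prbc_1h <- stats::rbinom(n, 1, stats::plogis(
    -2.34 + 1.9 * (shock_index - 0.85) + 0.33 * (spleen_grade - 3)))
  wholeblood_1h <- stats::rbinom(n, 1, stats::plogis(
    -5.1 + 1.2 * (shock_index - 0.85) + 0.2 * (spleen_grade - 3)))
  df <- data.frame(
    age = age, female = female, sbp = sbp, hr = hr, rr = rr, gcs = gcs,
    bmi = bmi, intubated = intubated, spleen_grade = spleen_grade,
    shock_index = shock_index, prbc_1h = prbc_1h,
    wholeblood_1h = wholeblood_1h,
    hypertension = stats::rbinom(n, 1, 0.192),
    diabetes = stats::rbinom(n, 1, 0.084),
    smoker = stats::rbinom(n, 1, 0.255),
    chf = stats::rbinom(n, 1, 0.016),
    copd = stats::rbinom(n, 1, 0.041),
    cirrhosis = stats::rbinom(n, 1, 0.015),
    bleeding_disorder = stats::rbinom(n, 1, 0.016),
    liver_injury = stats::rbinom(n, 1, 0.217),
    kidney_injury = stats::rbinom(n, 1, 0.140),
    tbi = stats::rbinom(n, 1, 0.201),
    pelvic_fracture = stats::rbinom(n, 1, 0.074),
    spine_injury = stats::rbinom(n, 1, 0.069)
  )
  df
}

#' Generate a synthetic cohort
#'
#' Draws covariates, assigns a treatment from the spec's softmax
#' propensities, draws in-hospital death from the assigned arm's true risk,
#' and stores the oracle risk (`p_obs`, `p_ae`, `p_splen`) and propensity
#' (`e_obs`, `e_ae`, `e_splen`) columns. Identical (spec, seed, n) give a
#' bit-identical table.
#'
#' @param spec `synthetic_spec`.
#' @param n number of patients (default `spec$n_patients`).
#' @param seed RNG seed (default `spec$seed`).
#' @return a validated cohort data.frame.
#' @export
generate_cohort <- function(spec, n = spec$n_patients, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"), n >= 0)
  if (n == 0) {
    df <- draw_covariates(spec, 0)
    df$treatment <- factor(character(0), levels = TREATMENTS)
    df$death <- integer(0)
    for (nm in c(ORACLE_RISK_COLS, ORACLE_PROP_COLS)) df[[nm]] <- numeric(0)
    return(df)
  }
  set.seed(seed)
  df <- draw_covariates(spec, n)
  e <- true_propensities(spec, df)
  u <- stats::runif(n)
  t_idx <- 1L + (u >= e[, 1L]) + (u >= e[, 1L] + e[, 2L])
  p <- true_risks(spec, df)
  death <- stats::rbinom(n, 1, p[cbind(seq_len(n), t_idx)])
  df$treatment <- factor(TREATMENTS[t_idx], levels = TREATMENTS)
  df$death <- death
  df$p_obs <- p[, "OBS"]; df$p_ae <- p[, "AE"]; df$p_splen <- p[, "SPLENECTOMY"]
  df$e_obs <- e[, "OBS"]; df$e_ae <- e[, "AE"]; df$e_splen <- e[, "SPLENECTOMY"]
  if (spec$sbp_missing_rate > 0) {
    drop <- stats::runif(n) < spec$sbp_missing_rate
    df$sbp[drop] <- NA_real_
  }
  validate_cohort(df)
  df
}

#' Default synthetic preset
#'
#' A documented stand-in for a national blunt-splenic-trauma registry
#' extract. Marginals are parameterized to sit near published registry
#' descriptives: median age 38 (IQR about 26-56), median SBP 124 (IQR about
#' 107-141) with roughly 2.5% presenting below 70 mmHg, median heart rate
#' 95, 33.6% female, about 10% intubated, splenic grade 4-5 in about 25% of
#' patients, early pRBC transfusion near 10%, and a treatment mix near 84%
#' observation / 3% angioembolization / 13% splenectomy with overall
#' in-hospital mortality near 8%. Treatment assignment is confounded: the
#' propensity model loads on splenic grade, shock index and early
#' transfusion, the same variables that drive mortality, so naive
#' (unadjusted) policy evaluation is visibly biased.
#'
#' The planted optimal policy is the depth-2 tree: shock index < 1.5 and
#' grade <= 3 -> observation; shock index < 1.5 and grade >= 4 ->
#' angioembolization; shock index >= 1.5 without early pRBC ->
#' angioembolization; shock index >= 1.5 with early pRBC -> splenectomy.
#'
#' @param n_patients cohort size (default 20000).
#' @param seed spec seed (default 1).
#' @return a `synthetic_spec`.
#' @export
default_preset <- function(n_patients = 20000, seed = 1L) {
  planted <- policy_tree(
    tree_split("shock_index", 1.5,
               tree_split("spleen_grade", 4,
                          tree_leaf("OBS"), tree_leaf("AE")),
               tree_split("prbc_1h", 0.5,
                          tree_leaf("AE"), tree_leaf("SPLENECTOMY"))))
  leaf_offsets <- rbind(
    c(0.0, 0.75, 1.50),   # SI < 1.5, grade <= 3: OBS optimal
    c(1.0, 0.00, 0.60),   # SI < 1.5, grade >= 4: AE optimal
    c(0.8, 0.00, 0.70),   # SI >= 1.5, no early pRBC: AE optimal
    c(1.4, 0.70, 0.00))   # SI >= 1.5, early pRBC: SPLENECTOMY optimal
  colnames(leaf_offsets) <- TREATMENTS
  propensity <- list(
    AE = c("(Intercept)" = -5.65, shock_index = 0.9, spleen_grade = 0.55,
           prbc_1h = 0.8),
    SPLENECTOMY = c("(Intercept)" = -5.94, shock_index = 1.5,
                    spleen_grade = 0.85, prbc_1h = 1.4, intubated = 0.5)
  )
  outcome_base <- c("(Intercept)" = -5.46, shock_index = 2.0,
                    spleen_grade = 0.30, prbc_1h = 0.6, intubated = 0.7,
                    age = 0.022, gcs = -0.12, tbi = 0.8)
  synthetic_spec(n_patients = n_patients, propensity = propensity,
                 outcome_base = outcome_base, planted_policy = planted,
                 leaf_offsets = leaf_offsets, seed = seed)
}

#' Monte-Carlo true value of a policy
#'
#' Expected in-hospital mortality if the whole population described by the
#' spec were treated according to `policy`: draws `n_mc` covariate vectors,
#' routes them through the policy, and averages the oracle risk of the
#' prescribed arm. The Monte-Carlo standard error is attached as attribute
#' `"se"`.
#'
#' @param spec `synthetic_spec`.
#' @param policy `policy_tree`, or a single arm name for a constant policy.
#' @param n_mc Monte-Carlo sample size.
#' @param seed RNG seed.
#' @return scalar mortality probability with attributes `se` and `n_mc`.
#' @export
true_policy_value <- function(spec, policy, n_mc = 20000, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"), n_mc >= 1)
  if (is.character(policy)) policy <- hand_tree(policy)
  set.seed(seed)
  df <- draw_covariates(spec, n_mc)
  p <- true_risks(spec, df)
  arm <- as.integer(prescribe(policy, df))
  v <- p[cbind(seq_len(n_mc), arm)]
  structure(mean(v), se = stats::sd(v) / sqrt(n_mc), n_mc = n_mc)
}
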