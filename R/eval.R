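#' Policy-value evaluation and reports
#'
#' Held-out evaluation mirrors the study protocol: nuisances and rewards are
#' fit on the held-out half only, and the "predicted mortality under the
#' policy" is the mean doubly-robust reward of the prescribed arms on those
#' rows. Reports place that figure next to the observed mortality of the
#' same rows and break the cohort down by terminal leaf, tabulating for each
#' leaf how many patients actually received each arm and their raw observed
#' death rates (plain ratios, no modeling).
#'
#' @name policy-evaluation
NULL

#' Doubly-robust value of a policy
#'
#' Mean over rows of the reward column selected by the policy's
#' prescription. Lower is better (mortality score).
#'
#' @param policy `policy_tree`, a single arm name (constant policy), or a
#'   precomputed prescription factor/character vector.
#' @param rewards `reward_matrix` for the evaluation rows.
#' @param data covariate data.frame aligned with `rewards` (not needed when
#'   `policy` is already a prescription vector or constant arm).
#' @return scalar estimated mortality with attribute `se` (naive standard
#'   error of the mean selected reward).
#' @export
policy_value_dr <- function(policy, rewards, data = NULL) {
  G <- unclass_rewards(rewards)
  n <- nrow(G)
  if (inherits(policy, "policy_tree")) {
    if (is.null(data)) stopf("data is required to route a policy_tree")
    if (nrow(data) != n) {
      stopf("rewards (%d rows) do not align with data (%d rows)", n, nrow(data))
    }
    arm <- as.integer(prescribe(policy, data))
  } else if (is.character(policy) && length(policy) == 1L) {
    arm <- rep.int(match(match.arg(policy, TREATMENTS), TREATMENTS), n)
  } else {
    arm <- as.integer(as_arm_factor(policy))
    if (length(arm) != n) {
      stopf("prescription vector (%d) does not align with rewards (%d rows)",
            length(arm), n)
    }
  }
  v <- G[cbind(seq_len(n), arm)]
  structure(mean(v), se = stats::sd(v) / sqrt(n))
}

#' Pointwise-argmin prescription
#'
#' The unconstrained row-wise best arm; its value lower-bounds every tree
#' policy's value on the same rewards.
#'
#' @param rewards `reward_matrix`.
#' @return factor of arms, levels `TREATMENTS`.
#' @export
argmin_prescription <- function(rewards) {
  G <- unclass_rewards(rewards)
  factor(TREATMENTS[row_which_min(G)], levels = TREATMENTS)
}

#' Observed in-hospital mortality
#'
#' Plain deaths / rows ratio.
#'
#' @param cohort validated cohort with a complete `death` column.
#' @return proportion in [0, 1].
#' @export
observed_mortality <- function(cohort) {
  validate_cohort(cohort)
  if (nrow(cohort) == 0) stopf("observed mortality is undefined for an empty cohort")
  mean(cohort$death)
}

#' Per-leaf observed mortality table
#'
#' Routes each patient to a terminal leaf and tabulates, per leaf and per
#' arm actually received, the patient count and the raw observed death
#' rate. Arms no patient in the leaf received are reported as `NA`, never
#' 0. The arm with the lowest observed rate in each leaf is flagged.
#'
#' @param policy `policy_tree`.
#' @param cohort validated cohort with treatment and death columns.
#' @return data.frame: `leaf_id`, `path`, `prescribed`, `n`, then per arm
#'   `n_<arm>` and `rate_<arm>`, and `lowest_observed` (arm with the lowest
#'   non-missing rate).
#' @export
leaf_report <- function(policy, cohort) {
  stopifnot(inherits(policy, "policy_tree"))
  validate_cohort(cohort)
  leaves <- tree_leaves(policy)
  r <- route_rows(policy, cohort)
  out <- leaves[c("leaf_id", "path", "arm")]
  names(out)[3L] <- "prescribed"
  out$n <- 0L
  for (arm in TREATMENTS) {
    out[[paste0("n_", arm)]] <- 0L
    out[[paste0("rate_", arm)]] <- NA_real_
  }
  out$lowest_observed <- NA_character_
  for (k in seq_len(nrow(out))) {
    in_leaf <- r == out$leaf_id[k]
    out$n[k] <- sum(in_leaf)
    rates <- rep(NA_real_, 3L)
    for (j in seq_along(TREATMENTS)) {
      sel <- in_leaf & cohort$treatment == TREATMENTS[j]
      nj <- sum(sel)
      out[[paste0("n_", TREATMENTS[j])]][k] <- nj
      if (nj > 0) {
        rates[j] <- mean(cohort$death[sel])
        out[[paste0("rate_", TREATMENTS[j])]][k] <- rates[j]
      }
    }
    if (any(!is.na(rates))) {
      out$lowest_observed[k] <- TREATMENTS[which.min(rates)]
    }
  }
  out
}

#' Policy value report
#'
#' The headline comparison for one evaluation stratum: estimated
#' mortality under the policy (held-out doubly-robust value), the naive
#' plug-in outcome-model value (diagnostic; labeled as such), the observed
#' mortality of the same rows, per-arm prescription counts, and the
#' per-leaf observed-mortality table.
#'
#' @param policy `policy_tree`.
#' @param rewards held-out `reward_matrix`.
#' @param cohort the held-out cohort rows (aligned with `rewards`).
#' @param nuisances optional `nuisance_models` for the plug-in diagnostic.
#' @param stratum optional stratum label (e.g. `"SBP < 70"`).
#' @return object of class `policy_value_report`.
#' @export
policy_report <- function(policy, rewards, cohort, nuisances = NULL,
                          stratum = NA_character_) {
  validate_cohort(cohort)
  est <- policy_value_dr(policy, rewards, cohort)
  pres <- prescribe(policy, cohort)
  plug_in <- NA_real_
  if (!is.null(nuisances)) {
    mu <- nuisances$mu
    plug_in <- mean(mu[cbind(seq_len(nrow(mu)), as.integer(pres))])
  }
  structure(
    list(stratum = stratum,
         n = nrow(cohort),
         estimated_policy_mortality = as.numeric(est),
         estimated_policy_mortality_se = attr(est, "se"),
         plug_in_policy_mortality = plug_in,
         observed_mortality = observed_mortality(cohort),
         prescription_counts = as.list(table(pres)),
         leaf_table = leaf_report(policy, cohort)),
    class = "policy_value_report"
  )
}

#' @export
print.policy_value_report <- function(x, ...) {
  lab <- if (is.na(x$stratum)) "" else sprintf(" [%s]", x$stratum)
  cat(sprintf("Policy value report%s (n = %d)\n", lab, x$n))
  cat(sprintf("  estimated mortality under policy (DR): %.2f%% (se %.2f%%)\n",
              100 * x$estimated_policy_mortality,
              100 * x$estimated_policy_mortality_se))
  if (!is.na(x$plug_in_policy_mortality)) {
    cat(sprintf("  plug-in outcome-model value (diagnostic): %.2f%%\n",
                100 * x$plug_in_policy_mortality))
  }
  cat(sprintf("  observed mortality (same rows): %.2f%%\n",
              100 * x$observed_mortality))
  counts <- unlist(x$prescription_counts)
  cat("  prescriptions:",
      paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), "\n")
  cat("  per-leaf observed mortality:\n")
  print(x$leaf_table, row.names = FALSE)
  invisible(x)
}

report_to_json <- function(report, path) {
  jsonlite::write_json(
    list(stratum = report$stratum, n = report$n,
         estimated_policy_mortality = report$estimated_policy_mortality,
         estimated_policy_mortality_se = report$estimated_policy_mortality_se,
         plug_in_policy_mortality = report$plug_in_policy_mortality,
         observed_mortality = report$observed_mortality,
         prescription_counts = report$prescription_counts,
         leaf_table = report$leaf_table),
    path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}
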