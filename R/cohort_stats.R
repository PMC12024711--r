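#' Descriptive cohort statistics
#'
#' Table-1-style summaries and the derived features/strata used throughout:
#' the shock index (heart rate over systolic blood pressure) and the
#' admission-SBP dichotomy at 70 mmHg. Quartiles use linear interpolation
#' (R's default type-7 quantiles) everywhere.
#'
#' @name cohort-statistics
NULL

#' Shock index
#'
#' Heart rate divided by systolic blood pressure; values around 1 or above
#' indicate hemodynamic compromise.
#'
#' @param hr heart rate, beats/min.
#' @param sbp systolic blood pressure, mmHg; must be positive where
#'   non-missing.
#' @return numeric vector `hr / sbp`; `NA` where either input is missing.
#' @export
shock_index <- function(hr, sbp) {
  if (any(!is.na(sbp) & sbp <= 0)) {
    stopf("shock index is undefined for sbp <= 0")
  }
  hr / sbp
}

#' Dichotomize a cohort on one variable
#'
#' Default reproduces the admission-SBP strata: below 70 mmHg versus at or
#' above 70 mmHg. Rows with a missing value are excluded from both strata.
#'
#' @param cohort cohort data.frame.
#' @param variable column to stratify on (default `"sbp"`).
#' @param threshold cut point (default 70); `< threshold` goes low,
#'   `>= threshold` goes high.
#' @return list with `low`, `high` (data.frames) and `n_dropped` (rows with
#'   missing values).
#' @export
stratify <- function(cohort, variable = "sbp", threshold = 70) {
  if (!variable %in% names(cohort)) {
    stopf("stratification variable '%s' not found", variable)
  }
  x <- cohort[[variable]]
  list(low = cohort[!is.na(x) & x < threshold, , drop = FALSE],
       high = cohort[!is.na(x) & x >= threshold, , drop = FALSE],
       n_dropped = sum(is.na(x)))
}

#' Treatment mix
#'
#' Per-arm counts and percentages (one decimal place), in the canonical arm
#' order.
#'
#' @param cohort validated cohort.
#' @return data.frame with `treatment`, `n`, `pct`.
#' @export
treatment_distribution <- function(cohort) {
  cohort <- validate_cohort(cohort, require_outcome = FALSE)
  if (nrow(cohort) == 0) stopf("treatment distribution is undefined for an empty cohort")
  counts <- table(cohort$treatment)
  data.frame(treatment = TREATMENTS,
             n = as.integer(counts[TREATMENTS]),
             pct = round(100 * as.numeric(counts[TREATMENTS]) / nrow(cohort), 1))
}

summarize_one <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return("-")
  if (all(x %in% c(0, 1))) {
    sprintf("%d (%.1f%%)", sum(x), 100 * mean(x))
  } else {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    sprintf("%g (%g-%g)", signif(q[2], 4), signif(q[1], 4), signif(q[3], 4))
  }
}

#' Table-1-style descriptive summary
#'
#' For each requested variable: count (percentage) for binary columns,
#' median (IQR, linear-interpolation quartiles) for continuous columns —
#' overall and within each treatment arm. Percentages use the group's
#' non-missing denominator for that variable.
#'
#' @param cohort validated cohort.
#' @param variables column names to summarize (default: all modeling
#'   features).
#' @return data.frame with one row per variable and columns `variable`,
#'   `overall`, and one column per arm.
#' @export
describe <- function(cohort, variables = modeling_features(cohort)) {
  cohort <- validate_cohort(cohort, require_outcome = FALSE)
  miss <- setdiff(variables, names(cohort))
  if (length(miss)) {
    stopf("unknown variable(s): %s", paste(miss, collapse = ", "))
  }
  out <- data.frame(variable = variables, stringsAsFactors = FALSE)
  out$overall <- vapply(variables, function(v) summarize_one(cohort[[v]]), "")
  for (arm in TREATMENTS) {
    sel <- cohort$treatment == arm
    out[[arm]] <- vapply(variables,
                         function(v) summarize_one(cohort[[v]][sel]), "")
  }
  rownames(out) <- NULL
  out
}

#' Published registry reference counts
#'
#' Loads the printed arm-level counts from the national blunt-splenic-trauma
#' registry descriptive table shipped with the package (patients, deaths and
#' grade-5 injuries per arm), used to reproduce the printed percentages
#' exactly.
#'
#' @return data.frame with columns `treatment`, `n`, `deaths`, `grade5`.
#' @export
registry_reference_counts <- function() {
  path <- system.file("extdata", "tqip_table1_counts.csv",
                      package = "traumapolicy", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$treatment <- factor(df$treatment, levels = TREATMENTS)
  df[order(df$treatment), ]
}

#' Expand arm-level counts into a minimal patient-level cohort
#'
#' Builds a cohort table (treatment, death, spleen_grade) whose marginals
#' reproduce the supplied counts exactly, so the package's descriptive
#' functions can recompute printed percentages from printed counts. Grade is
#' coded 5 for the `grade5` rows and 1 otherwise (only the grade-5 share is
#' meaningful in the result).
#'
#' @param counts data.frame as returned by [registry_reference_counts()].
#' @return a validated cohort data.frame.
#' @export
counts_to_cohort <- function(counts = registry_reference_counts()) {
  rows <- lapply(seq_len(nrow(counts)), function(k) {
    n <- counts$n[k]
    deaths <- counts$deaths[k]
    g5 <- counts$grade5[k]
    data.frame(
      treatment = rep(as.character(counts$treatment[k]), n),
      death = rep(c(1L, 0L), c(deaths, n - deaths)),
      spleen_grade = rep(c(5L, 1L), c(g5, n - g5)),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$treatment <- factor(df$treatment, levels = TREATMENTS)
  validate_cohort(df)
  df
}
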