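#' Cohort table schema
#'
#' A cohort is a plain \code{data.frame} with one row per patient: numeric and
#' 0/1 covariates (vitals, splenic injury grade, transfusion and comorbidity
#' flags), a three-level \code{treatment} column
#' (\code{"OBS"}, \code{"AE"}, \code{"SPLENECTOMY"}) and a binary \code{death}
#' column for in-hospital mortality. Synthetic cohorts additionally carry
#' oracle columns \code{p_obs}, \code{p_ae}, \code{p_splen} (true mortality
#' risk under each arm) and \code{e_obs}, \code{e_ae}, \code{e_splen} (true
#' assignment propensities); these are excluded from modeling features by
#' name.
#'
#' @name cohort-table
NULL

ORACLE_RISK_COLS <- c(OBS = "p_obs", AE = "p_ae", SPLENECTOMY = "p_splen")
ORACLE_PROP_COLS <- c(OBS = "e_obs", AE = "e_ae", SPLENECTOMY = "e_splen")

#' Validate a cohort table
#'
#' Checks the analysis contract: `treatment` present with known levels,
#' `death` present and coded 0/1, and `spleen_grade` (if present) an integer
#' in 1..5. Returns the cohort invisibly with `treatment` coerced to a factor
#' with the canonical arm order.
#'
#' @param cohort data.frame of patient rows.
#' @param require_outcome require a complete `death` column (default TRUE).
#' @return the validated cohort, invisibly.
#' @export
validate_cohort <- function(cohort, require_outcome = TRUE) {
  if (!is.data.frame(cohort)) stopf("cohort must be a data.frame")
  if (!"treatment" %in% names(cohort)) {
    stopf("cohort is missing required column 'treatment'")
  }
  tr <- as.character(cohort$treatment)
  bad <- setdiff(unique(tr[!is.na(tr)]), TREATMENTS)
  if (length(bad)) {
    stopf("unknown treatment level(s): %s", paste(bad, collapse = ", "))
  }
  if (nrow(cohort) > 0 && anyNA(tr)) stopf("treatment has missing values")
  cohort$treatment <- factor(tr, levels = TREATMENTS)
  if (require_outcome) {
    if (!"death" %in% names(cohort)) {
      stopf("cohort is missing required column 'death'")
    }
    y <- cohort$death
    if (nrow(cohort) > 0 && (anyNA(y) || !all(y %in% c(0, 1)))) {
      stopf("death must be complete and coded 0/1")
    }
  }
  if ("spleen_grade" %in% names(cohort) && nrow(cohort) > 0) {
    g <- cohort$spleen_grade
    ok <- !is.na(g) & g == round(g) & g >= 1 & g <= 5
    if (!all(ok)) stopf("spleen_grade must be an integer in 1..5")
  }
  invisible(cohort)
}

#' Default modeling feature list for a cohort
#'
#' All numeric columns except the treatment, the outcome, and the synthetic
#' oracle columns (`p_*`, `e_*`). Oracle risks/propensities exist only in
#' simulated cohorts and must never leak into nuisance models.
#'
#' @param cohort cohort data.frame.
#' @return character vector of feature column names.
#' @export
modeling_features <- function(cohort) {
  drop <- c("treatment", "death", ORACLE_RISK_COLS, ORACLE_PROP_COLS)
  keep <- setdiff(names(cohort), drop)
  keep[vapply(cohort[keep], is.numeric, logical(1))]
}

#' Write a cohort to CSV with a data-dictionary sidecar
#'
#' Writes `path` (plain CSV) plus `<path>.dict.json` describing each column
#' and a schema version tag, so cohorts can be exchanged with non-R tools.
#'
#' @param cohort cohort data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort, require_outcome = FALSE)
  utils::write.csv(cohort, path, row.names = FALSE)
  dict <- list(
    schema_version = "traumapolicy-cohort-1",
    n_rows = nrow(cohort),
    columns = lapply(names(cohort), function(nm) {
      list(name = nm, class = class(cohort[[nm]])[1L],
           oracle = nm %in% c(ORACLE_RISK_COLS, ORACLE_PROP_COLS))
    })
  )
  jsonlite::write_json(dict, paste0(path, ".dict.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a cohort CSV and validate its schema
#'
#' @param path CSV path as written by [write_cohort()] (or any CSV with the
#'   required columns).
#' @param require_outcome require the `death` column (default TRUE).
#' @return validated cohort data.frame.
#' @export
read_cohort <- function(path, require_outcome = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df, require_outcome = require_outcome)
  df$treatment <- factor(as.character(df$treatment), levels = TREATMENTS)
  df
}
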