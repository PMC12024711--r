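#' Serialize a synthetic spec as a flat YAML config
#'
#' Writes every scalar field, the named coefficient vectors, the per-leaf
#' offset matrix and the planted policy (embedded as its JSON string) to a
#' human-editable YAML file; [read_spec()] reconstructs an identical spec,
#' so `(config, seed)` fully reproduces a cohort.
#'
#' @param spec `synthetic_spec`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_spec <- function(spec, path) {
  stopifnot(inherits(spec, "synthetic_spec"))
  payload <- list(
    format = "traumapolicy-spec-1",
    n_patients = spec$n_patients,
    seed = spec$seed,
    sbp_missing_rate = spec$sbp_missing_rate,
    propensity = lapply(spec$propensity, as.list),
    outcome_base = as.list(spec$outcome_base),
    leaf_offsets = apply(spec$leaf_offsets, 1L, as.list, simplify = FALSE),
    planted_policy = as.character(policy_tree_json(spec$planted_policy))
  )
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' @rdname write_spec
#' @export
read_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!identical(obj$format, "traumapolicy-spec-1")) {
    stopf("not a traumapolicy spec config")
  }
  offs <- do.call(rbind, lapply(obj$leaf_offsets, function(r) unlist(r)))
  colnames(offs) <- TREATMENTS
  synthetic_spec(
    n_patients = obj$n_patients,
    propensity = lapply(obj$propensity, unlist),
    outcome_base = unlist(obj$outcome_base),
    planted_policy = policy_tree_from_json(obj$planted_policy),
    leaf_offsets = offs,
    sbp_missing_rate = obj$sbp_missing_rate %||% 0,
    seed = obj$seed
  )
}

#' Write a descriptive summary table as CSV or Markdown
#'
#' @param summary_table data.frame from [describe()] (or any flat table).
#' @param path output file path.
#' @param format `"csv"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_table1 <- function(summary_table, path, format = c("csv", "markdown")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(summary_table, path, row.names = FALSE)
  } else {
    cells <- vapply(summary_table, as.character, character(nrow(summary_table)))
    if (nrow(summary_table) == 1L) cells <- matrix(cells, nrow = 1L)
    header <- paste0("| ", paste(names(summary_table), collapse = " | "), " |")
    rule <- paste0("|", paste(rep(" --- |", ncol(summary_table)), collapse = ""))
    rows <- apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    writeLines(c(header, rule, rows), path)
  }
  invisible(path)
}
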