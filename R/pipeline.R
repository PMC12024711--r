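#' End-to-end prescription pipeline
#'
#' One call reproducing the full protocol shape: load or simulate a cohort,
#' optionally stratify at admission SBP 70 mmHg, split each stratum 50/50
#' into training and testing halves (stratified on treatment and outcome),
#' fit cross-fitted nuisances independently within each half, build
#' doubly-robust rewards, tune and train a policy tree on the training half
#' (grid search over depth and complexity penalty, validated honestly on an
#' internal split of the training half whose rewards come from nuisances
#' fit only on that internal split), and evaluate the winner on the test
#' half.
#' Artifacts (tree JSON and DOT, value reports, tuning tables, a structured
#' log) are written to an output directory when one is given; a run is
#' fully reproducible from (config, seed).
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param input cohort CSV path, or `NULL` to simulate from `spec`.
#' @param spec `synthetic_spec` used when `input` is `NULL`
#'   (default [default_preset()]).
#' @param seed master seed for every random stage.
#' @param stratify stratify at SBP 70 mmHg before fitting (default TRUE).
#' @param train_fraction training-half fraction (default 0.5).
#' @param val_fraction fraction of the training half held out internally
#'   for (depth, cp) selection (default 0.5).
#' @param min_leaf minimum training rows per leaf (default 20).
#' @param depth_grid candidate depths (default 3:8).
#' @param cp_grid candidate complexity penalties
#'   (default `c(0, 1e-4, 1e-3, 1e-2)`).
#' @param k_folds cross-fitting folds for the nuisances (default 5).
#' @param clip_bounds propensity clip interval for the pipeline (default
#'   `c(0.10, 0.90)`): inverse-propensity weights are truncated at 10.
#'   With an arm received by only ~3% of patients, untruncated weights let
#'   single survivors dominate the split search; the truncation trades a
#'   small known bias for a large variance reduction.
#' @param model_family `"forest"` or `"logistic"` nuisances.
#' @param num_trees forest size per nuisance fit (default 200).
#' @param n_restarts tree-search restarts per grid cell (default 2).
#' @param features feature list; `NULL` means [modeling_features()] of the
#'   cohort.
#' @param output_dir directory for artifacts, or `NULL` for none.
#' @return a `run_config` list.
#' @export
run_config <- function(input = NULL, spec = default_preset(), seed = 1L,
                       stratify = TRUE, train_fraction = 0.5,
                       val_fraction = 0.5, min_leaf = 20, depth_grid = 3:8,
                       cp_grid = c(0, 1e-4, 1e-3, 1e-2), k_folds = 5,
                       clip_bounds = c(0.10, 0.90),
                       model_family = c("forest", "logistic"),
                       num_trees = 300, n_restarts = 2L, features = NULL,
                       output_dir = NULL) {
  structure(
    list(input = input, spec = spec, seed = as.integer(seed),
         stratify = stratify, train_fraction = train_fraction,
         val_fraction = val_fraction, min_leaf = min_leaf,
         depth_grid = depth_grid, cp_grid = cp_grid, k_folds = k_folds,
         clip_bounds = clip_bounds, model_family = match.arg(model_family),
         num_trees = num_trees, n_restarts = n_restarts, features = features,
         output_dir = output_dir),
    class = "run_config")
}

config_echo <- function(config) {
  cfg <- config[setdiff(names(config), "spec")]
  cfg$spec <- if (is.null(config$input)) "synthetic preset" else NULL
  cfg
}

run_one_stratum <- function(cohort, config, label, seed) {
  min_needed <- max(4L * config$min_leaf, 80L)
  if (nrow(cohort) < min_needed) {
    warnf("stratum '%s' too small for min_leaf %d and the depth grid (n = %d); skipped",
          label, config$min_leaf, nrow(cohort))
    return(NULL)
  }
  tryCatch(
    run_one_stratum_impl(cohort, config, label, seed),
    error = function(e) {
      warnf("stratum '%s' skipped: %s", label, conditionMessage(e))
      NULL
    }
  )
}

run_one_stratum_impl <- function(cohort, config, label, seed) {
  features <- config$features %||% modeling_features(cohort)
  halves <- split_cohort(cohort, config$train_fraction, derive_seed(seed, 1L))
  fit_nu <- function(h, off) {
    fit_nuisances(h, features = features, k_folds = config$k_folds,
                  seed = derive_seed(seed, off),
                  model_family = config$model_family,
                  clip_bounds = config$clip_bounds,
                  num_trees = config$num_trees)
  }
  # internal validation split of the training half for (depth, cp); the
  # validation rewards come from nuisances fit only on the validation
  # subset, so model selection is honest (no shared nuisance errors)
  inner <- split_cohort(halves$train, 1 - config$val_fraction,
                        derive_seed(seed, 3L))
  nu_inner_tr <- fit_nu(inner$train, 4L)
  nu_inner_val <- fit_nu(inner$test, 5L)
  g_inner_tr <- doubly_robust_rewards(inner$train, nu_inner_tr)
  g_inner_val <- doubly_robust_rewards(inner$test, nu_inner_val)
  tuned <- tune_policy_tree(
    g_inner_tr, inner$train, g_inner_val, inner$test,
    features = features, depth_grid = config$depth_grid,
    cp_grid = config$cp_grid, min_leaf = config$min_leaf,
    seed = derive_seed(seed, 6L), n_restarts = config$n_restarts)
  # test half: independent nuisances, unbiased held-out evaluation
  nu_test <- fit_nu(halves$test, 2L)
  g_test <- doubly_robust_rewards(halves$test, nu_test)
  report <- policy_report(tuned$tree, g_test, halves$test,
                          nuisances = nu_test, stratum = label)
  list(label = label, tree = tuned$tree, tuning = tuned$grid,
       winner = tuned$winner, report = report,
       halves = halves,
       rewards = list(train = g_inner_tr, val = g_inner_val, test = g_test),
       n_clipped = c(train = nu_inner_tr$n_clipped + nu_inner_val$n_clipped,
                     test = nu_test$n_clipped),
       features = features)
}

#' Run the full pipeline
#'
#' @param config a [run_config()].
#' @param cohort optional pre-loaded cohort (overrides `config$input` and
#'   `config$spec`).
#' @return invisible list with per-stratum results (`strata`), the cohort,
#'   the echoed config, and the output directory (if any).
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(cohort)) {
    cohort <- if (!is.null(config$input)) {
      read_cohort(config$input)
    } else {
      generate_cohort(config$spec, seed = derive_seed(config$seed, 100L))
    }
  } else {
    validate_cohort(cohort)
  }
  strata <- if (config$stratify) {
    s <- stratify(cohort, "sbp", 70)
    list(`SBP < 70` = s$low, `SBP >= 70` = s$high)
  } else {
    list(`all` = cohort)
  }
  results <- list()
  for (k in seq_along(strata)) {
    res <- run_one_stratum(strata[[k]], config, names(strata)[k],
                           derive_seed(config$seed, 1000L + k))
    if (!is.null(res)) results[[names(strata)[k]]] <- res
  }
  out <- list(strata = results, cohort = cohort, config = config_echo(config),
              output_dir = config$output_dir)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(out$config,
                         file.path(config$output_dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    log_lines <- c(sprintf("seed: %d", config$seed),
                   sprintf("n_total: %d", nrow(cohort)),
                   sprintf("R: %s", R.version.string),
                   sprintf("packages: ranger %s, jsonlite %s",
                           as.character(utils::packageVersion("ranger")),
                           as.character(utils::packageVersion("jsonlite"))))
    for (nm in names(results)) {
      res <- results[[nm]]
      slug <- gsub("[^a-z0-9]+", "_", tolower(nm))
      write_policy_tree(res$tree,
                        file.path(config$output_dir, paste0("tree_", slug, ".json")))
      write_tree_dot(res$tree,
                     file.path(config$output_dir, paste0("tree_", slug, ".dot")))
      utils::write.csv(res$tuning,
                       file.path(config$output_dir, paste0("tuning_", slug, ".csv")),
                       row.names = FALSE)
      report_to_json(res$report,
                     file.path(config$output_dir, paste0("report_", slug, ".json")))
      log_lines <- c(log_lines,
                     sprintf("stratum %s: n=%d, clipped propensities train=%d test=%d",
                             nm, res$report$n + nrow(res$halves$train),
                             res$n_clipped[["train"]], res$n_clipped[["test"]]))
    }
    writeLines(log_lines, file.path(config$output_dir, "run.log"))
  }
  invisible(out)
}

#' Prescribe with a fitted pipeline result
#'
#' Routes new rows to the appropriate stratum tree (by admission SBP when
#' the run was stratified) and returns the prescribed arm per row.
#'
#' @param run result of [run_pipeline()].
#' @param rows cohort rows.
#' @return factor of arms, levels `TREATMENTS`; `NA` for rows whose stratum
#'   was skipped.
#' @export
pipeline_prescribe <- function(run, rows) {
  out <- factor(rep(NA_character_, nrow(rows)), levels = TREATMENTS)
  if ("all" %in% names(run$strata)) {
    return(prescribe(run$strata[["all"]]$tree, rows))
  }
  low <- !is.na(rows$sbp) & rows$sbp < 70
  if ("SBP < 70" %in% names(run$strata) && any(low)) {
    out[low] <- prescribe(run$strata[["SBP < 70"]]$tree, rows[low, , drop = FALSE])
  }
  if ("SBP >= 70" %in% names(run$strata) && any(!low)) {
    out[!low] <- prescribe(run$strata[["SBP >= 70"]]$tree, rows[!low, , drop = FALSE])
  }
  out
}
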