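#' Doubly-robust reward estimation
#'
#' The reward for patient i under arm t is the AIPW (augmented inverse
#' propensity weighted) mortality score
#' \deqn{\Gamma_i(t) = \hat\mu_t(x_i) + \frac{1\{T_i = t\}\,(Y_i -
#'   \hat\mu_t(x_i))}{\hat e_t(x_i)},}
#' combining a per-arm outcome model \eqn{\hat\mu_t} with a three-class
#' propensity model \eqn{\hat e_t}. Both nuisances are cross-fitted: every
#' row is predicted by models trained on folds that exclude it. Rewards are
#' mortality scores to be MINIMIZED everywhere in this package; entries can
#' legitimately fall outside [0, 1] because of the inverse-propensity
#' correction and are deliberately not clamped.
#'
#' @name doubly-robust-rewards
NULL

# stratified fold assignment on (treatment, death)
make_folds <- function(cohort, k_folds, seed) {
  set.seed(seed)
  fold <- integer(nrow(cohort))
  cells <- interaction(cohort$treatment, cohort$death, drop = TRUE)
  for (cell in levels(cells)) {
    idx <- which(cells == cell)
    fold[idx] <- sample(rep_len(seq_len(k_folds), length(idx)))
  }
  fold
}

fit_outcome_one <- function(train, features, family, num_trees, seed,
                            min_node = 25) {
  if (family == "forest") {
    fit <- ranger::ranger(
      x = train[features], y = factor(train$death, levels = c(0, 1)),
      probability = TRUE, num.trees = num_trees, seed = seed,
      num.threads = 1, min.node.size = min_node)
    function(newdata) {
      pr <- stats::predict(fit, data = newdata[features],
                           num.threads = 1)$predictions
      if ("1" %in% colnames(pr)) pr[, "1"] else rep(0, nrow(newdata))
    }
  } else {
    dat <- train[c(features, "death")]
    fit <- suppressWarnings(stats::glm(death ~ ., data = dat,
                                       family = stats::binomial()))
    function(newdata) {
      unname(stats::predict(fit, newdata = newdata[features],
                            type = "response"))
    }
  }
}

fit_propensity_one <- function(train, features, family, num_trees, seed,
                               min_node = 50) {
  if (family == "forest") {
    fit <- ranger::ranger(
      x = train[features], y = droplevels(train$treatment),
      probability = TRUE, num.trees = num_trees, seed = seed,
      num.threads = 1, min.node.size = min_node)
    function(newdata) {
      pr <- stats::predict(fit, data = newdata[features],
                           num.threads = 1)$predictions
      out <- matrix(0, nrow(newdata), 3L, dimnames = list(NULL, TREATMENTS))
      out[, colnames(pr)] <- pr
      out
    }
  } else {
    dat <- train[c(features, "treatment")]
    dat$treatment <- droplevels(dat$treatment)
    fit <- suppressWarnings(nnet::multinom(treatment ~ ., data = dat,
                                           trace = FALSE, maxit = 200))
    lev <- levels(dat$treatment)
    function(newdata) {
      pr <- stats::predict(fit, newdata = newdata[features], type = "probs")
      if (is.null(dim(pr))) pr <- matrix(pr, ncol = length(lev),
                                         dimnames = list(NULL, lev),
                                         byrow = length(lev) > 1 && nrow(newdata) == 1)
      out <- matrix(0, nrow(newdata), 3L, dimnames = list(NULL, TREATMENTS))
      out[, colnames(pr)] <- pr
      out
    }
  }
}

#' Fit cross-fitted nuisance models
#'
#' Fits, within each of `k_folds` folds (stratified on treatment and
#' outcome), a per-arm outcome model for mortality risk and a three-class
#' propensity model, and assembles out-of-fold predictions
#' \eqn{\hat\mu_t(x_i)} and \eqn{\hat e_t(x_i)} for every row, so no row is
#' ever scored by a model that saw it. The default family is a probability
#' random forest (ranger); a logistic family
#' (per-arm \code{glm} + multinomial logit) is available for fast,
#' well-specified tests.
#'
#' @param cohort validated cohort data.frame.
#' @param features feature columns (default [modeling_features()]).
#' @param k_folds number of cross-fitting folds (>= 2; default 5).
#' @param seed RNG seed for folds and forests.
#' @param model_family `"forest"` (default) or `"logistic"`.
#' @param clip_bounds two probabilities; propensities are clipped into this
#'   interval after prediction (default `c(0.01, 0.99)`), bounding the
#'   inverse-propensity weights on rare arms. Tighter floors trade a little
#'   bias for much lower reward variance; the pipeline default is 0.10 (see
#'   [run_config()]).
#' @param num_trees forest size per nuisance fit (default 300).
#' @param min_node_size named vector with elements `outcome` and
#'   `propensity`: ranger minimum node sizes (defaults 25 and 50;
#'   probability forests need large nodes to output calibrated
#'   probabilities, especially for the rare angioembolization arm).
#' @return object of class `nuisance_models`: list with `mu` and `e`
#'   (n x 3 matrices, columns `TREATMENTS`), `folds`, `n_clipped`,
#'   `clip_bounds`, `family`, `features`, `seed`.
#' @export
fit_nuisances <- function(cohort, features = modeling_features(cohort),
                          k_folds = 5, seed = 1L,
                          model_family = c("forest", "logistic"),
                          clip_bounds = c(0.01, 0.99), num_trees = 300,
                          min_node_size = c(outcome = 25, propensity = 50)) {
  model_family <- match.arg(model_family)
  validate_cohort(cohort)
  if (k_folds < 2) stopf("k_folds must be >= 2")
  bad_feat <- features[!vapply(cohort[features], is.numeric, logical(1))]
  if (length(bad_feat)) {
    stopf("non-numeric feature column(s): %s", paste(bad_feat, collapse = ", "))
  }
  counts <- table(cohort$treatment)
  for (arm in TREATMENTS) {
    if (counts[[arm]] == 0) stopf("treatment arm %s is absent from the cohort", arm)
  }
  for (arm in TREATMENTS) {
    if (counts[[arm]] < 2 * k_folds) {
      stopf("treatment arm %s too sparse for %d-fold cross-fitting (%d rows)",
            arm, k_folds, counts[[arm]])
    }
  }
  n <- nrow(cohort)
  fold <- make_folds(cohort, k_folds, derive_seed(seed, 0L))
  mu <- matrix(NA_real_, n, 3L, dimnames = list(NULL, TREATMENTS))
  e <- matrix(NA_real_, n, 3L, dimnames = list(NULL, TREATMENTS))
  for (f in seq_len(k_folds)) {
    hold <- fold == f
    train <- cohort[!hold, , drop = FALSE]
    for (j in seq_along(TREATMENTS)) {
      arm_train <- train[train$treatment == TREATMENTS[j], , drop = FALSE]
      pred <- fit_outcome_one(arm_train, features, model_family, num_trees,
                              derive_seed(seed, 10L * f + j),
                              min_node = min_node_size[["outcome"]])
      mu[hold, j] <- pred(cohort[hold, , drop = FALSE])
    }
    ppred <- fit_propensity_one(train, features, model_family, num_trees,
                                derive_seed(seed, 10L * f + 7L),
                                min_node = min_node_size[["propensity"]])
    e[hold, ] <- ppred(cohort[hold, , drop = FALSE])
  }
  e_raw <- e
  e <- pmin(pmax(e, clip_bounds[1L]), clip_bounds[2L])
  n_clipped <- sum(e != e_raw)
  structure(
    list(mu = mu, e = e, folds = fold, n_clipped = n_clipped,
         clip_bounds = clip_bounds, family = model_family,
         features = features, seed = seed, k_folds = k_folds),
    class = "nuisance_models"
  )
}

#' Assemble nuisance predictions by hand
#'
#' Wraps externally supplied risk and propensity matrices (for instance the
#' synthetic generator's oracle columns, or deliberately misspecified
#' models for robustness checks) in the `nuisance_models` container so they
#' can be fed to [doubly_robust_rewards()].
#'
#' @param mu n x 3 matrix of per-arm mortality risks.
#' @param e n x 3 matrix of assignment propensities (clipped into
#'   `clip_bounds`).
#' @param clip_bounds propensity clip interval.
#' @return a `nuisance_models` object.
#' @export
manual_nuisances <- function(mu, e, clip_bounds = c(0.01, 0.99)) {
  stopifnot(is.matrix(mu), is.matrix(e), nrow(mu) == nrow(e),
            ncol(mu) == 3L, ncol(e) == 3L)
  colnames(mu) <- TREATMENTS
  e_raw <- e
  e <- pmin(pmax(e, clip_bounds[1L]), clip_bounds[2L])
  colnames(e) <- TREATMENTS
  structure(
    list(mu = mu, e = e, folds = rep.int(0L, nrow(mu)),
         n_clipped = sum(e != e_raw), clip_bounds = clip_bounds,
         family = "manual", features = character(0), seed = NA_integer_,
         k_folds = 0L),
    class = "nuisance_models"
  )
}

unclass_rewards <- function(rewards) {
  m <- unclass(rewards)
  attributes(m) <- list(dim = dim(m), dimnames = list(NULL, TREATMENTS))
  m
}

#' Doubly-robust reward matrix
#'
#' For each row, the column of the observed arm carries the
#' inverse-propensity-weighted residual correction; the other columns equal
#' the outcome model's prediction. Provenance (clip counts, nuisance family,
#' seed) is attached as the `"provenance"` attribute.
#'
#' @param cohort validated cohort (the same rows the nuisances were
#'   cross-fitted on).
#' @param nuisances a `nuisance_models` object for these rows.
#' @return `reward_matrix`: an n x 3 numeric matrix (columns `TREATMENTS`)
#'   of mortality scores to minimize.
#' @export
doubly_robust_rewards <- function(cohort, nuisances) {
  stopifnot(inherits(nuisances, "nuisance_models"))
  validate_cohort(cohort)
  n <- nrow(cohort)
  if (nrow(nuisances$mu) != n) {
    stopf("nuisance predictions (%d rows) do not align with cohort (%d rows)",
          nrow(nuisances$mu), n)
  }
  gamma <- nuisances$mu
  t_idx <- as.integer(cohort$treatment)
  obs <- cbind(seq_len(n), t_idx)
  gamma[obs] <- gamma[obs] +
    (cohort$death - nuisances$mu[obs]) / nuisances$e[obs]
  if (any(!is.finite(gamma))) stopf("non-finite reward entries produced")
  structure(gamma, class = c("reward_matrix", "matrix"),
            provenance = list(
              n = n, family = nuisances$family, seed = nuisances$seed,
              k_folds = nuisances$k_folds,
              clip_bounds = nuisances$clip_bounds,
              n_clipped = nuisances$n_clipped))
}

#' Write / read a reward matrix as CSV with a provenance sidecar
#'
#' @param rewards `reward_matrix`.
#' @param path CSV path; provenance goes to `<path>.meta.json`.
#' @return `path` (write) or a `reward_matrix` (read).
#' @export
write_rewards <- function(rewards, path) {
  utils::write.csv(as.data.frame(unclass_rewards(rewards)), path,
                   row.names = FALSE)
  jsonlite::write_json(attr(rewards, "provenance") %||% list(),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_rewards
#' @export
read_rewards <- function(path) {
  m <- as.matrix(utils::read.csv(path))
  if (!identical(colnames(m), TREATMENTS)) {
    stopf("reward CSV must have columns %s", paste(TREATMENTS, collapse = ", "))
  }
  meta_path <- paste0(path, ".meta.json")
  prov <- if (file.exists(meta_path)) {
    jsonlite::fromJSON(meta_path, simplifyVector = TRUE)
  } else list()
  structure(m, class = c("reward_matrix", "matrix"), provenance = prov)
}

#' Stratified 50/50-style cohort split
#'
#' Partitions the cohort into disjoint, exhaustive training and testing
#' halves, stratified jointly on (treatment, death) so every arm and both
#' outcomes appear in both halves whenever counts permit. A
#' (treatment, death) cell with a single member goes to training with a
#' warning. Overall sizes match `round(train_fraction * n)` exactly via
#' largest-remainder allocation across cells.
#'
#' @param cohort validated cohort.
#' @param train_fraction proportion in (0, 1) for the training half
#'   (default 0.5).
#' @param seed RNG seed.
#' @return list with `train` and `test` cohort data.frames.
#' @export
split_cohort <- function(cohort, train_fraction = 0.5, seed = 1L) {
  validate_cohort(cohort)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stopf("train_fraction must lie strictly between 0 and 1")
  }
  n <- nrow(cohort)
  set.seed(seed)
  cells <- interaction(cohort$treatment, cohort$death, drop = TRUE)
  cell_idx <- split(seq_len(n), cells)
  singletons <- names(cell_idx)[lengths(cell_idx) == 1L]
  if (length(singletons)) {
    warnf("(treatment, death) cell(s) with one member assigned to training: %s",
          paste(singletons, collapse = ", "))
  }
  target_total <- round(train_fraction * n)
  sizes <- lengths(cell_idx)
  base_take <- ifelse(sizes == 1L, 1L, pmin(floor(train_fraction * sizes),
                                            sizes - 1L))
  base_take <- pmax(base_take, ifelse(sizes >= 2L, 1L, 1L))
  remainder <- train_fraction * sizes - base_take
  extra <- target_total - sum(base_take)
  if (extra > 0) {
    can_grow <- which(base_take < pmax(sizes - 1L, 1L))
    ord <- can_grow[order(-remainder[can_grow], -sizes[can_grow])]
    grow <- head(ord, extra)
    base_take[grow] <- base_take[grow] + 1L
  } else if (extra < 0) {
    can_shrink <- which(base_take > 1L)
    ord <- can_shrink[order(remainder[can_shrink], sizes[can_shrink])]
    shrink <- head(ord, -extra)
    base_take[shrink] <- base_take[shrink] - 1L
  }
  train_rows <- unlist(lapply(seq_along(cell_idx), function(k) {
    idx <- cell_idx[[k]]
    if (length(idx) == 1L) return(idx)
    idx[sample.int(length(idx), base_take[k])]
  }), use.names = FALSE)
  train_rows <- sort(train_rows)
  list(train = cohort[train_rows, , drop = FALSE],
       test = cohort[-train_rows, , drop = FALSE])
}
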