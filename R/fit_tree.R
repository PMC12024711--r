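#' Policy-tree learning
#'
#' Learns an axis-aligned binary tree prescribing one treatment per leaf so
#' as to minimize the penalized objective
#' `mean_i Gamma_i(pi(x_i)) + cp * (number of splits)` subject to a minimum
#' leaf size and a maximum depth. The optimizer is a local search: a greedy
#' grow pass (exact enumeration of every axis-aligned split at each node),
#' exact bottom-up complexity pruning, and coordinate-descent refinement
#' that revisits each internal node and either collapses it or re-optimizes
#' its split; the penalized objective never increases across accepted
#' moves. Randomized restarts (per-node feature subsampling during the grow
#' pass) guard against greedy local optima; the best restart wins.
#' An exhaustive enumerator for depth <= 2 on small inputs serves as an
#' exact reference.
#'
#' @name policy-tree-learning
NULL

EPS_OBJ <- 1e-9

# leaf value: total reward of the best single arm over rows idx
leaf_value <- function(G, idx) {
  if (!length(idx)) return(0)
  min(colSums(G[idx, , drop = FALSE]))
}

leaf_arm <- function(G, idx) {
  TREATMENTS[which.min(colSums(G[idx, , drop = FALSE]))]
}

# Best single split of rows idx: enumerates every boundary between distinct
# values of every candidate feature; children valued as leaves.
# Returns NULL when no feasible split exists.
node_best_split <- function(G, Xm, idx, min_leaf, feat_set = seq_len(ncol(Xm))) {
  n_i <- length(idx)
  if (n_i < 2L * min_leaf) return(NULL)
  Gi <- G[idx, , drop = FALSE]
  total <- colSums(Gi)
  best_val <- Inf
  best <- NULL
  j <- seq_len(n_i - 1L)
  for (f in feat_set) {
    x <- Xm[idx, f]
    o <- order(x, method = "radix")
    xs <- x[o]
    valid <- (xs[j] < xs[j + 1L]) & (j >= min_leaf) & (n_i - j >= min_leaf)
    if (!any(valid)) next
    cs1 <- cumsum(Gi[o, 1L]); cs2 <- cumsum(Gi[o, 2L]); cs3 <- cumsum(Gi[o, 3L])
    jv <- j[valid]
    vals <- pmin(cs1[jv], cs2[jv], cs3[jv]) +
      pmin(total[1L] - cs1[jv], total[2L] - cs2[jv], total[3L] - cs3[jv])
    k <- which.min(vals)
    if (vals[k] < best_val - EPS_OBJ) {
      best_val <- vals[k]
      best <- list(val = vals[k], feature = f,
                   threshold = (xs[jv[k]] + xs[jv[k] + 1L]) / 2)
    }
  }
  best
}

# greedy grow (no cp): split whenever the immediate gain is positive
grow_greedy <- function(G, Xm, idx, depth_left, min_leaf, mtry_frac = 1) {
  lv <- leaf_value(G, idx)
  make_leaf <- function() list(type = "leaf", arm = leaf_arm(G, idx),
                               n_train = length(idx), strength = NA_real_)
  if (depth_left == 0L || length(idx) < 2L * min_leaf) return(make_leaf())
  feat_set <- seq_len(ncol(Xm))
  if (mtry_frac < 1) {
    m <- max(1L, ceiling(length(feat_set) * mtry_frac))
    feat_set <- sort(sample(feat_set, m))
  }
  s <- node_best_split(G, Xm, idx, min_leaf, feat_set)
  if (is.null(s) || s$val >= lv - EPS_OBJ) return(make_leaf())
  x <- Xm[idx, s$feature]
  go_left <- x < s$threshold
  list(type = "split", feature = colnames(Xm)[s$feature],
       threshold = s$threshold, missing = "left",
       left = grow_greedy(G, Xm, idx[go_left], depth_left - 1L, min_leaf, mtry_frac),
       right = grow_greedy(G, Xm, idx[!go_left], depth_left - 1L, min_leaf, mtry_frac))
}

# exact bottom-up pruning under penalty cp_total (= cp * n_total) per split;
# returns list(node, val = penalized subtree total, nsplits)
prune_cp <- function(node, G, Xm, idx, cp_total) {
  if (node$type == "leaf") {
    return(list(node = node, val = leaf_value(G, idx), nsplits = 0L))
  }
  x <- Xm[idx, node$feature]
  go_left <- x < node$threshold
  l <- prune_cp(node$left, G, Xm, idx[go_left], cp_total)
  r <- prune_cp(node$right, G, Xm, idx[!go_left], cp_total)
  keep_val <- l$val + r$val + cp_total
  collapse_val <- leaf_value(G, idx)
  if (collapse_val <= keep_val + EPS_OBJ) {
    list(node = list(type = "leaf", arm = leaf_arm(G, idx),
                     n_train = length(idx), strength = NA_real_),
         val = collapse_val, nsplits = 0L)
  } else {
    node$left <- l$node
    node$right <- r$node
    list(node = node, val = keep_val, nsplits = l$nsplits + r$nsplits + 1L)
  }
}

# penalized total value of a fixed-structure subtree with re-optimized leaf
# arms; Inf when a leaf violates min_leaf
structure_value <- function(node, G, Xm, idx, min_leaf, cp_total) {
  if (node$type == "leaf") {
    if (length(idx) < min_leaf) return(Inf)
    return(leaf_value(G, idx))
  }
  x <- Xm[idx, node$feature]
  go_left <- x < node$threshold
  lv <- structure_value(node$left, G, Xm, idx[go_left], min_leaf, cp_total)
  if (!is.finite(lv)) return(Inf)
  rv <- structure_value(node$right, G, Xm, idx[!go_left], min_leaf, cp_total)
  if (!is.finite(rv)) return(Inf)
  lv + rv + cp_total
}

subtree_depth_left <- function(node) {
  if (node$type == "leaf") 0L else
    1L + max(subtree_depth_left(node$left), subtree_depth_left(node$right))
}

# best single-split total value per feature (Inf where infeasible); used to
# rank features when the refinement move must budget its enumeration
node_split_gains <- function(G, Xm, idx, min_leaf) {
  n_i <- length(idx)
  gains <- rep(Inf, ncol(Xm))
  if (n_i < 2L * min_leaf) return(gains)
  Gi <- G[idx, , drop = FALSE]
  total <- colSums(Gi)
  j <- seq_len(n_i - 1L)
  for (f in seq_len(ncol(Xm))) {
    x <- Xm[idx, f]
    o <- order(x, method = "radix")
    xs <- x[o]
    valid <- (xs[j] < xs[j + 1L]) & (j >= min_leaf) & (n_i - j >= min_leaf)
    if (!any(valid)) next
    cs1 <- cumsum(Gi[o, 1L]); cs2 <- cumsum(Gi[o, 2L]); cs3 <- cumsum(Gi[o, 3L])
    jv <- j[valid]
    gains[f] <- min(pmin(cs1[jv], cs2[jv], cs3[jv]) +
                      pmin(total[1L] - cs1[jv], total[2L] - cs2[jv],
                           total[3L] - cs3[jv]))
  }
  gains
}

# Exact (or budgeted) penalized-optimal subtree of depth <= 2 over rows ix:
# enumerate root (feature, threshold) candidates, solving each child as the
# exact depth-<=1 subproblem (single pass over sorted prefix sums). With
# `full = TRUE` every boundary of every feature is enumerated (the
# exhaustive oracle); otherwise the enumeration is budgeted to the
# top-gain features and a quantile threshold grid once the total boundary
# count grows large.
exact_subtree <- function(G, Xm, ix, depth_left, min_leaf, cp_total,
                          full = FALSE, feat_cap = 4L, th_cap = 16L,
                          full_limit = 20000L) {
  mk_leaf <- function(jx) list(type = "leaf", arm = leaf_arm(G, jx),
                               n_train = length(jx), strength = NA_real_)
  # best depth-<=1 subtree: penalized value + node + split count
  child_feats <- seq_len(ncol(Xm))
  best1 <- function(jx) {
    lv <- leaf_value(G, jx)
    if (length(jx) < min_leaf) lv <- Inf
    s <- node_best_split(G, Xm, jx, min_leaf, child_feats)
    if (!is.null(s) && s$val + cp_total < lv - EPS_OBJ) {
      go_left <- Xm[jx, s$feature] < s$threshold
      list(val = s$val + cp_total,
           node = list(type = "split", feature = colnames(Xm)[s$feature],
                       threshold = s$threshold, missing = "left",
                       left = mk_leaf(jx[go_left]),
                       right = mk_leaf(jx[!go_left])))
    } else {
      list(val = lv, node = mk_leaf(jx))
    }
  }
  best <- list(val = leaf_value(G, ix), node = mk_leaf(ix))
  if (depth_left >= 1L) {
    b1 <- best1(ix)
    if (b1$val < best$val - EPS_OBJ) best <- b1
  }
  if (depth_left >= 2L) {
    n_i <- length(ix)
    cand_mids <- lapply(seq_len(ncol(Xm)), function(f) {
      xs <- sort(unique(Xm[ix, f]))
      if (length(xs) < 2L) numeric(0) else (xs[-1L] + xs[-length(xs)]) / 2
    })
    feat_order <- seq_len(ncol(Xm))
    # the enumeration work scales as (root candidates) x (child features);
    # fall back to a budgeted search when that product grows large
    if (!full && sum(lengths(cand_mids)) * ncol(Xm) > full_limit) {
      gains <- node_split_gains(G, Xm, ix, min_leaf)
      feat_order <- order(gains)[seq_len(min(feat_cap, ncol(Xm)))]
      feat_order <- feat_order[is.finite(gains[feat_order])]
      child_feats <- sort(unique(c(feat_order,
                                   order(gains)[seq_len(min(2L * feat_cap,
                                                            ncol(Xm)))])))
      cand_mids <- lapply(cand_mids, function(m) {
        if (length(m) > th_cap) {
          unique(stats::quantile(m, probs = seq_len(th_cap) / (th_cap + 1),
                                 names = FALSE, type = 7))
        } else m
      })
    }
    for (f in feat_order) {
      x <- Xm[ix, f]
      for (th in cand_mids[[f]]) {
        go_left <- x < th
        nl <- sum(go_left)
        if (nl < min_leaf || n_i - nl < min_leaf) next
        l <- best1(ix[go_left])
        r <- best1(ix[!go_left])
        v <- l$val + r$val + cp_total
        if (v < best$val - EPS_OBJ) {
          best <- list(val = v,
                       node = list(type = "split", feature = colnames(Xm)[f],
                                   threshold = th, missing = "left",
                                   left = l$node, right = r$node))
        }
      }
    }
  }
  best
}

# one coordinate-descent refinement pass; returns list(node, improved).
# Re-split moves are confined to small nodes (where they matter and where
# the exact depth-<=2 regrow is affordable); larger nodes keep the collapse
# move and recurse — the grow pass already enumerated every split there.
refine_pass <- function(node, G, Xm, idx, depth_left, min_leaf, cp_total,
                        exact_n = 600L) {
  if (node$type == "leaf") return(list(node = node, improved = FALSE))
  improved <- FALSE
  cur_val <- structure_value(node, G, Xm, idx, min_leaf, cp_total)
  # move A: collapse to a leaf
  collapse_val <- leaf_value(G, idx)
  if (collapse_val < cur_val - EPS_OBJ) {
    return(list(node = list(type = "leaf", arm = leaf_arm(G, idx),
                            n_train = length(idx), strength = NA_real_),
                improved = TRUE))
  }
  # move B: re-optimize this node's subtree when it is small and shallow
  # enough for the (budgeted) depth-<=2 enumeration
  n_i <- length(idx)
  if (n_i <= exact_n && depth_left <= 2L) {
    ex <- exact_subtree(G, Xm, idx, depth_left, min_leaf, cp_total)
    if (ex$val < cur_val - EPS_OBJ) {
      node <- ex$node
      improved <- TRUE
      if (node$type == "leaf") return(list(node = node, improved = TRUE))
    }
  }
  # recurse into children
  x <- Xm[idx, node$feature]
  go_left <- x < node$threshold
  l <- refine_pass(node$left, G, Xm, idx[go_left], depth_left - 1L,
                   min_leaf, cp_total, exact_n)
  r <- refine_pass(node$right, G, Xm, idx[!go_left], depth_left - 1L,
                   min_leaf, cp_total, exact_n)
  node$left <- l$node
  node$right <- r$node
  list(node = node, improved = improved || l$improved || r$improved)
}

prepare_X <- function(data, features) {
  miss <- setdiff(features, names(data))
  if (length(miss)) {
    stopf("unknown feature column(s): %s", paste(miss, collapse = ", "))
  }
  bad <- features[!vapply(data[features], is.numeric, logical(1))]
  if (length(bad)) {
    stopf("non-numeric feature column(s): %s", paste(bad, collapse = ", "))
  }
  Xm <- as.matrix(data[features])
  # split search needs complete values; impute medians (prescribe-time
  # missingness is handled by majority-branch routing instead)
  for (f in seq_len(ncol(Xm))) {
    na <- is.na(Xm[, f])
    if (any(na)) Xm[na, f] <- stats::median(Xm[, f], na.rm = TRUE)
  }
  Xm
}

check_alignment <- function(rewards, data) {
  G <- unclass_rewards(rewards)
  if (nrow(G) != nrow(data)) {
    stopf("rewards (%d rows) do not align with features (%d rows)",
          nrow(G), nrow(data))
  }
  G
}

#' Train a policy tree by local search
#'
#' @param rewards `reward_matrix` of mortality scores (minimized).
#' @param data data.frame of covariates aligned row-by-row with `rewards`.
#' @param features feature columns to split on (default
#'   [modeling_features()]).
#' @param depth maximum tree depth (number of splits on any root-to-leaf
#'   path).
#' @param min_leaf minimum training rows per leaf (default 20).
#' @param cp complexity penalty per split, on the mean-reward scale
#'   (default 0).
#' @param seed RNG seed (restart randomization).
#' @param n_restarts number of randomized restarts; restart 1 is the
#'   deterministic full-feature greedy pass (default 5).
#' @return a `policy_tree` whose `meta` records the penalized objective,
#'   settings and seed.
#' @export
train_policy_tree <- function(rewards, data, features = modeling_features(data),
                              depth, min_leaf = 20, cp = 0, seed = 1L,
                              n_restarts = 5L) {
  G <- check_alignment(rewards, data)
  stopifnot(depth >= 1, min_leaf >= 1, cp >= 0, n_restarts >= 1)
  n <- nrow(G)
  if (min_leaf * 2 > n) {
    warnf("fewer than 2 * min_leaf rows; returning a single-leaf tree")
    depth <- 0L
  } else if (min_leaf * 2^depth > n) {
    feasible <- max(0L, floor(log2(n / min_leaf)))
    warnf("min_leaf * 2^depth exceeds n; reducing depth from %d to %d",
          depth, feasible)
    depth <- feasible
  }
  Xm <- prepare_X(data, features)
  idx <- seq_len(n)
  cp_total <- cp * n
  set.seed(derive_seed(seed, 0L))
  # grow + prune every restart; refine only the most promising few
  grown <- vector("list", n_restarts)
  grown_val <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    mtry_frac <- if (r == 1L) 1 else stats::runif(1, 0.5, 0.95)
    root <- grow_greedy(G, Xm, idx, depth, min_leaf, mtry_frac)
    pr <- prune_cp(root, G, Xm, idx, cp_total)
    grown[[r]] <- pr$node
    grown_val[r] <- pr$val
  }
  best <- NULL
  n_refine <- if (nrow(G) <= 2000L) min(n_restarts, 3L) else 1L
  for (r in order(grown_val)[seq_len(n_refine)]) {
    root <- grown[[r]]
    for (pass in seq_len(3L)) {
      res <- refine_pass(root, G, Xm, idx, depth, min_leaf, cp_total)
      root <- res$node
      if (!res$improved) break
    }
    val <- structure_value(root, G, Xm, idx, min_leaf, cp_total)
    if (is.null(best) || val < best$val - EPS_OBJ) {
      best <- list(node = root, val = val)
    }
  }
  if (is.null(best) || min(grown_val) < best$val - EPS_OBJ) {
    # refinement never worsens the best grown tree, but guard anyway
    r0 <- which.min(grown_val)
    if (is.null(best) || grown_val[r0] < best$val - EPS_OBJ) {
      best <- list(node = grown[[r0]], val = grown_val[r0])
    }
  }
  tree <- policy_tree(best$node, cp = cp,
                      meta = list(objective = best$val / n, n_train = n,
                                  depth_limit = depth, min_leaf = min_leaf,
                                  seed = seed, n_restarts = n_restarts))
  annotate_tree(tree, rewards, as.data.frame(Xm))
}

#' Exact policy tree by exhaustive enumeration (depth <= 2)
#'
#' Enumerates every axis-aligned split pair (thresholds at midpoints of
#' adjacent observed values) and every leaf-arm assignment; the exact
#' reference the local search is checked against. Guarded to small inputs.
#'
#' @inheritParams train_policy_tree
#' @param depth 0, 1 or 2.
#' @param min_leaf minimum rows per leaf (default 1).
#' @return a `policy_tree` attaining the exact minimum of
#'   `mean_i Gamma_i(pi(x_i))` among trees of the given depth.
#' @export
exhaustive_policy_tree <- function(rewards, data,
                                   features = modeling_features(data),
                                   depth, min_leaf = 1) {
  G <- check_alignment(rewards, data)
  n <- nrow(G)
  if (n > 2000L) stopf("exhaustive search is guarded to n <= 2000 rows (got %d)", n)
  if (depth > 2L) stopf("exhaustive search is guarded to depth <= 2 (got %d)", depth)
  Xm <- prepare_X(data, features)
  best <- exact_subtree(G, Xm, seq_len(n), as.integer(depth), min_leaf,
                        cp_total = 0, full = TRUE)
  tree <- policy_tree(best$node, cp = 0,
                      meta = list(objective = best$val / n, n_train = n,
                                  exhaustive = TRUE, min_leaf = min_leaf))
  annotate_tree(tree, rewards, as.data.frame(Xm))
}

#' Grid search over depth and complexity penalty
#'
#' Fits a tree on the training rewards for every (depth, cp) combination,
#' scores each on the validation rewards (mean validation reward of its
#' prescriptions), picks the cell with the smallest validation value —
#' breaking ties toward the smallest depth, then the smallest cp — and
#' refits the winning settings on the pooled training + validation rows.
#'
#' @param rewards_train,rewards_val disjoint `reward_matrix` objects.
#' @param data_train,data_val aligned covariate data.frames.
#' @param features split features (default from `data_train`).
#' @param depth_grid candidate depths (default 3:8).
#' @param cp_grid candidate complexity penalties
#'   (default `c(0, 1e-4, 1e-3, 1e-2)`).
#' @param min_leaf minimum rows per leaf (default 20).
#' @param seed RNG seed.
#' @param n_restarts restarts per fit (default 2).
#' @return list with `tree` (the refit winner), `grid` (data.frame of
#'   depth, cp, train objective, validation value), and `winner` (chosen
#'   row of the grid).
#' @export
tune_policy_tree <- function(rewards_train, data_train, rewards_val, data_val,
                             features = modeling_features(data_train),
                             depth_grid = 3:8,
                             cp_grid = c(0, 1e-4, 1e-3, 1e-2),
                             min_leaf = 20, seed = 1L, n_restarts = 2L) {
  if (!length(depth_grid) || !length(cp_grid)) {
    stopf("depth_grid and cp_grid must be non-empty")
  }
  Gv <- check_alignment(rewards_val, data_val)
  grid <- expand.grid(depth = sort(depth_grid), cp = sort(cp_grid))
  grid$train_objective <- NA_real_
  grid$val_value <- NA_real_
  trees <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    tr <- suppressWarnings(train_policy_tree(
      rewards_train, data_train, features = features,
      depth = grid$depth[k], min_leaf = min_leaf, cp = grid$cp[k],
      seed = derive_seed(seed, k), n_restarts = n_restarts))
    arm <- as.integer(prescribe(tr, data_val))
    grid$val_value[k] <- mean(Gv[cbind(seq_len(nrow(Gv)), arm)])
    grid$train_objective[k] <- tr$meta$objective
    trees[[k]] <- tr
  }
  # tie-break: smallest validation value, then smallest depth, then smallest cp
  tol <- 1e-12
  vmin <- min(grid$val_value)
  cand <- which(grid$val_value <= vmin + tol)
  cand <- cand[order(grid$depth[cand], grid$cp[cand])]
  win <- cand[1L]
  pooled_rewards <- structure(rbind(unclass_rewards(rewards_train),
                                    unclass_rewards(rewards_val)),
                              class = c("reward_matrix", "matrix"))
  pooled_data <- rbind(data_train[features], data_val[features])
  refit <- suppressWarnings(train_policy_tree(
    pooled_rewards, pooled_data, features = features,
    depth = grid$depth[win], min_leaf = min_leaf, cp = grid$cp[win],
    seed = derive_seed(seed, 0L), n_restarts = max(n_restarts, 3L)))
  list(tree = refit, grid = grid, winner = grid[win, , drop = FALSE])
}
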