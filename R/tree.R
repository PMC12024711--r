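#' Axis-aligned policy trees
#'
#' A policy tree is a binary decision tree over patient covariates whose
#' leaves prescribe one of the three treatment arms. Split semantics are
#' fixed package-wide: rows with feature value strictly below the threshold
#' follow the left branch, rows at or above it follow the right branch.
#' Leaves carry the number of training rows that reached them and a
#' `strength` value: the within-leaf mean reward of the second-best arm
#' minus that of the prescribed (best) arm — larger means a more confident
#' prescription.
#'
#' @name policy-tree
NULL

tree_leaf <- function(arm, n_train = NA_integer_, strength = NA_real_) {
  arm <- match.arg(arm, TREATMENTS)
  list(type = "leaf", arm = arm,
       n_train = as.integer(n_train), strength = as.numeric(strength))
}

tree_split <- function(feature, threshold, left, right, missing = "left") {
  stopifnot(is.character(feature), length(feature) == 1L,
            is.finite(threshold), missing %in% c("left", "right"))
  list(type = "split", feature = feature, threshold = as.numeric(threshold),
       missing = missing, left = left, right = right)
}

node_depth <- function(node) {
  if (node$type == "leaf") 0L else
    1L + max(node_depth(node$left), node_depth(node$right))
}

node_count_splits <- function(node) {
  if (node$type == "leaf") 0L else
    1L + node_count_splits(node$left) + node_count_splits(node$right)
}

#' Construct a policy tree object
#'
#' Usually produced by [train_policy_tree()], [exhaustive_policy_tree()] or
#' [tune_policy_tree()]; exported so hand-built trees (e.g. published
#' decision rules) can be evaluated with the same machinery.
#'
#' @param root nested node list built from internal split/leaf nodes; see
#'   [hand_tree()] for a convenient constructor.
#' @param cp complexity penalty used at fit time (0 for hand-built trees).
#' @param meta free-form provenance list (seed, objective, settings).
#' @return an object of class `policy_tree`.
#' @export
policy_tree <- function(root, cp = 0, meta = list()) {
  structure(
    list(node = root, depth = node_depth(root),
         n_splits = node_count_splits(root), cp = as.numeric(cp),
         meta = meta),
    class = "policy_tree"
  )
}

#' Build a policy tree from a nested specification
#'
#' `spec` is either a single arm name (a leaf) or a list
#' `list(feature =, threshold =, left =, right =)` whose children are again
#' such specifications. Example mirroring a published splenic-trauma rule:
#' split on shock index, then on early pRBC transfusion.
#'
#' @param spec nested list or arm name.
#' @return a `policy_tree`.
#' @export
hand_tree <- function(spec) {
  build <- function(s) {
    if (is.character(s) && length(s) == 1L) return(tree_leaf(s))
    stopifnot(is.list(s), all(c("feature", "threshold", "left", "right") %in% names(s)))
    tree_split(s$feature, s$threshold, build(s$left), build(s$right),
               missing = s$missing %||% "left")
  }
  policy_tree(build(spec))
}

tree_features <- function(tree) {
  feats <- character(0)
  walk <- function(node) {
    if (node$type == "split") {
      feats <<- c(feats, node$feature)
      walk(node$left); walk(node$right)
    }
  }
  walk(tree$node)
  unique(feats)
}

# Route rows of `data` through the tree; returns integer leaf ids (preorder)
# and, via attribute, the prescribed arm per row.
route_rows <- function(tree, data) {
  missing_feats <- setdiff(tree_features(tree), names(data))
  if (length(missing_feats)) {
    stopf("data is missing split feature(s): %s",
          paste(missing_feats, collapse = ", "))
  }
  n <- nrow(data)
  leaf_id <- integer(n)
  arm <- character(n)
  next_id <- 0L
  recurse <- function(node, idx) {
    if (node$type == "leaf") {
      next_id <<- next_id + 1L
      leaf_id[idx] <<- next_id
      arm[idx] <<- node$arm
      return(invisible(NULL))
    }
    next_id <<- next_id + 1L  # internal nodes consume an id too (preorder)
    x <- data[[node$feature]][idx]
    na <- is.na(x)
    go_left <- !na & x < node$threshold
    if (node$missing == "left") go_left <- go_left | na
    recurse(node$left, idx[go_left])
    recurse(node$right, idx[!go_left])
  }
  if (n > 0) recurse(tree$node, seq_len(n)) else recurse(tree$node, integer(0))
  structure(leaf_id, arm = arm)
}

#' Prescribe treatments for new rows
#'
#' Deterministic threshold descent: at each split, rows with the feature
#' strictly below the threshold go left, rows at or above go right; rows with
#' a missing value follow the branch recorded as the majority training branch
#' at fit time (default left).
#'
#' @param tree a `policy_tree`.
#' @param rows data.frame containing every split feature.
#' @return factor of prescribed arms with levels `TREATMENTS`.
#' @export
prescribe <- function(tree, rows) {
  stopifnot(inherits(tree, "policy_tree"))
  r <- route_rows(tree, rows)
  factor(attr(r, "arm"), levels = TREATMENTS)
}

#' Enumerate the leaves of a policy tree
#'
#' @param tree a `policy_tree`.
#' @return data.frame with one row per leaf: preorder `leaf_id`, `path`
#'   (human-readable rule), prescribed `arm`, `n_train`, `strength`.
#' @export
tree_leaves <- function(tree) {
  rows <- list()
  next_id <- 0L
  recurse <- function(node, path) {
    next_id <<- next_id + 1L
    id <- next_id
    if (node$type == "leaf") {
      rows[[length(rows) + 1L]] <<- data.frame(
        leaf_id = id, path = if (nzchar(path)) path else "(root)",
        arm = node$arm, n_train = node$n_train, strength = node$strength,
        stringsAsFactors = FALSE)
      return(invisible(NULL))
    }
    sep <- if (nzchar(path)) " & " else ""
    recurse(node$left, paste0(path, sep, node$feature, " < ", signif(node$threshold, 6)))
    recurse(node$right, paste0(path, sep, node$feature, " >= ", signif(node$threshold, 6)))
  }
  recurse(tree$node, "")
  do.call(rbind, rows)
}

#' @export
print.policy_tree <- function(x, ...) {
  cat(sprintf("Policy tree: depth %d, %d split(s), cp = %g\n",
              x$depth, x$n_splits, x$cp))
  recurse <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      cat(sprintf("%s=> %s  (n = %s, strength = %s)\n", pad, node$arm,
                  ifelse(is.na(node$n_train), "?", node$n_train),
                  ifelse(is.na(node$strength), "?", signif(node$strength, 3))))
    } else {
      cat(sprintf("%s%s < %s ?\n", pad, node$feature, signif(node$threshold, 6)))
      recurse(node$left, indent + 1L)
      recurse(node$right, indent + 1L)
    }
  }
  recurse(x$node, 0L)
  invisible(x)
}

#' Serialize / restore policy trees as JSON
#'
#' The JSON round-trip preserves prescriptions on any input exactly; fit
#' metadata travels in a `meta` block.
#'
#' @param tree a `policy_tree`.
#' @return `policy_tree_json()` returns a JSON string;
#'   `policy_tree_from_json()` returns a `policy_tree`.
#' @export
policy_tree_json <- function(tree) {
  stopifnot(inherits(tree, "policy_tree"))
  strip <- function(node) {
    if (node$type == "leaf") {
      list(type = "leaf", arm = node$arm, n_train = node$n_train,
           strength = node$strength)
    } else {
      list(type = "split", feature = node$feature, threshold = node$threshold,
           missing = node$missing, left = strip(node$left),
           right = strip(node$right))
    }
  }
  jsonlite::toJSON(
    list(format = "traumapolicy-tree-1", cp = tree$cp, meta = tree$meta,
         root = strip(tree$node)),
    auto_unbox = TRUE, digits = NA, null = "null", na = "null")
}

#' @rdname policy_tree_json
#' @param json JSON string or file path produced by [write_policy_tree()].
#' @export
policy_tree_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  if (!identical(obj$format, "traumapolicy-tree-1")) {
    stopf("not a traumapolicy tree JSON payload")
  }
  build <- function(node) {
    if (identical(node$type, "leaf")) {
      tree_leaf(node$arm, node$n_train %||% NA_integer_,
                node$strength %||% NA_real_)
    } else {
      tree_split(node$feature, node$threshold, build(node$left),
                 build(node$right), missing = node$missing %||% "left")
    }
  }
  policy_tree(build(obj$root), cp = obj$cp %||% 0,
              meta = obj$meta %||% list())
}

#' @rdname policy_tree_json
#' @param path file path.
#' @export
write_policy_tree <- function(tree, path) {
  writeLines(policy_tree_json(tree), path)
  invisible(path)
}

#' @rdname policy_tree_json
#' @export
read_policy_tree <- function(path) {
  policy_tree_from_json(paste(readLines(path, warn = FALSE), collapse = "\n"))
}

ARM_BASE_COLORS <- c(OBS = "#2c7fb8", AE = "#31a354", SPLENECTOMY = "#de2d26")

#' Export a policy tree as Graphviz DOT
#'
#' Leaves are filled with the arm's color; fill intensity is proportional to
#' the leaf's prescription strength relative to the strongest leaf, echoing
#' the convention that darker leaves mean a larger gap between the best and
#' second-best arm.
#'
#' @param tree a `policy_tree`.
#' @param path output `.dot` path.
#' @return `path`, invisibly.
#' @export
write_tree_dot <- function(tree, path) {
  strengths <- tree_leaves(tree)$strength
  smax <- suppressWarnings(max(strengths, na.rm = TRUE))
  if (!is.finite(smax) || smax <= 0) smax <- 1
  lines <- c("digraph policy_tree {", "  node [shape=box, style=filled];")
  next_id <- 0L
  recurse <- function(node) {
    next_id <<- next_id + 1L
    id <- next_id
    if (node$type == "leaf") {
      alpha <- if (is.na(node$strength)) 0.5 else
        0.25 + 0.75 * min(node$strength / smax, 1)
      hex <- sprintf("%s%02x", ARM_BASE_COLORS[[node$arm]],
                     as.integer(round(alpha * 255)))
      lab <- sprintf("Prescribe %s\\nN = %s", node$arm,
                     ifelse(is.na(node$n_train), "?", node$n_train))
      lines <<- c(lines, sprintf('  n%d [label="%s", fillcolor="%s"];',
                                 id, lab, hex))
      return(id)
    }
    lines <<- c(lines, sprintf(
      '  n%d [label="%s < %s ?", fillcolor="#f0f0f0"];',
      id, node$feature, signif(node$threshold, 6)))
    lid <- recurse(node$left)
    rid <- recurse(node$right)
    lines <<- c(lines,
                sprintf('  n%d -> n%d [label="yes"];', id, lid),
                sprintf('  n%d -> n%d [label="no"];', id, rid))
    id
  }
  recurse(tree$node)
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

# Recompute per-leaf n_train / strength and per-split majority branch for
# missing-value routing, using the training rewards and features.
annotate_tree <- function(tree, rewards, data) {
  G <- unclass_rewards(rewards)
  recurse <- function(node, idx) {
    if (node$type == "leaf") {
      node$n_train <- length(idx)
      if (length(idx)) {
        mu <- colMeans(G[idx, , drop = FALSE])
        o <- order(mu)
        node$arm <- TREATMENTS[o[1L]]
        node$strength <- unname(mu[o[2L]] - mu[o[1L]])
      }
      return(node)
    }
    x <- data[[node$feature]][idx]
    go_left <- !is.na(x) & x < node$threshold
    node$missing <- if (sum(go_left) >= sum(!go_left)) "left" else "right"
    node$left <- recurse(node$left, idx[go_left])
    node$right <- recurse(node$right, idx[!go_left])
    node
  }
  tree$node <- recurse(tree$node, seq_len(nrow(data)))
  tree
}
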