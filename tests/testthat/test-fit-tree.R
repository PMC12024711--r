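test_that("a uniformly dominant arm collapses to a single leaf", {
  set.seed(1)
  n <- 200
  g <- as_rewards(cbind(runif(n, 0.3, 0.4), runif(n, 0, 0.1),
                        runif(n, 0.5, 0.6)))
  df <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  for (cp in c(0, 1e-3)) {
    tr <- train_policy_tree(g, df, depth = 3, min_leaf = 5, cp = cp,
                            seed = 1, n_restarts = 2)
    expect_equal(tr$n_splits, 0)
    expect_equal(as.character(prescribe(tr, df[1, , drop = FALSE])), "AE")
  }
})

test_that("depth-1 objective equals a hand enumeration on 10 rows", {
  set.seed(7)
  g <- matrix(runif(30), 10, 3)
  x <- rep(c(0, 1), 5)
  df <- data.frame(x = x)

  # brute force: no-split (3 arm choices) and the single binary split
  # (3 x 3 leaf-arm choices)
  best <- min(colMeans(g))
  for (a in 1:3) for (b in 1:3) {
    best <- min(best, mean(c(g[x == 0, a], g[x == 1, b])))
  }

  tr <- train_policy_tree(as_rewards(g), df, depth = 1, min_leaf = 1, cp = 0,
                          seed = 1, n_restarts = 1)
  arm <- as.integer(prescribe(tr, df))
  expect_equal(mean(g[cbind(1:10, arm)]), best, tolerance = 1e-12)
  expect_equal(tr$meta$objective, best, tolerance = 1e-12)
})

test_that("exhaustive depth 0 returns the best constant arm", {
  set.seed(2)
  g <- as_rewards(matrix(runif(60), 20, 3))
  df <- data.frame(x = rnorm(20))
  tr <- exhaustive_policy_tree(g, df, depth = 0)
  expect_equal(as.character(prescribe(tr, df[1, , drop = FALSE])),
               TREATMENTS[which.min(colMeans(unclass(g)))])
})

test_that("exhaustive optimum never exceeds the local-search objective", {
  for (s in 1:5) {
    set.seed(s)
    n <- 200
    df <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rbinom(n, 1, 0.4))
    g <- as_rewards(matrix(runif(3 * n), n, 3))
    ex <- exhaustive_policy_tree(g, df, depth = 1, min_leaf = 5)
    ls <- train_policy_tree(g, df, depth = 1, min_leaf = 5, cp = 0,
                            seed = s, n_restarts = 2)
    expect_lte(ex$meta$objective, ls$meta$objective + 1e-9)
  }
})

test_that("local search attains the exhaustive depth-2 optimum", {
  hits <- 0
  for (s in 1:6) {
    set.seed(100 + s)
    n <- 300
    df <- data.frame(x1 = rnorm(n), x2 = runif(n), x3 = sample(1:5, n, TRUE))
    base <- runif(n, 0, 0.3)
    g <- as_rewards(cbind(base + 0.1 * (df$x1 > 0),
                          base + 0.1 * (df$x2 > 0.5),
                          base + runif(n, 0, 0.2)))
    ex <- exhaustive_policy_tree(g, df, depth = 2, min_leaf = 10)
    ls <- train_policy_tree(g, df, depth = 2, min_leaf = 10, cp = 0,
                            seed = s, n_restarts = 5)
    if (abs(ex$meta$objective - ls$meta$objective) < 1e-9) hits <- hits + 1
  }
  expect_gte(hits, 5)
})

test_that("exhaustive search guards its problem size", {
  g <- as_rewards(matrix(runif(9000), 3000, 3))
  df <- data.frame(x = rnorm(3000))
  expect_error(exhaustive_policy_tree(g, df, depth = 1), "2000")
  expect_error(exhaustive_policy_tree(g[1:100, ], df[1:100, , drop = FALSE],
                                      depth = 3), "depth")
})

test_that("min_leaf is respected and infeasible depth is reduced", {
  set.seed(3)
  n <- 100
  df <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  g <- as_rewards(matrix(runif(3 * n), n, 3))
  expect_warning(
    tr <- train_policy_tree(g, df, depth = 6, min_leaf = 20, cp = 0,
                            seed = 1, n_restarts = 2),
    "reducing depth")
  leaves <- tree_leaves(tr)
  expect_true(all(leaves$n_train >= 20))
  expect_lte(tr$depth, floor(log2(n / 20)))
})

test_that("refinement never worsens the grown-and-pruned objective", {
  for (s in 1:3) {
    set.seed(200 + s)
    n <- 400
    df <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = runif(n))
    g0 <- matrix(runif(3 * n), n, 3)
    g <- as_rewards(g0)
    tr <- train_policy_tree(g, df, depth = 3, min_leaf = 10, cp = 1e-3,
                            seed = s, n_restarts = 1)
    Xm <- traumapolicy:::prepare_X(df, c("x1", "x2", "x3"))
    root <- traumapolicy:::grow_greedy(g0, Xm, seq_len(n), 3L, 10L)
    pruned <- traumapolicy:::prune_cp(root, g0, Xm, seq_len(n), 1e-3 * n)
    greedy_obj <- (pruned$val) / n
    final_obj <- tr$meta$objective
    expect_lte(final_obj, greedy_obj + 1e-9)
  }
})

test_that("fixed seed gives an identical tree JSON", {
  set.seed(4)
  n <- 500
  df <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  g <- as_rewards(matrix(runif(3 * n), n, 3))
  t1 <- train_policy_tree(g, df, depth = 3, min_leaf = 10, seed = 9,
                          n_restarts = 4)
  t2 <- train_policy_tree(g, df, depth = 3, min_leaf = 10, seed = 9,
                          n_restarts = 4)
  expect_identical(as.character(policy_tree_json(t1)),
                   as.character(policy_tree_json(t2)))
})

test_that("grid tuning bookkeeping, tie-breaks and errors behave", {
  set.seed(5)
  n <- 300
  df <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  # dominant arm: every grid cell ties at the same validation value
  g <- as_rewards(cbind(rep(0, n), rep(0.5, n), rep(0.9, n)))
  halves_idx <- seq_len(150)
  fit <- tune_policy_tree(g[halves_idx, ], df[halves_idx, ],
                          g[-halves_idx, ], df[-halves_idx, ],
                          depth_grid = c(3, 4), cp_grid = c(0, 1e-3),
                          min_leaf = 10, seed = 1, n_restarts = 1)
  expect_equal(nrow(fit$grid), 4)
  expect_equal(fit$winner$depth, 3)
  expect_equal(fit$winner$cp, 0)
  expect_equal(as.character(prescribe(fit$tree, df[1, , drop = FALSE])),
               "OBS")
  expect_error(
    tune_policy_tree(g[halves_idx, ], df[halves_idx, ],
                     g[-halves_idx, ], df[-halves_idx, ],
                     depth_grid = integer(0)),
    "non-empty")
})

test_that("tuning recovers planted split features on oracle rewards", {
  spec <- default_preset()
  co <- generate_cohort(spec, n = 6000, seed = 23)
  g <- oracle_rewards(co)
  idx <- seq_len(3000)
  fit <- tune_policy_tree(g[idx, ], co[idx, ], g[-idx, ], co[-idx, ],
                          depth_grid = c(2, 3), cp_grid = c(1e-4, 1e-3),
                          min_leaf = 20, seed = 2, n_restarts = 2)
  feats <- traumapolicy:::tree_features(fit$tree)
  expect_true(all(c("shock_index", "spleen_grade") %in% feats) ||
                all(c("shock_index", "prbc_1h") %in% feats))
})
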