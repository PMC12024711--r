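test_that("AIPW score matches the hand-evaluated formula", {
  cohort <- data.frame(x1 = 0, treatment = factor("AE", levels = TREATMENTS),
                       death = 1L)
  nu <- manual_nuisances(mu = matrix(0.5, 1, 3), e = matrix(0.5, 1, 3))
  g <- doubly_robust_rewards(cohort, nu)
  expect_equal(unname(g[1, "AE"]), 0.5 + (1 - 0.5) / 0.5)  # 1.5
  expect_equal(unname(g[1, "OBS"]), 0.5)
  expect_equal(unname(g[1, "SPLENECTOMY"]), 0.5)
})

test_that("a perfect outcome model kills the correction term", {
  co <- independent_cohort(200, seed = 3)
  mu <- matrix(0.5, 200, 3)
  mu[cbind(1:200, as.integer(co$treatment))] <- co$death
  nu <- manual_nuisances(mu = mu, e = matrix(1 / 3, 200, 3))
  g <- doubly_robust_rewards(co, nu)
  expect_equal(unname(g[cbind(1:200, as.integer(co$treatment))]),
               as.numeric(co$death))
})

test_that("oracle nuisances recover the true all-in-one-arm mortality", {
  spec <- default_preset()
  n <- 20000
  co <- generate_cohort(spec, n = n, seed = 10)
  g <- doubly_robust_rewards(co, oracle_nuisances(co))
  truth <- colMeans(cbind(co$p_obs, co$p_ae, co$p_splen))
  for (j in 1:3) {
    se <- stats::sd(g[, j]) / sqrt(n)
    expect_lt(abs(mean(g[, j]) - truth[j]), 2 * se)
  }
})

test_that("reward magnitudes are bounded by the propensity clip floor", {
  spec <- default_preset()
  co <- generate_cohort(spec, n = 5000, seed = 12)
  nu <- oracle_nuisances(co, clip = c(0.01, 0.99))
  g <- doubly_robust_rewards(co, nu)
  expect_true(all(abs(g - nu$mu) <= 1 / 0.01 + 1e-9))
  expect_true(all(is.finite(g)))
})

test_that("cross-fitted propensities recover marginals under independence", {
  probs <- c(0.5, 0.3, 0.2)
  n <- 10000
  co <- independent_cohort(n, probs = probs, seed = 7)
  nu <- fit_nuisances(co, features = c("x1", "x2"), k_folds = 5, seed = 2,
                      model_family = "logistic")
  e_mean <- colMeans(nu$e)
  se <- sqrt(probs * (1 - probs) / n)
  expect_true(all(abs(e_mean - probs) < 3 * se + 0.01))
  # out-of-fold bookkeeping: every row has predictions and a fold id
  expect_false(anyNA(nu$mu))
  expect_false(anyNA(nu$e))
  expect_true(all(nu$folds %in% 1:5))
})

test_that("well-specified logistic outcome model tracks the oracle risks", {
  spec <- default_preset()
  n <- 20000
  co <- generate_cohort(spec, n = n, seed = 15)
  nu <- fit_nuisances(co, k_folds = 5, seed = 3, model_family = "logistic")
  truth <- cbind(co$p_obs, co$p_ae, co$p_splen)
  obs <- cbind(seq_len(n), as.integer(co$treatment))
  # accuracy is assessed where each arm's model has support: observed rows
  expect_lt(mean(abs(nu$mu[obs] - truth[obs])), 0.05)
})

test_that("degenerate arms are rejected with a named error", {
  co <- independent_cohort(60, seed = 4)
  co$treatment <- factor(rep(c("OBS", "AE"), c(57, 3)), levels = TREATMENTS)
  expect_error(fit_nuisances(co, features = "x1", k_folds = 2),
               "SPLENECTOMY")
  co$treatment <- factor(rep(c("OBS", "AE", "SPLENECTOMY"), c(54, 3, 3)),
                         levels = TREATMENTS)
  expect_error(fit_nuisances(co, features = "x1", k_folds = 2), "sparse")
})

test_that("non-numeric features are a schema error", {
  co <- independent_cohort(100, seed = 5)
  co$label <- sample(letters, 100, replace = TRUE)
  expect_error(fit_nuisances(co, features = c("x1", "label")), "label")
})

test_that("misaligned nuisances are rejected", {
  co <- independent_cohort(50, seed = 6)
  nu <- manual_nuisances(mu = matrix(0.5, 49, 3), e = matrix(1 / 3, 49, 3))
  expect_error(doubly_robust_rewards(co, nu), "align")
})

test_that("reward matrices round-trip through CSV", {
  co <- independent_cohort(30, seed = 8)
  nu <- manual_nuisances(mu = matrix(runif(90), 30, 3),
                         e = matrix(1 / 3, 30, 3))
  g <- doubly_robust_rewards(co, nu)
  path <- tempfile(fileext = ".csv")
  write_rewards(g, path)
  g2 <- read_rewards(path)
  expect_equal(unclass(g2)[, ], unclass(g)[, ], tolerance = 1e-12)
  expect_equal(attr(g2, "provenance")$n_clipped, 0)
})

test_that("doubly-robust value is consistent when either nuisance is wrong", {
  spec <- default_preset()
  n <- 20000
  co <- generate_cohort(spec, n = n, seed = 18)
  truth_mat <- cbind(co$p_obs, co$p_ae, co$p_splen)
  policy <- spec$planted_policy
  arm <- as.integer(prescribe(policy, co))
  truth <- mean(truth_mat[cbind(seq_len(n), arm)])

  # (a) oracle outcome model, badly misspecified propensities (marginal mix)
  marg <- as.numeric(table(co$treatment)) / n
  nu_a <- manual_nuisances(mu = truth_mat,
                           e = matrix(marg, n, 3, byrow = TRUE))
  v_a <- policy_value_dr(policy, doubly_robust_rewards(co, nu_a), co)
  expect_lt(abs(as.numeric(v_a) - truth), 2 * attr(v_a, "se"))

  # (b) oracle propensities, constant (wrong) outcome model
  nu_b <- manual_nuisances(mu = matrix(mean(co$death), n, 3),
                           e = cbind(co$e_obs, co$e_ae, co$e_splen))
  v_b <- policy_value_dr(policy, doubly_robust_rewards(co, nu_b), co)
  expect_lt(abs(as.numeric(v_b) - truth), 2 * attr(v_b, "se"))
})

test_that("stratified split halves exactly and preserves arm frequencies", {
  co <- independent_cohort(100, seed = 9)
  halves <- split_cohort(co, 0.5, seed = 1)
  expect_equal(nrow(halves$train), 50)
  expect_equal(nrow(halves$test), 50)
  expect_equal(sort(c(rownames(halves$train), rownames(halves$test))),
               sort(rownames(co)))

  halves2 <- split_cohort(co, 0.5, seed = 1)
  expect_identical(rownames(halves$train), rownames(halves2$train))

  big <- independent_cohort(20000, seed = 10)
  h <- split_cohort(big, 0.5, seed = 2)
  f_tr <- as.numeric(table(h$train$treatment)) / nrow(h$train)
  f_te <- as.numeric(table(h$test$treatment)) / nrow(h$test)
  expect_true(all(abs(f_tr - f_te) <= 0.02))
})

test_that("singleton (arm, outcome) cells go to training with a warning", {
  co <- independent_cohort(61, seed = 11)
  co$treatment <- factor(rep(c("OBS", "AE", "SPLENECTOMY"), c(30, 30, 1)),
                         levels = TREATMENTS)
  co$death <- c(rbinom(60, 1, 0.5), 1L)
  expect_warning(halves <- split_cohort(co, 0.5, seed = 3), "one member")
  expect_true("SPLENECTOMY" %in% halves$train$treatment)
  expect_false("SPLENECTOMY" %in% halves$test$treatment)
})

test_that("invalid split fractions are rejected", {
  co <- independent_cohort(20, seed = 12)
  expect_error(split_cohort(co, 0), "between")
  expect_error(split_cohort(co, 1), "between")
})
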