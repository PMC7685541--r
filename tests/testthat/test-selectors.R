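# Selector behaviour on small constructed problems. Forest sizes are kept
# small; the assertions are about selection decisions, not model quality.

test_that("Boruta confirms a perfect predictor among noise and is deterministic", {
  set.seed(10)
  n <- 60
  y <- rnorm(n)
  X <- cbind(leak = y, matrix(rnorm(n * 50), n, 50))
  colnames(X) <- c("leak", paste0("N", 1:50))
  spec <- forest_spec("regression", n_trees = 100, seed = 7)
  out <- boruta_select(X, y, spec, alpha = 0.05, max_runs = 50)
  expect_s3_class(out, "selection_outcome")
  expect_true("leak" %in% out$selected)
  expect_equal(unname(out$decision["leak"]), "confirmed")
  expect_true(all(out$decision %in% c("confirmed", "rejected", "tentative")))
  # fixed seed -> identical outcome
  out2 <- boruta_select(X, y, spec, alpha = 0.05, max_runs = 50)
  expect_identical(out$selected, out2$selected)
  expect_identical(out$decision, out2$decision)
  expect_error(boruta_select(X, y, spec, max_runs = 0), "max_runs")
})

test_that("Boruta on pure noise confirms (almost) nothing", {
  nz <- noise_regression(n = 50, p = 100, seed = 8)
  out <- boruta_select(nz$X, nz$y,
                       forest_spec("regression", n_trees = 100, seed = 8),
                       alpha = 0.05, max_runs = 40)
  # expected confirmed count is ~0; alpha * p = 5 bounds the type-I behaviour
  expect_lte(length(out$selected), 5)
})

test_that("permutation selection: a perfect predictor attains the minimal p-value", {
  set.seed(12)
  n <- 50
  y <- rnorm(n)
  X <- cbind(leak = y, matrix(rnorm(n * 4), n, 4))
  colnames(X) <- c("leak", paste0("N", 1:4))
  out <- permutation_select(X, y, forest_spec("regression", n_trees = 100, seed = 9),
                            n_perm = 99, alpha = 0.05)
  expect_equal(unname(out$p_value["leak"]), 1 / 100)
  expect_true("leak" %in% out$selected)
  expect_true(all(out$p_value >= 0 & out$p_value <= 1))
})

test_that("permutation p-values are approximately uniform under the null", {
  nz <- noise_regression(n = 40, p = 30, seed = 13)
  out <- permutation_select(nz$X, nz$y,
                            forest_spec("regression", n_trees = 80, seed = 13),
                            n_perm = 60, alpha = 0.05)
  ks <- suppressWarnings(ks.test(out$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Benjamini-Hochberg selection is a subset of the raw selection on shared nulls", {
  d <- small_uniform_sim(n_obs = 100, p_total = 40, seed = 14)
  spec <- forest_spec("regression", n_trees = 80, seed = 14)
  raw <- permutation_select(d$X, d$y, spec, n_perm = 40, correction = "none")
  corr <- permutation_select(d$X, d$y, spec, n_perm = 40,
                             correction = "benjamini_hochberg")
  # same seed -> shared null draws -> identical raw p-values
  expect_identical(raw$p_value, corr$diagnostics$p_raw)
  expect_true(all(corr$selected %in% raw$selected))
  expect_warning(permutation_select(d$X, d$y, spec, n_perm = 25, alpha = 0.01),
                 "too small")
  expect_error(permutation_select(d$X, d$y, spec, n_perm = 10), "n_perm")
})

test_that("model-level permutation test flags strong signal at the attainable floor", {
  d <- small_uniform_sim(n_obs = 100, p_total = 20, seed = 15)
  res <- model_permutation_test(d$X, d$y,
                                forest_spec("regression", n_trees = 80, seed = 15),
                                n_perm = 24)
  expect_equal(res$p_value, 1 / 25)
  expect_equal(res$min_attainable_p, 1 / 25)
  expect_error(model_permutation_test(d$X, d$y,
                                      forest_spec("regression"), n_perm = 19),
               "n_perm")
})

test_that("model-level permutation p-value is unremarkable when the outcome is pre-shuffled", {
  d <- small_uniform_sim(n_obs = 80, p_total = 20, seed = 16)
  set.seed(16)
  y_shuffled <- sample(d$y)
  res <- model_permutation_test(d$X, y_shuffled,
                                forest_spec("regression", n_trees = 60, seed = 16),
                                n_perm = 39)
  expect_gt(res$p_value, 0.05)
})

test_that("elimination schedule follows the ceiling drop rule", {
  traj <- powerforest:::rfe_trajectory(100, 0.2)
  expect_equal(traj[1:4], c(100, 80, 64, 51))
  expect_equal(traj[length(traj)], 1)
  expect_true(all(diff(traj) < 0))
  # closed-form oracle: independent re-derivation of the same rule
  oracle <- function(p, f) {
    out <- p
    while (p > 1) { p <- max(p - ceiling(f * p), 1); out <- c(out, p) }
    out
  }
  expect_equal(traj, oracle(100, 0.2))
  expect_equal(powerforest:::rfe_trajectory(7, 0.5), oracle(7, 0.5))
})

test_that("RFE keeps a perfect predictor and records its error trajectory", {
  set.seed(17)
  n <- 60
  y <- rnorm(n)
  X <- cbind(leak = y, matrix(rnorm(n * 30), n, 30))
  colnames(X) <- c("leak", paste0("N", 1:30))
  spec <- forest_spec("regression", n_trees = 100, seed = 17)
  out <- rfe_select(X, y, spec)
  expect_true("leak" %in% out$selected)
  expect_equal(out$diagnostics$n_vars,
               powerforest:::rfe_trajectory(31, 0.2))
  expect_length(out$diagnostics$error, length(out$diagnostics$n_vars))
  # always selects at least one variable, even on pure noise
  nz <- noise_regression(n = 40, p = 20, seed = 17)
  out_nz <- rfe_select(nz$X, nz$y, spec)
  expect_gte(length(out_nz$selected), 1)
  expect_error(rfe_select(X, y, spec, drop_fraction = 1.2), "drop_fraction")
})

test_that("selector dispatch maps method names onto the right algorithms", {
  d <- small_uniform_sim(n_obs = 80, p_total = 20, seed = 18)
  spec <- forest_spec("regression", n_trees = 60, seed = 18)
  out <- run_selector("rfe", d$X, d$y, spec)
  expect_equal(out$method, "rfe")
  out <- run_selector("perm_corrected", d$X, d$y, spec,
                      args = list(n_perm = 25))
  expect_equal(out$method, "perm_corrected")
})
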