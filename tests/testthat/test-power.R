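test_that("log-normal fit shifts non-positive variables and only those", {
  X <- cbind(a = c(1, 2, 3, 4), b = c(-2, 0, 1, 2), c = c(0.5, 0.6, 0.7, 0.8))
  m <- fit_lognormal(X)
  expect_equal(unname(m$shift[c("a", "c")]), c(0, 0))
  expect_gt(m$shift[["b"]], 2)
  expect_false(m$psd_repaired)
  expect_error(fit_lognormal(X[1:2, ]), "3 samples")
  # constant variable: flagged, retained
  Xc <- cbind(a = c(1, 2, 3, 4), k = rep(2, 4))
  expect_true(fit_lognormal(Xc)$zero_variance[["k"]])
})

test_that("synthesis round trip preserves the input Pearson correlations", {
  X <- lognormal_fixture(n = 5000, seed = 42)
  m <- fit_lognormal(X)
  S <- synthesize(m, 100000, seed = 1)
  expect_equal(dim(S), c(100000L, 4L))
  expect_true(max(abs(cor(S) - cor(X))) < 0.02)
})

test_that("synthesis is deterministic given a seed and handles degenerate structure", {
  X <- lognormal_fixture(n = 500, seed = 1)
  m <- fit_lognormal(X)
  expect_identical(synthesize(m, 50, seed = 7), synthesize(m, 50, seed = 7))
  expect_error(synthesize(m, 1), "n must be")
  # identity log-covariance, zero log-mean: approximately uncorrelated draws
  m0 <- structure(list(log_mean = rep(0, 3), log_cov = diag(3) * 0.2,
                       shift = rep(0, 3), zero_variance = rep(FALSE, 3),
                       psd_repaired = FALSE, variables = c("a", "b", "c")),
                  class = "lognormal_model")
  S0 <- synthesize(m0, 20000, seed = 2)
  off <- cor(S0)[upper.tri(diag(3))]
  expect_lt(max(abs(off)), 0.05)
  # two perfectly correlated inputs synthesize to correlation ~ 1
  set.seed(3)
  v <- exp(rnorm(300, 0, 0.4))
  X2 <- cbind(a = v, b = v, c = exp(rnorm(300, 0, 0.4)))
  S2 <- synthesize(fit_lognormal(X2), 5000, seed = 3)
  expect_gt(cor(S2[, "a"], S2[, "b"]), 0.99)
})

test_that("effect sizes match their definitions", {
  x <- rnorm(50)
  expect_equal(effect_size(x, x, "pearson_r")$value, 1)
  # pooled sd of {0,1,2} vs {2,3,4} is 1, so d = |1 - 3| / 1 = 2
  g <- rep(c("a", "b"), each = 3)
  expect_equal(effect_size(c(0, 1, 2, 2, 3, 4), g, "cohens_d")$value, 2)
  set.seed(4)
  expect_lt(abs(effect_size(rnorm(5000), rnorm(5000), "pearson_r")$value), 0.05)
  expect_error(effect_size(rep(1, 6), g, "cohens_d"), "zero pooled")
  expect_error(effect_size(rep(1, 10), rnorm(10), "pearson_r"), "zero variance")
  expect_equal(effect_size_label(1.82), "very large")
  expect_equal(effect_size_label(2.24), "huge")
  expect_equal(effect_size_label(0.1), "negligible")
})

test_that("correlated grouping finds the simulated groups plus a noise singleton", {
  d <- simulate_uniform(sim_config(n_obs = 200, p_total = 600, seed = 44))
  keep <- c(paste0("V", 1:60), "V600")
  X <- d$X[, keep]
  eff <- sapply(keep, function(v) cor(X[, v], d$y))
  gr <- group_correlated(X, eff, threshold = 0.8)
  sizes <- lengths(gr$groups)
  expect_equal(sum(sizes > 1), 6L)   # the six correlated groups
  expect_equal(sum(sizes == 1), 1L)  # the lone noise variable
  expect_true(all(vapply(seq_along(gr$groups), function(i)
    gr$representatives[i] %in% gr$groups[[i]], logical(1))))
  expect_equal(sort(unlist(gr$groups)), sort(keep)) # a partition
  # very strict threshold: everything is a singleton
  gr2 <- group_correlated(X, eff, threshold = 0.999)
  expect_true(all(lengths(gr2$groups) == 1))
})

test_that("representative of a tied group is its first member by column order", {
  set.seed(5)
  v <- rnorm(100)
  X <- cbind(dup1 = v, dup2 = v, other = rnorm(100))
  eff <- c(dup1 = 0.5, dup2 = 0.5, other = 0.2)
  gr <- group_correlated(X, eff, threshold = 0.9)
  dup_group <- gr$groups[[which(lengths(gr$groups) == 2)]]
  expect_setequal(dup_group, c("dup1", "dup2"))
  expect_true("dup1" %in% gr$representatives)
  # larger |effect| wins when not tied
  eff2 <- c(dup1 = 0.1, dup2 = -0.6, other = 0.2)
  gr2 <- group_correlated(X, eff2, threshold = 0.9)
  expect_true("dup2" %in% gr2$representatives)
})

test_that("regression power agrees with the Fisher-z closed form without partners", {
  m <- fit_lognormal(lognormal_fixture(n = 3000, seed = 6))
  reps <- 400
  pg <- power_regression(m, 0.5, target = "V4", n_grid = 50,
                         alpha = 0.05, reps = reps, seed = 6)
  oracle <- fisher_z_power(0.5, 50)
  mc_se <- sqrt(oracle * (1 - oracle) / reps)
  expect_lt(abs(pg$power - oracle), 3 * mc_se + 0.02)
})

test_that("classification power agrees with the noncentral-t closed form without partners", {
  m <- fit_lognormal(lognormal_fixture(n = 3000, seed = 7))
  reps <- 400
  pg <- power_classification(m, 1.0, target = "V4", n_grid = 20,
                             alpha = 0.05, reps = reps, seed = 7)
  oracle <- power.t.test(n = 20, delta = 1, sd = 1)$power
  mc_se <- sqrt(oracle * (1 - oracle) / reps)
  expect_lt(abs(pg$power - oracle), 3 * mc_se + 0.03)
})

test_that("null effects trigger at the alpha level only", {
  m <- fit_lognormal(lognormal_fixture(n = 1000, seed = 8))
  pg <- power_regression(m, 0, target = "V1", n_grid = c(20, 100),
                         alpha = 0.05, reps = 400, seed = 8)
  expect_true(all(abs(pg$power - 0.05) < 3 * sqrt(0.05 * 0.95 / 400)))
  pgc <- power_classification(m, 0, target = "V1", n_grid = 30,
                              alpha = 0.05, reps = 400, seed = 8)
  expect_lt(abs(pgc$power - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("power is monotone in sample size and effect size up to MC error", {
  m <- fit_lognormal(lognormal_fixture(n = 1000, seed = 9))
  pg <- power_regression(m, 0.35, target = "V4", n_grid = c(10, 30, 60, 120),
                         reps = 300, seed = 9)
  expect_true(all(diff(pg$power) > -0.06))
  p_small <- power_regression(m, 0.2, target = "V4", n_grid = 60,
                              reps = 300, seed = 10)$power
  p_large <- power_regression(m, 0.6, target = "V4", n_grid = 60,
                              reps = 300, seed = 10)$power
  expect_gt(p_large, p_small - 0.06)
})

test_that("sample-size recommendation reads the grid correctly", {
  row <- data.frame(n = c(10, 50, 100), power = c(0.2, 0.8, 1.0))
  expect_equal(sample_size_recommendation(row, 0.8),
               list(n = 50, beyond_grid = FALSE))
  expect_equal(sample_size_recommendation(row, 0.99)$beyond_grid, FALSE)
  expect_equal(sample_size_recommendation(row, 0.99)$n, 100)
  row2 <- data.frame(n = c(10, 50), power = c(0.2, 0.9))
  expect_true(sample_size_recommendation(row2, 0.99)$beyond_grid)
  expect_error(sample_size_recommendation(row, 1.5), "power_target")
  expect_error(sample_size_recommendation(row[0, ], 0.8), "empty")
})

test_that("the full power pipeline groups variables and recommends sample sizes", {
  d <- simulate_uniform(sim_config(n_obs = 200, p_total = 61, seed = 46))
  X <- d$X[, c(paste0("V", 1:20), "V61")]
  pr <- power_analysis(X, d$y, mode = "regression", n_grid = c(25, 100, 400),
                       group_threshold = 0.8, reps = 60, seed = 46)
  expect_s3_class(pr, "power_report")
  # one grid block per representative, all estimates are probabilities
  expect_true(all(pr$grid$power >= 0 & pr$grid$power <= 1))
  expect_true(all(pr$grid$fpr >= 0 & pr$grid$fpr <= 1, na.rm = TRUE))
  expect_equal(nrow(pr$grid), 3 * length(pr$recommendations))
  # the strongly informative group-1 representative reaches power 1 by n = 400
  rep1 <- pr$recommendations[[1]]
  expect_false(rep1$beyond_grid)
  # classification mode runs on a dichotomized outcome
  prc <- power_analysis(X[, 1:10], binarize_outcome(d$y, "mean"),
                        mode = "classification", n_grid = c(10, 40),
                        reps = 60, seed = 47)
  expect_true(all(prc$grid$effect > 0))
})
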