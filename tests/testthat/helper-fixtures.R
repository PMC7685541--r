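# Small fixtures shared across test files. Everything is generated in code;
# sizes are kept small so the default suite stays fast.

# Uniform-base simulation small enough for selector tests: 6 groups of 10
# plus noise columns.
small_uniform_sim <- function(n_obs = 200, p_total = 200, seed = 11,
                              n_groups = 6, group_size = 10) {
  if (p_total < n_groups * group_size) {  # shrink groups for tiny fixtures
    n_groups <- 3; group_size <- 3
  }
  simulate_uniform(sim_config(n_obs = n_obs, p_total = p_total,
                              n_groups = n_groups, group_size = group_size,
                              seed = seed))
}

# Pure-noise regression problem: no variable is associated with the outcome.
noise_regression <- function(n = 50, p = 100, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("V", seq_len(p))
  list(X = X, y = rnorm(n))
}

# A log-normal synthesis model with known modest log-scale covariance,
# built from data actually drawn from that model (so the round trip is exact
# up to sampling error).
lognormal_fixture <- function(n = 5000, seed = 42) {
  set.seed(seed)
  p <- 4
  A <- matrix(c(1, .8, .3, 0,
                .8, 1, .3, 0,
                .3, .3, 1, 0,
                0, 0, 0, 1), 4, 4)
  Sigma <- 0.2 * A
  X <- exp(MASS::mvrnorm(n, mu = rep(0, p), Sigma = Sigma))
  colnames(X) <- paste0("V", seq_len(p))
  X
}

fisher_z_power <- function(r, n, alpha = 0.05) {
  z <- atanh(abs(r)) * sqrt(n - 3)
  crit <- qnorm(1 - alpha / 2)
  pnorm(z - crit) + pnorm(-z - crit)
}
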