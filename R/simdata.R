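#' Simulation configuration for benchmark datasets
#'
#' Describes a simulated omics-style dataset with six (by default) groups of
#' correlated predictor variables, a nonlinear continuous outcome driven by the
#' first three group latents, and a bulk of uncorrelated noise predictors.
#'
#' Each correlated group `i` is built around a latent variable `x_i`. The
#' `j`-th member of group `i` is
#' \deqn{V_i^{(j)} = x_i + (0.01 + 0.5 (j-1) / (m-1)) \cdot \epsilon,}
#' where `m` is the group size and `epsilon ~ N(0, noise_sd_group)`, so the
#' correlation between a group member and its latent decays as `j` grows.
#' The outcome is computed from the first three latents by [eval_outcome()]
#' plus `N(0, noise_sd_outcome)` noise.
#'
#' @param n_obs Number of observations (rows). Default 200.
#' @param p_total Total number of predictor variables. Default 5000.
#' @param n_groups Number of correlated groups. Default 6.
#' @param group_size Variables per correlated group. Default 10.
#' @param base_distribution `"uniform01"` (latents and noise predictors drawn
#'   from U(0,1)) or `"standard_normal"` (drawn from N(0,1)).
#' @param noise_sd_group Standard deviation of the within-group noise term.
#'   Default 0.3.
#' @param noise_sd_outcome Standard deviation of the outcome noise. Default 0.2.
#' @param seed Integer seed; the dataset is a deterministic function of the
#'   configuration, including the seed.
#'
#' @return An object of class `sim_config` (a list of the validated fields).
#' @seealso [simulate_dataset()], [eval_outcome()]
#' @export
#' @examples
#' cfg <- sim_config(n_obs = 50, p_total = 100, seed = 1)
#' d <- simulate_dataset(cfg)
#' dim(d$X)
sim_config <- function(n_obs = 200, p_total = 5000, n_groups = 6,
                       group_size = 10,
                       base_distribution = c("uniform01", "standard_normal"),
                       noise_sd_group = 0.3, noise_sd_outcome = 0.2,
                       seed = 1L) {
  base_distribution <- match.arg(base_distribution)
  counts <- c(n_obs = n_obs, p_total = p_total, n_groups = n_groups,
              group_size = group_size)
  if (any(!is.finite(counts)) || any(counts < 1) || any(counts != floor(counts)))
    stop("sim_config: n_obs, p_total, n_groups and group_size must be positive integers",
         call. = FALSE)
  if (n_groups * group_size > p_total)
    stop("sim_config: n_groups * group_size must not exceed p_total", call. = FALSE)
  if (n_groups < 3)
    stop("sim_config: need n_groups >= 3 (the outcome model uses the first three latents)",
         call. = FALSE)
  if (!is.finite(noise_sd_group) || noise_sd_group <= 0 ||
      !is.finite(noise_sd_outcome) || noise_sd_outcome <= 0)
    stop("sim_config: noise standard deviations must be strictly positive",
         call. = FALSE)
  structure(list(n_obs = as.integer(n_obs), p_total = as.integer(p_total),
                 n_groups = as.integer(n_groups),
                 group_size = as.integer(group_size),
                 base_distribution = base_distribution,
                 noise_sd_group = noise_sd_group,
                 noise_sd_outcome = noise_sd_outcome,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Nonlinear outcome model of the simulated datasets
#'
#' The continuous outcome combines an exponential term in the first latent, a
#' steep logistic term in the second and a linear term in the third, so the
#' outcome correlates decreasingly with the three informative latents:
#' \deqn{y = 0.25 e^{4 x_1} + \frac{4}{1 + e^{-20 (x_2 - 0.5)}} + 3 x_3 + \mathrm{noise}.}
#'
#' @param x1,x2,x3 Latent variable values (vectors are recycled element-wise).
#' @param noise Additive noise term, default 0.
#' @return The outcome value(s).
#' @export
#' @examples
#' eval_outcome(0.5, 0.5, 0.5) # 0.25*exp(2) + 2 + 1.5
eval_outcome <- function(x1, x2, x3, noise = 0) {
  0.25 * exp(4 * x1) + 4 / (1 + exp(-20 * (x2 - 0.5))) + 3 * x3 + noise
}

# Noise coefficient of the j-th member of a correlated group of size m:
# 0.01 for j = 1, growing linearly to 0.51 for j = m.
group_noise_coefficients <- function(group_size) {
  j <- seq_len(group_size)
  if (group_size == 1L) return(0.01)
  0.01 + 0.5 * (j - 1) / (group_size - 1)
}

#' Simulate a benchmark dataset with correlated predictor groups
#'
#' Generates the simulated data described in [sim_config()]: `n_groups` groups
#' of `group_size` predictors correlated with latent variables `x_1..x_k`,
#' remaining predictors i.i.d. from the base distribution, and a continuous
#' outcome `y` from [eval_outcome()] on the first three latents. Variables are
#' named `V1..Vp`; group `i` occupies columns `V[(i-1)*m+1] .. V[i*m]`.
#'
#' Ground-truth labels mark the first three groups (whose latents generate the
#' outcome) as `"informative"`, the remaining groups as
#' `"correlated_noninformative"`, and all other predictors as `"noise"`.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `sim_dataset`: a list with elements `X` (numeric
#'   `n_obs` by `p_total` matrix), `y` (continuous outcome), `truth`
#'   (per-variable label), `latent` (the `n_obs` by `n_groups` latent draws,
#'   kept for diagnostics), and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_obs
  p <- config$p_total
  k <- config$n_groups
  m <- config$group_size
  rbase <- switch(config$base_distribution,
                  uniform01 = function(nn) stats::runif(nn),
                  standard_normal = function(nn) stats::rnorm(nn))

  latent <- matrix(rbase(n * k), nrow = n, ncol = k)
  colnames(latent) <- paste0("x", seq_len(k))

  coefs <- group_noise_coefficients(m)
  X <- matrix(0, nrow = n, ncol = p)
  for (i in seq_len(k)) {
    eps <- matrix(stats::rnorm(n * m, mean = 0, sd = config$noise_sd_group),
                  nrow = n, ncol = m)
    X[, (i - 1L) * m + seq_len(m)] <-
      latent[, i] + sweep(eps, 2L, coefs, `*`)
  }
  n_noise <- p - k * m
  if (n_noise > 0L)
    X[, k * m + seq_len(n_noise)] <- rbase(n * n_noise)
  colnames(X) <- paste0("V", seq_len(p))

  y <- eval_outcome(latent[, 1L], latent[, 2L], latent[, 3L],
                    noise = stats::rnorm(n, 0, config$noise_sd_outcome))

  truth <- rep("noise", p)
  truth[seq_len(min(3L, k) * m)] <- "informative"
  if (k > 3L) truth[(3L * m) + seq_len((k - 3L) * m)] <- "correlated_noninformative"
  names(truth) <- colnames(X)

  structure(list(X = X, y = y, y_class = NULL, truth = truth, latent = latent,
                 config = config),
            class = "sim_dataset")
}

#' @rdname simulate_dataset
#' @export
simulate_uniform <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$base_distribution != "uniform01")
    stop("simulate_uniform: config$base_distribution must be 'uniform01'",
         call. = FALSE)
  simulate_dataset(config)
}

#' @rdname simulate_dataset
#' @export
simulate_normal <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$base_distribution != "standard_normal")
    stop("simulate_normal: config$base_distribution must be 'standard_normal'",
         call. = FALSE)
  simulate_dataset(config)
}

#' Dichotomize a continuous outcome
#'
#' Converts a continuous outcome into a two-level factor. With `rule = "mean"`
#' observations below the mean form class `"1"` and the rest class `"2"`
#' (the split used with the uniform-base simulation, where the outcome is
#' right-skewed and the classes are deliberately unbalanced). With
#' `rule = "median"` the split is at the median, giving near-balanced classes
#' (used with the normal-base simulation).
#'
#' @param y Numeric outcome vector; must not be constant.
#' @param rule `"mean"` or `"median"`.
#' @return A factor with levels `"1"` (below the cutoff) and `"2"`.
#' @export
binarize_outcome <- function(y, rule = c("mean", "median")) {
  rule <- match.arg(rule)
  if (!is.numeric(y) || length(y) < 2L)
    stop("binarize_outcome: y must be a numeric vector of length >= 2", call. = FALSE)
  if (max(y) == min(y))
    stop("binarize_outcome: outcome is constant, cannot dichotomize", call. = FALSE)
  cut_value <- if (rule == "mean") mean(y) else stats::median(y)
  cls <- factor(ifelse(y < cut_value, "1", "2"), levels = c("1", "2"))
  if (any(table(cls) == 0L))
    stop("binarize_outcome: one class is empty after the split", call. = FALSE)
  cls
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated dataset:", nrow(x$X), "observations x", ncol(x$X),
      "predictors\n")
  cat("  base distribution:", x$config$base_distribution, "\n")
  cat("  correlated groups:", x$config$n_groups, "of size",
      x$config$group_size, "\n")
  if (!is.null(x$y_class)) cat("  classes:", paste(table(x$y_class), collapse = "/"), "\n")
  invisible(x)
}
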