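#' Fit a multivariate log-normal model to a data matrix
#'
#' Models the joint distribution of the columns of `X` as multivariate
#' log-normal so that synthetic data with the same correlation structure can
#' be drawn at arbitrary sample sizes. Variables that are not strictly
#' positive receive a per-variable shift before the log transform; the mean
#' vector and covariance matrix are estimated on the log scale. A covariance
#' matrix that is not positive semi-definite (possible only for degenerate
#' inputs) is repaired by clipping negative eigenvalues to zero, with a flag.
#'
#' @param X Numeric matrix (samples in rows, at least 3) with column names.
#' @return An object of class `lognormal_model` with `log_mean`, `log_cov`,
#'   `shift`, and flags `zero_variance` (per variable) and `psd_repaired`.
#' @seealso [synthesize()]
#' @export
fit_lognormal <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 3L) stop("fit_lognormal: need at least 3 samples", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (any(!is.finite(X))) stop("fit_lognormal: X contains non-finite values",
                               call. = FALSE)
  mins <- apply(X, 2L, min)
  shift <- ifelse(mins > 0, 0, 1 - mins)  # makes every shifted value >= 1
  logX <- log(sweep(X, 2L, shift, `+`))
  log_cov <- stats::cov(logX)
  zero_variance <- diag(log_cov) == 0
  eg <- eigen(log_cov, symmetric = TRUE)
  psd_repaired <- FALSE
  if (min(eg$values) < -1e-8 * max(abs(eg$values))) {
    vals <- pmax(eg$values, 0)
    log_cov <- eg$vectors %*% (vals * t(eg$vectors))
    dimnames(log_cov) <- dimnames(stats::cov(logX))
    psd_repaired <- TRUE
  }
  structure(list(log_mean = colMeans(logX), log_cov = log_cov, shift = shift,
                 zero_variance = zero_variance, psd_repaired = psd_repaired,
                 variables = colnames(X)),
            class = "lognormal_model")
}

#' Draw synthetic data from a fitted log-normal model
#'
#' Samples from the multivariate normal on the log scale, exponentiates, and
#' removes the per-variable shift, returning data on the original scale with
#' (approximately) the correlation structure of the data the model was fitted
#' to.
#'
#' @param model A [fit_lognormal()] model.
#' @param n Number of rows to draw (>= 2).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (so callers running many replicates can seed once).
#' @return An `n` by `p` numeric matrix with the model's variable names.
#' @export
synthesize <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "lognormal_model"))
  if (n < 2L) stop("synthesize: n must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  Z <- MASS::mvrnorm(n, mu = model$log_mean, Sigma = model$log_cov,
                     tol = 1e-6)
  out <- sweep(exp(Z), 2L, model$shift, `-`)
  colnames(out) <- model$variables
  out
}

#' Estimate a per-variable effect size
#'
#' For a continuous outcome the effect size is the sample Pearson correlation
#' between the variable and the outcome; for a two-group outcome it is
#' Cohen's d, the absolute difference of group means divided by the pooled
#' standard deviation.
#'
#' @param x Numeric variable.
#' @param outcome Continuous vector (`pearson_r`) or two-level factor/vector
#'   (`cohens_d`).
#' @param effect_type `"pearson_r"` or `"cohens_d"`.
#' @param variable Optional variable name carried in the result.
#' @return An object of class `effect_spec`: list with `variable`,
#'   `effect_type` and `value`.
#' @export
effect_size <- function(x, outcome, effect_type = c("pearson_r", "cohens_d"),
                        variable = NA_character_) {
  effect_type <- match.arg(effect_type)
  if (effect_type == "pearson_r") {
    if (stats::sd(x) == 0 || stats::sd(outcome) == 0)
      stop("effect_size: undefined effect, zero variance", call. = FALSE)
    value <- stats::cor(x, outcome)
  } else {
    g <- as.factor(outcome)
    if (nlevels(g) != 2L)
      stop("effect_size: cohens_d needs exactly two outcome levels", call. = FALSE)
    x1 <- x[g == levels(g)[1L]]; x2 <- x[g == levels(g)[2L]]
    n1 <- length(x1); n2 <- length(x2)
    pooled <- sqrt(((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) /
                     (n1 + n2 - 2))
    if (!is.finite(pooled) || pooled == 0)
      stop("effect_size: undefined effect, zero pooled standard deviation",
           call. = FALSE)
    value <- abs(mean(x1) - mean(x2)) / pooled
  }
  structure(list(variable = variable, effect_type = effect_type, value = value),
            class = "effect_spec")
}

#' Verbal effect-size descriptor (Cohen / Sawilowsky scale)
#'
#' Annotation only: maps an absolute effect size onto the conventional labels
#' small (0.2), medium (0.5), large (0.8), very large (1.2) and huge (2.0).
#'
#' @param value Effect size (Cohen's d scale).
#' @return A character label.
#' @export
effect_size_label <- function(value) {
  v <- abs(value)
  cuts <- c(small = 0.2, medium = 0.5, large = 0.8,
            `very large` = 1.2, huge = 2.0)
  below <- v < cuts
  if (all(below)) "negligible" else names(cuts)[max(which(!below))]
}

#' Group highly correlated variables and pick representatives
#'
#' Single-linkage grouping on absolute Pearson correlation: two variables end
#' up in the same group whenever a chain of pairwise correlations with
#' `|r| >= threshold` connects them. Each group is represented by its member
#' with the largest absolute effect size (ties broken by column order), so
#' downstream power calculations run once per group rather than once per
#' variable.
#'
#' @param X Numeric matrix with column names.
#' @param effects Named numeric vector of per-variable effect sizes (see
#'   [effect_size()]).
#' @param threshold Absolute-correlation cutoff in (0, 1), default 0.8.
#' @return An object of class `correlated_groups`: `groups` (list of member
#'   name vectors), `representatives` (one name per group), `membership`
#'   (named group index per variable) and `threshold`.
#' @export
group_correlated <- function(X, effects, threshold = 0.8) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (threshold <= 0 || threshold >= 1)
    stop("group_correlated: threshold must be in (0, 1)", call. = FALSE)
  vars <- colnames(X)
  if (!all(vars %in% names(effects)))
    stop("group_correlated: effects must name every column of X", call. = FALSE)
  ac <- abs(stats::cor(X))
  ac[is.na(ac)] <- 0
  if (ncol(X) == 1L) {
    membership <- stats::setNames(1L, vars)
  } else {
    hc <- stats::hclust(stats::as.dist(1 - ac), method = "single")
    membership <- stats::cutree(hc, h = 1 - threshold)
    names(membership) <- vars
  }
  groups <- split(vars, membership)
  # order groups by first member's column position for stable output
  groups <- groups[order(vapply(groups, function(g) match(g[1L], vars), numeric(1)))]
  groups <- lapply(groups, function(g) g[order(match(g, vars))])
  reps <- vapply(groups, function(g) {
    e <- abs(effects[g])
    g[which.max(e)]  # which.max returns the first maximum: tie -> first member
  }, character(1))
  structure(list(groups = unname(groups), representatives = unname(reps),
                 membership = membership, threshold = threshold),
            class = "correlated_groups")
}

mc_power_row <- function(variable, effect_type, effect, n, hits, fp_rates,
                         alpha, reps) {
  power <- mean(hits)
  data.frame(variable = variable, effect_type = effect_type, effect = effect,
             n = n, power = power, tpr = power,
             fpr = mean(fp_rates, na.rm = TRUE),
             mc_se = sqrt(power * (1 - power) / reps),
             reps = reps, alpha = alpha,
             stringsAsFactors = FALSE)
}

check_reps <- function(reps) {
  if (reps < 50L)
    warning("Monte-Carlo power with reps < 50 has a wide confidence interval",
            call. = FALSE)
}

#' Monte-Carlo power for a continuous outcome (regression mode)
#'
#' For each sample size `n` in the grid and each Monte-Carlo replicate,
#' synthetic data are drawn from the log-normal model and a continuous
#' outcome is constructed to have population Pearson correlation `r` with the
#' target variable (`outcome = r * standardized(target) + sqrt(1 - r^2) *
#' noise`). Every variable is then tested by simple linear regression against
#' the outcome; the replicate scores a true positive when the target or any
#' of its correlated partners is significant at `alpha`. Power at `n` is the
#' true-positive fraction over replicates; the false-positive rate is the
#' average fraction of significant non-member variables.
#'
#' @param model A [fit_lognormal()] model.
#' @param effect An [effect_size()] object of type `pearson_r` (or a bare
#'   number, interpreted as the correlation), with `|r| < 1`.
#' @param target Name of the target variable (defaults to
#'   `effect$variable`).
#' @param partners Character vector of correlated partner variables whose
#'   significance also counts as a true positive; empty for a strict
#'   per-variable power.
#' @param n_grid Strictly increasing vector of sample sizes.
#' @param alpha Test level, default 0.05.
#' @param reps Monte-Carlo replicates per sample size, default 200.
#' @param seed Integer seed.
#' @return A data frame (class `power_grid`) with one row per sample size:
#'   `variable`, `effect`, `n`, `power`, `tpr`, `fpr`, `mc_se`, `reps`.
#' @export
power_regression <- function(model, effect, target = NULL,
                             partners = character(), n_grid, alpha = 0.05,
                             reps = 200L, seed = 1L) {
  stopifnot(inherits(model, "lognormal_model"))
  r <- if (inherits(effect, "effect_spec")) effect$value else as.numeric(effect)
  if (is.null(target) && inherits(effect, "effect_spec")) target <- effect$variable
  if (abs(r) >= 1) stop("power_regression: |r| must be < 1", call. = FALSE)
  check_grid(n_grid); check_reps(reps)
  if (!target %in% model$variables)
    stop("power_regression: target not in model variables", call. = FALSE)
  members <- unique(c(target, partners))
  non_members <- setdiff(model$variables, members)
  set.seed(seed)
  rows <- lapply(n_grid, function(n) {
    hits <- logical(reps); fp <- numeric(reps)
    for (b in seq_len(reps)) {
      Xs <- synthesize(model, n)
      tv <- Xs[, target]
      outcome <- r * as.vector(scale(tv)) + sqrt(1 - r^2) * stats::rnorm(n)
      p <- regression_pvalues(Xs, outcome)
      hits[b] <- any(p[members] < alpha)
      fp[b] <- if (length(non_members)) mean(p[non_members] < alpha) else NA_real_
    }
    mc_power_row(target, "pearson_r", r, n, hits, fp, alpha, reps)
  })
  structure(do.call(rbind, rows), class = c("power_grid", "data.frame"))
}

#' Monte-Carlo power for a two-group outcome (classification mode)
#'
#' For each per-group sample size `n` and replicate, two groups of `n`
#' synthetic samples are drawn from the log-normal model and the target
#' variable (and each correlated partner) in the second group is shifted by
#' `d` times that variable's observed standard deviation, so the realized
#' Cohen's d matches the requested one. A one-way ANOVA (equivalently a
#' two-sample t-test for two groups) is run per variable; true/false
#' positives and power are scored as in [power_regression()].
#'
#' @inheritParams power_regression
#' @param effect An [effect_size()] object of type `cohens_d` (or a bare
#'   non-negative number).
#' @param n_grid Strictly increasing vector of per-group sample sizes.
#' @return A `power_grid` data frame, one row per sample size.
#' @export
power_classification <- function(model, effect, target = NULL,
                                 partners = character(), n_grid, alpha = 0.05,
                                 reps = 200L, seed = 1L) {
  stopifnot(inherits(model, "lognormal_model"))
  d <- if (inherits(effect, "effect_spec")) effect$value else as.numeric(effect)
  if (is.null(target) && inherits(effect, "effect_spec")) target <- effect$variable
  if (d < 0) stop("power_classification: d must be >= 0", call. = FALSE)
  check_grid(n_grid); check_reps(reps)
  if (!target %in% model$variables)
    stop("power_classification: target not in model variables", call. = FALSE)
  members <- unique(c(target, partners))
  non_members <- setdiff(model$variables, members)
  set.seed(seed)
  rows <- lapply(n_grid, function(n) {
    hits <- logical(reps); fp <- numeric(reps)
    for (b in seq_len(reps)) {
      Xs <- synthesize(model, 2L * n)
      sds <- apply(Xs, 2L, stats::sd)
      g2 <- n + seq_len(n)
      Xs[g2, members] <- sweep(Xs[g2, members, drop = FALSE], 2L,
                               d * sds[members], `+`)
      p <- anova_pvalues(Xs, n)
      hits[b] <- any(p[members] < alpha)
      fp[b] <- if (length(non_members)) mean(p[non_members] < alpha) else NA_real_
    }
    mc_power_row(target, "cohens_d", d, n, hits, fp, alpha, reps)
  })
  structure(do.call(rbind, rows), class = c("power_grid", "data.frame"))
}

check_grid <- function(n_grid) {
  if (length(n_grid) == 0L)
    stop("power: empty sample-size grid", call. = FALSE)
  if (any(diff(n_grid) <= 0))
    stop("power: sample-size grid must be strictly increasing", call. = FALSE)
  if (any(n_grid < 3L))
    stop("power: sample sizes must be >= 3", call. = FALSE)
}

# p-values of simple linear regressions of `outcome` on each column,
# vectorized through the correlation t statistic.
regression_pvalues <- function(X, outcome) {
  n <- length(outcome)
  r <- suppressWarnings(as.vector(stats::cor(outcome, X)))
  r[!is.finite(r)] <- 0
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  stats::setNames(2 * stats::pt(-abs(tstat), df = n - 2), colnames(X))
}

# Per-variable one-way ANOVA p-values for two equal groups of size n
# (first n rows = group 1), vectorized; identical to the equal-variance
# two-sample t-test since F = t^2 with two groups.
anova_pvalues <- function(X, n) {
  g1 <- X[seq_len(n), , drop = FALSE]
  g2 <- X[n + seq_len(n), , drop = FALSE]
  m1 <- colMeans(g1); m2 <- colMeans(g2)
  v1 <- apply(g1, 2L, stats::var); v2 <- apply(g2, 2L, stats::var)
  pooled <- (v1 + v2) / 2
  pooled[pooled == 0] <- NA_real_
  tstat <- (m2 - m1) / sqrt(pooled * 2 / n)
  p <- 2 * stats::pt(-abs(tstat), df = 2 * n - 2)
  p[is.na(p)] <- 1
  stats::setNames(p, colnames(X))
}

#' Smallest sample size reaching a power target
#'
#' @param grid_row A `power_grid` data frame for a single variable (rows
#'   ordered by `n`).
#' @param power_target Required power in (0, 1].
#' @return A list with `n` (smallest grid sample size whose estimated power
#'   reaches the target, or `NA`) and `beyond_grid` (`TRUE` when no grid
#'   point reaches it).
#' @export
sample_size_recommendation <- function(grid_row, power_target = 0.8) {
  if (power_target <= 0 || power_target > 1)
    stop("sample_size_recommendation: power_target must be in (0, 1]",
         call. = FALSE)
  if (is.null(grid_row) || nrow(grid_row) == 0L)
    stop("sample_size_recommendation: empty power grid", call. = FALSE)
  ok <- which(grid_row$power >= power_target)
  if (length(ok) == 0L) list(n = NA_integer_, beyond_grid = TRUE)
  else list(n = grid_row$n[min(ok)], beyond_grid = FALSE)
}

#' Full power analysis of a dataset
#'
#' The module-two pipeline: fit the log-normal synthesis model, estimate each
#' variable's effect size against the outcome (Pearson correlation in
#' regression mode, Cohen's d in classification mode), optionally group
#' highly correlated variables, and run the Monte-Carlo power calculation for
#' each group representative (with its group partners counting as true
#' positives) over a sample-size grid.
#'
#' @param X Numeric matrix of candidate biomarkers (samples x variables).
#' @param outcome Continuous vector (regression) or two-level vector
#'   (classification).
#' @param mode `"regression"` or `"classification"`.
#' @param n_grid Sample-size grid; default a doubling series 5, 10, ..., 2560
#'   (per group in classification mode).
#' @param group_threshold Absolute-correlation grouping cutoff, default 0.8;
#'   `NULL` disables grouping (every variable assessed on its own).
#' @param alpha Test level, default 0.05.
#' @param reps Monte-Carlo replicates, default 200.
#' @param power_target Power level for the sample-size recommendation,
#'   default 0.8.
#' @param seed Integer seed.
#' @return An object of class `power_report`: `grid` (long-format
#'   `power_grid` over all representatives), `effects` (per-variable effect
#'   sizes with verbal labels), `groups` (a [group_correlated()] result or
#'   `NULL`), `recommendations` (per representative) and the call settings.
#' @export
power_analysis <- function(X, outcome,
                           mode = c("regression", "classification"),
                           n_grid = 5L * 2L^(0:9), group_threshold = 0.8,
                           alpha = 0.05, reps = 200L, power_target = 0.8,
                           seed = 1L) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  etype <- if (mode == "regression") "pearson_r" else "cohens_d"
  effects <- vapply(colnames(X), function(v)
    effect_size(X[, v], outcome, etype, variable = v)$value, numeric(1))

  if (!is.null(group_threshold)) {
    groups <- group_correlated(X, effects, threshold = group_threshold)
    reps_vars <- groups$representatives
    partner_sets <- lapply(seq_along(groups$groups), function(i)
      setdiff(groups$groups[[i]], reps_vars[i]))
  } else {
    groups <- NULL
    reps_vars <- colnames(X)
    partner_sets <- rep(list(character()), ncol(X))
  }

  model <- fit_lognormal(X)
  grid <- do.call(rbind, lapply(seq_along(reps_vars), function(i) {
    v <- reps_vars[i]
    es <- structure(list(variable = v, effect_type = etype,
                         value = effects[v]), class = "effect_spec")
    fun <- if (mode == "regression") power_regression else power_classification
    out <- fun(model, es, partners = partner_sets[[i]], n_grid = n_grid,
               alpha = alpha, reps = reps, seed = seed + i)
    out$group <- i
    out
  }))

  recommendations <- lapply(seq_along(reps_vars), function(i) {
    rec <- sample_size_recommendation(grid[grid$variable == reps_vars[i], ,
                                           drop = FALSE], power_target)
    c(list(variable = reps_vars[i], effect = unname(effects[reps_vars[i]]),
           label = effect_size_label(effects[reps_vars[i]])), rec)
  })

  structure(list(grid = grid,
                 effects = data.frame(variable = colnames(X),
                                      effect = unname(effects),
                                      label = vapply(effects, effect_size_label,
                                                     character(1)),
                                      stringsAsFactors = FALSE),
                 groups = groups, recommendations = recommendations,
                 mode = mode, alpha = alpha, reps = reps, n_grid = n_grid,
                 power_target = power_target, seed = seed),
            class = "power_report")
}

#' @export
print.power_report <- function(x, ...) {
  cat("<power_report>", x$mode, "mode,", length(unique(x$grid$variable)),
      "representative variable(s),", x$reps, "Monte-Carlo reps\n")
  for (r in x$recommendations) {
    cat(sprintf("  %-10s effect %.3f (%s): ", r$variable, r$effect, r$label))
    if (r$beyond_grid) cat("power", x$power_target, "not reached on grid\n")
    else cat("n >=", r$n, "for power", x$power_target, "\n")
  }
  invisible(x)
}
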