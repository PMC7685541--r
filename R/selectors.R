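#' @title Random-forest feature-selection algorithms
#' @description Four selectors operating on a ranked random-forest importance
#'   measure: Boruta shadow-variable testing, outcome-permutation significance
#'   testing (raw and Benjamini-Hochberg corrected) and recursive feature
#'   elimination. Each returns a `selection_outcome` object.
#' @name selectors
NULL

selection_outcome <- function(method, selected, decision = NULL,
                              p_value = NULL, diagnostics = list()) {
  structure(list(method = method, selected = selected, decision = decision,
                 p_value = p_value, diagnostics = diagnostics),
            class = "selection_outcome")
}

#' @export
print.selection_outcome <- function(x, ...) {
  cat("<selection_outcome>", x$method, "-", length(x$selected),
      "variables selected\n")
  if (length(x$selected))
    cat("  ", paste(utils::head(x$selected, 10L), collapse = ", "),
        if (length(x$selected) > 10L) "..." else "", "\n")
  invisible(x)
}

prepare_xy <- function(x, y, task) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  list(x = x, y = as_outcome(y, task))
}

#' Boruta feature selection with shadow variables
#'
#' Each run appends a "shadow" copy of every still-undecided predictor, made by
#' permuting that column across observations, and fits a forest on the doubled
#' variable set. A variable scores a hit when its permutation importance
#' exceeds the maximum importance attained by any shadow. After each run a
#' two-sided binomial test on the accumulated hit counts (Bonferroni-adjusted
#' over the variables still undecided) confirms clear winners and rejects
#' clear losers; rejected variables and all shadows are dropped before the
#' next run. The loop stops when every variable is decided or `max_runs` is
#' reached; variables still tentative at that point are not selected.
#'
#' @param x,y Predictors and outcome (see [fit_forest()]).
#' @param spec A [forest_spec()]; its `n_trees`, `task` and `seed` are used
#'   (`mtry` is left to the learner default because the variable set changes
#'   between runs).
#' @param alpha Significance level of the binomial test, default 0.05.
#' @param max_runs Maximum number of forest runs, default 100.
#' @return A `selection_outcome` with `decision` in
#'   `{"confirmed","rejected","tentative"}` per variable and diagnostics
#'   (`runs`, per-variable hit counts).
#' @export
boruta_select <- function(x, y, spec, alpha = 0.05, max_runs = 100L) {
  stopifnot(inherits(spec, "forest_spec"))
  if (max_runs < 1L) stop("boruta_select: max_runs must be >= 1", call. = FALSE)
  set.seed(spec$seed)  # shadow permutations draw from the global stream
  d <- prepare_xy(x, y, spec$task)
  x <- d$x; y <- d$y
  p <- ncol(x)
  vars <- colnames(x)
  decision <- stats::setNames(rep("tentative", p), vars)
  hits <- stats::setNames(integer(p), vars)
  active <- vars               # not yet rejected: enters the forest
  run <- 0L
  while (run < max_runs && any(decision == "tentative")) {
    run <- run + 1L
    undecided <- vars[decision == "tentative"]
    shadows <- x[, active, drop = FALSE]
    for (k in seq_len(ncol(shadows)))
      shadows[, k] <- shadows[sample.int(nrow(shadows)), k]
    colnames(shadows) <- paste0(".shadow_", active)
    run_spec <- forest_spec(task = spec$task, n_trees = spec$n_trees,
                            min_node_size = spec$min_node_size,
                            seed = spec$seed + run)
    fit <- fit_forest(cbind(x[, active, drop = FALSE], shadows), y, run_spec)
    imp <- fit$importance
    max_shadow <- max(imp[colnames(shadows)])
    hit <- imp[undecided] > max_shadow
    hits[undecided] <- hits[undecided] + hit
    # two-sided binomial test at p = 0.5, Bonferroni over undecided variables
    alpha_adj <- alpha / length(undecided)
    p_hi <- stats::pbinom(hits[undecided] - 1L, run, 0.5, lower.tail = FALSE)
    p_lo <- stats::pbinom(hits[undecided], run, 0.5)
    decision[undecided][p_hi <= alpha_adj / 2] <- "confirmed"
    decision[undecided][p_lo <= alpha_adj / 2] <- "rejected"
    active <- vars[decision != "rejected"]
    if (length(active) == 0L) break
  }
  selection_outcome("boruta",
                    selected = vars[decision == "confirmed"],
                    decision = decision,
                    diagnostics = list(runs = run, hits = hits,
                                       alpha = alpha, max_runs = max_runs))
}

#' Outcome-permutation feature selection
#'
#' Fits a forest on the observed outcome to obtain per-variable permutation
#' importances, then refits on `n_perm` random permutations of the outcome to
#' build a per-variable null distribution of importances. The p-value of
#' variable `v` is `(1 + #\{null_v >= observed_v\}) / (n_perm + 1)`. With
#' `correction = "none"` variables with `p < alpha` are selected (the "raw"
#' variant); with `correction = "benjamini_hochberg"` p-values are BH-adjusted
#' first (the "corrected" variant). Setting `pooled_null = TRUE` compares each
#' observed importance against the nulls of all variables pooled together
#' instead of its own.
#'
#' @inheritParams boruta_select
#' @param n_perm Number of outcome permutations, default 1000.
#' @param alpha Selection threshold on the (adjusted) p-value, default 0.05.
#' @param correction `"none"` or `"benjamini_hochberg"`.
#' @param pooled_null Compare against the pooled null distribution instead of
#'   each variable's own. Default `FALSE`.
#' @return A `selection_outcome` carrying per-variable `p_value` (adjusted
#'   p-values when a correction is applied; raw ones in
#'   `diagnostics$p_raw`).
#' @export
permutation_select <- function(x, y, spec, n_perm = 1000L, alpha = 0.05,
                               correction = c("none", "benjamini_hochberg"),
                               pooled_null = FALSE) {
  stopifnot(inherits(spec, "forest_spec"))
  correction <- match.arg(correction)
  if (n_perm < 20L) stop("permutation_select: n_perm must be >= 20", call. = FALSE)
  if (1 / (n_perm + 1) > alpha)
    warning("permutation_select: n_perm too small to ever reach alpha; ",
            "selection may be empty", call. = FALSE)
  set.seed(spec$seed)  # outcome permutations draw from the global stream
  d <- prepare_xy(x, y, spec$task)
  x <- d$x; y <- d$y
  obs <- fit_forest(x, y, spec)$importance
  null_imp <- matrix(NA_real_, nrow = n_perm, ncol = ncol(x))
  for (b in seq_len(n_perm)) {
    y_perm <- y[sample.int(length(y))]
    null_imp[b, ] <- fit_forest(x, y_perm, spec, seed = spec$seed + b)$importance
  }
  exceed <- if (pooled_null) {
    vapply(obs, function(o) sum(null_imp >= o), numeric(1)) / ncol(x)
  } else {
    colSums(sweep(null_imp, 2L, obs, `>=`))
  }
  p_raw <- stats::setNames((1 + exceed) / (n_perm + 1), colnames(x))
  p_use <- if (correction == "benjamini_hochberg")
    stats::p.adjust(p_raw, method = "BH") else p_raw
  selection_outcome(if (correction == "none") "perm_raw" else "perm_corrected",
                    selected = colnames(x)[p_use < alpha],
                    p_value = p_use,
                    diagnostics = list(p_raw = p_raw, n_perm = n_perm,
                                       alpha = alpha, pooled_null = pooled_null,
                                       observed_importance = obs))
}

#' Model-level outcome-permutation test
#'
#' Tests whether the forest explains more of the outcome than expected by
#' chance: the OOB percent variance explained (regression) or OOB accuracy
#' (classification) of the observed fit is compared against the same statistic
#' from `n_perm` forests refit on permuted outcomes. The p-value is
#' `(1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' @inheritParams permutation_select
#' @return A list with `p_value`, `observed` and the `null` statistics.
#' @export
model_permutation_test <- function(x, y, spec, n_perm = 1000L) {
  stopifnot(inherits(spec, "forest_spec"))
  if (n_perm < 20L) stop("model_permutation_test: n_perm must be >= 20",
                         call. = FALSE)
  set.seed(spec$seed)
  d <- prepare_xy(x, y, spec$task)
  x <- d$x; y <- d$y
  stat <- function(fit) {
    if (spec$task == "regression") fit$performance$pct_var_explained
    else 1 - fit$performance$oob_error
  }
  observed <- stat(fit_forest(x, y, spec))
  null_stat <- vapply(seq_len(n_perm), function(b) {
    stat(fit_forest(x, y[sample.int(length(y))], spec, seed = spec$seed + b))
  }, numeric(1))
  list(p_value = (1 + sum(null_stat >= observed)) / (n_perm + 1),
       observed = observed, null = null_stat, n_perm = n_perm,
       min_attainable_p = 1 / (n_perm + 1))
}

# Subset sizes visited by the elimination schedule, from p down to 1.
rfe_trajectory <- function(p, drop_fraction) {
  sizes <- p
  while (p > 1L) {
    p <- p - as.integer(ceiling(drop_fraction * p))
    p <- max(p, 1L)
    sizes <- c(sizes, p)
  }
  sizes
}

#' Recursive feature elimination over a random forest
#'
#' Iteratively refits the forest, each time discarding the fraction of
#' variables with the smallest permutation importance, down to a single
#' variable. The OOB error (classification) or OOB MSE (regression) of every
#' visited subset is recorded, and the selected set is the smallest subset
#' whose error does not exceed the minimum error by more than `se_rule`
#' standard errors of that minimum (`se_rule = 0` selects the strict
#' minimizer).
#'
#' By default the importance ranking is computed once, on the initial
#' all-variable fit, and elimination proceeds along that fixed ranking while
#' every visited subset is refit for its OOB error; this avoids the
#' selection-bias feedback of re-ranking on ever-smaller variable sets.
#' `recompute_importance = TRUE` re-ranks at every iteration instead.
#'
#' @inheritParams boruta_select
#' @param drop_fraction Fraction of current variables discarded per iteration
#'   (ceiling), default 0.2.
#' @param se_rule Width of the tolerated error band in standard errors of the
#'   minimum error, default 1.
#' @param recompute_importance Re-rank variables at every iteration instead
#'   of using the initial ranking. Default `FALSE`.
#' @return A `selection_outcome` with an error trajectory in `diagnostics`
#'   (`n_vars`, `error`, `se` per visited subset).
#' @export
rfe_select <- function(x, y, spec, drop_fraction = 0.2, se_rule = 1,
                       recompute_importance = FALSE) {
  stopifnot(inherits(spec, "forest_spec"))
  if (drop_fraction <= 0 || drop_fraction >= 1)
    stop("rfe_select: drop_fraction must be in (0, 1)", call. = FALSE)
  d <- prepare_xy(x, y, spec$task)
  x <- d$x; y <- d$y
  n <- nrow(x)
  current <- colnames(x)
  subsets <- list(); errors <- numeric(0); ses <- numeric(0)
  ranked <- NULL
  step <- 0L
  repeat {
    step <- step + 1L
    fit <- fit_forest(x[, current, drop = FALSE], y, spec,
                      seed = spec$seed + step)
    oob_pred <- fit$model$predictions
    if (spec$task == "regression") {
      err <- fit$performance$oob_mse
      sq <- (oob_pred - y)^2
      se <- stats::sd(sq, na.rm = TRUE) / sqrt(sum(!is.na(sq)))
    } else {
      err <- fit$performance$oob_error
      se <- sqrt(err * (1 - err) / n)
    }
    subsets[[step]] <- current
    errors[step] <- err
    ses[step] <- se
    if (length(current) == 1L) break
    keep <- length(current) - as.integer(ceiling(drop_fraction * length(current)))
    keep <- max(keep, 1L)
    if (recompute_importance) {
      current <- current[fit$ranking[seq_len(keep)]]
    } else {
      if (is.null(ranked)) ranked <- current[fit$ranking]
      current <- ranked[seq_len(keep)]
    }
  }
  best <- which.min(errors)
  threshold <- errors[best] + se_rule * ses[best]
  within <- which(errors <= threshold)
  chosen <- within[which.min(lengths(subsets)[within])]
  selection_outcome("rfe",
                    selected = subsets[[chosen]],
                    diagnostics = list(
                      n_vars = lengths(subsets), error = errors, se = ses,
                      drop_fraction = drop_fraction, se_rule = se_rule,
                      chosen_step = chosen))
}

#' Run one selector by name
#'
#' Dispatch helper used by the stability engine and the command-line
#' interface: maps `"boruta"`, `"perm_raw"`, `"perm_corrected"` and `"rfe"`
#' onto the corresponding selector with the supplied arguments.
#'
#' @inheritParams boruta_select
#' @param method Selector name.
#' @param args Named list of extra arguments for the selector (e.g. `alpha`,
#'   `n_perm`, `drop_fraction`).
#' @return A `selection_outcome`.
#' @export
run_selector <- function(method = c("boruta", "perm_raw", "perm_corrected", "rfe"),
                         x, y, spec, args = list()) {
  method <- match.arg(method)
  fun <- switch(method,
    boruta = boruta_select,
    perm_raw = function(x, y, spec, ...)
      permutation_select(x, y, spec, correction = "none", ...),
    perm_corrected = function(x, y, spec, ...)
      permutation_select(x, y, spec, correction = "benjamini_hochberg", ...),
    rfe = rfe_select)
  do.call(fun, c(list(x = x, y = y, spec = spec), args))
}
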