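#' Random-forest specification
#'
#' A small container describing one random-forest fit. The forest learner
#' behind this contract is \pkg{ranger}; out-of-bag (OOB) samples (the roughly
#' one third of observations left out of each tree's bootstrap) provide the
#' performance estimates, and variable importance is unscaled permutation
#' importance (mean decrease in accuracy for classification, mean increase in
#' MSE for regression).
#'
#' @param task `"regression"` or `"classification"`.
#' @param n_trees Number of trees, default 500.
#' @param mtry Candidate variables per split; `NULL` uses the learner default
#'   (`sqrt(p)` for classification, `p/3` for regression).
#' @param min_node_size Minimal terminal node size; `NULL` uses 1 for
#'   classification and 5 for regression.
#' @param seed Integer seed for the forest's random stream.
#' @return An object of class `forest_spec`.
#' @export
forest_spec <- function(task = c("regression", "classification"),
                        n_trees = 500L, mtry = NULL, min_node_size = NULL,
                        seed = 1L) {
  task <- match.arg(task)
  if (!is.finite(n_trees) || n_trees < 1L)
    stop("forest_spec: n_trees must be >= 1", call. = FALSE)
  if (!is.null(mtry) && (!is.finite(mtry) || mtry < 1L))
    stop("forest_spec: mtry must be >= 1 when given", call. = FALSE)
  structure(list(task = task, n_trees = as.integer(n_trees),
                 mtry = if (is.null(mtry)) NULL else as.integer(mtry),
                 min_node_size = if (is.null(min_node_size)) NULL
                                 else as.integer(min_node_size),
                 seed = as.integer(seed)),
            class = "forest_spec")
}

as_outcome <- function(y, task) {
  if (task == "classification") {
    y <- as.factor(y)
    tab <- table(y)
    if (length(tab) < 2L || any(tab < 2L))
      stop("fit_forest: classification needs >= 2 samples in each of >= 2 classes",
           call. = FALSE)
    droplevels(y)
  } else {
    if (!is.numeric(y)) stop("fit_forest: regression outcome must be numeric",
                             call. = FALSE)
    if (stats::var(y) == 0)
      stop("fit_forest: outcome is constant", call. = FALSE)
    y
  }
}

#' Fit a random forest with OOB performance and permutation importance
#'
#' @param x Numeric matrix or data frame of predictors (samples in rows).
#' @param y Outcome: numeric (regression) or two-level factor/vector
#'   (classification), matching `spec$task`.
#' @param spec A [forest_spec()].
#' @param seed Optional seed overriding `spec$seed` (convenient in repeated
#'   selection loops).
#' @return A list of class `forest_fit` with elements `model` (the ranger
#'   object), `performance` (for regression: `oob_mse` and
#'   `pct_var_explained`; for classification: `oob_error`), `importance`
#'   (named per-variable scores) and `ranking` (variable indices by decreasing
#'   importance, ties broken by ascending index).
#' @export
fit_forest <- function(x, y, spec, seed = NULL) {
  stopifnot(inherits(spec, "forest_spec"))
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  y <- as_outcome(y, spec$task)
  if (nrow(x) != length(y)) stop("fit_forest: nrow(x) != length(y)", call. = FALSE)
  mns <- if (!is.null(spec$min_node_size)) spec$min_node_size
         else if (spec$task == "classification") 1L else 5L
  fit <- ranger::ranger(
    x = x, y = y,
    num.trees = spec$n_trees,
    mtry = if (is.null(spec$mtry)) NULL else min(spec$mtry, ncol(x)),
    min.node.size = mns,
    importance = "permutation",
    num.threads = 1L,
    seed = if (is.null(seed)) spec$seed else seed)
  imp <- fit$variable.importance
  perf <- if (spec$task == "regression") {
    list(oob_mse = fit$prediction.error,
         pct_var_explained = 100 * fit$r.squared)
  } else {
    list(oob_error = fit$prediction.error)
  }
  structure(list(model = fit, performance = perf, importance = imp,
                 ranking = order(-imp, seq_along(imp)), spec = spec),
            class = "forest_fit")
}

#' Default hyperparameter grid
#'
#' Builds a small `mtry` grid around the learner defaults: multiples of
#' `sqrt(p)` for classification and fractions of `p` for regression.
#'
#' @param p Number of predictors.
#' @param task `"regression"` or `"classification"`.
#' @param n_trees Trees per grid member, default 500.
#' @param seed Seed stored in each spec.
#' @return A list of [forest_spec()] objects.
#' @export
default_spec_grid <- function(p, task = c("regression", "classification"),
                              n_trees = 500L, seed = 1L) {
  task <- match.arg(task)
  mtries <- if (task == "classification") {
    r <- max(1L, floor(sqrt(p)))
    unique(pmin(p, pmax(1L, c(floor(r / 2), r, 2L * r))))
  } else {
    unique(pmin(p, pmax(1L, floor(p * c(0.1, 1 / 3, 0.5)))))
  }
  lapply(mtries, function(m)
    forest_spec(task = task, n_trees = n_trees, mtry = m, seed = seed))
}

# argmin over OOB error with the documented tie-break:
# smallest error, then smallest mtry, then smallest n_trees.
select_best_spec <- function(grid, errors) {
  mtries <- vapply(grid, function(s) if (is.null(s$mtry)) NA_integer_ else s$mtry,
                   integer(1))
  mtries[is.na(mtries)] <- .Machine$integer.max
  ntrees <- vapply(grid, function(s) s$n_trees, integer(1))
  grid[[order(errors, mtries, ntrees)[1L]]]
}

#' Tune forest hyperparameters by OOB error
#'
#' Fits each candidate specification on the tuning data and returns the one
#' with the smallest OOB error (classification) or OOB MSE (regression). Ties
#' are broken by the smaller `mtry`, then the smaller `n_trees`.
#'
#' @param x,y Tuning data, as in [fit_forest()].
#' @param grid Non-empty list of [forest_spec()] candidates.
#' @return The winning [forest_spec()].
#' @export
tune_hyperparameters <- function(x, y, grid) {
  if (length(grid) == 0L)
    stop("tune_hyperparameters: empty hyperparameter grid", call. = FALSE)
  errors <- vapply(grid, function(s) {
    f <- fit_forest(x, y, s)
    if (s$task == "regression") f$performance$oob_mse else f$performance$oob_error
  }, numeric(1))
  select_best_spec(grid, errors)
}
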