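#' Nested cross-validation plan for stable feature selection
#'
#' Describes the module-one resampling design: the samples are split into
#' `outer_rotations` rotations of roughly `outer_train_fraction` training
#' data, arranged so that every sample appears in exactly one outer test fold.
#' Within each rotation a `1/inner_folds` fraction of the outer training data
#' is reserved for hyperparameter tuning and the remainder hosts
#' `n_iterations` independently seeded runs of each feature-selection method.
#' Variables selected in more than `ls_threshold` of the iterations (strict
#' inequality) form the low-stringency (LS) stable set; variables selected in
#' at least `hs_threshold` iterations (inclusive) form the high-stringency
#' (HS) stable set.
#'
#' @param outer_train_fraction Outer training fraction, default 0.75.
#' @param outer_rotations Number of outer rotations, default 4 (so test folds
#'   of ~25% partition the data).
#' @param inner_folds Granularity of the inner split; `1/inner_folds` of the
#'   outer training data is used for tuning. Default 10.
#' @param n_iterations Selection iterations per rotation, default 100.
#' @param ls_threshold Low-stringency count threshold (exclusive), default 5.
#' @param hs_threshold High-stringency count threshold (inclusive), default 90.
#' @param seed Integer seed controlling splits and iteration seeds.
#' @return An object of class `nested_cv_plan`.
#' @export
nested_cv_plan <- function(outer_train_fraction = 0.75, outer_rotations = 4L,
                           inner_folds = 10L, n_iterations = 100L,
                           ls_threshold = 5L, hs_threshold = 90L, seed = 1L) {
  if (outer_train_fraction <= 0 || outer_train_fraction >= 1)
    stop("nested_cv_plan: outer_train_fraction must be in (0, 1)", call. = FALSE)
  if (outer_rotations < 1L || inner_folds < 2L || n_iterations < 1L)
    stop("nested_cv_plan: counts must be positive (inner_folds >= 2)", call. = FALSE)
  if (!(ls_threshold > 0L && ls_threshold < hs_threshold &&
        hs_threshold <= n_iterations))
    stop("nested_cv_plan: need 0 < ls_threshold < hs_threshold <= n_iterations",
         call. = FALSE)
  structure(list(outer_train_fraction = outer_train_fraction,
                 outer_rotations = as.integer(outer_rotations),
                 inner_folds = as.integer(inner_folds),
                 n_iterations = as.integer(n_iterations),
                 ls_threshold = as.integer(ls_threshold),
                 hs_threshold = as.integer(hs_threshold),
                 seed = as.integer(seed)),
            class = "nested_cv_plan")
}

#' Outer-loop splits with each sample tested exactly once
#'
#' Shuffles the samples once and partitions them into `outer_rotations`
#' near-equal test folds; each split uses one fold as the outer test set and
#' the remaining samples (about 75% with the defaults) as the outer training
#' set.
#'
#' @param n_samples Number of samples.
#' @param plan A [nested_cv_plan()].
#' @return A list of `outer_rotations` elements, each with integer vectors
#'   `train` and `test`; the `test` folds are pairwise disjoint and their
#'   union covers all samples.
#' @export
make_outer_splits <- function(n_samples, plan) {
  stopifnot(inherits(plan, "nested_cv_plan"))
  r <- plan$outer_rotations
  if (n_samples < r)
    stop("make_outer_splits: fewer samples than outer rotations", call. = FALSE)
  set.seed(plan$seed)
  shuffled <- sample.int(n_samples)
  # near-equal fold sizes, differing by at most one
  sizes <- tabulate(rep(seq_len(r), length.out = n_samples), r)
  fold_of <- integer(n_samples)
  fold_of[shuffled] <- rep(seq_len(r), times = sizes)
  lapply(seq_len(r), function(k)
    list(train = which(fold_of != k), test = which(fold_of == k)))
}

#' True/false positive counts of a selected set
#'
#' @param selected Character vector of selected variable names.
#' @param truth Named per-variable truth labels (`"informative"`,
#'   `"correlated_noninformative"`, `"noise"`), as produced by
#'   [simulate_dataset()].
#' @return A list with `tp` (selected variables labelled informative) and
#'   `fp` (all other selected variables).
#' @export
evaluate_truth <- function(selected, truth) {
  if (is.null(names(truth)))
    stop("evaluate_truth: truth must be a named vector", call. = FALSE)
  sel_truth <- truth[selected]
  list(tp = sum(sel_truth == "informative", na.rm = TRUE),
       fp = sum(sel_truth != "informative" | is.na(sel_truth)))
}

validate_on_holdout <- function(x_train, y_train, x_test, y_test, vars, spec) {
  if (length(vars) == 0L)
    return(list(skipped = TRUE, reason = "empty stable set"))
  fit <- fit_forest(x_train[, vars, drop = FALSE], y_train, spec)
  pred <- stats::predict(fit$model,
                         data = as.data.frame(x_test[, vars, drop = FALSE]))$predictions
  if (spec$task == "regression") {
    r2 <- 1 - sum((y_test - pred)^2) / sum((y_test - mean(y_test))^2)
    list(skipped = FALSE, r_squared = r2)
  } else {
    list(skipped = FALSE, class_error = mean(pred != y_test))
  }
}

#' Nested cross-validation stability selection
#'
#' Runs the module-one procedure on a dataset: for every outer rotation the
#' outer training data is split into a tuning subset (`1/inner_folds`) used
#' for hyperparameter optimisation and a selection subset hosting
#' `n_iterations` independently seeded runs of each requested method.
#' Per-variable selection counts are averaged across rotations into a
#' frequency table; the low- and high-stringency stable sets are read off the
#' averaged counts; and a validation forest restricted to each stable set is
#' trained on the outer training data and scored on the held-out outer test
#' fold of every rotation.
#'
#' @param data A `sim_dataset` (or any list with `X`, and `y` or `y_class`).
#' @param methods Character vector from
#'   `c("boruta", "perm_raw", "perm_corrected", "rfe")`.
#' @param plan A [nested_cv_plan()].
#' @param task `"regression"` (uses `data$y`) or `"classification"` (uses
#'   `data$y_class`).
#' @param n_trees Trees per forest in the selection iterations, default 500.
#' @param selector_args Named list of per-method argument lists, e.g.
#'   `list(perm_raw = list(n_perm = 100))`.
#' @param spec_grid Optional list of [forest_spec()] candidates for tuning;
#'   `NULL` uses [default_spec_grid()].
#' @return An object of class `stability_report`: `frequency` (methods x
#'   variables averaged selection counts), `ls_sets`, `hs_sets`, `truth_eval`
#'   (TP/FP per method and stringency, when truth labels are present),
#'   `validation` (per rotation, method and stringency) and `plan`.
#' @export
run_stability <- function(data, methods = c("boruta", "rfe"), plan,
                          task = c("regression", "classification"),
                          n_trees = 500L, selector_args = list(),
                          spec_grid = NULL) {
  stopifnot(inherits(plan, "nested_cv_plan"))
  task <- match.arg(task)
  methods <- match.arg(methods,
                       c("boruta", "perm_raw", "perm_corrected", "rfe"),
                       several.ok = TRUE)
  X <- as.matrix(data$X)
  y <- if (task == "regression") data$y else data$y_class
  if (is.null(y))
    stop("run_stability: dataset has no outcome for task '", task, "'",
         call. = FALSE)
  y <- as_outcome(y, task)
  n <- nrow(X)
  vars <- colnames(X)
  splits <- make_outer_splits(n, plan)

  counts <- array(0, dim = c(length(methods), length(vars),
                             plan$outer_rotations),
                  dimnames = list(methods, vars, NULL))
  validation <- list()

  for (rot in seq_along(splits)) {
    tr <- splits[[rot]]$train; te <- splits[[rot]]$test
    set.seed(plan$seed + 1000L * rot)
    tune_idx <- sample(tr, size = max(2L, round(length(tr) / plan$inner_folds)))
    sel_idx <- setdiff(tr, tune_idx)

    grid <- if (is.null(spec_grid))
      default_spec_grid(ncol(X), task = task, n_trees = n_trees,
                        seed = plan$seed + rot)
    else spec_grid
    tuned <- tryCatch(tune_hyperparameters(X[tune_idx, , drop = FALSE],
                                           y[tune_idx], grid),
                      error = function(e) grid[[1L]])

    for (it in seq_len(plan$n_iterations)) {
      it_seed <- plan$seed + 100000L * rot + 97L * it
      it_spec <- forest_spec(task = task, n_trees = n_trees, mtry = tuned$mtry,
                             min_node_size = tuned$min_node_size,
                             seed = it_seed)
      for (mth in methods) {
        out <- run_selector(mth, X[sel_idx, , drop = FALSE], y[sel_idx],
                            it_spec, args = selector_args[[mth]] %||% list())
        counts[mth, out$selected, rot] <- counts[mth, out$selected, rot] + 1
      }
    }

    val_spec <- forest_spec(task = task, n_trees = n_trees, mtry = NULL,
                            min_node_size = tuned$min_node_size,
                            seed = plan$seed + rot)
    for (mth in methods) {
      ls_rot <- vars[counts[mth, , rot] > plan$ls_threshold]
      hs_rot <- vars[counts[mth, , rot] >= plan$hs_threshold]
      validation[[length(validation) + 1L]] <- c(
        list(rotation = rot, method = mth),
        list(ls = validate_on_holdout(X[tr, , drop = FALSE], y[tr],
                                      X[te, , drop = FALSE], y[te],
                                      ls_rot, val_spec),
             hs = validate_on_holdout(X[tr, , drop = FALSE], y[tr],
                                      X[te, , drop = FALSE], y[te],
                                      hs_rot, val_spec)))
    }
  }

  frequency <- apply(counts, c(1L, 2L), mean)
  ls_sets <- lapply(methods, function(m) vars[frequency[m, ] > plan$ls_threshold])
  hs_sets <- lapply(methods, function(m) vars[frequency[m, ] >= plan$hs_threshold])
  names(ls_sets) <- names(hs_sets) <- methods

  truth_eval <- NULL
  if (!is.null(data$truth)) {
    truth_eval <- lapply(methods, function(m)
      list(ls = evaluate_truth(ls_sets[[m]], data$truth),
           hs = evaluate_truth(hs_sets[[m]], data$truth)))
    names(truth_eval) <- methods
  }

  structure(list(frequency = frequency, counts = counts,
                 ls_sets = ls_sets, hs_sets = hs_sets,
                 truth_eval = truth_eval, validation = validation,
                 methods = methods, task = task, plan = plan),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report>", x$task, "-", ncol(x$frequency), "variables,",
      x$plan$n_iterations, "iterations x", x$plan$outer_rotations,
      "rotations\n")
  for (m in x$methods) {
    cat(sprintf("  %-14s LS: %3d vars  HS: %3d vars", m,
                length(x$ls_sets[[m]]), length(x$hs_sets[[m]])))
    if (!is.null(x$truth_eval))
      cat(sprintf("  (HS TP/FP: %d/%d)", x$truth_eval[[m]]$hs$tp,
                  x$truth_eval[[m]]$hs$fp))
    cat("\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
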