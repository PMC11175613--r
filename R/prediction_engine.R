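# Nested 5x5 cross-validated prediction engine.
#
# For each outer fold: (1) tune one Elastic Net per feature set by
# inner-fold grid search and refit it on the whole outer-training set;
# (2) use the refitted models' in-sample predictions on the outer-training
# rows as stacking features and tune one stacked Elastic Net per stack
# specification on fresh inner folds; (3) apply everything to the held-out
# outer-fold test set. Pooled outer-test predictions are the Brain Age /
# Brain Cognition values used downstream.

#' Default stacked-model specifications
#'
#' Resolves the eight canonical stacked-model memberships from the
#' modality tags of the feature sets: All; All excluding Task FC; All
#' excluding Task Contrast; Non-Task (resting-state FC + structural);
#' Resting and Task FC; Task Contrast and FC; Task Contrast; Task FC.
#'
#' @param tags named character vector mapping feature-set name to one of
#'   `"task_contrast"`, `"task_fc"`, `"rest_fc"`, `"smri"`.
#' @return named list of character vectors (member feature sets).
#' @export
default_stack_specs <- function(tags) {
  all_sets <- names(tags)
  specs <- list(
    stack_all = all_sets,
    stack_all_excl_task_fc = all_sets[tags != "task_fc"],
    stack_all_excl_task_contrast = all_sets[tags != "task_contrast"],
    stack_non_task = all_sets[tags %in% c("rest_fc", "smri")],
    stack_rest_task_fc = all_sets[tags %in% c("rest_fc", "task_fc")],
    stack_task_contrast_fc = all_sets[tags %in% c("task_contrast",
                                                  "task_fc")],
    stack_task_contrast = all_sets[tags == "task_contrast"],
    stack_task_fc = all_sets[tags == "task_fc"]
  )
  specs[vapply(specs, length, integer(1)) > 0L]
}

.check_alignment <- function(features, ids) {
  for (nm in names(features)) {
    x <- features[[nm]]
    if (is.null(rownames(x)) || !setequal(rownames(x), ids))
      stop(sprintf("feature set '%s' is missing participants present in the cohort",
                   nm), call. = FALSE)
    if (anyNA(x))
      stop(sprintf("feature set '%s' contains missing values", nm),
           call. = FALSE)
  }
}

#' Level-1 models: one tuned Elastic Net per feature set per outer fold
#'
#' For every outer fold and feature set, hyperparameters are tuned by
#' inner-fold grid search on the outer-training set only, the tuned
#' configuration is refitted on the full outer-training set, and
#' predictions are emitted for both the outer-training rows (used as
#' stacking features) and the outer-fold test rows.
#'
#' @param features named list of raw feature matrices (rows = participant
#'   ids).
#' @param target numeric target named by participant id (chronological age
#'   or fluid cognition).
#' @param sex binary sex vector named by participant id.
#' @param scheme a [make_fold_scheme()] result.
#' @param grid a [hyper_grid()].
#' @param kinds named character vector (`"direct"`/`"connectivity"`) per
#'   set; defaults to the `kind` attribute of each matrix.
#' @param n_components PCA dimension for connectivity sets.
#' @param sex_before_pca alternative preprocessing order switch.
#' @param thresh glmnet threshold for the grid search.
#' @param verbose print progress.
#' @return a list of class `level1_result`: `sets[[set]]$folds[[f]]` holds
#'   the `tuned_model`, named `train_pred` and `test_pred`, and per-fold
#'   test metrics.
#' @export
run_level1 <- function(features, target, sex, scheme, grid,
                       kinds = NULL, n_components = 75L,
                       sex_before_pca = FALSE, thresh = 1e-8,
                       verbose = FALSE) {
  stopifnot(inherits(scheme, "fold_scheme"))
  ids <- scheme$ids
  .check_alignment(features, ids)
  if (!setequal(names(target), ids) || !setequal(names(sex), ids))
    stop("target and sex must be named by the scheme's participant ids",
         call. = FALSE)
  if (anyNA(target)) stop("target contains missing values", call. = FALSE)
  if (is.null(kinds))
    kinds <- vapply(features, function(x) {
      k <- attr(x, "kind"); if (is.null(k)) "direct" else k
    }, character(1))
  sets <- vector("list", length(features))
  names(sets) <- names(features)
  for (nm in names(features)) {
    x_all <- features[[nm]][ids, , drop = FALSE]
    folds <- vector("list", scheme$k_outer)
    for (f in seq_len(scheme$k_outer)) {
      tr_ids <- ids[scheme$outer != f]
      te_ids <- ids[scheme$outer == f]
      tm <- grid_search(x_all[tr_ids, , drop = FALSE], target[tr_ids],
                        sex[tr_ids], scheme$inner[[f]]$stage1, grid,
                        kind = kinds[[nm]], n_components = n_components,
                        sex_before_pca = sex_before_pca, thresh = thresh,
                        fit_fold_id = paste0("outer", f))
      train_pred <- predict(tm, x_all[tr_ids, , drop = FALSE], sex[tr_ids])
      test_pred <- predict(tm, x_all[te_ids, , drop = FALSE], sex[te_ids])
      folds[[f]] <- list(tuned = tm,
                         train_pred = train_pred,
                         test_pred = test_pred,
                         test_metrics = prediction_metrics(target[te_ids],
                                                           test_pred))
      if (verbose)
        message(sprintf("level1 %-24s fold %d: r2=%.3f (alpha=%.3g l1=%.2f)",
                        nm, f, folds[[f]]$test_metrics["r2"], tm$alpha,
                        tm$l1_ratio))
    }
    sets[[nm]] <- list(folds = folds, kind = kinds[[nm]])
  }
  structure(list(sets = sets, target = target, scheme = scheme),
            class = "level1_result")
}

.stack_design <- function(level1, members, fold, which_pred) {
  cols <- lapply(members, function(s) {
    fl <- level1$sets[[s]]
    if (is.null(fl))
      stop(sprintf("stack specification references unknown feature set '%s'",
                   s), call. = FALSE)
    fl$folds[[fold]][[which_pred]]
  })
  x <- do.call(cbind, cols)
  colnames(x) <- members
  x
}

#' Second-level stacked models
#'
#' For each outer fold and stack specification, builds the stacking design
#' matrix from the member sets' level-1 predictions on the outer-training
#' rows, tunes an Elastic Net on the stacking-stage inner folds, refits on
#' the full outer-training design, and predicts the outer-test rows from
#' their level-1 predictions. Stacking features are standardised with
#' training-fold parameters; no sex residualisation is applied at this
#' level (sex was removed from the brain features at level 1).
#'
#' @param level1 a [run_level1()] result.
#' @param scheme the same fold scheme.
#' @param grid a [hyper_grid()].
#' @param stack_specs named list of member-set vectors, e.g. from
#'   [default_stack_specs()].
#' @param thresh glmnet threshold.
#' @param verbose print progress.
#' @return a list of class `stack_result` shaped like `level1_result`.
#' @export
run_stacking <- function(level1, scheme, grid, stack_specs,
                         thresh = 1e-8, verbose = FALSE) {
  stopifnot(inherits(level1, "level1_result"))
  target <- level1$target
  ids <- scheme$ids
  sets <- vector("list", length(stack_specs))
  names(sets) <- names(stack_specs)
  for (nm in names(stack_specs)) {
    members <- stack_specs[[nm]]
    folds <- vector("list", scheme$k_outer)
    for (f in seq_len(scheme$k_outer)) {
      tr_ids <- ids[scheme$outer != f]
      te_ids <- ids[scheme$outer == f]
      xtr <- .stack_design(level1, members, f, "train_pred")[tr_ids, ,
                                                             drop = FALSE]
      xte <- .stack_design(level1, members, f, "test_pred")[te_ids, ,
                                                            drop = FALSE]
      tm <- grid_search(xtr, target[tr_ids], sex = NULL,
                        scheme$inner[[f]]$stage2, grid, kind = "direct",
                        thresh = thresh, fit_fold_id = paste0("outer", f))
      train_pred <- predict(tm, xtr)
      test_pred <- predict(tm, xte)
      folds[[f]] <- list(tuned = tm,
                         train_pred = train_pred,
                         test_pred = test_pred,
                         test_metrics = prediction_metrics(target[te_ids],
                                                           test_pred))
      if (verbose)
        message(sprintf("stack  %-24s fold %d: r2=%.3f", nm, f,
                        folds[[f]]$test_metrics["r2"]))
    }
    sets[[nm]] <- list(folds = folds, members = members, kind = "stack")
  }
  structure(list(sets = sets, target = target, scheme = scheme),
            class = "stack_result")
}

#' Assemble out-of-fold predictions for every model
#'
#' Pools each model's outer-fold test predictions into one out-of-fold
#' vector (every participant predicted exactly once, by the model trained
#' without that participant's fold) and collects per-fold metrics and
#' chosen hyperparameters. With the full default registry of 18 feature
#' sets and 8 stacks this yields 26 models per target.
#'
#' @param level1 a [run_level1()] result.
#' @param stacked optional [run_stacking()] result.
#' @return a list of class `prediction_results`: element `models` is a
#'   named list with, per model, `out_of_fold` (named vector),
#'   `per_fold` data frame (fold, pearson_r, r2, mae, alpha, l1_ratio) and
#'   `folds` (train/test predictions per fold); element `summary` is a data
#'   frame of mean per-fold metrics.
#' @export
assemble_out_of_fold <- function(level1, stacked = NULL) {
  scheme <- level1$scheme
  target <- level1$target
  ids <- scheme$ids
  all_sets <- level1$sets
  if (!is.null(stacked)) all_sets <- c(all_sets, stacked$sets)
  models <- vector("list", length(all_sets))
  names(models) <- names(all_sets)
  for (nm in names(all_sets)) {
    fl <- all_sets[[nm]]$folds
    oof <- rep(NA_real_, length(ids))
    names(oof) <- ids
    pf <- data.frame()
    for (f in seq_along(fl)) {
      te_ids <- names(fl[[f]]$test_pred)
      oof[te_ids] <- fl[[f]]$test_pred
      m <- fl[[f]]$test_metrics
      pf <- rbind(pf, data.frame(fold = f, pearson_r = m["pearson_r"],
                                 r2 = m["r2"], mae = m["mae"],
                                 alpha = fl[[f]]$tuned$alpha,
                                 l1_ratio = fl[[f]]$tuned$l1_ratio,
                                 row.names = NULL))
    }
    if (anyNA(oof))
      stop(sprintf("model '%s': some participants lack an out-of-fold prediction",
                   nm), call. = FALSE)
    models[[nm]] <- list(name = nm, out_of_fold = oof, per_fold = pf,
                         folds = fl)
  }
  summary <- do.call(rbind, lapply(models, function(m) {
    data.frame(model = m$name,
               mean_r = mean(m$per_fold$pearson_r),
               mean_r2 = mean(m$per_fold$r2),
               mean_mae = mean(m$per_fold$mae),
               row.names = NULL)
  }))
  structure(list(models = models, summary = summary, target = target,
                 scheme = scheme),
            class = "prediction_results")
}

#' Feature importance from a refit on the full data
#'
#' Tunes the Elastic Net on the full dataset (inner-CV-style grid search
#' without an outer split) and reports coefficients as importance. For
#' connectivity sets the 75 component coefficients are back-projected to
#' region pairs: importance of pair j = sum over components of
#' `|loading_cj| * coefficient_c`.
#'
#' @param x raw feature matrix for all participants.
#' @param target named target vector.
#' @param sex named binary sex vector.
#' @param grid a [hyper_grid()].
#' @param kind,n_components as in [fit_preproc()].
#' @param k_inner folds for the tuning search.
#' @param seed seed for the tuning fold assignment.
#' @return list of class `importance_table`: `importance` (named numeric,
#'   one value per input feature or region pair) and `tuned` model.
#' @export
refit_importance <- function(x, target, sex, grid, kind = "direct",
                             n_components = 75L, k_inner = 5L, seed = 1L) {
  x <- as.matrix(x)
  ids <- rownames(x)
  assign <- withr::with_seed(as.integer(seed), .partition(ids, k_inner))
  tm <- grid_search(x, target[ids], sex[ids], assign, grid, kind = kind,
                    n_components = n_components, fit_fold_id = "full")
  if (kind == "connectivity") {
    rot <- tm$preproc$pca$rotation[, tm$preproc$kept, drop = FALSE]
    imp <- as.numeric(abs(rot) %*% tm$coefficients)
    names(imp) <- rownames(rot)
  } else {
    imp <- tm$coefficients
  }
  structure(list(importance = imp, tuned = tm), class = "importance_table")
}

#' Rank stability of feature importance across outer folds
#'
#' Spearman rank correlation of per-fold coefficient vectors for every
#' unordered pair of outer folds; five folds yield choose(5, 2) = 10 rhos.
#' Pairs involving a constant vector are undefined and reported as `NA`.
#'
#' @param coef_list list of equal-length numeric vectors, one per fold.
#' @return data frame with columns `fold_i`, `fold_j`, `rho`.
#' @export
importance_stability <- function(coef_list) {
  k <- length(coef_list)
  len <- unique(vapply(coef_list, length, integer(1)))
  if (length(len) != 1L)
    stop("coefficient vectors must have equal length", call. = FALSE)
  pairs <- combn(k, 2)
  rho <- apply(pairs, 2, function(ij) {
    a <- coef_list[[ij[1]]]; b <- coef_list[[ij[2]]]
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b, method = "spearman")
  })
  data.frame(fold_i = pairs[1, ], fold_j = pairs[2, ], rho = rho)
}
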