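# Brain Age indices from out-of-fold age predictions.
#
# Brain Age           = out-of-fold predicted age
# Brain Age Gap       = Brain Age - chronological age
# Corrected Brain Age = (Brain Age - beta0) / beta1, where (beta0, beta1)
#                       are the intercept/slope of the training-fold OLS of
#                       Brain Age on chronological age (regression-to-the-
#                       mean de-biasing)
# Corrected Brain Age Gap = Corrected Brain Age - chronological age

#' Brain Age Gap
#' @param brain_age,age numeric vectors in years.
#' @return `brain_age - age`.
#' @export
brain_age_gap <- function(brain_age, age) {
  if (any(!is.finite(brain_age)) || any(!is.finite(age)))
    stop("non-finite inputs", call. = FALSE)
  brain_age - age
}

#' Fit the age-bias regression in a training fold
#'
#' OLS of Brain Age on chronological age, fitted on training-fold rows
#' only; its slope and intercept de-bias the corresponding test fold.
#'
#' @param train_brain_age,train_age training-fold vectors (>= 3 rows, age
#'   not constant).
#' @param tolerance minimum `|slope|`; below it the correction is
#'   undefined and an error is raised.
#' @param fit_fold_id identifier recorded with the fit.
#' @return list of class `bias_model` with `beta0`, `beta1`,
#'   `fit_fold_id`.
#' @export
fit_bias <- function(train_brain_age, train_age, tolerance = 1e-6,
                     fit_fold_id = NA) {
  if (length(train_age) < 3L)
    stop("need at least 3 training rows to fit the bias line",
         call. = FALSE)
  if (sd(train_age) == 0)
    stop("chronological age is constant in the training fold",
         call. = FALSE)
  cf <- lm.fit(cbind(1, train_age), train_brain_age)$coefficients
  if (abs(cf[2]) < tolerance)
    stop("constant-prediction degenerate: correction undefined",
         call. = FALSE)
  structure(list(beta0 = unname(cf[1]), beta1 = unname(cf[2]),
                 fit_fold_id = fit_fold_id),
            class = "bias_model")
}

#' De-bias Brain Age with a fitted bias model
#' @param brain_age predicted ages (years), typically test-fold values.
#' @param bias a [fit_bias()] result.
#' @return `(brain_age - beta0) / beta1`.
#' @export
corrected_brain_age <- function(brain_age, bias) {
  stopifnot(inherits(bias, "bias_model"))
  (brain_age - bias$beta0) / bias$beta1
}

#' Build the per-participant index table for one model
#'
#' Combines out-of-fold Brain Age and Brain Cognition with chronological
#' age and fluid cognition into one table, applying the bias correction
#' fold-wise: the bias line is fitted on each outer-training set's
#' in-sample Brain Age predictions and applied to the corresponding
#' outer-fold test set.
#'
#' @param age_model one model element from an age-target
#'   [assemble_out_of_fold()] result (`$models[[name]]`).
#' @param cognition_model matching model element from the cognition-target
#'   results (or `NULL` to omit Brain Cognition).
#' @param cohort cohort data frame with `participant_id`, `age`,
#'   `fluid_cognition`.
#' @param scheme the fold scheme used for both targets.
#' @return data frame of class `index_table` with one row per participant:
#'   `participant_id`, `age`, `fluid_cognition`, `brain_age`,
#'   `brain_age_gap`, `corrected_brain_age`, `corrected_brain_age_gap`,
#'   `brain_cognition`, `outer_fold`.
#' @export
build_index_table <- function(age_model, cognition_model = NULL, cohort,
                              scheme) {
  stopifnot(inherits(scheme, "fold_scheme"))
  ids <- scheme$ids
  if (!setequal(cohort$participant_id, ids))
    stop("cohort does not match the fold scheme", call. = FALSE)
  age <- stats::setNames(cohort$age, cohort$participant_id)[ids]
  cog <- stats::setNames(cohort$fluid_cognition,
                         cohort$participant_id)[ids]
  ba <- age_model$out_of_fold[ids]
  corrected <- rep(NA_real_, length(ids))
  names(corrected) <- ids
  for (f in seq_len(scheme$k_outer)) {
    fold <- age_model$folds[[f]]
    tr_ids <- names(fold$train_pred)
    te_ids <- names(fold$test_pred)
    if (!setequal(te_ids, ids[scheme$outer == f]))
      stop("fold mismatch between predictions and scheme", call. = FALSE)
    bias <- fit_bias(fold$train_pred, age[tr_ids],
                     fit_fold_id = paste0("outer", f))
    corrected[te_ids] <- corrected_brain_age(fold$test_pred, bias)
  }
  bc <- if (is.null(cognition_model)) rep(NA_real_, length(ids))
        else cognition_model$out_of_fold[ids]
  out <- data.frame(participant_id = ids,
                    age = unname(age),
                    fluid_cognition = unname(cog),
                    brain_age = unname(ba),
                    brain_age_gap = unname(ba - age),
                    corrected_brain_age = unname(corrected),
                    corrected_brain_age_gap = unname(corrected - age),
                    brain_cognition = unname(bc),
                    outer_fold = unname(scheme$outer[ids]),
                    stringsAsFactors = FALSE)
  class(out) <- c("index_table", "data.frame")
  out
}
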