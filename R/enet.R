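# Elastic Net under the objective
#   argmin_b ||y - Xb||^2 / (2 n) + alpha * l1 * ||b||_1
#                                 + 0.5 * alpha * (1 - l1) * ||b||_2^2
# solved through glmnet. glmnet parameterises the penalty on the scale of
# the response standardised by its 1/n standard deviation, so the exact
# correspondence is
#   lambda_glmnet = alpha * (l1 + (1 - l1) * sd_n(y))
#   alpha_glmnet  = l1 / (l1 + (1 - l1) * sd_n(y))
# (verified against closed-form ridge and an independent coordinate-descent
# solver in the test suite). Single-column designs, which glmnet rejects,
# are solved by the exact univariate soft-threshold solution.

.sd_n <- function(y) sqrt(mean((y - mean(y))^2))

.glmnet_map <- function(y, l1_ratio) {
  s <- .sd_n(y)
  fac <- l1_ratio + (1 - l1_ratio) * s
  list(fac = fac, alpha_g = if (fac > 0) l1_ratio / fac else 1)
}

#' Hyperparameter grid for the Elastic Net search
#'
#' Defaults follow the study grid: 70 penalty strengths log10-spaced over
#' `[0.1, 100]` and 25 mixing ratios linearly spaced over `[0, 1]`
#' (0 = ridge, 1 = lasso), endpoints inclusive.
#'
#' @param n_alpha,alpha_range penalty grid size and range.
#' @param n_l1,l1_range mixing-ratio grid size and range.
#' @return an object of class `hyper_grid` with strictly increasing `alphas`
#'   and `l1_ratios`.
#' @export
hyper_grid <- function(n_alpha = 70L, alpha_range = c(0.1, 100),
                       n_l1 = 25L, l1_range = c(0, 1)) {
  alphas <- 10^seq(log10(alpha_range[1]), log10(alpha_range[2]),
                   length.out = n_alpha)
  l1_ratios <- seq(l1_range[1], l1_range[2], length.out = n_l1)
  if (n_alpha < 1L || n_l1 < 1L) stop("empty hyperparameter grid")
  structure(list(alphas = alphas, l1_ratios = l1_ratios),
            class = "hyper_grid")
}

#' Reduced grid for demonstrations and tests (7 x 5 points)
#' @return a `hyper_grid`.
#' @export
reduced_grid <- function() hyper_grid(n_alpha = 7L, n_l1 = 5L)

.enet_fit1 <- function(x, y, alpha, l1_ratio) {
  # exact univariate solution
  xc <- x - mean(x); yc <- y - mean(y)
  vx <- mean(xc^2); cxy <- mean(xc * yc)
  z <- sign(cxy) * max(abs(cxy) - alpha * l1_ratio, 0)
  b <- if (vx + alpha * (1 - l1_ratio) > 0)
    z / (vx + alpha * (1 - l1_ratio)) else 0
  list(coefficients = stats::setNames(b, colnames(x)),
       intercept = unname(mean(y) - b * mean(x)))
}

#' Fit an Elastic Net at one grid point
#'
#' Minimises `||y - Xb||^2 / (2n) + alpha*l1_ratio*||b||_1 +
#' 0.5*alpha*(1-l1_ratio)*||b||_2^2` with an unpenalised intercept.
#' Features are expected to be standardised already; no internal
#' standardisation is applied.
#'
#' @param x numeric feature matrix (column-standardised upstream).
#' @param y numeric target.
#' @param alpha penalty strength (>= 0).
#' @param l1_ratio lasso/ridge mixing in `[0, 1]`.
#' @param thresh glmnet convergence threshold.
#' @return list with `coefficients` (named) and `intercept`.
#' @export
enet_fit <- function(x, y, alpha, l1_ratio, thresh = 1e-12) {
  x <- as.matrix(x)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in features or target", call. = FALSE)
  if (alpha < 0 || l1_ratio < 0 || l1_ratio > 1)
    stop("alpha must be >= 0 and l1_ratio in [0, 1]", call. = FALSE)
  if (ncol(x) == 1L) return(.enet_fit1(x, y, alpha, l1_ratio))
  map <- .glmnet_map(y, l1_ratio)
  if (map$fac == 0 || alpha == 0) {
    # unpenalised least squares
    fit <- lm.fit(cbind(1, x), y)
    b <- fit$coefficients
    b[is.na(b)] <- 0
    return(list(coefficients = stats::setNames(b[-1], colnames(x)),
                intercept = b[1]))
  }
  lam <- alpha * map$fac
  # short warm-start path down to the target penalty
  path <- sort(unique(lam * c(1000, 100, 10, 3, 1)), decreasing = TRUE)
  fit <- glmnet::glmnet(x, y, alpha = map$alpha_g, lambda = path,
                        standardize = FALSE, thresh = thresh, maxit = 1e7)
  cf <- coef(fit)[, length(path)]
  list(coefficients = stats::setNames(unname(cf[-1]), colnames(x)),
       intercept = unname(cf[1]))
}

.enet_predict <- function(fit, x) {
  nm <- names(fit$coefficients)
  if (!is.null(nm) && !is.null(colnames(x)))
    x <- x[, nm, drop = FALSE]
  stopifnot(ncol(x) == length(fit$coefficients))
  as.numeric(x %*% fit$coefficients) + fit$intercept
}

# fit the whole alpha path for one l1_ratio; returns a (p+1) x n_alpha
# coefficient matrix (intercept first), columns in the order of `alphas`
.enet_path <- function(x, y, alphas, l1_ratio, thresh = 1e-8) {
  if (ncol(x) == 1L) {
    cf <- vapply(alphas, function(a) {
      f <- .enet_fit1(x, y, a, l1_ratio)
      c(f$intercept, f$coefficients)
    }, numeric(2))
    return(cf)
  }
  map <- .glmnet_map(y, l1_ratio)
  if (map$fac == 0) {
    b <- rep(0, ncol(x))
    return(matrix(c(mean(y), b), ncol(x) + 1L, length(alphas)))
  }
  lam <- alphas * map$fac
  ord <- order(lam, decreasing = TRUE)
  fit <- glmnet::glmnet(x, y, alpha = map$alpha_g, lambda = lam[ord],
                        standardize = FALSE, thresh = thresh, maxit = 1e6)
  cf <- as.matrix(coef(fit))
  # glmnet may drop path points it deems redundant; map back by lambda
  got <- fit$lambda
  idx <- vapply(lam, function(l) which.min(abs(got - l)), integer(1))
  cf[, idx, drop = FALSE]
}

#' Prediction metrics: Pearson r, sum-of-squares R2, MAE
#'
#' `r2 = 1 - SS_res / SS_tot` (may be negative on test folds and is reported
#' unclipped). When the predictions are constant, `pearson_r` is undefined
#' and reported as `NA`; `r2` and `mae` are still computed.
#'
#' @param observed,predicted equal-length numeric vectors (length >= 2).
#' @return named numeric vector `(pearson_r, r2, mae)`.
#' @export
prediction_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2L)
    stop("observed and predicted must have equal length >= 2", call. = FALSE)
  r <- if (sd(predicted) == 0 || sd(observed) == 0) NA_real_
       else cor(observed, predicted)
  r2 <- 1 - sum((observed - predicted)^2) /
    sum((observed - mean(observed))^2)
  c(pearson_r = r, r2 = r2, mae = mean(abs(observed - predicted)))
}

#' Inner-cross-validated grid search for one model
#'
#' Fits every `(alpha, l1_ratio)` grid point on each inner-training set,
#' with preprocessing re-fitted per inner fold (no parameters leak from the
#' validation rows), scores the inner-validation sets with sum-of-squares
#' R2, selects the grid point with the highest mean validation R2 (ties
#' broken by the first point in ascending `(alpha, l1_ratio)` order), then
#' refits preprocessing and model on all supplied rows.
#'
#' @param x raw (untransformed) feature matrix for the outer-training rows.
#' @param y target for the same rows.
#' @param sex binary sex vector, or `NULL` to skip residualisation.
#' @param inner_assign named inner-fold assignment covering the rows of `x`.
#' @param grid a [hyper_grid()].
#' @param kind,n_components,sex_before_pca passed to [fit_preproc()].
#' @param thresh glmnet threshold used during the search.
#' @param fit_fold_id recorded in the refitted preprocessing parameters.
#' @return an object of class `tuned_model`: `alpha`, `l1_ratio`,
#'   `validation_score` (mean inner-fold R2), `score_grid`, `preproc`,
#'   `coefficients`, `intercept`.
#' @export
grid_search <- function(x, y, sex = NULL, inner_assign, grid,
                        kind = "direct", n_components = 75L,
                        sex_before_pca = FALSE, thresh = 1e-8,
                        fit_fold_id = NA) {
  stopifnot(inherits(grid, "hyper_grid"))
  x <- as.matrix(x)
  ids <- rownames(x)
  if (!setequal(names(inner_assign), ids))
    stop("inner fold assignment must partition the rows of x", call. = FALSE)
  folds <- inner_assign[ids]
  k <- max(folds)
  n_a <- length(grid$alphas); n_l <- length(grid$l1_ratios)
  score <- matrix(0, n_a, n_l,
                  dimnames = list(signif(grid$alphas, 6),
                                  signif(grid$l1_ratios, 6)))
  nfold_used <- 0L
  for (f in seq_len(k)) {
    tr <- folds != f
    if (sum(tr) < 2L || sum(!tr) < 1L) next
    pp <- suppressWarnings(
      fit_preproc(x[tr, , drop = FALSE],
                  if (is.null(sex)) NULL else sex[tr],
                  kind = kind, n_components = n_components,
                  sex_before_pca = sex_before_pca,
                  fit_fold_id = paste0("inner", f)))
    xtr <- apply_preproc(x[tr, , drop = FALSE],
                         if (is.null(sex)) NULL else sex[tr], pp)
    xva <- apply_preproc(x[!tr, , drop = FALSE],
                         if (is.null(sex)) NULL else sex[!tr], pp)
    ytr <- y[tr]; yva <- y[!tr]
    sst <- sum((yva - mean(yva))^2)
    for (j in seq_len(n_l)) {
      cf <- .enet_path(xtr, ytr, grid$alphas, grid$l1_ratios[j], thresh)
      pred <- cbind(1, xva) %*% cf
      ssr <- colSums((yva - pred)^2)
      score[, j] <- score[, j] + (1 - ssr / sst)
    }
    nfold_used <- nfold_used + 1L
  }
  if (nfold_used == 0L) stop("no usable inner folds", call. = FALSE)
  score <- score / nfold_used
  best <- max(score)
  # ties: first point in (alpha ascending, l1_ratio ascending) order
  hit <- which(score == best, arr.ind = TRUE)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  ia <- hit[1, 1]; il <- hit[1, 2]
  pp <- suppressWarnings(
    fit_preproc(x, sex, kind = kind, n_components = n_components,
                sex_before_pca = sex_before_pca, fit_fold_id = fit_fold_id))
  xt <- apply_preproc(x, sex, pp)
  fit <- enet_fit(xt, y, grid$alphas[ia], grid$l1_ratios[il])
  structure(list(alpha = grid$alphas[ia],
                 l1_ratio = grid$l1_ratios[il],
                 validation_score = best,
                 score_grid = score,
                 preproc = pp,
                 coefficients = fit$coefficients,
                 intercept = fit$intercept,
                 fit_fold_id = fit_fold_id),
            class = "tuned_model")
}

#' Predict from a tuned model (preprocessing + Elastic Net)
#'
#' @param object a `tuned_model` from [grid_search()].
#' @param newdata raw feature matrix.
#' @param sex binary sex vector aligned to `newdata`, or `NULL`.
#' @param ... unused.
#' @return numeric predictions named by row.
#' @export
predict.tuned_model <- function(object, newdata, sex = NULL, ...) {
  xt <- apply_preproc(as.matrix(newdata), sex, object$preproc)
  stats::setNames(.enet_predict(object, xt), rownames(newdata))
}
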