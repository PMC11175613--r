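# Training-fold-anchored preprocessing with strict train-to-test parameter
# transfer: (optional PCA for connectivity-like sets) -> residualisation of
# biological sex -> centering/scaling. Every parameter is a pure function of
# the training rows; apply_preproc() only replays stored parameters.

#' Fisher r-to-z transformation
#'
#' @param r correlation value(s), `|r| < 1`.
#' @return `atanh(r)`.
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    stop("fisher_z is defined only for |r| < 1", call. = FALSE)
  atanh(r)
}

#' Vectorise the unique off-diagonal entries of a symmetric matrix
#'
#' Returns the `p*(p-1)/2` upper-triangle entries in row-major order:
#' (1,2), (1,3), ..., (1,p), (2,3), ... — the documented ordering used for
#' connectivity feature tables.
#'
#' @param m symmetric `p x p` matrix (e.g. a region-by-region correlation
#'   matrix with unit diagonal).
#' @param tol symmetry tolerance.
#' @return numeric vector of length `p*(p-1)/2`, named `r<i>_r<j>` (or from
#'   `rownames(m)` when present).
#' @export
vectorize_offdiagonal <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("input must be a square matrix", call. = FALSE)
  if (max(abs(m - t(m))) > tol)
    stop("input matrix is not symmetric", call. = FALSE)
  p <- nrow(m)
  ut <- upper.tri(m)
  # row-major upper triangle == column-major lower triangle of the transpose
  v <- t(m)[lower.tri(m)]
  idx <- which(ut, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  nms <- rownames(m)
  if (is.null(nms)) nms <- sprintf("r%03d", seq_len(p))
  names(v) <- paste0(nms[idx[, 1]], "_", nms[idx[, 2]])
  v
}

.fit_sex_residual <- function(x, sex) {
  # per-feature OLS on sex (intercept + slope), slopes zero when sex is
  # constant in the training rows
  if (is.null(sex)) {
    return(list(intercept = rep(0, ncol(x)), slope = rep(0, ncol(x))))
  }
  sexc <- sex - mean(sex)
  ssx <- sum(sexc^2)
  if (ssx < .Machine$double.eps) {
    slope <- rep(0, ncol(x))
  } else {
    slope <- as.numeric(crossprod(sexc, x)) / ssx
  }
  intercept <- colMeans(x) - slope * mean(sex)
  list(intercept = intercept, slope = slope)
}

#' Fit preprocessing parameters on a training partition
#'
#' For `kind = "connectivity"`: PCA (centered on training means, components
#' ordered by decreasing explained variance, sign fixed so each loading
#' vector's largest-magnitude entry is positive) is fitted first, then sex
#' residualisation and standardisation are fitted on the component scores.
#' For `kind = "direct"`: sex residualisation then standardisation on the
#' raw features. Zero-variance features are dropped with a warning.
#'
#' @param train_features training-row feature matrix.
#' @param train_sex binary sex vector for the training rows, or `NULL` to
#'   skip residualisation.
#' @param kind `"direct"` or `"connectivity"`.
#' @param n_components PCA dimension for connectivity sets (default 75);
#'   reduced to the available rank with a warning if it exceeds it.
#' @param sex_before_pca if `TRUE`, residualise sex from the raw features
#'   before the PCA instead of from the component scores.
#' @param fit_fold_id identifier recorded in the parameters.
#' @return an object of class `preproc_params`.
#' @export
fit_preproc <- function(train_features, train_sex = NULL,
                        kind = c("direct", "connectivity"),
                        n_components = 75L, sex_before_pca = FALSE,
                        fit_fold_id = NA) {
  kind <- match.arg(kind)
  x <- as.matrix(train_features)
  if (nrow(x) < 2L) stop("need at least 2 training rows", call. = FALSE)
  if (!is.null(train_sex) && length(train_sex) != nrow(x))
    stop("train_sex length must match training rows", call. = FALSE)
  sds0 <- apply(x, 2, sd)
  keep <- sds0 > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d zero-variance feature(s)", sum(!keep)))
    x <- x[, keep, drop = FALSE]
  }
  pca <- NULL
  pre_sex <- NULL
  if (kind == "connectivity") {
    if (sex_before_pca && !is.null(train_sex)) {
      pre_sex <- .fit_sex_residual(x, train_sex)
      x <- x - tcrossprod(rep(1, nrow(x)), pre_sex$intercept) -
        tcrossprod(train_sex, pre_sex$slope)
    }
    max_rank <- min(nrow(x) - 1L, ncol(x))
    k <- as.integer(n_components)
    if (k > max_rank) {
      warning(sprintf("n_components reduced from %d to available rank %d",
                      k, max_rank))
      k <- max_rank
    }
    ctr <- colMeans(x)
    xc <- sweep(x, 2, ctr)
    sv <- svd(xc, nu = 0, nv = k)
    rot <- sv$v[, seq_len(k), drop = FALSE]
    # deterministic sign: largest-|entry| of each loading vector positive
    flip <- apply(rot, 2, function(v) sign(v[which.max(abs(v))]))
    rot <- sweep(rot, 2, flip, `*`)
    rownames(rot) <- colnames(x)
    colnames(rot) <- sprintf("PC%03d", seq_len(k))
    pca <- list(center = ctr, rotation = rot)
    x <- xc %*% rot
  }
  sex_fit <- if (kind == "connectivity" && sex_before_pca) {
    list(intercept = rep(0, ncol(x)), slope = rep(0, ncol(x)))
  } else {
    .fit_sex_residual(x, train_sex)
  }
  res <- x - tcrossprod(rep(1, nrow(x)), sex_fit$intercept)
  if (!is.null(train_sex))
    res <- res - tcrossprod(train_sex, sex_fit$slope)
  ctr <- colMeans(res)
  scl <- apply(res, 2, sd)
  keep2 <- scl > 0
  if (!all(keep2)) {
    warning(sprintf("dropping %d zero-variance transformed feature(s)",
                    sum(!keep2)))
  }
  structure(list(kind = kind,
                 input_features = names(which(keep)),
                 pca = pca,
                 pre_sex = pre_sex,
                 sex_intercept = sex_fit$intercept[keep2],
                 sex_slope = sex_fit$slope[keep2],
                 feature_means = ctr[keep2],
                 feature_sds = scl[keep2],
                 kept = keep2,
                 n_components = if (is.null(pca)) NA_integer_
                                else ncol(pca$rotation),
                 fit_fold_id = fit_fold_id),
            class = "preproc_params")
}

#' Apply fitted preprocessing parameters to new rows
#'
#' Replays, using stored training-fold parameters only: PCA projection (for
#' connectivity sets), sex residualisation and centering/scaling. Test rows
#' transformed with training means generally do not have mean zero — that is
#' the transfer contract.
#'
#' @param features feature matrix whose columns match those the parameters
#'   were fitted on.
#' @param sex binary sex vector aligned to `features`, or `NULL`.
#' @param params a [fit_preproc()] result.
#' @return transformed matrix.
#' @export
apply_preproc <- function(features, sex = NULL, params) {
  stopifnot(inherits(params, "preproc_params"))
  x <- as.matrix(features)
  if (!all(params$input_features %in% colnames(x)))
    stop("feature columns do not match preprocessing parameters",
         call. = FALSE)
  x <- x[, params$input_features, drop = FALSE]
  if (!is.null(params$pre_sex)) {
    if (is.null(sex)) stop("sex vector required by these parameters")
    x <- x - tcrossprod(rep(1, nrow(x)), params$pre_sex$intercept) -
      tcrossprod(sex, params$pre_sex$slope)
  }
  if (!is.null(params$pca)) {
    x <- sweep(x, 2, params$pca$center) %*% params$pca$rotation
  }
  x <- x[, params$kept, drop = FALSE]
  x <- x - tcrossprod(rep(1, nrow(x)), params$sex_intercept)
  if (!is.null(sex))
    x <- x - tcrossprod(sex, params$sex_slope)
  x <- sweep(x, 2, params$feature_means)
  sweep(x, 2, params$feature_sds, `/`)
}

#' Serialise preprocessing parameters to JSON for audit
#'
#' @param params a `preproc_params`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_preproc_json <- function(params, path) {
  stopifnot(inherits(params, "preproc_params"))
  out <- list(kind = params$kind,
              fit_fold_id = params$fit_fold_id,
              n_components = params$n_components,
              sex_intercept = params$sex_intercept,
              sex_slope = params$sex_slope,
              feature_means = params$feature_means,
              feature_sds = params$feature_sds,
              pca_center = params$pca$center,
              pca_rotation = params$pca$rotation)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
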