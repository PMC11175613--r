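# Commonality analysis: decompose the R2 of a multiple regression
# explaining fluid cognition into unique effects (one per regressor block)
# and common effects (one per subset of two or more blocks), with
# hierarchical-regression F tests for the unique effects. All R2 here are
# in-sample, on the pooled out-of-fold table; these are explanatory
# regressions, not cross-validated predictions.

.block_matrix <- function(b) {
  m <- as.matrix(b)
  if (any(!is.finite(m))) stop("regressor block contains non-finite values",
                               call. = FALSE)
  m
}

#' In-sample R-squared of an OLS fit on one or more regressor blocks
#'
#' @param outcome numeric response.
#' @param blocks named list of regressor blocks (vectors or matrices
#'   treated as units, e.g. `list(age = age)` or
#'   `list(age = cbind(age, age^2))`).
#' @return R2 (`1 - SS_res/SS_tot`) of the intercept-included OLS fit on
#'   the concatenated columns.
#' @export
ols_r2 <- function(outcome, blocks) {
  if (!is.list(blocks)) blocks <- list(blocks)
  mats <- lapply(blocks, .block_matrix)
  design <- cbind(1, do.call(cbind, mats))
  n <- length(outcome)
  if (n <= ncol(design))
    stop("need more observations than regressors", call. = FALSE)
  # incremental rank check names the offending block
  run <- matrix(1, n, 1)
  for (i in seq_along(mats)) {
    cand <- cbind(run, mats[[i]])
    if (qr(cand)$rank < qr(run)$rank + ncol(mats[[i]]))
      stop(sprintf("rank-deficient design: block '%s' is collinear",
                   if (is.null(names(blocks)[i]) || names(blocks)[i] == "")
                     as.character(i) else names(blocks)[i]),
           call. = FALSE)
    run <- cand
  }
  fit <- lm.fit(design, outcome)
  1 - sum(fit$residuals^2) / sum((outcome - mean(outcome))^2)
}

# in-sample sum-of-squares R2 of a ridge fit (used by the ridge variant);
# columns standardised in-sample for penalty comparability
.ridge_r2 <- function(outcome, blocks, penalty) {
  x <- do.call(cbind, lapply(blocks, .block_matrix))
  x <- scale(x)
  fit <- enet_fit(x, outcome, alpha = penalty, l1_ratio = 0)
  pred <- .enet_predict(fit, x)
  1 - sum((outcome - pred)^2) / sum((outcome - mean(outcome))^2)
}

.subset_r2 <- function(outcome, blocks, r2_fun) {
  k <- length(blocks)
  subsets <- unlist(lapply(seq_len(k), function(m)
    combn(k, m, simplify = FALSE)), recursive = FALSE)
  r2 <- vapply(subsets, function(s) r2_fun(outcome, blocks[s]), numeric(1))
  names(r2) <- vapply(subsets, function(s)
    paste(names(blocks)[s], collapse = ","), character(1))
  list(subsets = subsets, r2 = r2)
}

.subset_key <- function(blocks, s) paste(names(blocks)[s], collapse = ",")

#' F test for an R-squared change between nested regression models
#'
#' `F = (n - k2 - 1) * delta_r2 / (k_change * (1 - r2_full))` with
#' `(k_change, n - k2 - 1)` degrees of freedom.
#'
#' @param r2_full R2 of the larger model (with `k2` regressors).
#' @param delta_r2 increase in R2 contributed by the `k_change` added
#'   regressors.
#' @param n number of observations.
#' @param k2 number of regressors in the larger model.
#' @param k_change number of added regressors.
#' @return named numeric vector `(f, p, df1, df2)`.
#' @export
f_change <- function(r2_full, delta_r2, n, k2, k_change) {
  if (r2_full >= 1) stop("full-model R2 must be below 1", call. = FALSE)
  if (delta_r2 < 0 || delta_r2 > r2_full)
    stop("delta_r2 must lie in [0, r2_full]", call. = FALSE)
  df2 <- n - k2 - 1
  f <- df2 * delta_r2 / (k_change * (1 - r2_full))
  c(f = f, p = pf(f, k_change, df2, lower.tail = FALSE), df1 = k_change,
    df2 = df2)
}

#' Commonality decomposition of a two- or three-block regression
#'
#' Computes the R2 of every non-empty subset model and returns the
#' closed-form decomposition: unique effects
#' `Delta R2_b = R2_full - R2_without_b`, pairwise common effects, and (for
#' three blocks) the triple common effect; the components sum to the full
#' model's R2. Unique effects carry hierarchical-regression F tests.
#'
#' @param outcome numeric response (fluid cognition).
#' @param blocks named list of 2 or 3 regressor blocks.
#' @param r2_fun function `(outcome, blocks) -> R2`; defaults to [ols_r2()].
#' @return an object of class `commonality_result`: `full_r2`, `components`
#'   (named: `unique_<b>`, `common_<b1>,<b2>`, ...), `subset_r2`,
#'   `f_change` data frame, `n`, `k2`, `rescaled = FALSE`.
#' @export
commonality <- function(outcome, blocks, r2_fun = ols_r2) {
  k <- length(blocks)
  if (!k %in% c(2L, 3L))
    stop("commonality is implemented for 2 or 3 regressor blocks",
         call. = FALSE)
  if (is.null(names(blocks)) || any(names(blocks) == ""))
    names(blocks) <- paste0("block", seq_len(k))
  sub <- .subset_r2(outcome, blocks, r2_fun)
  r2 <- sub$r2
  key <- function(...) .subset_key(blocks, c(...))
  nm <- names(blocks)
  if (k == 2L) {
    full <- r2[[key(1, 2)]]
    comp <- c(full - r2[[key(2)]],
              full - r2[[key(1)]],
              r2[[key(1)]] + r2[[key(2)]] - full)
    names(comp) <- c(paste0("unique_", nm[1]), paste0("unique_", nm[2]),
                     paste0("common_", nm[1], ",", nm[2]))
  } else {
    full <- r2[[key(1, 2, 3)]]
    u1 <- full - r2[[key(2, 3)]]
    u2 <- full - r2[[key(1, 3)]]
    u3 <- full - r2[[key(1, 2)]]
    c12 <- r2[[key(1, 3)]] + r2[[key(2, 3)]] - r2[[key(3)]] - full
    c13 <- r2[[key(1, 2)]] + r2[[key(2, 3)]] - r2[[key(2)]] - full
    c23 <- r2[[key(1, 2)]] + r2[[key(1, 3)]] - r2[[key(1)]] - full
    c123 <- r2[[key(1)]] + r2[[key(2)]] + r2[[key(3)]] -
      r2[[key(1, 2)]] - r2[[key(1, 3)]] - r2[[key(2, 3)]] + full
    comp <- c(u1, u2, u3, c12, c13, c23, c123)
    names(comp) <- c(paste0("unique_", nm),
                     paste0("common_", nm[1], ",", nm[2]),
                     paste0("common_", nm[1], ",", nm[3]),
                     paste0("common_", nm[2], ",", nm[3]),
                     paste0("common_", nm[1], ",", nm[2], ",", nm[3]))
  }
  n <- length(outcome)
  k2 <- sum(vapply(blocks, function(b) ncol(.block_matrix(b)), integer(1)))
  fch <- do.call(rbind, lapply(seq_len(k), function(i) {
    kc <- ncol(.block_matrix(blocks[[i]]))
    delta <- max(0, comp[[paste0("unique_", nm[i])]])
    fc <- f_change(full, delta, n, k2, kc)
    data.frame(block = nm[i], delta_r2 = delta, f = fc["f"], p = fc["p"],
               df1 = fc["df1"], df2 = fc["df2"], row.names = NULL)
  }))
  structure(list(full_r2 = unname(full), components = comp,
                 subset_r2 = r2, f_change = fch, n = n, k2 = k2,
                 rescaled = FALSE),
            class = "commonality_result")
}

#' Zero negative common effects and rescale
#'
#' Negative common effects (which arise under multicollinearity) are set to
#' zero and the remaining components are rescaled proportionally so they
#' again sum to the full model's R2.
#'
#' @param result a [commonality()] result.
#' @return the result with adjusted `components` and `rescaled = TRUE`.
#' @export
zero_and_rescale <- function(result) {
  stopifnot(inherits(result, "commonality_result"))
  comp <- result$components
  comp[comp < 0] <- 0
  s <- sum(comp)
  if (s <= 0 && result$full_r2 > 0)
    stop("pathological decomposition: no positive components to rescale",
         call. = FALSE)
  if (s > 0) comp <- comp * result$full_r2 / s
  result$components <- comp
  result$rescaled <- TRUE
  result
}

#' Commonality decomposition on Ridge regression
#'
#' Replaces each subset's OLS R2 with the in-sample sum-of-squares R2 of a
#' ridge fit. The penalty is selected once, by k-fold cross-validation on
#' the full model, and reused for every subset.
#'
#' @param outcome numeric response.
#' @param blocks named list of 2 or 3 regressor blocks.
#' @param penalty_grid candidate penalties (default `10^seq(-4, 2)` by
#'   half-decades).
#' @param k_cv,seed cross-validation folds and seed for penalty selection.
#' @return a `commonality_result` with attribute `penalty`.
#' @export
ridge_commonality <- function(outcome, blocks,
                              penalty_grid = 10^seq(-4, 2, by = 0.5),
                              k_cv = 5L, seed = 1L) {
  x <- scale(do.call(cbind, lapply(blocks, .block_matrix)))
  n <- length(outcome)
  assign <- withr::with_seed(as.integer(seed),
                             rep(seq_len(k_cv), length.out = n)[sample.int(n)])
  cv_mse <- vapply(penalty_grid, function(pen) {
    err <- 0
    for (f in seq_len(k_cv)) {
      tr <- assign != f
      fit <- enet_fit(x[tr, , drop = FALSE], outcome[tr], pen, 0)
      pred <- .enet_predict(fit, x[!tr, , drop = FALSE])
      err <- err + sum((outcome[!tr] - pred)^2)
    }
    err / n
  }, numeric(1))
  penalty <- penalty_grid[which.min(cv_mse)]
  res <- commonality(outcome, blocks,
                     r2_fun = function(y, b) .ridge_r2(y, b, penalty))
  attr(res, "penalty") <- penalty
  res
}

#' Regression suite over index tables: the utility of Brain Age indices
#'
#' For each model's index table, emits (a) the simple-regression R2 of each
#' Brain Age index and of Brain Cognition as sole regressor for fluid
#' cognition; (b) the two-block commonality of chronological age and each
#' index, with the F-change test of each unique effect; (c) the three-block
#' commonality of age, index and Brain Cognition. Optional variants treat
#' `{age, age^2}` as one block, or replace the OLS engine by ridge.
#'
#' @param index_tables named list of [build_index_table()] results (one per
#'   age/cognition model pair).
#' @param quadratic_age include the quadratic-age block variant.
#' @param ridge use the ridge engine instead of OLS.
#' @param rescale apply [zero_and_rescale()] to reported components.
#' @param alpha_level significance threshold for the F-change flag.
#' @return list of class `analysis_suite` with data frames `simple`,
#'   `commonality2`, `commonality3`.
#' @export
analysis_suite <- function(index_tables, quadratic_age = FALSE,
                           ridge = FALSE, rescale = TRUE,
                           alpha_level = 0.05) {
  indices <- c("brain_age", "brain_age_gap", "corrected_brain_age",
               "corrected_brain_age_gap")
  if (inherits(index_tables, "index_table"))
    index_tables <- list(model = index_tables)
  com_fun <- if (ridge) function(y, b) ridge_commonality(y, b)
             else function(y, b) commonality(y, b)
  simple <- list(); com2 <- list(); com3 <- list()
  for (mn in names(index_tables)) {
    tab <- index_tables[[mn]]
    need <- c("age", "fluid_cognition", indices)
    if (!all(need %in% names(tab)))
      stop(sprintf("index table '%s' is missing required columns", mn),
           call. = FALSE)
    y <- tab$fluid_cognition
    age_block <- if (quadratic_age) cbind(age = tab$age, age2 = tab$age^2)
                 else tab$age
    has_bc <- !anyNA(tab$brain_cognition)
    if (has_bc)
      simple[[paste(mn, "brain_cognition")]] <-
        data.frame(model = mn, regressor = "brain_cognition",
                   r2 = ols_r2(y, list(bc = tab$brain_cognition)))
    for (ix in indices) {
      simple[[paste(mn, ix)]] <-
        data.frame(model = mn, regressor = ix,
                   r2 = ols_r2(y, list(index = tab[[ix]])))
      cres <- com_fun(y, list(age = age_block, index = tab[[ix]]))
      crep <- if (rescale) zero_and_rescale(cres) else cres
      fch <- cres$f_change
      com2[[paste(mn, ix)]] <- data.frame(
        model = mn, index = ix,
        unique_age = crep$components[["unique_age"]],
        unique_index = crep$components[["unique_index"]],
        common = crep$components[["common_age,index"]],
        full_r2 = cres$full_r2,
        f_index = fch$f[fch$block == "index"],
        p_index = fch$p[fch$block == "index"],
        significant = fch$p[fch$block == "index"] < alpha_level)
      if (has_bc) {
        cres3 <- com_fun(y, list(age = age_block, index = tab[[ix]],
                                 cognition = tab$brain_cognition))
        crep3 <- if (rescale) zero_and_rescale(cres3) else cres3
        f3 <- cres3$f_change
        co <- crep3$components
        com3[[paste(mn, ix)]] <- data.frame(
          model = mn, index = ix,
          unique_age = co[["unique_age"]],
          unique_index = co[["unique_index"]],
          unique_cognition = co[["unique_cognition"]],
          common_age_index = co[["common_age,index"]],
          common_age_cognition = co[["common_age,cognition"]],
          common_index_cognition = co[["common_index,cognition"]],
          common_all = co[["common_age,index,cognition"]],
          full_r2 = cres3$full_r2,
          f_cognition = f3$f[f3$block == "cognition"],
          p_cognition = f3$p[f3$block == "cognition"],
          significant = f3$p[f3$block == "cognition"] < alpha_level)
      }
    }
  }
  structure(list(simple = do.call(rbind, c(simple,
                                           list(make.row.names = FALSE))),
                 commonality2 = do.call(rbind, c(com2,
                                                 list(make.row.names = FALSE))),
                 commonality3 = if (length(com3))
                   do.call(rbind, c(com3, list(make.row.names = FALSE)))
                   else NULL),
            class = "analysis_suite")
}
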