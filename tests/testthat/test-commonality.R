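test_that("OLS R2 matches hand-computed normal equations", {
  y <- c(1, 2, 2, 3, 5, 4)
  x1 <- c(0, 1, 1, 2, 3, 2)
  x2 <- c(1, 0, 2, 1, 2, 3)
  # independent computation via the normal equations
  X <- cbind(1, x1, x2)
  bhat <- solve(crossprod(X), crossprod(X, y))
  ref <- 1 - sum((y - X %*% bhat)^2) / sum((y - mean(y))^2)
  expect_equal(ols_r2(y, list(a = x1, b = x2)), ref, tolerance = 1e-12)
  expect_equal(ols_r2(x1, list(a = x1)), 1)
  # outcome orthogonal to the regressor by construction
  z <- resid(lm(y ~ x1))
  expect_equal(ols_r2(z, list(a = x1)), 0, tolerance = 1e-10)
})

test_that("rank-deficient designs are rejected naming the collinear block", {
  y <- rnorm(20)
  a <- rnorm(20)
  expect_error(ols_r2(y, list(first = a, doubled = 2 * a)),
               "block 'doubled'")
  expect_error(ols_r2(rnorm(3), list(a = matrix(rnorm(12), 3, 4))),
               "more observations")
})

test_that("two-block commonality handles orthogonal and duplicated regressors", {
  set.seed(31)
  n <- 200
  a <- rnorm(n)
  b <- resid(lm(rnorm(n) ~ a))  # orthogonal to a
  y <- a + b + rnorm(n)
  res <- commonality(y, list(a = a, b = b))
  expect_equal(unname(res$components["common_a,b"]), 0, tolerance = 1e-10)
  expect_equal(unname(res$components["unique_a"]),
               ols_r2(y, list(a = a)), tolerance = 1e-10)
  expect_equal(sum(res$components), res$full_r2, tolerance = 1e-8)
  # duplicated information: the blocks differ only in a direction orthogonal
  # to both the outcome and the shared signal, so all unique effects vanish
  e <- resid(lm(rnorm(n) ~ y + a))
  res2 <- commonality(y, list(a = a, b = a + 1e-4 * e))
  expect_lt(max(res2$components[c("unique_a", "unique_b")]), 1e-6)
})

test_that("three identical-information blocks put everything in the triple common", {
  set.seed(32)
  n <- 100
  a <- rnorm(n)
  y <- 2 * a + rnorm(n)
  eps <- 1e-4
  e1 <- resid(lm(rnorm(n) ~ y + a))
  e2 <- resid(lm(rnorm(n) ~ y + a + e1))
  res <- commonality(y, list(a = a, b = a + eps * e1,
                             c = a + eps * e2))
  expect_lt(max(abs(res$components[1:6])), 1e-5)
  expect_equal(unname(res$components["common_a,b,c"]), res$full_r2,
               tolerance = 1e-5)
})

test_that("closed forms equal the inclusion-exclusion oracle on random instances", {
  set.seed(33)
  for (i in 1:100) {
    n <- 50
    k <- sample(2:3, 1)
    blocks <- lapply(seq_len(k), function(j)
      matrix(rnorm(n * sample(1:2, 1)), n))
    names(blocks) <- letters[seq_len(k)]
    y <- rnorm(n) + rowSums(vapply(blocks, function(b) b[, 1],
                                   numeric(n)))
    res <- commonality(y, blocks)
    oracle <- commonality_oracle(y, blocks)
    expect_equal(res$components[names(oracle)], oracle,
                 tolerance = 1e-10)
    expect_equal(sum(res$components), res$full_r2, tolerance = 1e-8)
  }
})

test_that("F-change follows the printed formula and an independent oracle", {
  expect_equal(unname(f_change(0.5, 0, 104, 2, 1)[c("f", "p")]), c(0, 1))
  fc <- f_change(0.5, 0.1, 104, 2, 1)
  expect_equal(unname(fc["f"]), 101 * 0.1 / 0.5, tolerance = 1e-12)
  expect_equal(unname(fc["p"]),
               pf(20.2, 1, 101, lower.tail = FALSE), tolerance = 1e-12)
  # p decreases monotonically in delta
  ps <- vapply(seq(0, 0.4, by = 0.05), function(d)
    unname(f_change(0.5, d, 104, 2, 1)["p"]), numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_error(f_change(1, 0.1, 100, 2, 1), "below 1")
  # against anova() on a random hierarchical pair
  set.seed(34)
  n <- 80
  a <- rnorm(n); b <- rnorm(n); y <- a + 0.3 * b + rnorm(n)
  full <- lm(y ~ a + b); redu <- lm(y ~ a)
  r2f <- summary(full)$r.squared
  dr2 <- r2f - summary(redu)$r.squared
  fc2 <- f_change(r2f, dr2, n, 2, 1)
  ref <- anova(redu, full)
  expect_equal(unname(fc2["f"]), ref$F[2], tolerance = 1e-8)
  expect_equal(unname(fc2["p"]), ref$`Pr(>F)`[2], tolerance = 1e-8)
})

test_that("negative common effects are zeroed and the rest rescaled proportionally", {
  res <- structure(list(full_r2 = 0.35,
                        components = c(unique_a = 0.30, unique_b = 0.10,
                                       `common_a,b` = -0.05),
                        rescaled = FALSE),
                   class = "commonality_result")
  out <- zero_and_rescale(res)
  expect_equal(unname(out$components),
               c(0.35 * 0.30 / 0.40, 0.35 * 0.10 / 0.40, 0))
  expect_equal(sum(out$components), 0.35)
  expect_true(out$rescaled)
  # without negatives the components are unchanged, flag still set
  res2 <- res
  res2$components <- c(unique_a = 0.2, unique_b = 0.1, `common_a,b` = 0.05)
  res2$full_r2 <- 0.35
  out2 <- zero_and_rescale(res2)
  expect_equal(out2$components, res2$components)
  expect_true(out2$rescaled)
  res3 <- res
  res3$components <- c(unique_a = -0.1, unique_b = -0.1, `common_a,b` = 0)
  res3$full_r2 <- 0.2
  expect_error(zero_and_rescale(res3), "pathological")
})

test_that("ridge commonality converges to OLS as the penalty vanishes", {
  set.seed(35)
  n <- 150
  a <- rnorm(n); b <- 0.6 * a + 0.8 * rnorm(n)
  y <- a + b + rnorm(n)
  blocks <- list(a = a, b = b)
  ols <- commonality(y, blocks)
  tiny <- commonality(y, blocks,
                      r2_fun = function(yy, bb)
                        cognage:::.ridge_r2(yy, bb, 1e-8))
  expect_equal(tiny$components, ols$components, tolerance = 1e-4)
  huge <- commonality(y, blocks,
                      r2_fun = function(yy, bb)
                        cognage:::.ridge_r2(yy, bb, 1e8))
  expect_lt(huge$full_r2, 1e-6)
  expect_lt(max(abs(huge$components)), 1e-6)
  # CV-selected moderate penalty stays near OLS on a well-conditioned case
  rc <- ridge_commonality(y, blocks)
  expect_equal(rc$components, ols$components, tolerance = 0.02)
  expect_equal(sum(rc$components), rc$full_r2, tolerance = 1e-8)
})

test_that("a quadratic age block barely moves components under a linear truth", {
  set.seed(36)
  n <- 400
  age <- runif(n, 36, 100)
  idx <- 0.8 * age + rnorm(n, 0, 5)
  y <- -0.5 * age + rnorm(n, 0, 6)
  lin <- commonality(y, list(age = age, index = idx))
  quad <- commonality(y, list(age = cbind(age, age^2), index = idx))
  expect_lt(max(abs(lin$components - quad$components)), 0.01)
})

test_that("the analysis suite emits conserving tables with the expected shape", {
  tabs <- small_index_tables()[c("thickness", "stack_all")]
  suite <- analysis_suite(tabs, rescale = FALSE)
  expect_equal(nrow(suite$commonality2), 8)  # 2 models x 4 indices
  expect_equal(nrow(suite$commonality3), 8)
  with(suite$commonality2,
       expect_true(all(abs(unique_age + unique_index + common - full_r2)
                       < 1e-8)))
  with(suite$commonality3,
       expect_true(all(abs(unique_age + unique_index + unique_cognition +
                             common_age_index + common_age_cognition +
                             common_index_cognition + common_all -
                             full_r2) < 1e-8)))
  # simple regressions cover the four indices plus brain cognition
  expect_setequal(unique(suite$simple$regressor),
                  c("brain_age", "brain_age_gap", "corrected_brain_age",
                    "corrected_brain_age_gap", "brain_cognition"))
})
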