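make_toy <- function(n = 150, seed = 21) {
  withr::with_seed(seed, {
    ids <- sprintf("sub%04d", 1:n)
    y <- stats::setNames(rnorm(n, 50, 10), ids)
    sex <- stats::setNames(rbinom(n, 1, 0.5), ids)
    planted <- matrix(c(y, rnorm(n), rnorm(n)), n, 3,
                      dimnames = list(ids, c("signal", "n1", "n2")))
    noise <- matrix(rnorm(n * 4), n, 4,
                    dimnames = list(ids, paste0("f", 1:4)))
    list(ids = ids, y = y, sex = sex,
         features = list(planted = planted, noise = noise))
  })
}

test_that("a planted signal is recovered and a shuffled target is not", {
  toy <- make_toy()
  sch <- make_fold_scheme(toy$ids, seed = 2)
  l1 <- run_level1(toy$features["planted"], toy$y, toy$sex, sch,
                   reduced_grid())
  res <- assemble_out_of_fold(l1)
  expect_gt(res$summary$mean_r2[1], 0.99)
  # breaking participant alignment destroys the signal
  y_shuf <- stats::setNames(unname(toy$y)[withr::with_seed(4,
                                                           sample(150))],
                            toy$ids)
  l1n <- run_level1(toy$features["planted"], y_shuf, toy$sex, sch,
                    reduced_grid())
  resn <- assemble_out_of_fold(l1n)
  expect_lte(resn$summary$mean_r2[1], 0.05)
})

test_that("misaligned or incomplete feature sets are rejected", {
  toy <- make_toy()
  sch <- make_fold_scheme(toy$ids, seed = 2)
  broken <- toy$features
  broken$planted <- broken$planted[-1, ]
  expect_error(run_level1(broken, toy$y, toy$sex, sch, reduced_grid()),
               "missing participants")
  nas <- toy$features
  nas$noise[3, 2] <- NA
  expect_error(run_level1(nas, toy$y, toy$sex, sch, reduced_grid()),
               "missing values")
})

test_that("outer-fold models never depend on their test rows", {
  toy <- make_toy(n = 100)
  sch <- make_fold_scheme(toy$ids, seed = 5)
  l1a <- run_level1(toy$features["noise"], toy$y, toy$sex, sch,
                    reduced_grid())
  # perturb features and target of a fold-1 test participant
  te_id <- toy$ids[sch$outer == 1][1]
  toy$features$noise[te_id, ] <- toy$features$noise[te_id, ] + 50
  y2 <- toy$y
  y2[te_id] <- y2[te_id] + 100
  l1b <- run_level1(toy$features["noise"], y2, toy$sex, sch,
                    reduced_grid())
  fa <- l1a$sets$noise$folds[[1]]
  fb <- l1b$sets$noise$folds[[1]]
  expect_identical(fa$tuned$coefficients, fb$tuned$coefficients)
  expect_identical(fa$tuned$preproc, fb$tuned$preproc)
  expect_identical(c(fa$tuned$alpha, fa$tuned$l1_ratio),
                   c(fb$tuned$alpha, fb$tuned$l1_ratio))
  expect_identical(fa$train_pred, fb$train_pred)
})

test_that("stacked models combine members sensibly", {
  res <- small_age_results()
  ids <- small_sim()$cohort$participant_id
  age <- stats::setNames(small_sim()$cohort$age, ids)
  asm <- res$assembled
  r2 <- stats::setNames(asm$summary$mean_r2, asm$summary$model)
  # a single-member stack tracks its member
  expect_equal(unname(r2["stack_task_fc"]),
               mean(vapply(res$l1$sets$task_fc_a$folds,
                           function(f) f$test_metrics["r2"], numeric(1))),
               tolerance = 0.05)
  # stacking all sets is at least as good as any single set, minus slack
  single_best <- max(r2[c("contrast_a", "task_fc_a", "thickness",
                          "rest_fc")])
  expect_gte(r2["stack_all"], single_best - 0.02)
})

test_that("a stack member that equals the target dominates", {
  toy <- make_toy()
  sch <- make_fold_scheme(toy$ids, seed = 2)
  l1 <- run_level1(toy$features, toy$y, toy$sex, sch, reduced_grid())
  st <- run_stacking(l1, sch, reduced_grid(),
                     list(both = c("planted", "noise")))
  res <- assemble_out_of_fold(l1, st)
  expect_gt(res$summary[res$summary$model == "both", "mean_r2"], 0.99)
  expect_error(run_stacking(l1, sch, reduced_grid(),
                            list(bad = c("planted", "absent"))),
               "unknown feature set")
})

test_that("out-of-fold assembly covers each participant exactly once", {
  asm <- small_age_results()$assembled
  sch <- small_scheme()
  for (m in asm$models) {
    expect_setequal(names(m$out_of_fold), sch$ids)
    expect_false(anyNA(m$out_of_fold))
    # each prediction comes from the fold that held the participant out
    for (f in 1:5)
      expect_setequal(names(m$folds[[f]]$test_pred),
                      sch$ids[sch$outer == f])
    # stored per-fold metrics match recomputation from stored predictions
    y <- asm$target
    for (f in 1:5) {
      m_rec <- prediction_metrics(y[names(m$folds[[f]]$test_pred)],
                                  m$folds[[f]]$test_pred)
      expect_equal(m$per_fold$r2[f], unname(m_rec["r2"]), tolerance = 1e-12)
    }
  }
  expect_equal(nrow(asm$summary), 12) # 4 sets + 8 stacks here
})

test_that("connectivity importance back-projects through absolute loadings", {
  # hand example: loadings rows (1,-1)/(1,1), coefficients (2,3)
  rot <- cbind(PC1 = c(1, -1), PC2 = c(1, 1))
  rownames(rot) <- c("p1", "p2")
  cf <- c(PC1 = 2, PC2 = 3)
  imp <- as.numeric(abs(rot) %*% cf)
  expect_equal(imp, c(5, 5))
  # through the exported interface
  set.seed(30)
  n <- 100; p <- 20
  ids <- sprintf("sub%04d", 1:n)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(ids, paste0("e", 1:p)))
  y <- stats::setNames(x[, 1] - x[, 2] + rnorm(n, sd = 0.1), ids)
  sex <- stats::setNames(rbinom(n, 1, 0.5), ids)
  it <- refit_importance(x, y, sex, reduced_grid(), kind = "connectivity",
                         n_components = 5)
  expect_length(it$importance, p)
  manual <- as.numeric(abs(it$tuned$preproc$pca$rotation) %*%
                         it$tuned$coefficients)
  expect_equal(unname(it$importance), manual)
  # all-zero coefficients give all-zero importances
  expect_equal(as.numeric(abs(it$tuned$preproc$pca$rotation) %*%
                            rep(0, 5)), rep(0, p))
})

test_that("importance stability yields ten Spearman rhos with rank semantics", {
  v <- rnorm(30)
  same <- replicate(5, v, simplify = FALSE)
  st <- importance_stability(same)
  expect_equal(nrow(st), 10)
  expect_true(all(st$rho == 1))
  flipped <- same
  flipped[[3]] <- -v
  st2 <- importance_stability(flipped)
  pair3 <- st2$fold_i == 3 | st2$fold_j == 3
  expect_true(all(st2$rho[pair3] == -1))
  expect_true(all(st2$rho[!pair3] == 1))
  # random vectors match an independent rank-then-Pearson computation
  set.seed(9)
  rnd <- replicate(5, rnorm(25), simplify = FALSE)
  st3 <- importance_stability(rnd)
  ref <- cor(rank(rnd[[1]]), rank(rnd[[2]]))
  expect_equal(st3$rho[1], ref, tolerance = 1e-12)
  # constant vectors yield undefined rho
  cst <- rnd
  cst[[2]] <- rep(1, 25)
  expect_true(anyNA(importance_stability(cst)$rho))
})

test_that("pooled out-of-fold accuracy tracks the designed ground truth", {
  sim <- small_sim()
  gt <- sim$ground_truth$expected_r2_features_age
  asm <- small_age_results()$assembled
  age <- stats::setNames(sim$cohort$age, sim$cohort$participant_id)
  for (nm in names(sim$features)) {
    pooled <- prediction_metrics(age[names(asm$models[[nm]]$out_of_fold)],
                                 asm$models[[nm]]$out_of_fold)
    expect_lt(abs(pooled["r2"] - gt[nm]), 0.12)
  }
})
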