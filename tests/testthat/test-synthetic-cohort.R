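test_that("cohort spec validation names the offending field", {
  expect_error(cohort_spec(100, set_dims = 5L, set_kinds = "direct",
                           age_signal_share = 1.2,
                           cognition_signal_share = 0.3),
               "age_signal_share")
  expect_error(cohort_spec(100, set_dims = 5L, set_kinds = "direct",
                           age_signal_share = 0.3,
                           cognition_signal_share = 0.3,
                           cognition_age_share = 0.7,
                           cognition_brain_share = 0.5),
               "exceeds 1")
  expect_error(cohort_spec(100, set_dims = c(5L, 6L),
                           set_kinds = "direct",
                           age_signal_share = c(0.3, 0.3),
                           cognition_signal_share = c(0.3, 0.3)),
               "equal length")
})

test_that("generation is deterministic and respects demographics", {
  spec <- cohort_spec(504, age_range = c(36, 100),
                      female_fraction = 293 / 504,
                      set_dims = 6L, set_kinds = "direct",
                      age_signal_share = 0.4,
                      cognition_signal_share = 0.3)
  sim <- generate_cohort(spec, seed = 5)
  expect_equal(nrow(sim$cohort), 504)
  expect_true(all(sim$cohort$age >= 36 & sim$cohort$age <= 100))
  expect_true(all(sim$cohort$sex %in% c(0, 1)))
  expect_false(anyNA(sim$cohort))
  expect_identical(sim, generate_cohort(spec, seed = 5))
  expect_false(identical(sim$cohort$age,
                         generate_cohort(spec, seed = 6)$cohort$age))
})

test_that("noise-free age-only cognition is perfectly anticorrelated with age", {
  spec <- cohort_spec(200, set_dims = 4L, set_kinds = "direct",
                      age_signal_share = 0.4,
                      cognition_signal_share = 0,
                      cognition_age_share = 1,
                      cognition_brain_share = 0)
  sim <- generate_cohort(spec, seed = 2)
  expect_equal(cor(sim$cohort$age, sim$cohort$fluid_cognition), -1,
               tolerance = 1e-12)
})

test_that("designed variance shares are recovered empirically at large n", {
  spec <- cohort_spec(1e5, set_dims = c(15L, 45L),
                      set_kinds = c("direct", "connectivity"),
                      age_signal_share = c(0.55, 0),
                      cognition_signal_share = c(0.4, 0.3),
                      cognition_age_share = 0.32,
                      cognition_brain_share = 0.18,
                      sex_effect_size = 0.25)
  sim <- generate_cohort(spec, seed = 9)
  gt <- sim$ground_truth
  r2_cog <- summary(lm(fluid_cognition ~ age, sim$cohort))$r.squared
  expect_equal(r2_cog, 0.32, tolerance = 0.01)
  expect_lt(cor(sim$cohort$age, sim$cohort$fluid_cognition), 0)
  for (s in 1:2) {
    x <- sim$features[[s]]
    emp_age <- summary(lm(sim$cohort$age ~ x))$r.squared
    emp_cog <- summary(lm(sim$cohort$fluid_cognition ~ x))$r.squared
    expect_lt(abs(emp_age - gt$expected_r2_features_age[s]), 0.01)
    expect_lt(abs(emp_cog - gt$expected_r2_features_cognition[s]), 0.01)
    # additive sex shift recovered by per-feature regression on sex
    slopes <- apply(x[, 1:5], 2,
                    function(v) coef(lm(v ~ sim$cohort$sex))[2])
    expect_true(all(abs(slopes - 0.25) < 0.02))
  }
  # a set with zero age share carries no age signal
  expect_equal(unname(gt$expected_r2_features_age[2]), 0)
})

test_that("closed-form ground truth matches its trivial special cases", {
  spec <- cohort_spec(100, set_dims = c(8L, 8L),
                      set_kinds = c("direct", "direct"),
                      age_signal_share = c(0.5, 0),
                      cognition_signal_share = c(0.3, 0.3),
                      cognition_age_share = 0.32,
                      cognition_brain_share = 0.1)
  gt <- ground_truth_r2(spec)
  expect_equal(gt$expected_r2_age_cognition, 0.32)
  expect_equal(unname(gt$expected_r2_features_age[2]), 0)
  expect_true(all(unlist(gt[1:3]) >= 0 & unlist(gt[1:3]) <= 1))
})

test_that("without a brain share, cognition is conditionally independent of features given age", {
  spec <- cohort_spec(5e4, set_dims = 10L, set_kinds = "direct",
                      age_signal_share = 0.5,
                      cognition_signal_share = 0.5,
                      cognition_age_share = 0.4,
                      cognition_brain_share = 0)
  sim <- generate_cohort(spec, seed = 3)
  res_cog <- resid(lm(sim$cohort$fluid_cognition ~ sim$cohort$age))
  res_x <- resid(lm(sim$features[[1]][, 1] ~ sim$cohort$age))
  expect_lt(abs(cor(res_cog, res_x)), 0.02)
})

test_that("cohort round-trips through the CSV/JSON layout", {
  spec <- cohort_spec(40, set_dims = c(4L, 10L),
                      set_kinds = c("direct", "connectivity"),
                      set_tags = c("smri", "rest_fc"),
                      age_signal_share = c(0.4, 0.4),
                      cognition_signal_share = c(0.3, 0.3))
  sim <- generate_cohort(spec, seed = 1)
  dir <- withr::local_tempdir()
  write_cohort(sim, dir)
  back <- read_cohort(dir)
  expect_equal(back$cohort$age, sim$cohort$age, tolerance = 1e-12)
  expect_equal(unname(back$features[[2]]), unname(sim$features[[2]]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(attr(back$features[[2]], "kind"), "connectivity")
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_length(manifest, 2)
  expect_identical(manifest[[2]]$tag, "rest_fc")
})
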