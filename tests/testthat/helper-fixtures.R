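# Shared fixtures, built in code and cached across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# small four-set cohort covering all modality tags
small_spec <- function(n = 250, seed_sets = NULL) {
  cohort_spec(n_participants = n,
              set_dims = c(12, 66, 8, 66),
              set_kinds = c("direct", "connectivity", "direct",
                            "connectivity"),
              set_names = c("contrast_a", "task_fc_a", "thickness",
                            "rest_fc"),
              set_tags = c("task_contrast", "task_fc", "smri", "rest_fc"),
              age_signal_share = c(0.30, 0.45, 0.60, 0.50),
              cognition_signal_share = c(0.20, 0.35, 0.50, 0.45))
}

small_sim <- function() memo("small_sim", generate_cohort(small_spec(), 11))

small_scheme <- function() {
  memo("small_scheme",
       make_fold_scheme(small_sim()$cohort$participant_id, seed = 11))
}

# level-1 + stacked age-prediction results on the small cohort
small_age_results <- function() {
  memo("small_age_results", {
    sim <- small_sim()
    ids <- sim$cohort$participant_id
    l1 <- run_level1(sim$features,
                     stats::setNames(sim$cohort$age, ids),
                     stats::setNames(sim$cohort$sex, ids),
                     small_scheme(), reduced_grid(), n_components = 10)
    tags <- vapply(sim$features, attr, character(1), "tag")
    st <- run_stacking(l1, small_scheme(), reduced_grid(),
                       default_stack_specs(tags))
    list(l1 = l1, st = st, assembled = assemble_out_of_fold(l1, st))
  })
}

small_cognition_results <- function() {
  memo("small_cognition_results", {
    sim <- small_sim()
    ids <- sim$cohort$participant_id
    l1 <- run_level1(sim$features,
                     stats::setNames(sim$cohort$fluid_cognition, ids),
                     stats::setNames(sim$cohort$sex, ids),
                     small_scheme(), reduced_grid(), n_components = 10)
    tags <- vapply(sim$features, attr, character(1), "tag")
    st <- run_stacking(l1, small_scheme(), reduced_grid(),
                       default_stack_specs(tags))
    assemble_out_of_fold(l1, st)
  })
}

small_index_tables <- function() {
  memo("small_index_tables", {
    age <- small_age_results()$assembled
    cogn <- small_cognition_results()
    out <- lapply(names(age$models), function(mn)
      build_index_table(age$models[[mn]], cogn$models[[mn]],
                        small_sim()$cohort, small_scheme()))
    names(out) <- names(age$models)
    out
  })
}

# independent all-subsets inclusion-exclusion oracle for commonality:
# commonality coefficient of subset S is -sum_{T subseteq S} (-1)^|T|
# R2(complement(S) union T)
commonality_oracle <- function(outcome, blocks) {
  k <- length(blocks)
  r2_of <- function(s) if (length(s) == 0) 0 else
    ols_r2(outcome, blocks[s])
  subsets_of <- function(v) {
    out <- list(integer(0))
    for (el in v) out <- c(out, lapply(out, function(s) c(s, el)))
    out
  }
  all_s <- setdiff(subsets_of(seq_len(k)), list(integer(0)))
  comp <- vapply(all_s, function(s) {
    comp_s <- setdiff(seq_len(k), s)
    -sum(vapply(subsets_of(s), function(t)
      (-1)^length(t) * r2_of(sort(c(comp_s, t))), numeric(1)))
  }, numeric(1))
  names(comp) <- vapply(all_s, function(s) {
    pre <- if (length(s) == 1) "unique_" else "common_"
    paste0(pre, paste(names(blocks)[s], collapse = ","))
  }, character(1))
  comp
}
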