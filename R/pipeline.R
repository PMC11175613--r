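# End-to-end orchestration: simulate (or load) -> predict both targets ->
# Brain Age indices -> commonality tables, written as CSV/JSON artifacts.
# A run is a pure function of its configuration; re-running the same
# configuration reproduces every numeric output.

#' Build a run configuration
#'
#' @param seed master seed for simulation and fold assignment.
#' @param cohort either a [cohort_spec()] (simulate) or a directory path of
#'   user tables in the [write_cohort()] layout.
#' @param grid `"full"` (70 x 25), `"reduced"` (7 x 5) or a [hyper_grid()].
#' @param stack_specs named list of member vectors, or `NULL` for
#'   [default_stack_specs()].
#' @param n_components PCA dimension for connectivity sets.
#' @param variants character subset of `c("ridge", "quadratic",
#'   "sex_before_pca")`.
#' @param out_dir output directory for [run_pipeline()].
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, cohort, grid = "reduced",
                       stack_specs = NULL, n_components = 75L,
                       variants = character(), out_dir = tempfile("run")) {
  if (is.character(grid))
    grid <- switch(match.arg(grid, c("full", "reduced")),
                   full = hyper_grid(), reduced = reduced_grid())
  stopifnot(inherits(grid, "hyper_grid"))
  bad <- setdiff(variants, c("ridge", "quadratic", "sex_before_pca"))
  if (length(bad)) stop("unknown variants: ", paste(bad, collapse = ", "))
  structure(list(seed = as.integer(seed), cohort = cohort, grid = grid,
                 stack_specs = stack_specs, n_components = n_components,
                 variants = variants, out_dir = out_dir),
            class = "run_config")
}

#' Read a YAML or JSON run configuration file
#'
#' Recognised fields: `seed`, `cohort_dir` (or a `cohort_spec` block with
#' the arguments of [cohort_spec()]), `grid`, `n_components`, `variants`,
#' `out_dir`.
#'
#' @param path configuration file (`.yaml`/`.yml`/`.json`).
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  cohort <- if (!is.null(cfg$cohort_dir)) cfg$cohort_dir
            else do.call(cohort_spec, cfg$cohort_spec)
  run_config(seed = cfg$seed %||% 1L, cohort = cohort,
             grid = cfg$grid %||% "reduced",
             n_components = cfg$n_components %||% 75L,
             variants = cfg$variants %||% character(),
             out_dir = cfg$out_dir %||% tempfile("run"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.log <- function(con, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...))
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full evaluation pipeline
#'
#' Executes all stages for both targets (chronological age and fluid
#' cognition): level-1 and stacked prediction models under the nested fold
#' scheme, out-of-fold assembly, Brain Age index construction with
#' fold-wise bias correction, and the commonality analysis suite. Writes
#' `predictions.csv`, `metrics.csv`, `fold_scheme.csv`, `indices.csv`,
#' `simple_regression.csv`, `commonality2.csv`, `commonality3.csv` and
#' `run_info.json` to the output directory.
#'
#' @param config a [run_config()].
#' @param verbose log progress.
#' @return invisibly, a list with all in-memory stage results (`sim`,
#'   `scheme`, `results` per target, `index_tables`, `suite`, `out_dir`).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logcon <- file(file.path(config$out_dir, "run.log"), open = "wt")
  on.exit(close(logcon))
  logf <- function(...) if (verbose) .log(logcon, ...) else
    .log(NULL, ...)
  timings <- list()
  stage <- function(name, expr) {
    ts <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    timings[[name]] <<- as.numeric(difftime(Sys.time(), ts, units = "secs"))
    logf("stage %-12s done in %.1fs", name, timings[[name]])
    out
  }

  sim <- stage("simulate", {
    if (inherits(config$cohort, "cohort_spec"))
      generate_cohort(config$cohort, seed = config$seed)
    else read_cohort(config$cohort)
  })
  cohort <- sim$cohort
  features <- sim$features
  ids <- cohort$participant_id
  sex <- stats::setNames(cohort$sex, ids)
  age <- stats::setNames(cohort$age, ids)
  cogn <- stats::setNames(cohort$fluid_cognition, ids)
  scheme <- make_fold_scheme(ids, seed = config$seed)
  tags <- vapply(features, function(x) attr(x, "tag") %||% "smri",
                 character(1))
  stack_specs <- config$stack_specs %||% default_stack_specs(tags)
  sbp <- "sex_before_pca" %in% config$variants

  results <- list()
  for (target_name in c("age", "cognition")) {
    y <- if (target_name == "age") age else cogn
    l1 <- stage(paste0("level1_", target_name),
                run_level1(features, y, sex, scheme, config$grid,
                           n_components = config$n_components,
                           sex_before_pca = sbp, verbose = FALSE))
    st <- stage(paste0("stack_", target_name),
                run_stacking(l1, scheme, config$grid, stack_specs))
    results[[target_name]] <- assemble_out_of_fold(l1, st)
  }

  index_tables <- stage("indices", {
    mods <- names(results$age$models)
    out <- lapply(mods, function(mn)
      build_index_table(results$age$models[[mn]],
                        results$cognition$models[[mn]], cohort, scheme))
    names(out) <- mods
    out
  })

  suite <- stage("commonality",
                 analysis_suite(index_tables,
                                quadratic_age = "quadratic" %in%
                                  config$variants,
                                ridge = "ridge" %in% config$variants))

  stage("write", {
    od <- config$out_dir
    pred <- do.call(rbind, lapply(names(results), function(tn) {
      do.call(rbind, lapply(results[[tn]]$models, function(m)
        data.frame(participant_id = names(m$out_of_fold), model = m$name,
                   target = tn, prediction = unname(m$out_of_fold),
                   outer_fold = unname(scheme$outer[names(m$out_of_fold)]),
                   row.names = NULL)))
    }))
    write.csv(pred, file.path(od, "predictions.csv"), row.names = FALSE)
    met <- do.call(rbind, lapply(names(results), function(tn) {
      do.call(rbind, lapply(results[[tn]]$models, function(m)
        cbind(model = m$name, target = tn, m$per_fold)))
    }))
    write.csv(met, file.path(od, "metrics.csv"), row.names = FALSE)
    write.csv(data.frame(participant_id = names(scheme$outer),
                         outer_fold = unname(scheme$outer)),
              file.path(od, "fold_scheme.csv"), row.names = FALSE)
    idx <- do.call(rbind, lapply(names(index_tables), function(mn)
      cbind(model = mn, as.data.frame(index_tables[[mn]]))))
    write.csv(idx, file.path(od, "indices.csv"), row.names = FALSE)
    write.csv(suite$simple, file.path(od, "simple_regression.csv"),
              row.names = FALSE)
    write.csv(suite$commonality2, file.path(od, "commonality2.csv"),
              row.names = FALSE)
    if (!is.null(suite$commonality3))
      write.csv(suite$commonality3, file.path(od, "commonality3.csv"),
                row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed,
           n_participants = length(ids),
           n_feature_sets = length(features),
           n_models_per_target = length(results$age$models),
           grid = list(n_alpha = length(config$grid$alphas),
                       n_l1 = length(config$grid$l1_ratios)),
           variants = config$variants,
           r_version = as.character(getRversion()),
           wall_clock_seconds = timings,
           total_seconds = as.numeric(difftime(Sys.time(), t0,
                                               units = "secs"))),
      file.path(od, "run_info.json"), auto_unbox = TRUE, digits = NA)
    invisible(NULL)
  })
  logf("run complete: %s", config$out_dir)
  invisible(list(sim = sim, scheme = scheme, results = results,
                 index_tables = index_tables, suite = suite,
                 out_dir = config$out_dir))
}

#' Summarise a completed run directory
#'
#' Reads the run artifacts, ranks model performance per target, summarises
#' the commonality tables, and re-verifies at report time that (a) every
#' commonality row's components sum to its full-model R2 and (b) the
#' stored per-fold metrics equal a recomputation from the stored
#' predictions.
#'
#' @param run_dir a directory written by [run_pipeline()].
#' @param tol verification tolerance.
#' @return list with `performance` (per target, ranked by mean R2),
#'   `commonality2`, `commonality3`, `run_info`.
#' @export
report_run <- function(run_dir, tol = 1e-8) {
  need <- c("predictions.csv", "metrics.csv", "indices.csv",
            "commonality2.csv", "run_info.json")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing))
    stop("incomplete run, missing artifacts: ",
         paste(missing, collapse = ", "), call. = FALSE)
  met <- read.csv(file.path(run_dir, "metrics.csv"))
  pred <- read.csv(file.path(run_dir, "predictions.csv"))
  idx <- read.csv(file.path(run_dir, "indices.csv"))
  com2 <- read.csv(file.path(run_dir, "commonality2.csv"))
  info <- jsonlite::read_json(file.path(run_dir, "run_info.json"),
                              simplifyVector = TRUE)
  # conservation check (components were rescaled to sum to full_r2)
  gap <- with(com2, abs(unique_age + unique_index + common - full_r2))
  if (any(gap > tol))
    stop("conservation violated in commonality2.csv", call. = FALSE)
  # recompute pooled metrics from stored predictions for one cross-check
  obs <- unique(idx[, c("participant_id", "age", "fluid_cognition")])
  recompute <- do.call(rbind, lapply(split(pred,
                                           pred[, c("model", "target")],
                                           drop = TRUE), function(d) {
    y <- if (d$target[1] == "age") obs$age[match(d$participant_id,
                                                 obs$participant_id)]
         else obs$fluid_cognition[match(d$participant_id,
                                        obs$participant_id)]
    m <- prediction_metrics(y, d$prediction)
    data.frame(model = d$model[1], target = d$target[1],
               pooled_r2 = m["r2"], pooled_mae = m["mae"],
               row.names = NULL)
  }))
  perf <- merge(stats::aggregate(cbind(pearson_r, r2, mae) ~ model + target,
                                 met, mean), recompute,
                by = c("model", "target"))
  perf <- perf[order(perf$target, -perf$r2), ]
  com3 <- if (file.exists(file.path(run_dir, "commonality3.csv")))
    read.csv(file.path(run_dir, "commonality3.csv")) else NULL
  list(performance = perf, commonality2 = com2, commonality3 = com3,
       run_info = info)
}
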