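# Linear-Gaussian synthetic cohort with closed-form ground truth.
#
# Participant-level latents:
#   z   standardised chronological age (age ~ Uniform(age_range))
#   w   age-independent distortion; u = sqrt(rho) z + sqrt(1-rho) w is the
#       "brain aging" latent shared by every feature set, so that no
#       combination of brain features can explain more than rho of the
#       variance in age (rho = age_latent_ceiling)
#   g   brain latent driving the age-independent part of fluid cognition
# Per-set latents t_s (age-bearing) and q_s (cognition-bearing) mix u and g
# with set-specific noise so that the population R2 of age on the whole set
# is exactly age_signal_share[s], and the brain-driven cognition signal
# recoverable from the set is cognition_signal_share[s] of g.
#
# fluid_cognition = 100 + 15 * ( -sqrt(A) z + sqrt(B) g + sqrt(1-A-B) nu )
# with A = cognition_age_share, B = cognition_brain_share; the age term is
# negative by convention (older participants score lower).

# per-feature variance budget on the set latents (unit-variance features
# before the additive sex shift)
.W_AGE <- sqrt(0.55)
.W_COG <- sqrt(0.30)
.W_EPS <- sqrt(0.15)

#' Specify a synthetic cohort
#'
#' Defines the demographic structure, feature-set geometry and variance
#' shares of a simulated aging cohort. All shares are population variance
#' proportions in `[0, 1]`.
#'
#' @param n_participants number of participants.
#' @param age_range numeric length-2, minimum and maximum age in years; ages
#'   are drawn uniformly on this range.
#' @param female_fraction proportion of females (sex coded 1).
#' @param set_dims integer vector, number of features (columns) per set.
#' @param set_kinds character vector, `"direct"` or `"connectivity"` per set;
#'   connectivity-like sets are wide pairwise tables meant for PCA reduction.
#' @param set_names optional names for the sets.
#' @param set_tags optional modality tags (`"task_contrast"`, `"task_fc"`,
#'   `"rest_fc"`, `"smri"`) used to resolve stacked-model membership.
#' @param age_signal_share per-set proportion of recoverable feature variance
#'   driven by the age-linked latent (the population R2 of age on the whole
#'   set approaches this value).
#' @param cognition_signal_share per-set proportion of the brain-cognition
#'   latent recoverable from the set.
#' @param cognition_age_share proportion of fluid-cognition variance driven
#'   by chronological age.
#' @param cognition_brain_share proportion of fluid-cognition variance driven
#'   by brain latents independent of age.
#' @param sex_effect_size additive standardised mean shift on every feature
#'   for females.
#' @param age_latent_ceiling upper bound on the age variance any combination
#'   of brain features can explain; every `age_signal_share` must not exceed
#'   it.
#' @param recode_90plus if `TRUE`, ages above 90 are recoded to 100,
#'   emulating the privacy recoding applied in some aging releases.
#' @param noise_seed default seed used by [generate_cohort()] when none is
#'   given.
#'
#' @return an object of class `cohort_spec`.
#' @seealso [generate_cohort()], [ground_truth_r2()], [hcpa_like_spec()]
#' @export
cohort_spec <- function(n_participants,
                        age_range = c(36, 100),
                        female_fraction = 0.5,
                        set_dims = integer(),
                        set_kinds = character(),
                        set_names = NULL,
                        set_tags = NULL,
                        age_signal_share = numeric(),
                        cognition_signal_share = numeric(),
                        cognition_age_share = 0.32,
                        cognition_brain_share = 0.15,
                        sex_effect_size = 0.2,
                        age_latent_ceiling = 0.78,
                        recode_90plus = FALSE,
                        noise_seed = 1L) {
  n_sets <- length(set_dims)
  if (is.null(set_names)) set_names <- sprintf("set%02d", seq_len(n_sets))
  if (is.null(set_tags)) set_tags <- rep("smri", n_sets)
  chk_share <- function(x, field) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
      stop(sprintf("invalid variance share in field '%s': must lie in [0, 1]",
                   field), call. = FALSE)
  }
  if (length(set_kinds) != n_sets || length(set_names) != n_sets ||
      length(set_tags) != n_sets)
    stop("set_dims, set_kinds, set_names and set_tags must have equal length",
         call. = FALSE)
  if (length(age_signal_share) == 1L)
    age_signal_share <- rep(age_signal_share, n_sets)
  if (length(cognition_signal_share) == 1L)
    cognition_signal_share <- rep(cognition_signal_share, n_sets)
  if (length(age_signal_share) != n_sets ||
      length(cognition_signal_share) != n_sets)
    stop("per-set shares must match the number of feature sets", call. = FALSE)
  chk_share(age_signal_share, "age_signal_share")
  chk_share(cognition_signal_share, "cognition_signal_share")
  chk_share(cognition_age_share, "cognition_age_share")
  chk_share(cognition_brain_share, "cognition_brain_share")
  chk_share(age_latent_ceiling, "age_latent_ceiling")
  if (cognition_age_share + cognition_brain_share > 1 + 1e-12)
    stop("invalid variance shares: cognition_age_share + cognition_brain_share exceeds 1",
         call. = FALSE)
  if (any(age_signal_share > age_latent_ceiling + 1e-12))
    stop("invalid variance share in field 'age_signal_share': exceeds age_latent_ceiling",
         call. = FALSE)
  if (!all(set_kinds %in% c("direct", "connectivity")))
    stop("set_kinds must be 'direct' or 'connectivity'", call. = FALSE)
  if (female_fraction < 0 || female_fraction > 1)
    stop("invalid value in field 'female_fraction': must lie in [0, 1]",
         call. = FALSE)
  if (length(age_range) != 2L || diff(age_range) <= 0)
    stop("age_range must be an increasing (min, max) pair", call. = FALSE)
  structure(list(
    n_participants = as.integer(n_participants),
    age_range = as.numeric(age_range),
    female_fraction = female_fraction,
    n_feature_sets = n_sets,
    set_dims = as.integer(set_dims),
    set_kinds = set_kinds,
    set_names = set_names,
    set_tags = set_tags,
    age_signal_share = age_signal_share,
    cognition_signal_share = cognition_signal_share,
    cognition_age_share = cognition_age_share,
    cognition_brain_share = cognition_brain_share,
    sex_effect_size = sex_effect_size,
    age_latent_ceiling = age_latent_ceiling,
    recode_90plus = recode_90plus,
    noise_seed = as.integer(noise_seed)
  ), class = "cohort_spec")
}

#' Study-like cohort specification
#'
#' A ready-made [cohort_spec()] emulating an aging cohort with 18 feature
#' sets of heterogeneous dimensionality: ten task-contrast sets (one value
#' per brain region), three task-FC and one resting-state-FC connectivity
#' sets (pairwise region-by-region tables, PCA-reduced downstream), and four
#' structural sets. `n_regions` controls the parcellation size; the default
#' 379 yields 71,631 region-pair features per connectivity set. Use a small
#' `n_regions` (and smaller dims) for fast demonstrations.
#'
#' @param n_participants cohort size (default 504).
#' @param n_regions parcellation size for connectivity sets.
#' @param contrast_dim features per task-contrast set.
#' @param smri_dims features of the four structural sets (cortical thickness,
#'   cortical surface area, subcortical volume, total brain volume).
#' @param ... further arguments passed to [cohort_spec()].
#' @return a `cohort_spec`.
#' @export
hcpa_like_spec <- function(n_participants = 504,
                           n_regions = 379,
                           contrast_dim = 379,
                           smri_dims = c(148, 148, 19, 5),
                           ...) {
  fc_dim <- n_regions * (n_regions - 1L) / 2L
  contrast_names <- c("facename_encode", "facename_recall",
                      "facename_distractor", "facename_encode_vs_distractor",
                      "facename_recall_vs_distractor",
                      "facename_encode_vs_recall", "carit_nogo", "carit_go",
                      "carit_nogo_vs_go", "vismotor")
  fc_names <- c("facename_fc", "carit_fc", "vismotor_fc", "rest_fc")
  smri_names <- c("cortical_thickness", "cortical_surface_area",
                  "subcortical_volume", "total_brain_volume")
  set_names <- c(contrast_names, fc_names, smri_names)
  set_dims <- c(rep(contrast_dim, 10L), rep(fc_dim, 4L), smri_dims)
  set_kinds <- c(rep("direct", 10L), rep("connectivity", 4L),
                 rep("direct", 4L))
  set_tags <- c(rep("task_contrast", 10L), rep("task_fc", 3L), "rest_fc",
                rep("smri", 4L))
  # heterogeneous age signal: contrasts weakest, FC intermediate, structure
  # strongest (cortical thickness best single set)
  age_share <- c(seq(0.20, 0.38, length.out = 10L),
                 0.45, 0.42, 0.40, 0.55,
                 0.65, 0.50, 0.45, 0.30)
  cog_share <- c(seq(0.15, 0.30, length.out = 10L),
                 0.35, 0.30, 0.25, 0.45,
                 0.50, 0.35, 0.30, 0.20)
  cohort_spec(n_participants = n_participants,
              age_range = c(36, 100),
              female_fraction = 293 / 504,
              set_dims = set_dims,
              set_kinds = set_kinds,
              set_names = set_names,
              set_tags = set_tags,
              age_signal_share = age_share,
              cognition_signal_share = cog_share,
              ...)
}

.sex_var <- function(spec) spec$female_fraction * (1 - spec$female_fraction)

# loadings of one feature set on (t_s, q_s, sex): p x 3; the cognition
# latent enters with alternating sign so that the two set latents remain
# separable from the features
.set_loadings <- function(p) {
  cbind(age = rep(.W_AGE, p),
        cog = .W_COG * (-1)^(seq_len(p) - 1L),
        sex = rep(NA_real_, p)) # sex column filled by caller
}

#' Generate a synthetic cohort and feature sets
#'
#' Draws a cohort (age, sex, fluid cognition) and one numeric feature matrix
#' per set under the linear-Gaussian latent model described in
#' [cohort_spec()]. Identical `(spec, seed)` reproduce identical output
#' bit-wise.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; defaults to `spec$noise_seed`.
#' @return a list of class `cohort_sim` with elements `cohort` (data frame:
#'   `participant_id`, `age`, `sex`, `fluid_cognition`), `features` (named
#'   list of participant-by-feature matrices with row names = participant
#'   ids), `ground_truth` (see [ground_truth_r2()]) and `spec`.
#' @export
generate_cohort <- function(spec, seed = spec$noise_seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_participants
  withr::with_seed(as.integer(seed), {
    age <- runif(n, spec$age_range[1], spec$age_range[2])
    if (spec$recode_90plus) age[age > 90] <- 100
    sex <- rbinom(n, 1L, spec$female_fraction)
    z <- (age - mean(spec$age_range)) / (diff(spec$age_range) / sqrt(12))
    g <- rnorm(n)
    w <- rnorm(n)
    rho <- spec$age_latent_ceiling
    u <- sqrt(rho) * z + sqrt(1 - rho) * w
    A <- spec$cognition_age_share
    B <- spec$cognition_brain_share
    resid_share <- max(0, 1 - A - B)
    cog <- 100 + 15 * (-sqrt(A) * z + sqrt(B) * g +
                         sqrt(resid_share) * rnorm(n))
    ids <- sprintf("sub%04d", seq_len(n))
    features <- vector("list", spec$n_feature_sets)
    names(features) <- spec$set_names
    for (s in seq_len(spec$n_feature_sets)) {
      p <- spec$set_dims[s]
      a_s <- spec$age_signal_share[s]
      c_s <- spec$cognition_signal_share[s]
      t_s <- sqrt(a_s / rho) * u + sqrt(1 - a_s / rho) * rnorm(n)
      q_s <- sqrt(c_s) * g + sqrt(1 - c_s) * rnorm(n)
      L <- .set_loadings(p)
      x <- tcrossprod(t_s, L[, "age"]) + tcrossprod(q_s, L[, "cog"]) +
        .W_EPS * matrix(rnorm(n * p), n, p) +
        spec$sex_effect_size * sex
      colnames(x) <- .feature_names(spec, s)
      rownames(x) <- ids
      attr(x, "kind") <- spec$set_kinds[s]
      attr(x, "tag") <- spec$set_tags[s]
      features[[s]] <- x
    }
    cohort <- data.frame(participant_id = ids, age = age, sex = sex,
                         fluid_cognition = cog, stringsAsFactors = FALSE)
    structure(list(cohort = cohort, features = features,
                   ground_truth = ground_truth_r2(spec), spec = spec,
                   seed = as.integer(seed)),
              class = "cohort_sim")
  })
}

.feature_names <- function(spec, s) {
  p <- spec$set_dims[s]
  if (spec$set_kinds[s] == "connectivity") {
    # region-pair labels in row-major upper-triangle order
    nr <- (1 + sqrt(1 + 8 * p)) / 2
    if (abs(nr - round(nr)) < 1e-8) {
      nr <- as.integer(round(nr))
      idx <- which(upper.tri(matrix(0, nr, nr)), arr.ind = TRUE)
      idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
      return(sprintf("r%03d_r%03d", idx[, 1], idx[, 2]))
    }
  }
  sprintf("%s_f%04d", spec$set_names[s], seq_len(p))
}

#' Closed-form population R-squared values implied by a cohort specification
#'
#' Computes, exactly from the generative covariance structure (no
#' simulation), the population R2 of fluid cognition on age, and the
#' population R2 of the best linear predictor of age and of fluid cognition
#' from each complete feature set. Feature-set values use the
#' Woodbury identity on the factor covariance, so connectivity-sized sets
#' are cheap.
#'
#' @param spec a [cohort_spec()].
#' @return a list of class `ground_truth` with `expected_r2_age_cognition`,
#'   `expected_r2_features_age` and `expected_r2_features_cognition` (named
#'   per-set vectors), and `latent_loadings` (per-set loading matrices on the
#'   set latents and sex).
#' @export
ground_truth_r2 <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  A <- spec$cognition_age_share
  B <- spec$cognition_brain_share
  sv <- .sex_var(spec)
  r2_age <- numeric(spec$n_feature_sets)
  r2_cog <- numeric(spec$n_feature_sets)
  loadings <- vector("list", spec$n_feature_sets)
  for (s in seq_len(spec$n_feature_sets)) {
    p <- spec$set_dims[s]
    a_s <- spec$age_signal_share[s]
    c_s <- spec$cognition_signal_share[s]
    L <- .set_loadings(p)
    L[, "sex"] <- spec$sex_effect_size
    # Sigma_xx = L V L' + d I, V = diag(1, 1, sex_var), d = unique noise
    V <- c(1, 1, sv)
    d <- .W_EPS^2
    # cov(x, z) and cov(x, standardised cognition)
    cz <- L[, "age"] * sqrt(a_s)
    ccog <- L[, "age"] * (-sqrt(A * a_s)) + L[, "cog"] * sqrt(B * c_s)
    # Woodbury: Sigma^-1 v = v/d - L M^-1 L' v / d^2, M = diag(1/V) + L'L/d
    M <- diag(1 / V, 3) + crossprod(L) / d
    quad <- function(v) {
      Ltv <- crossprod(L, v)
      as.numeric(crossprod(v, v) / d -
                   crossprod(Ltv, solve(M, Ltv)) / d^2)
    }
    r2_age[s] <- quad(cz)
    r2_cog[s] <- quad(ccog)
    loadings[[s]] <- L
  }
  names(r2_age) <- names(r2_cog) <- names(loadings) <- spec$set_names
  structure(list(expected_r2_age_cognition = A,
                 expected_r2_features_age = r2_age,
                 expected_r2_features_cognition = r2_cog,
                 latent_loadings = loadings),
            class = "ground_truth")
}

#' Write a simulated cohort to delimited text files
#'
#' Writes `phenotype.csv` (participant_id, age_years, sex, fluid_cognition),
#' one `features/<set>.csv` per feature set, `manifest.json` (set name,
#' path, kind, tag, n_features) and `ground_truth.json`.
#'
#' @param sim a `cohort_sim` from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "cohort_sim"))
  dir.create(file.path(dir, "features"), recursive = TRUE,
             showWarnings = FALSE)
  ph <- sim$cohort
  names(ph)[names(ph) == "age"] <- "age_years"
  write.csv(ph, file.path(dir, "phenotype.csv"), row.names = FALSE)
  sets <- lapply(names(sim$features), function(nm) {
    x <- sim$features[[nm]]
    path <- file.path("features", paste0(nm, ".csv"))
    df <- data.frame(participant_id = rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.csv(df, file.path(dir, path), row.names = FALSE)
    list(name = nm, path = path, kind = attr(x, "kind"),
         tag = attr(x, "tag"), n_features = ncol(x))
  })
  jsonlite::write_json(sets, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  gt <- sim$ground_truth
  jsonlite::write_json(
    list(expected_r2_age_cognition = gt$expected_r2_age_cognition,
         expected_r2_features_age = as.list(gt$expected_r2_features_age),
         expected_r2_features_cognition =
           as.list(gt$expected_r2_features_cognition)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()] (or user-supplied tables in the
#' same layout)
#'
#' @param dir directory containing `phenotype.csv` and `manifest.json`.
#' @return a list with `cohort` and `features` shaped as in
#'   [generate_cohort()] (no ground truth).
#' @export
read_cohort <- function(dir) {
  ph <- read.csv(file.path(dir, "phenotype.csv"), stringsAsFactors = FALSE)
  names(ph)[names(ph) == "age_years"] <- "age"
  if (anyNA(ph)) stop("phenotype table contains missing values")
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  features <- list()
  for (entry in manifest) {
    df <- read.csv(file.path(dir, entry$path), check.names = FALSE,
                   stringsAsFactors = FALSE)
    x <- as.matrix(df[, -1, drop = FALSE])
    rownames(x) <- df$participant_id
    x <- x[ph$participant_id, , drop = FALSE]
    attr(x, "kind") <- entry$kind
    attr(x, "tag") <- entry$tag
    features[[entry$name]] <- x
  }
  list(cohort = ph, features = features)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("cohort_spec: %d participants, ages %g-%g, %d feature sets\n",
              x$n_participants, x$age_range[1], x$age_range[2],
              x$n_feature_sets))
  cat(sprintf("  cognition variance: %.2f age + %.2f brain + %.2f noise\n",
              x$cognition_age_share, x$cognition_brain_share,
              max(0, 1 - x$cognition_age_share - x$cognition_brain_share)))
  invisible(x)
}
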