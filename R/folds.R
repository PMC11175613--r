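# Deterministic nested fold assignments: 5 outer folds over all
# participants; within each outer-training set, two independent 5-fold inner
# partitions (one for level-1 tuning, one for tuning the stacked models).

.partition <- function(ids, k) {
  n <- length(ids)
  f <- rep(seq_len(k), length.out = n)[sample.int(n)]
  names(f) <- ids
  f
}

#' Create a nested cross-validation fold scheme
#'
#' Participants are partitioned uniformly at random into `k_outer` folds
#' whose sizes differ by at most one. For each outer fold, its training set
#' (all other folds) is partitioned into `k_inner` inner folds, drawn
#' independently for the level-1 stage and the stacking stage.
#'
#' @param n number of participants, or a character vector of participant ids.
#' @param k_outer,k_inner fold counts (default 5 and 5).
#' @param seed integer seed; the scheme is deterministic given `(n, seed)`.
#' @return an object of class `fold_scheme` with elements `outer` (named
#'   fold assignment), `inner[[f]]$stage1` / `$stage2` (named assignments of
#'   the outer-training ids), `k_outer`, `k_inner`, `seed`.
#' @export
make_fold_scheme <- function(n, k_outer = 5L, k_inner = 5L, seed = 1L) {
  ids <- if (is.character(n)) n else sprintf("sub%04d", seq_len(n))
  n <- length(ids)
  if (n < k_outer * k_inner)
    stop(sprintf("need at least %d participants for %d x %d nested folds",
                 k_outer * k_inner, k_outer, k_inner), call. = FALSE)
  withr::with_seed(as.integer(seed), {
    outer <- .partition(ids, k_outer)
    inner <- lapply(seq_len(k_outer), function(f) {
      train_ids <- ids[outer != f]
      list(stage1 = .partition(train_ids, k_inner),
           stage2 = .partition(train_ids, k_inner))
    })
  })
  structure(list(outer = outer, inner = inner, ids = ids,
                 k_outer = as.integer(k_outer),
                 k_inner = as.integer(k_inner), seed = as.integer(seed)),
            class = "fold_scheme")
}

#' @export
print.fold_scheme <- function(x, ...) {
  cat(sprintf("fold_scheme: %d participants, %d outer x %d inner, seed %d\n",
              length(x$outer), x$k_outer, x$k_inner, x$seed))
  cat("outer fold sizes:", paste(tabulate(x$outer, x$k_outer),
                                 collapse = ", "), "\n")
  invisible(x)
}
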