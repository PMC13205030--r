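#' Five contiguous temporal blocks of one subject's windows
#'
#' Splits the chronologically ordered window indices into 5 contiguous blocks
#' whose sizes differ by at most 1, the remainder going to the earliest
#' blocks. Subjects with fewer than 5 windows cannot be blocked.
#'
#' @param n_windows number of windows for the subject.
#' @param n_blocks number of blocks.
#' @return list of integer index vectors.
#' @export
make_blocks <- function(n_windows, n_blocks = 5) {
  if (n_windows < n_blocks) stop("subject has fewer windows than blocks")
  base <- n_windows %/% n_blocks
  rem <- n_windows %% n_blocks
  sizes <- rep(base, n_blocks) + c(rep(1L, rem), rep(0L, n_blocks - rem))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  Map(seq.int, starts, ends)
}

#' Personalized temporal-split fold plan
#'
#' For every subject, the chronologically ordered windows are cut into 5
#' contiguous blocks and a seeded uniform permutation assigns one block to
#' each fold (without replacement), independently per subject. Subjects with
#' fewer than 5 windows are excluded and logged.
#'
#' @param features a feature (or window) table with `subject_id` and
#'   `window_start` columns; row order defines the dataset indexing.
#' @param seed integer seed.
#' @param n_folds number of folds.
#' @return a `fold_plan`: per subject the block row-index sets and the
#'   block-to-fold permutation; attribute `excluded`.
#' @export
plan_folds <- function(features, seed = 1L, n_folds = 5) {
  set.seed(as.integer(seed))
  subjects <- unique(features$subject_id)
  plan <- list()
  excluded <- character(0)
  for (sid in subjects) {
    rows <- which(features$subject_id == sid)
    rows <- rows[order(features$window_start[rows])]
    if (length(rows) < n_folds) {
      excluded <- c(excluded, sid)
      next
    }
    blocks <- lapply(make_blocks(length(rows), n_folds), function(ix) rows[ix])
    perm <- sample(n_folds)   # perm[b] = fold in which block b is the test set
    plan[[sid]] <- list(blocks = blocks, block_fold = perm)
  }
  structure(list(plan = plan, seed = as.integer(seed), n_folds = n_folds),
            class = "fold_plan", excluded = excluded)
}

#' Materialize one fold of a plan
#'
#' @param plan a `fold_plan`.
#' @param fold fold number in `1..n_folds`.
#' @return list with disjoint integer row-index vectors `train` and `test`.
#' @export
materialize_fold <- function(plan, fold) {
  stopifnot(inherits(plan, "fold_plan"), fold >= 1, fold <= plan$n_folds)
  train <- integer(0); test <- integer(0)
  for (sp in plan$plan) {
    b_test <- which(sp$block_fold == fold)
    test <- c(test, sp$blocks[[b_test]])
    train <- c(train, unlist(sp$blocks[-b_test]))
  }
  if (length(intersect(train, test))) stop("train/test overlap detected")
  list(train = sort(train), test = sort(test))
}

#' Fold class composition diagnostic
#'
#' Counts hyperglycemia windows in each fold's test set, the style of
#' diagnostic used to explain fold-to-fold sensitivity differences.
#'
#' @param plan a `fold_plan`.
#' @param labels character vector of window labels aligned with the table the
#'   plan was built from.
#' @return data.frame `fold`, `n_test`, `n_hyper`.
#' @export
fold_composition <- function(plan, labels) {
  do.call(rbind, lapply(seq_len(plan$n_folds), function(f) {
    te <- materialize_fold(plan, f)$test
    data.frame(fold = f, n_test = length(te),
               n_hyper = sum(labels[te] == "hyperglycemia"))
  }))
}
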