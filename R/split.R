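# Stratified train/test splitting with largest-remainder allocation of
# per-stratum test counts. This allocation (floors first, then +1 to the
# largest fractional remainders until the rounded global total is
# reached) uniquely reproduces the published test denominators.

#' Per-stratum test counts by largest-remainder rounding
#'
#' @param stratum_sizes Named integer vector of stratum sizes.
#' @param test_fraction Test fraction (default 0.2).
#' @return Named integer vector of test counts summing to
#'   `round(test_fraction * sum(stratum_sizes))`.
#' @export
#' @examples
#' largest_remainder_counts(c(ENV = 975, SELF = 307, PREF = 84,
#'                            COMP = 104, NONSTRAT = 106))
largest_remainder_counts <- function(stratum_sizes, test_fraction = 0.2) {
  exact <- test_fraction * stratum_sizes
  target <- round(test_fraction * sum(stratum_sizes))
  base <- floor(exact)
  left <- target - sum(base)
  if (left > 0) {
    rem <- exact - base
    # larger remainder first; ties to the larger stratum, then name order
    ord <- order(-rem, -stratum_sizes, names(stratum_sizes))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  setNames(as.integer(base), names(stratum_sizes))
}

#' Stratified train/test split
#'
#' Splits record indices so that each stratum contributes exactly its
#' largest-remainder share to the test set; membership within a stratum
#' is chosen uniformly at random under `seed`.
#'
#' @param labels Character vector of stratum labels (one per record).
#' @param test_fraction Test fraction (default 0.2).
#' @param seed RNG seed.
#' @return A list with integer index vectors `train` and `test`
#'   (disjoint, exhaustive) and the `test_counts` allocation.
#' @export
stratified_split <- function(labels, test_fraction = 0.2, seed = 42) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("empty label vector")
  sizes <- table(labels)
  if (any(sizes == 0L)) stop("empty stratum")
  sizes <- setNames(as.integer(sizes), names(sizes))
  counts <- largest_remainder_counts(sizes, test_fraction)
  test <- integer(0L)
  with_seed(seed, {
    for (cls in names(sizes)) {
      idx <- which(labels == cls)
      k <- counts[[cls]]
      if (k > 0L) test <- c(test, sample(idx, k))
    }
  })
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test,
       test_counts = counts)
}

#' Stratified fold assignment for cross-validation
#'
#' Assigns each record to one of `folds` validation folds, stratified by
#' label. When the smallest stratum has fewer records than `folds`, the
#' fold count is reduced to that size with a warning.
#'
#' @param labels Character vector of stratum labels.
#' @param folds Number of folds (default 10).
#' @param seed RNG seed.
#' @return Integer vector of fold ids (1..folds), one per record, with
#'   attribute `folds` (the possibly reduced count).
#' @export
stratified_folds <- function(labels, folds = 10, seed = 42) {
  labels <- as.character(labels)
  min_stratum <- min(table(labels))
  if (min_stratum < folds) {
    warning(sprintf("reducing folds from %d to %d (smallest stratum)",
                    folds, min_stratum))
    folds <- min_stratum
  }
  assign <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  attr(assign, "folds") <- folds
  assign
}
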