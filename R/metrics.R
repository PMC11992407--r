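#' Contingency table of two partitions
#'
#' Class x cluster counts with marginals; the shared basis of all quality
#' and stability metrics. Inputs may be partition tibbles (aligned by
#' `cell_id`), annotation tibbles, or plain label vectors of equal length.
#'
#' @param a,b two labelings of the same cells.
#' @return a list of class `contingency_table` with `counts` (matrix),
#'   `row_marginals`, `col_marginals`, `n`.
#' @export
pairwise_contingency <- function(a, b) {
  ab <- align_label_pair(a, b)
  counts <- unclass(table(ab$a, ab$b))
  structure(
    list(counts = counts,
         row_marginals = rowSums(counts),
         col_marginals = colSums(counts),
         n = sum(counts)),
    class = "contingency_table"
  )
}

align_label_pair <- function(a, b) {
  is_part <- function(x) is.data.frame(x) &&
    (all(c("cell_id", "cluster") %in% names(x)) ||
       all(c("cell_id", "type_label") %in% names(x)))
  get_ids <- function(x) {
    if (is_part(x)) as.character(x$cell_id) else names(x)
  }
  ids_a <- get_ids(a); ids_b <- get_ids(b)
  if (!is.null(ids_a) && !is.null(ids_b)) {
    if (!setequal(ids_a, ids_b)) abort("the two labelings cover different cell sets")
    ids <- sort(ids_a)
    list(a = partition_labels(a, ids), b = partition_labels(b, ids))
  } else {
    la <- partition_labels(a); lb <- partition_labels(b)
    if (length(la) != length(lb)) abort("labelings have different lengths")
    list(a = la, b = lb)
  }
}

entropy_nats <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

cond_entropy_nats <- function(ct) {
  # H(row | col), zero-count cells contributing 0
  n <- ct$n
  h <- 0
  for (j in seq_len(ncol(ct$counts))) {
    nk <- ct$col_marginals[j]
    if (nk == 0) next
    h <- h + (nk / n) * entropy_nats(ct$counts[, j])
  }
  h
}

#' Homogeneity of a clustering
#'
#' `1 - H(C|K) / H(C)` with entropies in nats: 1 when every cluster
#' contains members of a single class only, 0 when clusters are as mixed as
#' the class distribution allows. Defined as 1 when `H(C) = 0` (a single
#' class).
#'
#' @param truth true class labels.
#' @param pred predicted clustering.
#' @return a number in `[0, 1]`.
#' @export
#' @examples
#' homogeneity(c("A", "A", "B", "B"), c(1, 1, 2, 2))
homogeneity <- function(truth, pred) {
  ct <- pairwise_contingency(truth, pred)
  hc <- entropy_nats(ct$row_marginals)
  if (hc == 0) return(1)
  as.numeric(1 - cond_entropy_nats(ct) / hc)
}

#' Completeness of a clustering
#'
#' `1 - H(K|C) / H(K)`: 1 when all members of each class land in one
#' cluster. Defined as 1 when `H(K) = 0` (a single cluster). Dual of
#' [homogeneity()] under swapping the roles of classes and clusters.
#'
#' @inheritParams homogeneity
#' @return a number in `[0, 1]`.
#' @export
completeness <- function(truth, pred) {
  homogeneity(pred, truth)
}

#' V-measure
#'
#' Weighted harmonic combination of homogeneity `h` and completeness `c`:
#' `V_beta = (1 + beta) * h * c / (beta * h + c)`, with `beta = 1` giving
#' equal weighting; 0 when either term is 0.
#'
#' @inheritParams homogeneity
#' @param beta relative weight of homogeneity, default 1.
#' @return a number in `[0, 1]`.
#' @export
v_measure <- function(truth, pred, beta = 1) {
  h <- homogeneity(truth, pred)
  cm <- completeness(truth, pred)
  if (beta * h + cm == 0) return(0)
  (1 + beta) * h * cm / (beta * h + cm)
}

#' Rand index
#'
#' Fraction of the `n(n-1)/2` cell pairs on which two partitions agree
#' (both together or both apart): `(n_TP + n_TN) / n_pairs`.
#'
#' @param a,b two partitions of the same cells.
#' @return a number in `[0, 1]`.
#' @export
#' @examples
#' rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2))
rand_index <- function(a, b) {
  ct <- pairwise_contingency(a, b)
  n <- ct$n
  if (n < 2) abort("rand index needs at least 2 cells")
  n_pairs <- choose(n, 2)
  tp <- sum(choose(ct$counts, 2))
  sum_a <- sum(choose(ct$row_marginals, 2))
  sum_b <- sum(choose(ct$col_marginals, 2))
  (n_pairs + 2 * tp - sum_a - sum_b) / n_pairs
}

#' Adjusted Rand index
#'
#' Rand index adjusted for chance under the permutation model:
#' `(RI - E[RI]) / (max RI - E[RI])`, computed from the contingency
#' marginals. Independent random partitions score about 0; identical
#' partitions score 1. In the fully degenerate case where both partitions
#' are trivial (one cluster each, or all singletons) the adjustment is 0/0
#' and the index is defined as 1, since the partitions are identical; a
#' message reports when this convention is hit.
#'
#' @param a,b two partitions of the same cells.
#' @return a number in `(-1, 1]`.
#' @export
#' @examples
#' adjusted_rand_index(c("A", "A", "B", "B"), c(1, 1, 1, 2))
adjusted_rand_index <- function(a, b) {
  ct <- pairwise_contingency(a, b)
  n <- ct$n
  if (n < 2) abort("adjusted rand index needs at least 2 cells")
  tp <- sum(choose(ct$counts, 2))
  sum_a <- sum(choose(ct$row_marginals, 2))
  sum_b <- sum(choose(ct$col_marginals, 2))
  n_pairs <- choose(n, 2)
  expected <- sum_a * sum_b / n_pairs
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) {
    inform("degenerate partitions (max index equals expected index); ARI defined as 1")
    return(1)
  }
  (tp - expected) / (maximum - expected)
}
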