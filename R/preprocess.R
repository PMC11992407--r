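#' Depth-normalize and log-transform a count matrix
#'
#' The fixed normalization in front of every clustering arm: per-cell depth
#' normalization to the median total count, then `log(1 + x)`. Cells with a
#' zero total (all-zero rows, possible at extreme sparsity) are left as
#' zeros and reported via a message. Deterministic.
#'
#' @param matrix nonnegative cells x genes matrix.
#' @return normalized matrix of the same shape and dimnames.
#' @export
#' @examples
#' m <- matrix(c(1, 0, 2, 4, 0, 8), 2, 3, byrow = TRUE)
#' preprocess_counts(m)
preprocess_counts <- function(matrix) {
  check_count_matrix(matrix)
  totals <- rowSums(matrix)
  zero_cells <- totals == 0
  if (any(zero_cells)) {
    inform(sprintf("%d all-zero cell(s) left as zeros during normalization",
                   sum(zero_cells)))
  }
  med <- median(totals[!zero_cells])
  fac <- ifelse(zero_cells, 0, med / totals)
  log1p(matrix * fac)
}

#' PCA embedding
#'
#' Principal-component scores of the (column-centred) normalized matrix,
#' components ordered by decreasing explained variance. Computed by exact
#' eigendecomposition of the Gram matrix (cells x cells) or the covariance
#' matrix (genes x genes), whichever is smaller, so large gene counts stay
#' cheap; component signs are fixed (the entry of largest magnitude in each
#' score column is positive) so the embedding is fully deterministic.
#'
#' @param matrix normalized cells x genes matrix.
#' @param n_components number of components, `< min(n_cells, n_genes)`.
#' @param random_state accepted for interface parity with randomized
#'   solvers; the exact solver ignores it.
#' @return cells x `n_components` score matrix with an
#'   `explained_variance` attribute.
#' @export
pca_embed <- function(matrix, n_components = 15, random_state = 12345L) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) abort("`matrix` must be numeric")
  n <- nrow(matrix); g <- ncol(matrix)
  if (n_components >= min(n, g)) {
    abort(sprintf("n_components = %d must be smaller than min(n_cells, n_genes) = %d",
                  n_components, min(n, g)))
  }
  xc <- sweep(matrix, 2, colMeans(matrix))
  if (n <= g) {
    e <- eigen(tcrossprod(xc), symmetric = TRUE)
    ev <- pmax(e$values[seq_len(n_components)], 0)
    scores <- e$vectors[, seq_len(n_components), drop = FALSE] %*%
      diag(sqrt(ev), n_components)
  } else {
    e <- eigen(crossprod(xc), symmetric = TRUE)
    scores <- xc %*% e$vectors[, seq_len(n_components), drop = FALSE]
    ev <- pmax(e$values[seq_len(n_components)], 0)
  }
  # deterministic sign convention
  for (j in seq_len(ncol(scores))) {
    k <- which.max(abs(scores[, j]))
    if (scores[k, j] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- rownames(matrix)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  attr(scores, "explained_variance") <- ev / max(n - 1, 1)
  scores
}
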