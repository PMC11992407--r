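#' Expression-weighted dropout injection calibrated to a target sparsity
#'
#' Adds dropouts per class (cell type): within each class, nonzero entries
#' are zeroed by weighted sampling without replacement until the class's
#' zero fraction reaches `f`, with low expression values having a strictly
#' higher probability to drop. The default weight of an entry with value `x`
#' is `exp(-x / xbar)` where `xbar` is the class's mean nonzero expression;
#' alternative weight functions can be plugged in. Existing zeros are never
#' un-zeroed and surviving entries are unchanged, so the zeros of the output
#' are a superset of the zeros of the input. A class whose sparsity already
#' exceeds `f` is returned unchanged with a warning. The number of zeros per
#' class is `round(f * n_entries)` (half-up).
#'
#' Corruption is always applied to the same stored baseline matrix, never
#' cumulatively across levels, so that every level is comparable against
#' one fixed baseline.
#'
#' @param matrix nonnegative cells x genes matrix (rownames are cell ids).
#' @param annotation class label per cell: a tibble with `cell_id`,
#'   `type_label` or a named character vector.
#' @param f target zero fraction in `[0, 1]`, calibrated within each class.
#' @param seed integer seed.
#' @param weight_fun function mapping a vector of nonzero values and the
#'   class mean nonzero expression to sampling weights; must be positive and
#'   decreasing in the value. Default `exp(-x / xbar)`.
#' @return corrupted matrix with a `provenance` attribute.
#' @export
#' @examples
#' m <- matrix(rpois(60, 3) + 1, 6, 10,
#'             dimnames = list(paste0("c", 1:6), paste0("g", 1:10)))
#' ann <- rep("A", 6); names(ann) <- rownames(m)
#' zero_fraction(add_dropouts(m, ann, f = 0.5, seed = 1))
add_dropouts <- function(matrix, annotation, f, seed = 1L,
                         weight_fun = function(x, xbar) exp(-x / xbar)) {
  check_count_matrix(matrix)
  if (!is.numeric(f) || length(f) != 1L || f < 0 || f > 1) {
    abort("`f` must be a single value in [0, 1]")
  }
  labels <- align_annotation(annotation, rownames(matrix))
  out <- matrix
  set.seed(seed)
  for (cls in sort(unique(labels))) {
    rows <- which(labels == cls)
    sub <- matrix[rows, , drop = FALSE]
    total <- length(sub)
    target <- round_half_up(f * total)
    z0 <- sum(sub == 0)
    n_add <- target - z0
    if (n_add < 0) {
      warn(sprintf(
        "class '%s' already has zero fraction %.3f > f = %.3f; returned unchanged",
        cls, z0 / total, f))
      next
    }
    if (n_add == 0) next
    nz <- which(sub != 0)
    vals <- sub[nz]
    w <- weight_fun(vals, mean(vals))
    # weighted sampling without replacement (exponential race): the n_add
    # smallest keys rexp(1)/w are the sampled entries
    keys <- rexp(length(nz)) / w
    drop_idx <- nz[order(keys)[seq_len(n_add)]]
    sub[drop_idx] <- 0
    out[rows, ] <- sub
  }
  attr(out, "provenance") <- sprintf("dropout_expression f=%g seed=%d", f, seed)
  out
}

#' Read-depth dropouts by binomial thinning
#'
#' Emulates reduced sequencing depth: each count `x` is replaced by a
#' `Binomial(x, depth_factor)` draw, so the expected total count is
#' `depth_factor` times the original and sparsity increases as the factor
#' decreases. Defined on integer counts only.
#'
#' @param matrix integer-valued nonnegative matrix.
#' @param depth_factor retention probability in `(0, 1]`.
#' @param seed integer seed.
#' @return thinned integer matrix with a `provenance` attribute.
#' @export
#' @examples
#' m <- matrix(10L, 2, 2)
#' downsample_depth(m, 0.3, seed = 1)
downsample_depth <- function(matrix, depth_factor, seed = 1L) {
  check_count_matrix(matrix)
  if (!is_integer_valued(matrix)) {
    abort("binomial thinning is defined on integer count matrices")
  }
  if (depth_factor <= 0 || depth_factor > 1) {
    abort("`depth_factor` must be in (0, 1]")
  }
  if (depth_factor == 1) return(matrix)
  set.seed(seed)
  out <- matrix
  out[] <- rbinom(length(matrix), size = as.integer(round(matrix)),
                  prob = depth_factor)
  attr(out, "provenance") <- sprintf("dropout_depth q=%g seed=%d", depth_factor, seed)
  out
}

#' Additive and replacement noise models
#'
#' Each entry is independently selected for corruption with probability
#' `p`. Three models:
#' * model 1 — add a draw from `Normal(0, sigma1)`; `sigma1` defaults to
#'   0.1 times the global standard deviation of the nonzero entries
#'   (mild, systematic noise);
#' * model 2 — add a draw from `Normal(mu_g, sigma_g)`, the mean and
#'   standard deviation of that entry's gene computed on the input matrix
#'   (systematic, expression-scaled noise);
#' * model 3 — replace the entry with a uniformly chosen other entry value
#'   of the same cell (random noise ignoring expression level).
#'
#' The absolute value is taken after models 1 and 2 so expression stays
#' nonnegative.
#'
#' @param matrix nonnegative matrix.
#' @param model 1, 2 or 3.
#' @param p per-entry corruption probability in `[0, 1]`.
#' @param seed integer seed.
#' @param sigma1 standard deviation for model 1; default
#'   `0.1 * sd(nonzero entries)`.
#' @return corrupted matrix with a `provenance` attribute.
#' @export
add_noise <- function(matrix, model, p, seed = 1L, sigma1 = NULL) {
  check_count_matrix(matrix)
  if (!model %in% 1:3) abort("`model` must be 1, 2 or 3")
  if (p < 0 || p > 1) abort("`p` must be in [0, 1]")
  out <- matrix
  set.seed(seed)
  sel <- which(stats::runif(length(matrix)) < p)
  if (length(sel) == 0L) {
    attr(out, "provenance") <- sprintf("noise%d p=%g seed=%d", model, p, seed)
    return(out)
  }
  if (model == 1) {
    if (is.null(sigma1)) {
      nz <- matrix[matrix != 0]
      sigma1 <- if (length(nz) > 1) 0.1 * sd(nz) else 0.1
    }
    out[sel] <- abs(matrix[sel] + rnorm(length(sel), 0, sigma1))
  } else if (model == 2) {
    mu_g <- colMeans(matrix)
    sd_g <- apply(matrix, 2, sd)
    sd_g[is.na(sd_g)] <- 0
    gene_of <- ((sel - 1) %/% nrow(matrix)) + 1
    out[sel] <- abs(matrix[sel] + rnorm(length(sel), mu_g[gene_of], sd_g[gene_of]))
  } else {
    if (ncol(matrix) < 2) abort("noise model 3 needs at least 2 genes per cell")
    cell_of <- ((sel - 1) %% nrow(matrix)) + 1
    own_col <- ((sel - 1) %/% nrow(matrix)) + 1
    # uniform donor column among the cell's other entries, vectorized
    donor_col <- 1L + floor(stats::runif(length(sel)) * (ncol(matrix) - 1))
    donor_col <- donor_col + (donor_col >= own_col)
    out[sel] <- matrix[cbind(cell_of, donor_col)]
  }
  attr(out, "provenance") <- sprintf("noise%d p=%g seed=%d", model, p, seed)
  out
}

#' Apply a corruption specification
#'
#' Dispatches on `kind` to [add_dropouts()], [downsample_depth()] or
#' [add_noise()]; the orchestration layer drives sweeps through this single
#' entry point.
#'
#' @param matrix baseline matrix.
#' @param annotation class labels (needed for `dropout_expression`).
#' @param kind one of `"dropout_expression"`, `"dropout_depth"`, `"noise1"`,
#'   `"noise2"`, `"noise3"`.
#' @param level the level on the kind's own scale: target sparsity `f`,
#'   depth factor, or noise probability `p`.
#' @param seed integer seed.
#' @return corrupted matrix.
#' @export
apply_corruption <- function(matrix, annotation, kind, level, seed = 1L) {
  switch(kind,
    dropout_expression = add_dropouts(matrix, annotation, f = level, seed = seed),
    dropout_depth = downsample_depth(matrix, depth_factor = level, seed = seed),
    noise1 = add_noise(matrix, 1, p = level, seed = seed),
    noise2 = add_noise(matrix, 2, p = level, seed = seed),
    noise3 = add_noise(matrix, 3, p = level, seed = seed),
    abort(sprintf("unknown corruption kind '%s'", kind))
  )
}
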