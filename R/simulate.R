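#' Simulation parameters
#'
#' Bundles the settings of the hierarchical gamma–negative-binomial count
#' simulator. Biological structure (cell-type heterogeneity) is baked into
#' the baseline counts; technical corruption is applied later by the
#' corruption operators, so every corruption level can be compared against
#' one fixed baseline.
#'
#' @param n_cells number of cells. The study designs use
#'   500/1,000 cells with 20,000 genes or 5,000–50,000 cells with 2,000
#'   genes, but any positive size is accepted.
#' @param n_genes number of genes.
#' @param tree a [cell_type_tree()]; defaults to `preset_tree("separate3")`.
#' @param library_size_location,library_size_scale log-normal location and
#'   scale of the per-cell relative depth factor (scale 0 disables depth
#'   variation).
#' @param gene_mean_shape,gene_mean_rate gamma parameters of baseline gene
#'   mean expression. The baseline emulates the biological-noise-only first
#'   step of a two-step simulation (true counts before any technical
#'   corruption), so defaults are chosen to keep the baseline near-dense
#'   (zero fraction just under 0.1, from per-type silenced genes and
#'   sampling zeros); the dropout operators then own essentially the whole
#'   sparsity grid.
#' @param dispersion negative-binomial overdispersion; counts are drawn with
#'   `size = 1/dispersion` so variance is `mu + dispersion * mu^2`.
#' @param type_effect_scale magnitude of the tree-propagated log-fold
#'   effects: an edge of branch weight `w` contributes i.i.d. per-gene
#'   effects `Normal(0, (type_effect_scale * sqrt(w))^2)` on the log scale.
#' @param cell_heterogeneity within-type biological cell heterogeneity: each
#'   cell draws latent extrinsic-variation factors that modulate gene
#'   expression through shared loadings, giving cells of the same type a
#'   continuous, correlated sub-structure (total log-scale sd ~
#'   `cell_heterogeneity`). This is the "true cell-cell relationship"
#'   layer whose preservation the stability metrics probe; 0 disables it.
#' @param n_heterogeneity_factors number of latent factors.
#' @param seed integer seed; identical parameters give bitwise-identical
#'   output.
#' @return a `simulation_params` list.
#' @export
simulation_params <- function(n_cells, n_genes,
                              tree = preset_tree("separate3"),
                              library_size_location = 0,
                              library_size_scale = 0.3,
                              gene_mean_shape = 3,
                              gene_mean_rate = 0.15,
                              dispersion = 0.3,
                              type_effect_scale = 1,
                              cell_heterogeneity = 0.15,
                              n_heterogeneity_factors = 5L,
                              seed = 1L) {
  if (n_cells < 1 || n_genes < 1) abort("n_cells and n_genes must be positive")
  if (!inherits(tree, "cell_type_tree")) abort("`tree` must be a cell_type_tree")
  for (p in c(gene_mean_shape, gene_mean_rate, dispersion, type_effect_scale,
              cell_heterogeneity)) {
    if (!is.finite(p) || p < 0) abort("shape/rate/dispersion/effect parameters must be nonnegative")
  }
  if (gene_mean_shape <= 0 || gene_mean_rate <= 0 || dispersion <= 0) {
    abort("gene_mean_shape, gene_mean_rate and dispersion must be strictly positive")
  }
  structure(
    list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
         tree = tree,
         library_size_location = library_size_location,
         library_size_scale = library_size_scale,
         gene_mean_shape = gene_mean_shape, gene_mean_rate = gene_mean_rate,
         dispersion = dispersion, type_effect_scale = type_effect_scale,
         cell_heterogeneity = cell_heterogeneity,
         n_heterogeneity_factors = as.integer(n_heterogeneity_factors),
         seed = as.integer(seed)),
    class = "simulation_params"
  )
}

#' Simulate a labeled baseline count matrix
#'
#' Two-layer generative model emulating a biological-noise-first simulation:
#' (1) per-gene baseline means are gamma distributed; per-leaf mean profiles
#' are obtained by propagating independent Gaussian log-fold effects along
#' the cell-type tree, with effect standard deviation
#' `type_effect_scale * sqrt(branch_weight)` per edge, so leaves sharing a
#' recent ancestor have correlated profiles; (2) each cell draws a
#' log-normal library-size factor and negative-binomial counts around its
#' leaf profile. The result is the uncorrupted baseline every corruption
#' level is later compared against.
#'
#' @param params a [simulation_params()] object.
#' @return a list of class `sc_simulation` with elements
#'   * `counts`: integer cells x genes matrix with cell/gene ids,
#'   * `annotation`: tibble with `cell_id` and `type_label` (the tree leaf,
#'     i.e. the true class); two-level trees add `group_label`, the coarse
#'     parent type of the leaf state,
#'   * `tree`, `params`, and a `provenance` character record.
#' @export
#' @examples
#' sim <- simulate_baseline(simulation_params(60, 100, seed = 1))
#' dim(sim$counts)
#' head(sim$annotation)
simulate_baseline <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  tree <- params$tree
  n <- params$n_cells
  g <- params$n_genes

  set.seed(params$seed)

  base_mean <- rgamma(g, shape = params$gene_mean_shape, rate = params$gene_mean_rate)

  # per-edge log-fold effects, then per-leaf sums along the root->leaf path
  edge_eff <- lapply(seq_len(nrow(tree$edges)), function(i) {
    rnorm(g, 0, params$type_effect_scale * sqrt(tree$edges$branch_weight[i]))
  })
  leaf_logfc <- lapply(tree$leaves, function(leaf) {
    idx <- tree_path_edges(tree, leaf)
    Reduce(`+`, edge_eff[idx], accumulate = FALSE)
  })
  names(leaf_logfc) <- tree$leaves

  # deterministic cell allocation: largest-remainder rounding of fractions
  target <- tree$cell_fractions * n
  n_leaf <- floor(target)
  rem <- n - sum(n_leaf)
  if (rem > 0) {
    extra <- order(target - n_leaf, decreasing = TRUE)[seq_len(rem)]
    n_leaf[extra] <- n_leaf[extra] + 1
  }
  leaf_of_cell <- rep(tree$leaves, times = n_leaf)

  lib <- rlnorm(n, params$library_size_location, params$library_size_scale)
  lib <- lib / mean(lib)

  # extrinsic cell heterogeneity: latent per-cell factors with shared gene
  # loadings, the continuous within-type structure (true cell-cell
  # relationships) that corruption may destroy
  L <- params$n_heterogeneity_factors
  het <- NULL
  if (params$cell_heterogeneity > 0 && L > 0) {
    loadings <- matrix(rnorm(g * L, 0, params$cell_heterogeneity / sqrt(L)), g, L)
    factors <- matrix(rnorm(n * L), n, L)
    het <- tcrossprod(factors, loadings)  # n x g log-scale modulation
  }

  counts <- matrix(0L, nrow = n, ncol = g)
  size <- 1 / params$dispersion
  for (leaf in tree$leaves) {
    rows <- which(leaf_of_cell == leaf)
    if (length(rows) == 0L) next
    mu_leaf <- base_mean * exp(leaf_logfc[[leaf]])
    mu <- outer(lib[rows], mu_leaf)
    if (!is.null(het)) mu <- mu * exp(het[rows, , drop = FALSE])
    counts[rows, ] <- rnbinom(length(mu), size = size, mu = mu)
  }

  cell_ids <- sprintf("cell%0*d", nchar(n), seq_len(n))
  gene_ids <- sprintf("gene%0*d", nchar(g), seq_len(g))
  dimnames(counts) <- list(cell_ids, gene_ids)

  # type_label is always the leaf (the simulation's true class); two-level
  # trees additionally expose the coarse parent type as group_label
  parent_of <- stats::setNames(tree$edges$parent, tree$edges$child)
  leaf_parent <- unname(parent_of[leaf_of_cell])
  two_level <- any(leaf_parent != tree$root)
  annotation <- tibble::tibble(cell_id = cell_ids, type_label = leaf_of_cell)
  if (two_level) {
    annotation$group_label <- ifelse(leaf_parent == tree$root,
                                     leaf_of_cell, leaf_parent)
  }

  structure(
    list(counts = counts, annotation = annotation, tree = tree,
         params = params,
         provenance = sprintf("baseline gamma-NB simulation (seed %d)", params$seed)),
    class = "sc_simulation"
  )
}

#' @export
print.sc_simulation <- function(x, ...) {
  cat(sprintf("<sc_simulation> %d cells x %d genes, %d leaves, zero fraction %.3f\n",
              nrow(x$counts), ncol(x$counts), length(x$tree$leaves),
              zero_fraction(x$counts)))
  invisible(x)
}

#' Ground-truth labels of a simulation
#'
#' The "true classes" used for quality metrics: the tree leaves — cell
#' states where the design is nested, plain cell types otherwise.
#'
#' @param sim an `sc_simulation`.
#' @return character vector of leaf labels named by cell id.
#' @export
true_labels <- function(sim) {
  stats::setNames(sim$annotation$type_label, sim$annotation$cell_id)
}

#' Fraction of zero entries
#'
#' The sparsity of an expression matrix: the quantity the dropout grid
#' `f = 0.1, ..., 0.9` is calibrated against.
#'
#' @param matrix a non-empty cells x genes matrix.
#' @return a number in `[0, 1]`.
#' @export
#' @examples
#' zero_fraction(matrix(c(0, 1, 2, 0), 2))
zero_fraction <- function(matrix) {
  check_count_matrix(matrix)
  sum(matrix == 0) / length(matrix)
}
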