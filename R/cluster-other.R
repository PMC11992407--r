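#' K-Means clustering on a PCA embedding
#'
#' @param embedding cells x dims matrix.
#' @param k number of clusters, `>= 2` and `<= n_cells`.
#' @param random_state integer seed; 10 restarts emulate a k-means++-grade
#'   initialization.
#' @return a partition tibble.
#' @export
kmeans_cluster <- function(embedding, k, random_state = 12345L) {
  if (k < 2 || k > nrow(embedding)) {
    abort("`k` must satisfy 2 <= k <= n_cells")
  }
  set.seed(random_state)
  fit <- stats::kmeans(embedding, centers = k, nstart = 10, iter.max = 100)
  as_partition(fit$cluster, cell_ids = rownames(embedding),
               algorithm = "kmeans", seed = random_state)
}

#' Agglomerative (Ward) clustering on a PCA embedding
#'
#' Ward linkage on Euclidean distances; fully deterministic.
#'
#' @param embedding cells x dims matrix.
#' @param k number of clusters, `>= 2` and `<= n_cells`.
#' @return a partition tibble.
#' @export
agglomerative_cluster <- function(embedding, k) {
  if (k < 2 || k > nrow(embedding)) {
    abort("`k` must satisfy 2 <= k <= n_cells")
  }
  hc <- stats::hclust(stats::dist(embedding), method = "ward.D2")
  as_partition(stats::cutree(hc, k = k), cell_ids = rownames(embedding),
               algorithm = "agglomerative", seed = NA_integer_)
}

#' Silhouette-based estimation of the number of clusters
#'
#' For each candidate `k` in `k_range` the partitioner is fitted and the
#' mean silhouette width computed; the estimate is the `k` with the best
#' silhouette. For seeded K-Means the search is repeated `n_runs` times
#' (default 10) and the rounded mean of the per-run argmax values returned;
#' agglomerative clustering is deterministic, so a single pass suffices.
#' Above 5,000 cells the silhouette is computed on a seeded subsample of
#' 5,000 cells for tractability.
#'
#' @param embedding cells x dims matrix.
#' @param k_range integer vector `c(min, max)`; default `c(2, 50)`, clipped
#'   to `n_cells - 1`.
#' @param n_runs silhouette repetitions for K-Means.
#' @param random_state integer seed.
#' @param method `"kmeans"` or `"agglomerative"`.
#' @return a single integer, the estimated number of clusters.
#' @export
estimate_k <- function(embedding, k_range = c(2, 50), n_runs = 10,
                       random_state = 12345L,
                       method = c("kmeans", "agglomerative")) {
  method <- match.arg(method)
  n <- nrow(embedding)
  ks <- seq(max(2, k_range[1]), min(k_range[2], n - 1))
  if (length(ks) == 0L) abort("empty k range")
  if (length(ks) == 1L) return(ks)

  sil_cells <- seq_len(n)
  if (n > 5000) {
    set.seed(derive_seed(random_state, "silhouette_subsample"))
    sil_cells <- sort(sample.int(n, 5000))
  }
  dmat <- as.matrix(stats::dist(embedding[sil_cells, , drop = FALSE]))

  mean_sil <- function(labels) {
    lab <- labels[sil_cells]
    if (length(unique(lab)) < 2) return(-Inf)
    mean(cluster::silhouette(as.integer(factor(lab)), dmatrix = dmat)[, "sil_width"])
  }

  if (method == "agglomerative") {
    hc <- stats::hclust(stats::dist(embedding), method = "ward.D2")
    sil <- vapply(ks, function(k) mean_sil(stats::cutree(hc, k = k)), 0)
    return(ks[which.max(sil)])
  }

  best <- vapply(seq_len(n_runs), function(r) {
    seed_r <- derive_seed(random_state, "estimate_k", r)
    sil <- vapply(ks, function(k) {
      set.seed(derive_seed(seed_r, k))
      fit <- stats::kmeans(embedding, centers = k, nstart = 10, iter.max = 100)
      mean_sil(fit$cluster)
    }, 0)
    ks[which.max(sil)]
  }, 0L)
  as.integer(round_half_up(mean(best)))
}

#' Per-cell-type random clustering null
#'
#' The non-informative reference: within each cell type, cells are assigned
#' independently and uniformly to one of `n_clusters_per_type` clusters;
#' clusters of different types get disjoint labels. Such partitions respect
#' the global type structure perfectly (homogeneity 1 by construction when
#' classes are the types) but carry no sub-type information, which is the
#' scenario the null represents. The cluster counts worth evaluating are
#' those the baseline pipeline produced across corruption levels.
#'
#' @param annotation class labels: tibble with `cell_id`, `type_label` or a
#'   named vector.
#' @param n_clusters_per_type integer `>= 1`.
#' @param seed integer seed.
#' @return a partition tibble.
#' @export
random_clusters <- function(annotation, n_clusters_per_type, seed = 1L) {
  if (n_clusters_per_type < 1) abort("`n_clusters_per_type` must be >= 1")
  if (is.data.frame(annotation)) {
    ids <- as.character(annotation$cell_id)
    labels <- as.character(annotation$type_label)
  } else {
    ids <- names(annotation) %||% as.character(seq_along(annotation))
    labels <- as.character(annotation)
  }
  set.seed(seed)
  out <- integer(length(ids))
  offset <- 0L
  for (cls in sort(unique(labels))) {
    rows <- which(labels == cls)
    out[rows] <- offset + sample.int(n_clusters_per_type, length(rows),
                                     replace = TRUE)
    offset <- offset + n_clusters_per_type
  }
  as_partition(out, cell_ids = ids, algorithm = "random", seed = seed)
}
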