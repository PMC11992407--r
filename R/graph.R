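pairwise_distances <- function(embedding, metric = c("euclidean", "cosine", "manhattan")) {
  metric <- match.arg(metric)
  if (metric == "cosine") {
    nrm <- sqrt(rowSums(embedding^2))
    nrm[nrm == 0] <- 1  # zero vectors: cosine distance 1 to everything but themselves
    u <- embedding / nrm
    d <- 1 - tcrossprod(u)
    d[d < 0] <- 0
    diag(d) <- 0
    d
  } else {
    as.matrix(stats::dist(embedding, method = metric))
  }
}

#' k-nearest-neighbour graph of an embedding
#'
#' Connects each cell to its `n_neighbors` nearest cells under the chosen
#' metric, using exact neighbour search (deterministic; ties broken by cell
#' order), and symmetrizes by union. Edge weights come from a local-scaling
#' kernel in `(0, 1]`: each directed neighbour gets membership
#' `exp(-(d - rho_i) / sigma_i)` with `rho_i` the distance to the nearest
#' neighbour and `sigma_i` the mean neighbour distance beyond `rho_i`; the
#' undirected weight is the fuzzy union `a + b - ab`, the construction used
#' by default single-cell neighbourhood routines. Set `weighted = FALSE`
#' for a plain unweighted union graph.
#'
#' @param embedding cells x dims matrix (e.g. from [pca_embed()]).
#' @param n_neighbors neighbours per cell, `< n_cells`.
#' @param metric `"euclidean"`, `"cosine"` or `"manhattan"`.
#' @param weighted logical; fuzzy-union kernel weights (default) or all-1.
#' @return an undirected \pkg{igraph} graph whose vertices are named by the
#'   embedding's rownames, with a `weight` edge attribute.
#' @export
knn_graph <- function(embedding, n_neighbors = 30,
                      metric = c("euclidean", "cosine", "manhattan"),
                      weighted = TRUE) {
  metric <- match.arg(metric)
  n <- nrow(embedding)
  if (n_neighbors >= n) abort("`n_neighbors` must be smaller than the number of cells")
  d <- pairwise_distances(embedding, metric)

  nn_idx <- matrix(0L, n, n_neighbors)
  memb <- matrix(0, n, n_neighbors)
  for (i in seq_len(n)) {
    ord <- order(d[i, ])            # stable; self (distance 0) sorts first
    nbr <- setdiff(ord, i)[seq_len(n_neighbors)]
    nn_idx[i, ] <- nbr
    if (weighted) {
      dd <- d[i, nbr]
      rho <- min(dd)
      sigma <- mean(pmax(dd - rho, 0))
      if (sigma <= 0) sigma <- 1
      memb[i, ] <- exp(-pmax(dd - rho, 0) / sigma)
    } else {
      memb[i, ] <- 1
    }
  }

  from <- rep(seq_len(n), each = n_neighbors)
  to <- as.integer(t(nn_idx))
  m <- as.numeric(t(memb))
  # fuzzy union over the two directions
  key_lo <- pmin(from, to); key_hi <- pmax(from, to)
  key <- paste(key_lo, key_hi)
  first <- !duplicated(key)
  a <- m[first]
  match_back <- match(key, key[first])
  b <- rep(0, sum(first))
  dup <- which(!first)
  b[match_back[dup]] <- m[dup]
  w <- if (weighted) a + b - a * b else rep(1, length(a))

  g <- igraph::graph_from_edgelist(cbind(key_lo[first], key_hi[first]),
                                   directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = w)
  ids <- rownames(embedding) %||% as.character(seq_len(n))
  igraph::set_vertex_attr(g, "name", value = ids)
}

#' Graph community detection (Leiden / Louvain)
#'
#' Runs modularity-based community detection on a kNN graph at resolution
#' 1.0 (the pipeline default), seeded through R's RNG so repeated calls with
#' the same `random_state` give identical partitions.
#'
#' @param graph an \pkg{igraph} graph from [knn_graph()].
#' @param method `"leiden"` or `"louvain"`.
#' @param random_state integer seed; the pipeline default is 12345.
#' @param resolution modularity resolution, default 1.
#' @return a partition tibble (see [as_partition()]).
#' @export
community_cluster <- function(graph, method = c("leiden", "louvain"),
                              random_state = 12345L, resolution = 1) {
  method <- match.arg(method)
  if (igraph::vcount(graph) == 0L) abort("empty graph")
  set.seed(random_state)
  comm <- if (method == "leiden") {
    igraph::cluster_leiden(graph, objective_function = "modularity",
                           resolution = resolution, n_iterations = 3)
  } else {
    igraph::cluster_louvain(graph, resolution = resolution)
  }
  as_partition(igraph::membership(comm),
               cell_ids = igraph::V(graph)$name,
               algorithm = method, seed = random_state)
}

#' Build a partition object
#'
#' A partition is a tibble with columns `cell_id` and `cluster`, where
#' cluster labels are relabelled to the contiguous integers `0..k-1` in
#' order of first appearance. Attributes record the producing algorithm and
#' seed.
#'
#' @param labels cluster labels (any atomic type), one per cell.
#' @param cell_ids cell identifiers; defaults to `names(labels)` or an
#'   integer sequence.
#' @param algorithm,seed provenance attributes.
#' @return a tibble of class `partition`.
#' @export
as_partition <- function(labels, cell_ids = NULL, algorithm = NA_character_,
                         seed = NA_integer_) {
  cell_ids <- cell_ids %||% names(labels) %||% as.character(seq_along(labels))
  cluster <- match(labels, unique(labels)) - 1L
  out <- tibble::tibble(cell_id = as.character(cell_ids), cluster = cluster)
  class(out) <- c("partition", class(out))
  attr(out, "algorithm") <- algorithm
  attr(out, "seed") <- seed
  out
}

#' Number of clusters of a partition
#' @param partition a `partition` tibble or label vector.
#' @return integer count of distinct clusters.
#' @export
n_clusters <- function(partition) {
  length(unique(partition_labels(partition)))
}

partition_labels <- function(x, cell_ids = NULL) {
  if (inherits(x, "partition") || (is.data.frame(x) && all(c("cell_id", "cluster") %in% names(x)))) {
    lab <- stats::setNames(x$cluster, x$cell_id)
  } else if (is.data.frame(x) && all(c("cell_id", "type_label") %in% names(x))) {
    lab <- stats::setNames(x$type_label, x$cell_id)
  } else {
    lab <- x
  }
  if (!is.null(cell_ids)) {
    if (is.null(names(lab)) || !all(cell_ids %in% names(lab))) {
      abort("labels do not cover the requested cell ids")
    }
    lab <- lab[cell_ids]
  }
  unname(lab)
}
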