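test_that("kNN graph: mutual neighbours, completeness limit, determinism", {
  b <- make_blobs(10, rbind(c(0, 0), c(5, 5)), sd = 0.2, seed = 2)
  g <- knn_graph(b$x, n_neighbors = 3)
  expect_equal(igraph::vcount(g), 20)
  expect_true(all(igraph::E(g)$weight > 0 & igraph::E(g)$weight <= 1))

  # identical points are mutual nearest neighbours
  x <- b$x; x[2, ] <- x[1, ]
  g2 <- knn_graph(x, n_neighbors = 2)
  expect_true(igraph::are_adjacent(g2, "c001", "c002"))

  # n_neighbors = n - 1 gives the complete graph
  gc <- knn_graph(b$x[1:6, ], n_neighbors = 5)
  expect_equal(igraph::ecount(gc), choose(6, 2))

  expect_identical(igraph::as_edgelist(knn_graph(b$x, 4)),
                   igraph::as_edgelist(knn_graph(b$x, 4)))
  expect_error(knn_graph(b$x, n_neighbors = 20), "smaller")
})

test_that("cosine and manhattan metrics produce valid graphs", {
  b <- make_blobs(15, rbind(c(0, 0, 1), c(4, 4, 0), c(-4, 4, 2)), seed = 3)
  for (metric in c("cosine", "manhattan")) {
    g <- knn_graph(b$x, n_neighbors = 5, metric = metric)
    expect_equal(igraph::vcount(g), 45)
    expect_true(all(igraph::E(g)$weight > 0))
  }
})

test_that("community detection recovers separable structure and is seeded", {
  # two disjoint cliques -> exactly the two cliques
  g <- igraph::make_full_graph(6) + igraph::make_full_graph(6)
  g <- igraph::set_vertex_attr(g, "name", value = paste0("v", 1:12))
  g <- igraph::set_edge_attr(g, "weight", value = 1)
  for (method in c("leiden", "louvain")) {
    p <- community_cluster(g, method, random_state = 1)
    expect_equal(n_clusters(p), 2)
    expect_equal(adjusted_rand_index(p, as_partition(rep(1:2, each = 6),
                                                     paste0("v", 1:12))), 1)
    expect_identical(community_cluster(g, method, random_state = 7),
                     community_cluster(g, method, random_state = 7))
  }
  expect_error(community_cluster(igraph::make_empty_graph(0), "leiden"),
               "empty")
})

test_that("all four arms recover three well-separated simulated cell types", {
  # type sizes commensurate with the neighbourhood scale: communities much
  # larger than n_neighbors invite degenerate modularity sub-splits
  sim <- small_sim(n = 210, g = 400, seed = 19, type_effect_scale = 1.5)
  emb <- pca_embed(preprocess_counts(sim$counts), 15)
  g <- knn_graph(emb, 30)
  truth <- true_labels(sim)
  for (method in c("leiden", "louvain")) {
    p <- community_cluster(g, method)
    expect_gte(adjusted_rand_index(p, truth), 0.95)
  }
  expect_gte(adjusted_rand_index(kmeans_cluster(emb, 3, 1), truth), 0.95)
  expect_gte(adjusted_rand_index(agglomerative_cluster(emb, 3), truth), 0.95)
})

test_that("kmeans and agglomerative recover blobs exactly and obey contracts", {
  b <- make_blobs(20, rbind(c(0, 0), c(6, 6)), sd = 0.3, seed = 5)
  truth <- as_partition(b$labels, rownames(b$x))
  expect_equal(adjusted_rand_index(kmeans_cluster(b$x, 2, 1), truth), 1)
  expect_equal(adjusted_rand_index(agglomerative_cluster(b$x, 2), truth), 1)
  expect_error(kmeans_cluster(b$x, 1), "k")
  expect_error(agglomerative_cluster(b$x, 1), "k")
  p_all <- agglomerative_cluster(b$x, nrow(b$x))
  expect_equal(n_clusters(p_all), nrow(b$x))  # singletons
  expect_identical(kmeans_cluster(b$x, 3, 11), kmeans_cluster(b$x, 3, 11))
})

test_that("silhouette search finds the true number of blob clusters", {
  b <- make_blobs(25, rbind(c(0, 0), c(8, 0), c(0, 8)), sd = 0.4, seed = 6)
  # brute-force oracle over the same k grid (agglomerative, deterministic)
  d <- as.matrix(dist(b$x))
  hc <- hclust(dist(b$x), method = "ward.D2")
  sil <- vapply(2:8, function(k) {
    mean(cluster::silhouette(cutree(hc, k), dmatrix = d)[, "sil_width"])
  }, 0)
  expect_equal((2:8)[which.max(sil)], 3)

  expect_equal(estimate_k(b$x, c(2, 8), method = "agglomerative"), 3)
  expect_equal(estimate_k(b$x, c(2, 8), n_runs = 5, random_state = 3,
                          method = "kmeans"), 3)
  expect_equal(estimate_k(b$x, c(2, 2)), 2)  # degenerate range
})

test_that("random per-type clusters respect types and are chance-level", {
  ann <- tibble::tibble(cell_id = sprintf("c%03d", 1:120),
                        type_label = rep(c("A", "B", "C"), each = 40))
  # n = 1 per type reproduces the type partition
  p1 <- random_clusters(ann, 1, seed = 2)
  expect_equal(adjusted_rand_index(p1, stats::setNames(ann$type_label,
                                                       ann$cell_id)), 1)

  p3 <- random_clusters(ann, 3, seed = 2)
  lab <- stats::setNames(p3$cluster, p3$cell_id)[ann$cell_id]
  # disjoint label ranges per type
  for (ty in c("A", "B", "C")) {
    others <- lab[ann$type_label != ty]
    expect_length(intersect(unique(lab[ann$type_label == ty]), unique(others)), 0)
  }
  # chance-adjusted: mean ARI against an independent global uniform
  # partition ~ 0 (two per-type draws share the type blocks, so their
  # mutual ARI is genuinely positive and is not tested here)
  aris <- vapply(1:100, function(s) {
    a <- random_clusters(ann, 3, seed = s)
    set.seed(10000 + s)
    b <- stats::setNames(sample.int(9, nrow(ann), replace = TRUE), ann$cell_id)
    adjusted_rand_index(a, b)
  }, 0)
  expect_lt(abs(mean(aris)), 0.02)
  expect_error(random_clusters(ann, 0), "n_clusters_per_type")
})

test_that("partitions have contiguous 0-based labels covering every cell", {
  p <- as_partition(c(x = "b", y = "b", z = "a", w = "c"))
  expect_setequal(p$cluster, 0:2)
  expect_equal(p$cluster[1], 0L)  # first-appearance order
  expect_equal(n_clusters(p), 3)
})
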