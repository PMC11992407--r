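test_that("seed derivation is stable, bounded and collision-spread", {
  expect_identical(derive_seed(1, "a", 0.5, 3), derive_seed(1, "a", 0.5, 3))
  expect_false(derive_seed(1, "a", 0.5, 3) == derive_seed(1, "a", 0.5, 4))
  expect_false(derive_seed(1, "a") == derive_seed(2, "a"))
  seeds <- vapply(1:500, function(i) derive_seed(42, "kind", i), 1L)
  expect_equal(length(unique(seeds)), 500)
  expect_true(all(seeds >= 0 & seeds < 2^31))
})

test_that("baseline variability: deterministic arm gives exact 1s, leiden stays near 1", {
  sim <- small_sim(n = 150, g = 200, seed = 23, type_effect_scale = 2)
  agg <- run_baseline(sim$counts, clustering_config(algorithm = "agglomerative",
                                                    k_range = c(2, 8)),
                      n_variability_runs = 5)
  expect_true(all(agg$variability$ari_vs_baseline == 1))

  lei <- run_baseline(sim$counts, clustering_config(), n_variability_runs = 10,
                      master_seed = 3)
  expect_true(all(lei$variability$ari_vs_baseline >= -1 &
                    lei$variability$ari_vs_baseline <= 1))
  expect_gte(mean(lei$variability$ari_vs_baseline), 0.95)
  g <- glance(lei)
  expect_equal(g$n_runs, 10)
  expect_equal(g$mean_ari, mean(lei$variability$ari_vs_baseline))
})

test_that("a small sweep has exact bookkeeping and perfect self-stability at the baseline seed", {
  sim <- small_sim(n = 150, g = 200, seed = 29, type_effect_scale = 2)
  cfg <- sweep_config(kinds = "dropout_expression", levels = c(0.6, 0.9),
                      algorithms = c("leiden", "louvain"),
                      runs_per_combination = 2, master_seed = 11)
  res <- run_sweep(sim$counts, sim$annotation, cfg, dataset_id = "toy")
  expect_s3_class(res, "stability_sweep")
  expect_equal(nrow(res), 2 * 2 * 2)  # levels x algorithms x runs
  expect_true(all(res$status == "ok"))
  expect_true(all(res$ari_vs_baseline <= 1 & res$homogeneity >= 0 &
                    res$homogeneity <= 1 & res$v_measure <= 1))

  # identical master seed reproduces the whole table
  res2 <- run_sweep(sim$counts, sim$annotation, cfg, dataset_id = "toy")
  expect_identical(as.data.frame(res), as.data.frame(res2))

  # clustering the uncorrupted matrix with the baseline seed is B itself
  part <- cluster_pipeline(sim$counts, clustering_config())
  base <- run_baseline(sim$counts, clustering_config(), n_variability_runs = 1)
  expect_equal(adjusted_rand_index(part, base$partition), 1)

  s <- tidy(res)
  expect_true(all(c("mean_ari_vs_baseline", "sd_homogeneity") %in% names(s)))
  expect_equal(sum(s$n_runs), nrow(res))
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(plot_quality_curves(res), "ggplot")
  expect_equal(glance(res)$n_failed, 0)
})

test_that("parameter-grid sweeps attach the perturbed parameters to each record", {
  sim <- small_sim(n = 100, g = 150, seed = 31, type_effect_scale = 2)
  cfg <- sweep_config(levels = 0.7, algorithms = "leiden",
                      runs_per_combination = 1,
                      param_grid = data.frame(n_neighbors = c(5, 15)),
                      master_seed = 2)
  res <- run_sweep(sim$counts, sim$annotation, cfg)
  expect_equal(sort(res$n_neighbors), c(5L, 15L))
  expect_equal(nrow(res), 2)
})

test_that("random-null records: homogeneity exactly 1, ARI-vs-truth matches the oracle", {
  sim <- small_sim(n = 90, g = 120, seed = 37)
  truth <- true_labels(sim)
  base <- cluster_pipeline(sim$counts, clustering_config(n_neighbors = 15))
  null <- run_random_null(sim$annotation, base, cluster_counts = c(2, 4),
                          n_seeds = 10, master_seed = 5)
  expect_equal(nrow(null), 20)
  expect_true(all(null$homogeneity == 1))
  # re-derive one row's partition and check its ARI via the pair oracle
  row <- null[7, ]
  part <- random_clusters(sim$annotation, row$n_clusters_per_type, seed = row$seed)
  lab <- stats::setNames(part$cluster, part$cell_id)[names(truth)]
  expect_equal(row$ari_vs_truth, ari_oracle(lab, truth), tolerance = 1e-12)
})

test_that("external-matrix evaluation reuses the pipeline and enforces contracts", {
  sim <- small_sim(n = 100, g = 150, seed = 41, type_effect_scale = 2)
  base <- run_baseline(sim$counts, clustering_config(), n_variability_runs = 1)
  rec <- evaluate_external_matrix(sim$counts, base$partition, sim$annotation)
  expect_equal(rec$ari_vs_baseline, 1)  # same matrix, same seed -> B itself

  bad_ids <- sim$counts; rownames(bad_ids)[1] <- "intruder"
  expect_error(evaluate_external_matrix(bad_ids, base$partition, sim$annotation),
               "cell ids")
  neg <- sim$counts; neg[1, 1] <- -3
  expect_error(evaluate_external_matrix(neg, base$partition, sim$annotation),
               "negative")
})
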