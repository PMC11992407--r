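#' Clustering pipeline configuration
#'
#' The printed defaults of the baseline pipeline: 15 principal components,
#' 30 neighbours, Euclidean metric, random state 12345; silhouette search
#' over k = 2..50 with 10 runs for the k-requiring algorithms.
#'
#' @param algorithm `"leiden"`, `"louvain"`, `"kmeans"`, `"agglomerative"`
#'   or `"random"`.
#' @param n_components PCA dimensions.
#' @param n_neighbors kNN graph neighbours.
#' @param metric `"euclidean"`, `"cosine"` or `"manhattan"`.
#' @param random_state baseline seed.
#' @param k_range silhouette search interval.
#' @param n_silhouette_runs silhouette repetitions (K-Means).
#' @param weighted_graph use kernel edge weights (default) or unweighted.
#' @return a `clustering_config` list.
#' @export
clustering_config <- function(algorithm = "leiden", n_components = 15,
                              n_neighbors = 30, metric = "euclidean",
                              random_state = 12345L, k_range = c(2, 50),
                              n_silhouette_runs = 10, weighted_graph = TRUE) {
  algorithm <- match.arg(algorithm,
                         c("leiden", "louvain", "kmeans", "agglomerative", "random"))
  metric <- match.arg(metric, c("euclidean", "cosine", "manhattan"))
  stopifnot(n_components >= 1, n_neighbors >= 1, n_silhouette_runs >= 1)
  structure(
    list(algorithm = algorithm, n_components = as.integer(n_components),
         n_neighbors = as.integer(n_neighbors), metric = metric,
         random_state = as.integer(random_state), k_range = k_range,
         n_silhouette_runs = n_silhouette_runs,
         weighted_graph = weighted_graph),
    class = "clustering_config"
  )
}

# shared front half of every pipeline: normalize -> PCA
pipeline_embed <- function(matrix, config) {
  norm <- suppressMessages(preprocess_counts(matrix))
  pca_embed(norm, n_components = config$n_components,
            random_state = config$random_state)
}

#' Run one clustering pipeline end to end
#'
#' Normalization, PCA, then the configured clustering arm: kNN graph plus
#' community detection for Leiden/Louvain, or silhouette-k estimation plus
#' K-Means/agglomerative. `seed` overrides the config's `random_state` for
#' the stochastic stage only (graph construction and PCA are exact), which
#' is how seed-varied re-runs are produced.
#'
#' @param matrix count (or corrupted) matrix, cells x genes.
#' @param config a [clustering_config()].
#' @param seed optional seed override for the clustering stage.
#' @param embedding optionally, a precomputed [pca_embed()] result to reuse.
#' @param graph optionally, a precomputed [knn_graph()] to reuse.
#' @param k for K-Means/agglomerative, fix the number of clusters instead
#'   of estimating it.
#' @return a partition tibble.
#' @export
cluster_pipeline <- function(matrix, config = clustering_config(),
                             seed = NULL, embedding = NULL, graph = NULL,
                             k = NULL) {
  seed <- seed %||% config$random_state
  if (config$algorithm %in% c("leiden", "louvain")) {
    if (is.null(graph)) {
      if (is.null(embedding)) embedding <- pipeline_embed(matrix, config)
      graph <- knn_graph(embedding, n_neighbors = config$n_neighbors,
                         metric = config$metric,
                         weighted = config$weighted_graph)
    }
    community_cluster(graph, method = config$algorithm, random_state = seed)
  } else if (config$algorithm %in% c("kmeans", "agglomerative")) {
    if (is.null(embedding)) embedding <- pipeline_embed(matrix, config)
    if (is.null(k)) {
      k <- estimate_k(embedding, k_range = config$k_range,
                      n_runs = config$n_silhouette_runs,
                      random_state = seed, method = config$algorithm)
    }
    if (config$algorithm == "kmeans") {
      kmeans_cluster(embedding, k, random_state = seed)
    } else {
      agglomerative_cluster(embedding, k)
    }
  } else {
    abort("use random_clusters() for the random-null arm")
  }
}

evaluate_partition <- function(partition, baseline, truth) {
  tibble::tibble(
    ari_vs_baseline = if (is.null(baseline)) NA_real_ else
      adjusted_rand_index(partition, baseline),
    ari_vs_truth = adjusted_rand_index(partition, truth),
    homogeneity = homogeneity(truth, partition),
    completeness = completeness(truth, partition),
    v_measure = v_measure(truth, partition),
    n_clusters = n_clusters(partition)
  )
}

#' Baseline partition and algorithmic variability
#'
#' Clusters the uncorrupted matrix once with the default seed — the
#' baseline partition B that all stability scores are measured against —
#' then re-runs the stochastic stage `n_variability_runs` times (default
#' 100) with distinct seeds and records each re-run's ARI against B. The
#' spread is the algorithm-based (not data-driven) variability band.
#' Deterministic algorithms (agglomerative) give a band of exact 1s.
#'
#' @param matrix uncorrupted count matrix.
#' @param config a [clustering_config()].
#' @param n_variability_runs number of seed-varied re-runs.
#' @param master_seed seed the per-run seeds are derived from.
#' @return list of class `baseline_run`: `partition` (B), `variability`
#'   (tibble with `run`, `seed`, `ari_vs_baseline`, `n_clusters`), `config`.
#' @export
run_baseline <- function(matrix, config = clustering_config(),
                         n_variability_runs = 100, master_seed = 1L) {
  embedding <- pipeline_embed(matrix, config)
  graph <- NULL
  if (config$algorithm %in% c("leiden", "louvain")) {
    graph <- knn_graph(embedding, n_neighbors = config$n_neighbors,
                       metric = config$metric,
                       weighted = config$weighted_graph)
  }
  k_fixed <- NULL
  baseline <- cluster_pipeline(matrix, config, embedding = embedding,
                               graph = graph)
  if (config$algorithm %in% c("kmeans", "agglomerative")) {
    k_fixed <- n_clusters(baseline)
  }
  variability <- purrr::map_dfr(seq_len(n_variability_runs), function(r) {
    seed_r <- derive_seed(master_seed, "baseline_variability", r)
    part <- cluster_pipeline(matrix, config, seed = seed_r,
                             embedding = embedding, graph = graph,
                             k = k_fixed)
    tibble::tibble(run = r, seed = seed_r,
                   ari_vs_baseline = adjusted_rand_index(part, baseline),
                   n_clusters = n_clusters(part))
  })
  structure(list(partition = baseline, variability = variability,
                 config = config),
            class = "baseline_run")
}

#' @export
print.baseline_run <- function(x, ...) {
  cat(sprintf("<baseline_run> %s: %d clusters; variability over %d runs: mean ARI %.3f (sd %.3f)\n",
              x$config$algorithm, n_clusters(x$partition),
              nrow(x$variability), mean(x$variability$ari_vs_baseline),
              sd(x$variability$ari_vs_baseline)))
  invisible(x)
}

#' Sweep configuration
#'
#' The corruption/parameter grid of a stability study. Defaults follow the
#' study protocol: dropout/noise levels 0.1..0.9, 10 runs per combination,
#' Leiden and Louvain arms, and the printed pipeline parameters. Optional
#' `param_grid` rows (columns among `n_neighbors`, `metric`,
#' `n_components`) replicate the perturbation grids
#' (`n_neighbors` 5/30/100, metric euclidean/cosine/manhattan,
#' `n_components` 2/15/50/100/400).
#'
#' @param kinds corruption kinds, see [apply_corruption()].
#' @param levels corruption levels per kind (list or single vector).
#' @param algorithms clustering arms to run.
#' @param runs_per_combination replicate corruptions per level, default 10.
#' @param param_grid optional data frame of pipeline-parameter overrides.
#' @param base_config the unperturbed [clustering_config()].
#' @param master_seed master seed; all per-run seeds derive from it.
#' @return a `sweep_config` list.
#' @export
sweep_config <- function(kinds = "dropout_expression",
                         levels = seq(0.1, 0.9, by = 0.1),
                         algorithms = c("leiden", "louvain"),
                         runs_per_combination = 10,
                         param_grid = NULL,
                         base_config = clustering_config(),
                         master_seed = 1L) {
  if (!is.list(levels)) levels <- stats::setNames(rep(list(levels), length(kinds)), kinds)
  stopifnot(length(kinds) > 0, all(kinds %in% names(levels)),
            runs_per_combination >= 1)
  for (k in kinds) {
    if (any(levels[[k]] < 0 | levels[[k]] > 1)) abort("levels must lie in [0, 1]")
  }
  structure(
    list(kinds = kinds, levels = levels, algorithms = algorithms,
         runs_per_combination = as.integer(runs_per_combination),
         param_grid = param_grid, base_config = base_config,
         master_seed = as.integer(master_seed)),
    class = "sweep_config"
  )
}

apply_config_override <- function(config, override) {
  for (nm in names(override)) config[[nm]] <- override[[nm]]
  config
}

#' Run a corruption sweep
#'
#' The full stability/quality experiment on one dataset: for every
#' (corruption kind, level, pipeline-parameter combination, run), the
#' stored baseline matrix is corrupted (never cumulatively — each level
#' starts from the same baseline), pushed through normalization, PCA and
#' graph construction once, then clustered by every requested algorithm and
#' evaluated against both the algorithm's baseline partition B (stability,
#' ARI) and the true labels (quality: ARI, homogeneity, completeness,
#' v-measure). Per-run seeds are derived from the master seed and the grid
#' coordinates, so the whole sweep is reproducible from one integer. A
#' failing combination is recorded with `status = "error"` rather than
#' dropped.
#'
#' @param matrix baseline (uncorrupted) count matrix.
#' @param annotation class labels (tibble or named vector).
#' @param config a [sweep_config()].
#' @param dataset_id identifier copied into every record.
#' @return a tibble of class `stability_sweep`, one row per run:
#'   `dataset_id`, `kind`, `level`, `run`, `algorithm`, `n_components`,
#'   `n_neighbors`, `metric`, `seed`, `ari_vs_baseline`, `ari_vs_truth`,
#'   `homogeneity`, `completeness`, `v_measure`, `n_clusters`, `status`.
#' @export
run_sweep <- function(matrix, annotation, config = sweep_config(),
                      dataset_id = "dataset") {
  check_count_matrix(matrix)
  truth <- align_annotation(annotation, rownames(matrix))
  truth <- stats::setNames(truth, rownames(matrix))

  grid <- config$param_grid
  if (is.null(grid)) grid <- tibble::tibble(.combo = 1L) else {
    grid <- tibble::as_tibble(grid); grid$.combo <- seq_len(nrow(grid))
  }

  # baseline partition per (algorithm, parameter combo)
  baselines <- list()
  fixed_k <- list()
  for (ci in grid$.combo) {
    over <- grid[grid$.combo == ci, setdiff(names(grid), ".combo"), drop = FALSE]
    cfg0 <- apply_config_override(config$base_config, as.list(over))
    emb0 <- pipeline_embed(matrix, cfg0)
    for (alg in config$algorithms) {
      cfg <- cfg0; cfg$algorithm <- alg
      key <- paste(alg, ci)
      baselines[[key]] <- cluster_pipeline(matrix, cfg, embedding = emb0)
      if (alg %in% c("kmeans", "agglomerative")) {
        fixed_k[[key]] <- NULL  # k re-estimated per corrupted matrix
      }
    }
  }

  rows <- list()
  for (kind in config$kinds) {
    for (level in config$levels[[kind]]) {
      for (run in seq_len(config$runs_per_combination)) {
        corr_seed <- derive_seed(config$master_seed, dataset_id, kind, level, run)
        corrupted <- tryCatch(
          suppressWarnings(apply_corruption(matrix, truth, kind, level,
                                            seed = corr_seed)),
          error = function(e) e)
        for (ci in grid$.combo) {
          over <- grid[grid$.combo == ci, setdiff(names(grid), ".combo"), drop = FALSE]
          cfg0 <- apply_config_override(config$base_config, as.list(over))
          shared <- NULL
          for (alg in config$algorithms) {
            cfg <- cfg0; cfg$algorithm <- alg
            key <- paste(alg, ci)
            clust_seed <- derive_seed(config$master_seed, dataset_id, kind,
                                      level, run, alg, ci)
            rec <- tibble::tibble(
              dataset_id = dataset_id, kind = kind, level = level, run = run,
              algorithm = alg, n_components = cfg$n_components,
              n_neighbors = cfg$n_neighbors, metric = cfg$metric,
              seed = clust_seed)
            res <- tryCatch({
              if (inherits(corrupted, "error")) stop(conditionMessage(corrupted))
              if (is.null(shared)) {
                emb <- pipeline_embed(corrupted, cfg0)
                gph <- if (any(config$algorithms %in% c("leiden", "louvain"))) {
                  knn_graph(emb, n_neighbors = cfg0$n_neighbors,
                            metric = cfg0$metric,
                            weighted = cfg0$weighted_graph)
                } else NULL
                shared <- list(embedding = emb, graph = gph)
              }
              part <- cluster_pipeline(
                corrupted, cfg, seed = clust_seed,
                embedding = shared$embedding,
                graph = if (alg %in% c("leiden", "louvain")) shared$graph else NULL)
              cbind(rec, evaluate_partition(part, baselines[[key]], truth),
                    tibble::tibble(status = "ok"))
            }, error = function(e) {
              cbind(rec, tibble::tibble(
                ari_vs_baseline = NA_real_, ari_vs_truth = NA_real_,
                homogeneity = NA_real_, completeness = NA_real_,
                v_measure = NA_real_, n_clusters = NA_integer_,
                status = paste("error:", conditionMessage(e))))
            })
            rows[[length(rows) + 1L]] <- tibble::as_tibble(res)
          }
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("stability_sweep", class(out))
  attr(out, "sweep_config") <- config
  out
}

#' Random-null evaluation
#'
#' Evaluates per-cell-type random partitions — for each requested cluster
#' count and each seed — through the identical metric path as the pipeline
#' arms, giving the non-informative reference band. The cluster counts to
#' use are typically the counts the baseline pipeline produced across all
#' corruption levels of a sweep (e.g.
#' `unique(sweep_result$n_clusters)`).
#'
#' @param annotation class labels.
#' @param baseline the baseline partition B (stability reference), or
#'   `NULL` to skip the stability column.
#' @param cluster_counts integer vector of per-type cluster counts to test.
#' @param n_seeds random repetitions per count.
#' @param master_seed seed the per-draw seeds derive from.
#' @return tibble, one row per (count, seed), same metric columns as
#'   [run_sweep()].
#' @export
run_random_null <- function(annotation, baseline, cluster_counts,
                            n_seeds = 100, master_seed = 1L) {
  if (is.data.frame(annotation)) {
    truth <- stats::setNames(as.character(annotation$type_label),
                             as.character(annotation$cell_id))
  } else truth <- annotation
  purrr::map_dfr(cluster_counts, function(nc) {
    purrr::map_dfr(seq_len(n_seeds), function(s) {
      seed <- derive_seed(master_seed, "random_null", nc, s)
      part <- random_clusters(truth, n_clusters_per_type = nc, seed = seed)
      cbind(tibble::tibble(algorithm = "random", n_clusters_per_type = nc,
                           run = s, seed = seed),
            evaluate_partition(part, baseline, truth))
    })
  })
}

#' Evaluate an externally produced matrix
#'
#' Pushes any matrix on the same cells — e.g. an imputed version of a
#' corrupted matrix — through the identical cluster-and-evaluate path, so
#' external processing tools can be compared against the corruption arms.
#'
#' @param matrix nonnegative matrix with the same cell ids as the baseline.
#' @param baseline baseline partition B.
#' @param annotation true labels.
#' @param config a [clustering_config()].
#' @param seed clustering seed (defaults to the config's random state).
#' @return one-row tibble of metrics.
#' @export
evaluate_external_matrix <- function(matrix, baseline, annotation,
                                     config = clustering_config(),
                                     seed = NULL) {
  check_count_matrix(matrix)
  if (!setequal(rownames(matrix), baseline$cell_id)) {
    abort("matrix cell ids do not match the baseline partition")
  }
  truth <- align_annotation(annotation, rownames(matrix))
  truth <- stats::setNames(truth, rownames(matrix))
  part <- cluster_pipeline(matrix, config, seed = seed)
  cbind(tibble::tibble(algorithm = config$algorithm,
                       seed = seed %||% config$random_state),
        evaluate_partition(part, baseline, truth))
}
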