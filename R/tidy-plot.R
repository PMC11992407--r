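#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Summarize a sweep as mean-and-sd curves
#'
#' Collapses the one-row-per-run sweep table to the mean and standard
#' deviation of every metric per (dataset, corruption kind, level,
#' algorithm, parameter combination) — the quantities plotted as stability
#' and quality curves.
#'
#' @param x a `stability_sweep` from [run_sweep()].
#' @param ... unused.
#' @return a tibble with `mean_*` and `sd_*` columns per metric.
#' @method tidy stability_sweep
#' @export
tidy.stability_sweep <- function(x, ...) {
  x |>
    dplyr::filter(.data$status == "ok") |>
    dplyr::group_by(.data$dataset_id, .data$kind, .data$level,
                    .data$algorithm, .data$n_components, .data$n_neighbors,
                    .data$metric) |>
    dplyr::summarise(
      dplyr::across(
        c("ari_vs_baseline", "ari_vs_truth", "homogeneity",
          "completeness", "v_measure", "n_clusters"),
        list(mean = ~mean(.x), sd = ~sd(.x)),
        .names = "{.fn}_{.col}"),
      n_runs = dplyr::n(), .groups = "drop")
}

#' One-line summary of a sweep
#'
#' @param x a `stability_sweep`.
#' @param ... unused.
#' @return a one-row tibble: run counts, failure count, and the stability
#'   drop (mean baseline-ARI at the lowest minus at the highest level).
#' @method glance stability_sweep
#' @export
glance.stability_sweep <- function(x, ...) {
  ok <- dplyr::filter(x, .data$status == "ok")
  rng <- range(ok$level)
  drop <- ok |>
    dplyr::filter(.data$level %in% rng) |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(m = mean(.data$ari_vs_baseline), .groups = "drop")
  tibble::tibble(
    n_records = nrow(x),
    n_failed = sum(x$status != "ok"),
    n_levels = dplyr::n_distinct(x$level),
    stability_drop = drop$m[drop$level == rng[1]][1] -
      drop$m[drop$level == rng[2]][1]
  )
}

#' Variability summary of a baseline run
#'
#' @param x a `baseline_run` from [run_baseline()].
#' @param ... unused.
#' @return one-row tibble: algorithm, cluster count of B, and the mean/sd/
#'   min of the seed-varied re-run ARIs.
#' @method glance baseline_run
#' @export
glance.baseline_run <- function(x, ...) {
  tibble::tibble(
    algorithm = x$config$algorithm,
    n_clusters = n_clusters(x$partition),
    n_runs = nrow(x$variability),
    mean_ari = mean(x$variability$ari_vs_baseline),
    sd_ari = sd(x$variability$ari_vs_baseline),
    min_ari = min(x$variability$ari_vs_baseline)
  )
}

#' @export
#' @rdname glance.baseline_run
#' @return for `tidy`, the per-run variability tibble.
tidy.baseline_run <- function(x, ...) x$variability

#' Stability curves of a sweep
#'
#' Mean ARI-vs-baseline per corruption level and algorithm, with a ±1 sd
#' ribbon — the stability figure of a corruption experiment. Use
#' [plot_quality_curves()] for the homogeneity/completeness/v-measure
#' counterpart.
#'
#' @param object a `stability_sweep`.
#' @param metric which metric column to draw, default `ari_vs_baseline`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot stability_sweep
#' @export
autoplot.stability_sweep <- function(object, metric = "ari_vs_baseline", ...) {
  s <- tidy.stability_sweep(object)
  m <- paste0("mean_", metric); d <- paste0("sd_", metric)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$level, y = .data[[m]],
                                  colour = .data$algorithm,
                                  fill = .data$algorithm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data[[m]] - .data[[d]],
                                      ymax = .data[[m]] + .data[[d]]),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linetype = "dotted") +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(. ~ kind) +
    ggplot2::labs(x = "corruption level", y = metric) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Quality curves of a sweep
#'
#' Homogeneity, completeness and v-measure means per corruption level and
#' algorithm.
#'
#' @param sweep a `stability_sweep`.
#' @return a ggplot object.
#' @export
plot_quality_curves <- function(sweep) {
  s <- tidy.stability_sweep(sweep) |>
    tidyr::pivot_longer(c("mean_homogeneity", "mean_completeness",
                          "mean_v_measure"),
                        names_to = "measure", values_to = "value") |>
    dplyr::mutate(measure = sub("^mean_", "", .data$measure))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$level, y = .data$value,
                                  colour = .data$algorithm,
                                  linetype = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(. ~ kind) +
    ggplot2::labs(x = "corruption level", y = "score") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
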