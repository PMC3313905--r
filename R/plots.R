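# ggplot2 visualizations of the main result types.

#' M-A scatter plot of a ratio profile
#'
#' @param profile Tibble with `M`, `A` (e.g. [compute_ma()] or
#'   [normalize_loess_ma()] output).
#' @param span Loess span of the overlaid trend.
#' @return A ggplot.
#' @export
plot_ma <- function(profile, span = 0.10) {
  assert_columns(profile, c("M", "A"), "profile")
  ggplot2::ggplot(dplyr::filter(profile, is.finite(.data$M)),
                  ggplot2::aes(x = .data$A, y = .data$M)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_smooth(method = "loess", span = span,
                         formula = y ~ x, se = FALSE, colour = "red") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "A (mean log2 intensity)", y = "M (log2 ratio)")
}

#' @describeIn plot_silhouette_curve autoplot method.
#' @method autoplot gc_kselect
#' @export
autoplot.gc_kselect <- function(object, ...) {
  plot_silhouette_curve(object)
}

#' Silhouette curve over candidate cluster numbers
#'
#' @param x A `gc_kselect` object.
#' @return A ggplot of the best mean silhouette width against k, the
#'   optimum marked.
#' @export
plot_silhouette_curve <- function(x) {
  stopifnot(inherits(x, "gc_kselect"))
  ggplot2::ggplot(x$curve,
                  ggplot2::aes(x = .data$k, y = .data$mean_silhouette)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = x$k_star, linetype = 2,
                        colour = "red") +
    ggplot2::labs(x = "number of clusters k",
                  y = "best mean silhouette width")
}

#' @describeIn plot_cluster_profiles autoplot method (needs the profiles
#'   used for clustering).
#' @param object,... Passed through.
#' @method autoplot gc_cluster
#' @export
autoplot.gc_cluster <- function(object, profiles, ...) {
  plot_cluster_profiles(profiles, object$assignment)
}

#' Per-cluster expression profiles
#'
#' One panel per cluster: gene log-ratio trajectories across the
#' experiments with the cluster mean overlaid.
#'
#' @param profiles Wide tibble (`gene_id` + one column per experiment).
#' @param assignment Tibble with `gene_id`, `cluster`.
#' @return A ggplot.
#' @export
plot_cluster_profiles <- function(profiles, assignment) {
  long <- profiles |>
    dplyr::inner_join(assignment, by = "gene_id") |>
    tidyr::pivot_longer(!c("gene_id", "cluster"),
                        names_to = "experiment_id", values_to = "M")
  means <- long |>
    dplyr::group_by(.data$cluster, .data$experiment_id) |>
    dplyr::summarise(M = mean(.data$M), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$experiment_id, y = .data$M,
                                     group = .data$gene_id)) +
    ggplot2::geom_line(alpha = 0.25, colour = "grey50") +
    ggplot2::geom_line(data = means,
                       ggplot2::aes(group = .data$cluster),
                       colour = "red", linewidth = 1) +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = "experiment", y = "log2 ratio M")
}

#' Chromosome-level mean expression
#'
#' Sign-split mean log ratios per chromosome for one scope.
#'
#' @param profiles Output of [chromosome_means()].
#' @return A ggplot.
#' @export
plot_chromosome_means <- function(profiles) {
  assert_columns(profiles, c("chromosome", "m_pos", "m_neg"),
                 "chromosome profiles")
  long <- profiles |>
    tidyr::pivot_longer(c("m_pos", "m_neg"), names_to = "sign",
                        values_to = "mean_M") |>
    dplyr::filter(is.finite(.data$mean_M))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$chromosome,
                                     y = .data$mean_M,
                                     fill = .data$sign)) +
    ggplot2::geom_col(position = "identity") +
    ggplot2::labs(x = "chromosome", y = "mean log2 ratio", fill = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
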