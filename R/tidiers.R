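# broom-style accessors for the fitted objects.

#' Tidy a clustering result
#'
#' @param x A `gc_cluster` object.
#' @param ... Unused.
#' @return Per-gene tibble: `gene_id`, `cluster`, `silhouette`.
#' @method tidy gc_cluster
#' @export
tidy.gc_cluster <- function(x, ...) {
  dplyr::left_join(x$assignment, x$silhouettes, by = "gene_id")
}

#' One-row summary of a clustering result
#'
#' @param x A `gc_cluster` object.
#' @param ... Unused.
#' @method glance gc_cluster
#' @export
glance.gc_cluster <- function(x, ...) {
  tibble(k = x$k, within_sse = x$within_sse,
         mean_silhouette = x$mean_silhouette, n_init = x$n_init)
}

#' Tidy a cluster-number selection
#'
#' @param x A `gc_kselect` object.
#' @param ... Unused.
#' @return The silhouette curve: `k`, `mean_silhouette`, and whether each
#'   k is the optimum.
#' @method tidy gc_kselect
#' @export
tidy.gc_kselect <- function(x, ...) {
  dplyr::mutate(x$curve, optimal = .data$k == x$k_star)
}

#' One-row summary of a cluster-number selection
#'
#' @param x A `gc_kselect` object.
#' @param ... Unused.
#' @method glance gc_kselect
#' @export
glance.gc_kselect <- function(x, ...) {
  tibble(k_star = x$k_star,
         max_mean_silhouette = max(x$curve$mean_silhouette),
         k_min = min(x$curve$k), k_max = max(x$curve$k),
         n_init = x$n_init)
}

#' Tidy a pipeline result
#'
#' @param x A `gc_pipeline` object.
#' @param ... Unused.
#' @return The flat verdict table.
#' @method tidy gc_pipeline
#' @export
tidy.gc_pipeline <- function(x, ...) {
  flatten_verdicts(x$verdicts)
}

#' One-row summary of a pipeline run
#'
#' @param x A `gc_pipeline` object.
#' @param ... Unused.
#' @method glance gc_pipeline
#' @export
glance.gc_pipeline <- function(x, ...) {
  tibble(
    n_cgs = length(x$cgs),
    n_loop_removed = sum(!x$loop_filter$keep),
    k_star = x$kselect$k_star,
    mean_silhouette = x$clustering$mean_silhouette,
    n_inherent = sum(x$verdicts$resistance == "inherent"),
    n_acquired = sum(x$verdicts$resistance == "acquired"),
    n_undefined = sum(x$verdicts$resistance == "undefined")
  )
}
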