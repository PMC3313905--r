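# Cluster analysis: SD-ranked gene selection, restarted k-means with
# random data-point seeding, squared-Euclidean silhouette widths, and
# silhouette-based selection of the number of clusters.

profiles_to_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
    return(x)
  }
  assert_columns(x, "gene_id", "profiles")
  mat <- as.matrix(dplyr::select(x, !"gene_id"))
  rownames(mat) <- x$gene_id
  storage.mode(mat) <- "double"
  mat
}

#' Select the highest-variance genes
#'
#' Ranks genes by the sample SD of their profile across experiments and
#' keeps the top `n` (the study's "SD100" selection when `n = 100`). Ties
#' are broken by gene identifier so the selection is deterministic.
#'
#' @param profiles Wide tibble: `gene_id` plus one numeric column per
#'   experiment.
#' @param n Number of genes to keep.
#' @return The selected rows of `profiles`, highest SD first.
#' @export
select_high_variance <- function(profiles, n = 100) {
  assert_columns(profiles, "gene_id", "profiles")
  if (n > nrow(profiles)) {
    abort(sprintf("`n` (%d) exceeds the number of genes (%d).",
                  n, nrow(profiles)))
  }
  mat <- profiles_to_matrix(profiles)
  sds <- apply(mat, 1, sd)
  ord <- order(-sds, profiles$gene_id)
  profiles[ord[seq_len(n)], , drop = FALSE]
}

# One k-means restart from k distinct random data points. Retries with a
# fresh draw if the seeding is degenerate (duplicate points / empty
# cluster failure inside stats::kmeans).
kmeans_restart <- function(mat, k, iter.max = 50) {
  for (try in seq_len(25)) {
    centers <- mat[sample.int(nrow(mat), k), , drop = FALSE]
    if (anyDuplicated(centers)) next
    km <- tryCatch(
      suppressWarnings(stats::kmeans(mat, centers, iter.max = iter.max)),
      error = function(e) NULL
    )
    if (!is.null(km) && all(km$size > 0)) return(km)
  }
  abort("k-means failed repeatedly: could not find a non-degenerate seeding.")
}

# Silhouette widths from a precomputed full distance matrix (any metric).
silhouette_from_dist <- function(D, grp) {
  k <- length(unique(grp))
  if (k < 2) abort("silhouettes need at least 2 clusters.")
  grp <- as.integer(factor(grp))
  n <- length(grp)
  sums <- rowsum(D, grp) # k x n: total distance from cluster c to point i
  counts <- tabulate(grp, nbins = max(grp))
  denom <- matrix(counts, nrow = max(grp), ncol = n)
  own <- cbind(grp, seq_len(n))
  denom[own] <- denom[own] - 1L # exclude the point itself from a_i
  means <- sums / denom
  a <- means[own]
  means[own] <- Inf
  b <- apply(means, 2, min)
  s <- ifelse(counts[grp] == 1L, 0, # singleton convention
              ifelse(pmax(a, b) == 0, 0, (b - a) / pmax(a, b)))
  as.numeric(s)
}

#' Silhouette widths of a clustering
#'
#' `S_i = (b_i - a_i) / max(a_i, b_i)` with `a_i` the mean distance of
#' point i to its own cluster's other members and `b_i` the smallest mean
#' distance to another cluster. The squared Euclidean distance is used by
#' default, matching the clustering objective. Singleton clusters get
#' `S_i = 0`, as do points with `a_i = b_i = 0`.
#'
#' @param profiles Wide tibble (`gene_id` + numeric columns) or matrix.
#' @param assignment Integer cluster labels, or a tibble with `gene_id`
#'   and `cluster`.
#' @param metric `"sqeuclidean"` (default) or `"euclidean"`.
#' @return A list with `silhouettes` (tibble: `gene_id`, `silhouette`) and
#'   `mean_silhouette`.
#' @export
silhouette_mean <- function(profiles, assignment,
                            metric = c("sqeuclidean", "euclidean")) {
  metric <- match.arg(metric)
  mat <- profiles_to_matrix(profiles)
  if (is.data.frame(assignment)) {
    assert_columns(assignment, c("gene_id", "cluster"), "assignment")
    grp <- assignment$cluster[match(rownames(mat), assignment$gene_id)]
  } else {
    grp <- assignment
  }
  D <- as.matrix(dist(mat))
  if (metric == "sqeuclidean") D <- D^2
  s <- silhouette_from_dist(D, grp)
  list(silhouettes = tibble(gene_id = rownames(mat), silhouette = s),
       mean_silhouette = mean(s))
}

#' Restarted k-means, best of n runs
#'
#' Runs k-means `n_init` times from random data-point seedings and returns
#' the run minimizing the total within-cluster sum of squared
#' point-to-centroid distances. Silhouette widths (squared Euclidean) of
#' the winning run are attached.
#'
#' @param profiles Wide tibble (`gene_id` + numeric columns) or matrix.
#' @param k Number of clusters (2..n).
#' @param n_init Number of random restarts.
#' @param seed Integer master seed, split into per-restart seeds.
#' @return An object of class `gc_cluster`: assignment, centroids,
#'   `within_sse`, per-gene silhouettes, `mean_silhouette`, and the
#'   within-SSE of every restart (`restart_sse`).
#' @export
kmeans_best_of <- function(profiles, k, n_init = 100, seed = 1L) {
  mat <- profiles_to_matrix(profiles)
  if (k < 2 || k > nrow(mat)) abort("`k` must lie in 2..number of points.")
  seeds <- split_seed(seed, n_init)
  best <- NULL
  sse <- numeric(n_init)
  for (i in seq_len(n_init)) {
    km <- withr::with_seed(seeds[i], kmeans_restart(mat, k))
    sse[i] <- km$tot.withinss
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  sil <- silhouette_mean(mat, best$cluster)
  structure(
    list(
      assignment = tibble(gene_id = rownames(mat),
                          cluster = as.integer(best$cluster)),
      centroids = best$centers,
      within_sse = best$tot.withinss,
      restart_sse = sse,
      silhouettes = sil$silhouettes,
      mean_silhouette = sil$mean_silhouette,
      k = as.integer(k),
      n_init = as.integer(n_init)
    ),
    class = "gc_cluster"
  )
}

#' @export
print.gc_cluster <- function(x, ...) {
  cat(sprintf(
    "k-means clustering: k = %d, best of %d restarts\n  within-cluster SSE %.4g, mean silhouette width %.4f\n",
    x$k, x$n_init, x$within_sse, x$mean_silhouette))
  invisible(x)
}

#' Silhouette-based selection of the number of clusters
#'
#' For each k in `k_min..k_max`, k-means is restarted `n_init` times and
#' the best (maximum) average silhouette width over the restarts is
#' recorded; the optimal k is the one maximizing this curve (ties go to
#' the smallest k).
#'
#' @param profiles Wide tibble (`gene_id` + numeric columns) or matrix.
#' @param k_min,k_max Range of k to scan.
#' @param n_init Restarts per k.
#' @param seed Integer master seed.
#' @return An object of class `gc_kselect`: `k_star`, the `curve` tibble
#'   (`k`, `mean_silhouette`), and the winning clustering (`best`, a
#'   `gc_cluster`-like list for `k_star`).
#' @export
select_optimal_k <- function(profiles, k_min = 2, k_max = 30,
                             n_init = 1000, seed = 1L) {
  mat <- profiles_to_matrix(profiles)
  if (k_max >= nrow(mat)) abort("`k_max` must be smaller than the number of points.")
  if (k_min < 2) abort("`k_min` must be at least 2.")
  D2 <- as.matrix(dist(mat))^2
  ks <- seq.int(k_min, k_max)
  seeds <- split_seed(seed, length(ks))
  best_by_k <- purrr::map(seq_along(ks), function(j) {
    k <- ks[j]
    rseeds <- split_seed(seeds[j], n_init)
    best <- list(sbar = -Inf)
    for (i in seq_len(n_init)) {
      km <- withr::with_seed(rseeds[i], kmeans_restart(mat, k))
      sbar <- mean(silhouette_from_dist(D2, km$cluster))
      if (sbar > best$sbar) best <- list(sbar = sbar, km = km)
    }
    best
  })
  curve <- tibble(k = ks,
                  mean_silhouette = purrr::map_dbl(best_by_k, "sbar"))
  j_star <- which.max(curve$mean_silhouette) # which.max takes the first, i.e. smallest k
  km <- best_by_k[[j_star]]$km
  sil <- silhouette_mean(mat, km$cluster)
  structure(
    list(
      k_star = curve$k[j_star],
      curve = curve,
      best = list(
        assignment = tibble(gene_id = rownames(mat),
                            cluster = as.integer(km$cluster)),
        centroids = km$centers,
        within_sse = km$tot.withinss,
        silhouettes = sil$silhouettes,
        mean_silhouette = sil$mean_silhouette
      ),
      n_init = as.integer(n_init)
    ),
    class = "gc_kselect"
  )
}

#' @export
print.gc_kselect <- function(x, ...) {
  cat(sprintf(
    "optimal cluster number: k* = %d (max mean silhouette %.4f over k = %d..%d, %d restarts each)\n",
    x$k_star, max(x$curve$mean_silhouette), min(x$curve$k),
    max(x$curve$k), x$n_init))
  invisible(x)
}

#' Per-cluster mean profiles
#'
#' @param profiles Wide tibble (`gene_id` + one column per experiment).
#' @param assignment Tibble with `gene_id`, `cluster`.
#' @return Long tibble: `cluster`, `experiment_id`, `mean_M`, `n_genes`.
#' @export
cluster_mean_profiles <- function(profiles, assignment) {
  profiles |>
    dplyr::inner_join(assignment, by = "gene_id") |>
    tidyr::pivot_longer(!c("gene_id", "cluster"),
                        names_to = "experiment_id", values_to = "M") |>
    dplyr::group_by(.data$cluster, .data$experiment_id) |>
    dplyr::summarise(mean_M = mean(.data$M),
                     n_genes = dplyr::n_distinct(.data$gene_id),
                     .groups = "drop")
}
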