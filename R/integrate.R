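# Cross-platform integration: reporter-to-gene mapping with one-to-one
# validation, the common gene set (CGS), and median rank score (MRS)
# normalization against a reference platform.

#' Map reporter-level profiles to gene identifiers
#'
#' Renames reporters to gene identifiers through a mapping table, enforcing
#' a one-to-one relationship *within the profile being mapped*: reporters
#' absent from the mapping are dropped, as are groups of reporters sharing
#' a gene (ambiguous) and duplicated mapping rows. Drop counts are logged.
#'
#' @param profile A tibble keyed by `feature_id` (reporter identifiers).
#' @param mapping A tibble with `reporter_id`, `gene_id`; rows with missing
#'   entries are ignored. The table may cover several platforms; the
#'   one-to-one check is applied after restricting to this profile's
#'   reporters.
#' @return The profile keyed by `gene_id` instead of `feature_id`.
#' @export
map_reporters <- function(profile, mapping) {
  assert_columns(profile, "feature_id", "profile")
  assert_columns(mapping, c("reporter_id", "gene_id"), "mapping")
  mapping <- dplyr::filter(mapping, !is.na(.data$reporter_id),
                           !is.na(.data$gene_id))
  if (nrow(mapping) == 0) abort("the mapping table is empty.")
  sub <- mapping |>
    dplyr::filter(.data$reporter_id %in% profile$feature_id) |>
    dplyr::distinct(.data$reporter_id, .data$gene_id)
  multi_reporter <- sub$reporter_id[duplicated(sub$reporter_id)]
  shared_gene <- sub |>
    dplyr::count(.data$gene_id) |>
    dplyr::filter(.data$n > 1) |>
    dplyr::pull(.data$gene_id)
  ambiguous <- sub |>
    dplyr::filter(.data$reporter_id %in% multi_reporter |
                    .data$gene_id %in% shared_gene) |>
    dplyr::pull(.data$reporter_id) |>
    unique()
  sub <- dplyr::filter(sub, !.data$reporter_id %in% ambiguous)
  n_unmapped <- sum(!profile$feature_id %in% mapping$reporter_id)
  inform(sprintf(
    "map_reporters: %d reporter(s) without mapping omitted, %d violating one-to-one dropped, %d retained.",
    n_unmapped, length(ambiguous), nrow(sub)))
  profile |>
    dplyr::inner_join(sub, by = c(feature_id = "reporter_id")) |>
    dplyr::select(!"feature_id") |>
    dplyr::relocate("gene_id")
}

#' Common gene set across platforms
#'
#' Intersection of two or more gene lists, sorted. An empty intersection is
#' an error: nothing downstream could run on it.
#'
#' @param ... Character vectors (or a single list of them).
#' @return Sorted character vector of shared genes.
#' @export
common_gene_set <- function(...) {
  lists <- list(...)
  if (length(lists) == 1L && is.list(lists[[1]])) lists <- lists[[1]]
  if (length(lists) < 2) abort("at least two gene lists are required.")
  cgs <- sort(Reduce(intersect, lists))
  if (length(cgs) == 0) abort("the common gene set is empty: the platforms share no genes.")
  cgs
}

#' Per-rank medians of a reference experiment set
#'
#' Sorts each reference experiment's values and takes the median across
#' experiments at every rank; these are the values MRS normalization
#' assigns to the target's ranks.
#'
#' @param reference A list of equal-length numeric vectors (one per
#'   reference experiment), or a single vector.
#' @return Ascending numeric vector of per-rank medians.
#' @export
mrs_reference_medians <- function(reference) {
  if (is.numeric(reference)) reference <- list(reference)
  n <- unique(lengths(reference))
  if (length(n) != 1) abort("reference experiments must have equal length.")
  sorted <- vapply(reference, sort, numeric(n))
  if (length(reference) == 1L) as.numeric(sorted)
  else apply(sorted, 1, median)
}

#' Median rank score normalization of one experiment
#'
#' Replaces the value at rank r of the target experiment by the reference
#' set's per-rank median at rank r. The sorted output is therefore exactly
#' the sorted reference medians, and the target's rank order is preserved.
#' Ties in the target are broken deterministically by `(value, gene_id)`
#' and logged.
#'
#' @param target Numeric values of one non-reference experiment.
#' @param reference_rank_medians Output of [mrs_reference_medians()], same
#'   length as `target`.
#' @param gene_id Optional identifiers used as a stable tie-break.
#' @return Normalized values in the original order of `target`.
#' @export
mrs_normalize <- function(target, reference_rank_medians, gene_id = NULL) {
  if (length(target) != length(reference_rank_medians)) {
    abort("`target` and `reference_rank_medians` must have equal length.")
  }
  if (anyDuplicated(target)) {
    inform(sprintf("mrs_normalize: %d tie(s) in target resolved by (value, gene_id) order.",
                   sum(duplicated(target))))
  }
  ord <- if (is.null(gene_id)) order(target) else order(target, gene_id)
  out <- numeric(length(target))
  out[ord] <- sort(reference_rank_medians)
  out
}

#' Integrate preprocessed experiments into a unified matrix
#'
#' Restricts gene-level profiles to the common gene set and applies MRS
#' normalization of the log ratios, with the per-rank medians pooled over
#' the reference experiments. Reference experiments are left untouched.
#'
#' @param profiles Long tibble with `gene_id`, `experiment_id`, `M` (and
#'   optionally `A`, carried through).
#' @param reference_experiments Experiments forming the reference set
#'   (default the late 4.8 k-platform experiments `"4"` and `"5"`).
#' @param normalize Set `FALSE` to skip MRS and only restrict to the CGS.
#' @return A long tibble over the CGS with `M` replaced by its normalized
#'   value for non-reference experiments; the CGS is attached as attribute
#'   `cgs`.
#' @export
integrate_experiments <- function(profiles,
                                  reference_experiments = c("4", "5"),
                                  normalize = TRUE) {
  assert_columns(profiles, c("gene_id", "experiment_id", "M"), "profiles")
  by_exp <- split(profiles, profiles$experiment_id)
  cgs <- common_gene_set(purrr::map(by_exp, "gene_id"))
  by_exp <- purrr::map(by_exp, ~ dplyr::arrange(
    dplyr::filter(.x, .data$gene_id %in% cgs), .data$gene_id))
  if (normalize) {
    refs <- intersect(reference_experiments, names(by_exp))
    if (length(refs) == 0) abort("no reference experiment present in `profiles`.")
    ref_medians <- mrs_reference_medians(
      purrr::map(by_exp[refs], "M"))
    for (e in setdiff(names(by_exp), refs)) {
      by_exp[[e]]$M <- mrs_normalize(by_exp[[e]]$M, ref_medians,
                                     by_exp[[e]]$gene_id)
    }
  }
  out <- purrr::list_rbind(by_exp)
  attr(out, "cgs") <- cgs
  out
}

#' Pivot a unified long matrix to genes-by-experiments form
#'
#' @param unified Long tibble with `gene_id`, `experiment_id`, `M`.
#' @return Wide tibble: `gene_id` plus one `M` column per experiment.
#' @export
unified_wide <- function(unified) {
  assert_columns(unified, c("gene_id", "experiment_id", "M"), "unified")
  unified |>
    dplyr::select("gene_id", "experiment_id", "M") |>
    tidyr::pivot_wider(names_from = "experiment_id", values_from = "M") |>
    dplyr::arrange(.data$gene_id)
}
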