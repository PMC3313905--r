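# The resistance decision logic: per-experiment U/D/S gene sets, the ten
# named set intersections, and the rule engine translating a set's
# functional-category enrichments into an inherent / acquired / undefined
# verdict.

set_ops <- "∩" # the intersection sign used in set labels, e.g. "D1∩D3"

intersection_pairs <- function() {
  tibble(
    a = c("S1", "U1", "D1", "U1", "D1", "S4", "U4", "D4", "U4", "D4"),
    b = c("S3", "U3", "D3", "D3", "U3", "S5", "U5", "D5", "D5", "U5")
  ) |>
    dplyr::mutate(set_label = paste0(.data$a, set_ops, .data$b),
                  timepoint = ifelse(.data$a %in% c("S1", "U1", "D1"),
                                     "4h", "72h"))
}

#' Build per-experiment U/D/S gene sets
#'
#' Partitions the genes of each experiment into up-regulated (`U`),
#' down-regulated (`D`) and unchanged (`S`) according to their
#' differential-expression labels.
#'
#' @param de A labeling tibble ([call_de()] output) with `gene_id`,
#'   `experiment_id`, `label`.
#' @return A long tibble of class `gc_sets` with `experiment_id`, `label`
#'   and `gene_id`; within each experiment the three sets partition the
#'   gene universe.
#' @export
build_sets <- function(de) {
  assert_columns(de, c("gene_id", "experiment_id", "label"), "labeling")
  if (anyNA(de$label)) {
    missing <- de$gene_id[is.na(de$label)]
    abort(sprintf("missing label for %d gene(s), e.g. %s.",
                  length(missing), paste(head(missing, 3), collapse = ", ")))
  }
  out <- de |>
    dplyr::select("experiment_id", "label", "gene_id") |>
    dplyr::arrange(.data$experiment_id, .data$label, .data$gene_id)
  class(out) <- c("gc_sets", class(out))
  out
}

set_members <- function(sets, label, experiment) {
  sets$gene_id[sets$label == label & sets$experiment_id == experiment]
}

#' Form the named set intersections
#'
#' Materializes the ten intersections driving the resistance hypotheses:
#' `S1∩S3`, `U1∩U3`, `D1∩D3`, `U1∩D3`, `D1∩U3`
#' for the early (4 h) experiments and `S4∩S5`, `U4∩U5`,
#' `D4∩D5`, `U4∩D5`, `D4∩U5` for the late (72 h) ones.
#'
#' @param sets A `gc_sets` tibble ([build_sets()]); experiments '1', '3',
#'   '4' and '5' must be present.
#' @return A tibble with `set_label`, `timepoint`, `n_genes` and a
#'   list-column `genes`.
#' @export
intersect_sets <- function(sets) {
  assert_columns(sets, c("experiment_id", "label", "gene_id"), "sets")
  need <- c("1", "3", "4", "5")
  absent <- setdiff(need, unique(sets$experiment_id))
  if (length(absent) > 0) {
    abort(sprintf("experiment(s) %s missing from the labeling.",
                  paste(absent, collapse = ", ")))
  }
  intersection_pairs() |>
    dplyr::mutate(
      genes = purrr::map2(.data$a, .data$b, function(a, b) {
        sort(intersect(
          set_members(sets, substr(a, 1, 1), substr(a, 2, 2)),
          set_members(sets, substr(b, 1, 1), substr(b, 2, 2))))
      }),
      n_genes = lengths(.data$genes)
    ) |>
    dplyr::select("set_label", "timepoint", "n_genes", "genes")
}

#' The default resistance rule table
#'
#' Encodes, per gene-set label and functional category, the verdict of the
#' decision flowcharts: whether the observed enrichment points to an
#' inherent (intrinsic) or an acquired resistance mechanism, or leaves it
#' undefined. Rules exist for the ten intersections and for the individual
#' up/down sets of every experiment ('1'-'3' early, '4'-'5' late); the
#' individual-set rules mirror the published per-set verdicts and can be
#' overridden by passing a modified copy to [classify_resistance()].
#'
#' @return A tibble with `set_label`, `category`, `verdict`, `qualified`.
#' @export
resistance_rules <- function() {
  x <- function(a, b) paste0(a, set_ops, b)
  inter <- dplyr::tribble(
    ~set_label,      ~category, ~verdict,    ~qualified,
    x("S1", "S3"),   "F_p",     "acquired",  FALSE,
    x("S1", "S3"),   "F_a",     "inherent",  FALSE,
    x("U1", "U3"),   "F_p",     "inherent",  FALSE,
    x("U1", "U3"),   "F_a",     "acquired",  FALSE,
    x("D1", "D3"),   "F_p",     "acquired",  FALSE,
    x("D1", "D3"),   "F_a",     "inherent",  FALSE,
    x("U1", "D3"),   "F_p",     "acquired",  FALSE,
    x("U1", "D3"),   "F_a",     "inherent",  FALSE,
    x("D1", "U3"),   "F_p",     "inherent",  FALSE,
    x("D1", "U3"),   "F_a",     "acquired",  FALSE,
    x("S4", "S5"),   "F_p",     "acquired",  FALSE,
    x("S4", "S5"),   "F_a",     "undefined", FALSE,
    x("U4", "U5"),   "F_p",     "acquired",  FALSE,
    x("U4", "U5"),   "F_a",     "undefined", FALSE,
    x("D4", "D5"),   "F_p",     "undefined", FALSE,
    x("D4", "D5"),   "F_a",     "inherent",  FALSE,
    x("U4", "D5"),   "F_p",     "acquired",  FALSE,
    x("U4", "D5"),   "F_a",     "undefined", FALSE,
    x("D4", "U5"),   "F_p",     "acquired",  FALSE,
    x("D4", "U5"),   "F_a",     "undefined", FALSE
  )
  early <- purrr::map(c("1", "2", "3"), function(e) {
    dplyr::tribble(
      ~set_label,        ~category, ~verdict,   ~qualified,
      paste0("U", e),    "F_p",     "inherent", FALSE,
      paste0("U", e),    "F_a",     "acquired", FALSE,
      paste0("D", e),    "F_p",     "acquired", FALSE,
      paste0("D", e),    "F_a",     "inherent", FALSE
    )
  }) |> purrr::list_rbind()
  late <- purrr::map(c("4", "5"), function(e) {
    dplyr::tribble(
      ~set_label,        ~category, ~verdict,    ~qualified,
      paste0("U", e),    "F_p",     "acquired",  FALSE,
      paste0("U", e),    "F_a",     "undefined", FALSE,
      paste0("D", e),    "F_p",     "acquired",  FALSE,
      paste0("D", e),    "F_a",     "inherent",  TRUE
    )
  }) |> purrr::list_rbind()
  dplyr::bind_rows(inter, early, late)
}

#' Classify a gene set's resistance mechanism
#'
#' Pure rule lookup: given a set label and the functional categories
#' significantly enriched in that set, returns the verdict(s). Only `F_p`
#' and `F_a` drive verdicts; with neither present the resistance is
#' `undefined`, with both present both sub-verdicts are returned (the
#' overall call is then mixed/undefined).
#'
#' @param set_label A label known to the rule table (e.g. `"D1∩D3"`,
#'   `"U5"`).
#' @param categories_present Character vector of enriched categories.
#' @param rules Rule table (default [resistance_rules()]).
#' @return A tibble with one row per fired rule: `set_label`, `category`,
#'   `resistance`, `qualified`; a single `undefined` row when no relevant
#'   category is present.
#' @export
classify_resistance <- function(set_label, categories_present,
                                rules = resistance_rules()) {
  stopifnot(length(set_label) == 1L)
  if (!set_label %in% rules$set_label) {
    abort(sprintf("unknown set label '%s'; known labels: %s.", set_label,
                  paste(unique(rules$set_label), collapse = ", ")))
  }
  relevant <- intersect(categories_present, c("F_p", "F_a"))
  if (length(relevant) == 0) {
    return(tibble(set_label = set_label, category = NA_character_,
                  resistance = "undefined", qualified = FALSE))
  }
  rules |>
    dplyr::filter(.data$set_label == !!set_label,
                  .data$category %in% relevant) |>
    dplyr::transmute(set_label = .data$set_label,
                     category = .data$category,
                     resistance = .data$verdict,
                     qualified = .data$qualified)
}

#' Per-experiment cluster-mean thresholds for behavioural labels
#'
#' The threshold against which a cluster's mean log ratio is compared when
#' summarizing its behaviour: the DE critical value times the experiment's
#' median local SD.
#'
#' @param de A `gc_de` labeling ([call_de()]).
#' @return Tibble with `experiment_id` and `threshold`.
#' @export
de_thresholds <- function(de) {
  z_crit <- attr(de, "z_crit") %||% qnorm(0.975)
  de |>
    dplyr::group_by(.data$experiment_id) |>
    dplyr::summarise(threshold = z_crit * median(.data$sd_local),
                     .groups = "drop")
}

#' Map cluster mean profiles to behavioural set labels
#'
#' Labels each cluster U/D/S per experiment by thresholding its mean log
#' ratio, and reports the composite behaviour: `"~S all"` for clusters
#' flat everywhere, otherwise a `~`-prefixed concatenation of the non-flat
#' behaviours (e.g. `"~D5"` for a cluster down only in experiment '5').
#'
#' @param cluster_means Long tibble from [cluster_mean_profiles()]
#'   (`cluster`, `experiment_id`, `mean_M`).
#' @param thresholds Tibble from [de_thresholds()].
#' @return A tibble with `cluster`, `profile` (per-experiment labels,
#'   comma-separated) and `set_label`.
#' @export
map_cluster_to_set <- function(cluster_means, thresholds) {
  assert_columns(cluster_means, c("cluster", "experiment_id", "mean_M"),
                 "cluster means")
  cluster_means |>
    dplyr::inner_join(thresholds, by = "experiment_id") |>
    dplyr::mutate(lab = dplyr::case_when(
      .data$mean_M >= .data$threshold ~ "U",
      .data$mean_M <= -.data$threshold ~ "D",
      TRUE ~ "S")) |>
    dplyr::arrange(.data$cluster, .data$experiment_id) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      profile = paste(.data$lab, collapse = ","),
      set_label = {
        hits <- paste0(.data$lab, .data$experiment_id)[.data$lab != "S"]
        if (length(hits) == 0) "~S all" else paste0("~", paste(hits, collapse = ""))
      },
      .groups = "drop")
}

#' Verdicts for a collection of gene sets
#'
#' Runs the enrichment and rule engine over each gene set: parent-child-
#' union overrepresentation against the reference, categorization of the
#' significant terms, and the resistance rule lookup. Empty sets are
#' reported as `not_applicable`; sets where both `F_p` and `F_a` fire are
#' summarized as `undefined` (mixed) with the sub-verdicts retained.
#'
#' @param gene_sets Tibble with `set_label` and list-column `genes`
#'   ([intersect_sets()] output, or any sets labelled per the rule table).
#' @param reference Reference gene set (the CGS).
#' @param ontology,annotations,category_map See
#'   [parent_child_union_ora()] and [categorize_terms()].
#' @param alpha Significance threshold for term enrichment.
#' @param rules Rule table passed to [classify_resistance()].
#' @return A tibble with `set_label`, `n_genes`, `categories`
#'   (comma-separated), overall `resistance`, `qualified` and nested
#'   `detail` (the fired rules) and `enrichment` (the ORA records).
#' @export
classify_gene_sets <- function(gene_sets, reference, ontology, annotations,
                               category_map, alpha = 0.05,
                               rules = resistance_rules()) {
  assert_columns(gene_sets, c("set_label", "genes"), "gene sets")
  if (!isTRUE(attr(annotations, "closed"))) {
    annotations <- propagate_annotations(ontology, annotations)
  }
  purrr::map2(gene_sets$set_label, gene_sets$genes, function(lab, genes) {
    if (length(genes) == 0) {
      return(tibble(set_label = lab, n_genes = 0L, categories = "",
                    resistance = "not_applicable", qualified = FALSE,
                    detail = list(tibble()), enrichment = list(tibble())))
    }
    ora <- parent_child_union_ora(genes, reference, ontology, annotations)
    cats <- categorize_terms(ora, category_map, alpha)
    fired <- classify_resistance(lab, cats$category, rules)
    verdicts <- unique(fired$resistance[!is.na(fired$category)])
    overall <- if (length(verdicts) == 1) verdicts else "undefined"
    tibble(set_label = lab, n_genes = length(genes),
           categories = paste(cats$category, collapse = ","),
           resistance = overall,
           qualified = length(verdicts) == 1 &&
             any(fired$qualified[fired$resistance == overall]),
           detail = list(fired), enrichment = list(ora))
  }) |> purrr::list_rbind()
}
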