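# Parent-child-union overrepresentation analysis: each term's
# hypergeometric universe is conditioned on the genes annotated to the
# union of its parents, so that enrichment already explained by a parent
# term does not cascade to its children.

#' Parent-child-union term overrepresentation
#'
#' For every non-root term t with parents P(t), the sampling universe is
#' the set of reference genes annotated to the union of P(t); among them,
#' the genes annotated to t are the successes, the study genes in the
#' universe are the draws, and the study genes annotated to t the observed
#' successes. The p-value is the hypergeometric upper tail
#' `P(X >= observed)`. Terms with an empty parent-union universe or no
#' reference annotation are skipped.
#'
#' @param study Character vector of study genes; must be a subset of
#'   `reference`.
#' @param reference Character vector of reference genes (the common gene
#'   set in the pipeline).
#' @param ontology A `gc_ontology`.
#' @param annotations Closed gene-term annotations
#'   ([propagate_annotations()] output); a direct table is closed on the
#'   fly.
#' @param correction `"none"` (default, matching the raw p < 0.05 usage),
#'   `"bonferroni"` or `"BH"`; adds a `p_adjust` column.
#' @return A tibble sorted by p-value with the count fields
#'   `n_pop_parents`, `n_pop_term`, `n_study_parents`, `n_study_term` and
#'   `p_value`.
#' @export
parent_child_union_ora <- function(study, reference, ontology, annotations,
                                   correction = c("none", "bonferroni", "BH")) {
  correction <- match.arg(correction)
  stopifnot(inherits(ontology, "gc_ontology"))
  extra <- setdiff(study, reference)
  if (length(extra) > 0) {
    abort(sprintf("study set is not a subset of the reference: %s%s",
                  paste(head(extra, 5), collapse = ", "),
                  if (length(extra) > 5) ", ..." else ""))
  }
  if (!isTRUE(attr(annotations, "closed"))) {
    annotations <- propagate_annotations(ontology, annotations)
  }
  annotations <- dplyr::filter(annotations, .data$gene_id %in% reference)
  genes_of <- split(annotations$gene_id, annotations$term_id)
  study <- unique(study)

  terms <- setdiff(ontology$terms$term_id, ontology$root)
  rows <- purrr::map(terms, function(t) {
    pop_term <- genes_of[[t]] %||% character(0)
    if (length(pop_term) == 0) return(NULL)
    parent_genes <- unique(unlist(genes_of[ontology$parents[[t]]],
                                  use.names = FALSE))
    if (length(parent_genes) == 0) return(NULL)
    study_parents <- intersect(study, parent_genes)
    study_term <- intersect(study, pop_term)
    p <- phyper(length(study_term) - 1L,
                m = length(pop_term),
                n = length(parent_genes) - length(pop_term),
                k = length(study_parents),
                lower.tail = FALSE)
    tibble(term_id = t,
           n_pop_parents = length(parent_genes),
           n_pop_term = length(pop_term),
           n_study_parents = length(study_parents),
           n_study_term = length(study_term),
           p_value = p)
  })
  out <- purrr::list_rbind(purrr::keep(rows, ~ !is.null(.x)))
  if (nrow(out) > 0) {
    out <- out |>
      dplyr::left_join(ontology$terms, by = "term_id") |>
      dplyr::relocate("name", .after = "term_id") |>
      dplyr::arrange(.data$p_value, .data$term_id)
    if (correction != "none") {
      out$p_adjust <- stats::p.adjust(out$p_value, method = correction)
    }
  }
  out
}

#' Summarise enriched terms by functional category
#'
#' Maps significantly enriched terms to their functional super-categories
#' (`F_p` apoptosis evasion / cell-cycle progression, `F_a` apoptosis
#' induction / cell-cycle arrest; further categories such as `F_m`, `F_i`
#' are free extras of the map) and reports which categories fire.
#'
#' @param records Output of [parent_child_union_ora()].
#' @param category_map Tibble with `term_id`, `category`.
#' @param alpha Significance threshold on the raw p-value (default 0.05).
#' @return A tibble with one row per category present among significant
#'   terms: `category`, `n_terms`, `min_p`. Zero rows mean no category
#'   fired (downstream verdict "undefined").
#' @export
categorize_terms <- function(records, category_map, alpha = 0.05) {
  assert_columns(category_map, c("term_id", "category"), "category map")
  if (nrow(records) == 0) {
    return(tibble(category = character(0), n_terms = integer(0),
                  min_p = numeric(0)))
  }
  hits <- records |>
    dplyr::filter(.data$p_value < alpha) |>
    dplyr::inner_join(category_map, by = "term_id",
                      relationship = "many-to-many")
  if (nrow(hits) == 0) {
    return(tibble(category = character(0), n_terms = integer(0),
                  min_p = numeric(0)))
  }
  hits |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(n_terms = dplyr::n_distinct(.data$term_id),
                     min_p = min(.data$p_value), .groups = "drop") |>
    dplyr::arrange(.data$category)
}
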