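# Chromosome-level aggregation: per-chromosome gene counts and
# sign-split mean expression, and Pearson correlation of counts with the
# mean expression summaries.

scope_experiments <- function(scope, experiments) {
  switch(scope,
         all = experiments,
         "4h" = intersect(experiments, c("1", "2", "3")),
         "72h" = intersect(experiments, c("4", "5")),
         abort("`scope` must be one of 'all', '4h', '72h'."))
}

#' Per-chromosome mean expression profiles
#'
#' Pools the log ratios of all genes on each chromosome over the
#' experiments in scope and averages the positive and the negative values
#' separately (`m_pos`, `m_neg`); zero values enter neither mean. Genes
#' absent from the chromosome map are dropped with a log message.
#'
#' @param unified Long tibble with `gene_id`, `experiment_id`, `M`.
#' @param chromosome_map Tibble with `gene_id`, `chromosome`.
#' @param scope `"all"`, `"4h"` (experiments 1-3) or `"72h"` (4-5).
#' @return A tibble with `chromosome`, `scope`, `gene_count`, `m_pos`,
#'   `m_neg` (`NA` where no value of that sign exists).
#' @export
chromosome_means <- function(unified, chromosome_map, scope = "all") {
  assert_columns(unified, c("gene_id", "experiment_id", "M"), "unified")
  assert_columns(chromosome_map, c("gene_id", "chromosome"),
                 "chromosome map")
  exps <- scope_experiments(scope, unique(unified$experiment_id))
  unmapped <- setdiff(unique(unified$gene_id), chromosome_map$gene_id)
  if (length(unmapped) > 0) {
    inform(sprintf("chromosome_means: %d gene(s) without chromosome assignment dropped.",
                   length(unmapped)))
  }
  unified |>
    dplyr::filter(.data$experiment_id %in% exps) |>
    dplyr::inner_join(chromosome_map, by = "gene_id") |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::summarise(
      scope = scope,
      gene_count = dplyr::n_distinct(.data$gene_id),
      m_pos = if (any(.data$M > 0)) mean(.data$M[.data$M > 0]) else NA_real_,
      m_neg = if (any(.data$M < 0)) mean(.data$M[.data$M < 0]) else NA_real_,
      .groups = "drop")
}

#' Correlate per-chromosome gene counts with mean expression
#'
#' Builds the chromosome-by-variable table (gene count plus the sign-split
#' means for the all / 4 h / 72 h scopes) and computes all pairwise
#' Pearson correlations with two-sided p-values, pairwise-complete over
#' chromosomes with defined values.
#'
#' @param unified Long tibble with `gene_id`, `experiment_id`, `M`.
#' @param chromosome_map Tibble with `gene_id`, `chromosome`.
#' @return A list with `variables` (the chromosome-by-variable tibble),
#'   `r` and `p` (symmetric matrices with unit / zero diagonal), and the
#'   tidy `pairs` tibble (`var1`, `var2`, `r`, `p`, `n`). Pairs where a
#'   vector has zero variance get `NA` and are flagged.
#' @export
correlate_counts_expression <- function(unified, chromosome_map) {
  profiles <- purrr::map(c("all", "4h", "72h"),
                         ~ chromosome_means(unified, chromosome_map, .x))
  vars <- profiles[[1]] |>
    dplyr::select("chromosome", "gene_count",
                  m_pos_all = "m_pos", m_neg_all = "m_neg") |>
    dplyr::left_join(dplyr::select(profiles[[2]], "chromosome",
                                   m_pos_4h = "m_pos", m_neg_4h = "m_neg"),
                     by = "chromosome") |>
    dplyr::left_join(dplyr::select(profiles[[3]], "chromosome",
                                   m_pos_72h = "m_pos", m_neg_72h = "m_neg"),
                     by = "chromosome")
  if (nrow(vars) < 3) abort("at least 3 chromosomes with defined values are required.")
  cols <- setdiff(names(vars), "chromosome")
  k <- length(cols)
  r <- matrix(NA_real_, k, k, dimnames = list(cols, cols))
  p <- r
  pairs <- list()
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      x <- vars[[cols[i]]]
      y <- vars[[cols[j]]]
      ok <- is.finite(x) & is.finite(y)
      if (i == j) {
        r[i, j] <- 1
        p[i, j] <- 0
        next
      }
      if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
        pairs[[length(pairs) + 1]] <- tibble(
          var1 = cols[i], var2 = cols[j], r = NA_real_, p = NA_real_,
          n = sum(ok), degenerate = TRUE)
        next
      }
      ct <- cor.test(x[ok], y[ok], method = "pearson")
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
      if (i < j) {
        pairs[[length(pairs) + 1]] <- tibble(
          var1 = cols[i], var2 = cols[j], r = r[i, j], p = p[i, j],
          n = sum(ok), degenerate = FALSE)
      }
    }
  }
  list(variables = vars, r = r, p = p,
       pairs = purrr::list_rbind(pairs))
}
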