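# Shared fixture builders: all tiny, all generated in code.

# A minimal log2-scale slide with a prescribed background relationship.
make_slide <- function(n = 60, bg = function(f) 4 + 0.25 * f, seed = 1) {
  withr::with_seed(seed, {
    f_r <- runif(n, 6, 16)
    f_g <- runif(n, 6, 16)
    tibble::tibble(
      feature_id = sprintf("FT%03d", seq_len(n)),
      F_R = f_r, B_R = bg(f_r),
      F_G = f_g, B_G = bg(f_g)
    )
  })
}

# A three-term chain ontology: root <- mid <- leaf.
chain_ontology <- function() {
  build_ontology(
    tibble::tibble(term_id = c("root", "mid", "leaf")),
    list(root = character(0), mid = "root", leaf = "mid")
  )
}

# Exhaustive hypergeometric upper-tail oracle from binomial coefficients:
# P(X >= x) with m successes among N, k draws.
hyper_tail_oracle <- function(x, m, N, k) {
  i <- seq(from = x, to = min(k, m))
  if (length(i) == 0 || x > min(k, m)) return(0)
  sum(choose(m, i) * choose(N - m, k - i)) / choose(N, k)
}

# Brute-force parent-child-union counts for one term.
ora_oracle_term <- function(term, study, reference, onto, closed) {
  genes_of <- function(t) unique(closed$gene_id[closed$term_id == t])
  parent_genes <- intersect(
    unique(unlist(lapply(onto$parents[[term]], genes_of))), reference)
  pop_term <- intersect(genes_of(term), reference)
  list(
    n_pop_parents = length(parent_genes),
    n_pop_term = length(pop_term),
    n_study_parents = length(intersect(study, parent_genes)),
    n_study_term = length(intersect(study, pop_term)),
    p = hyper_tail_oracle(length(intersect(study, pop_term)),
                          length(pop_term), length(parent_genes),
                          length(intersect(study, parent_genes)))
  )
}
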