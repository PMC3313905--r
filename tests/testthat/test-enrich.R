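test_that("annotations propagate along the chain and the closure is idempotent", {
  onto <- chain_ontology()
  ann <- tibble::tibble(gene_id = "g1", term_id = "leaf")
  closed <- propagate_annotations(onto, ann)
  expect_setequal(closed$term_id, c("leaf", "mid", "root"))
  expect_equal(propagate_annotations(onto, closed), closed,
               ignore_attr = TRUE)
})

test_that("diamond-shaped ancestry is counted once", {
  onto <- build_ontology(
    tibble::tibble(term_id = c("r", "a", "b", "bottom")),
    list(r = character(0), a = "r", b = "r", bottom = c("a", "b"))
  )
  closed <- propagate_annotations(
    onto, tibble::tibble(gene_id = "g1", term_id = "bottom"))
  expect_equal(nrow(closed), 4) # bottom, a, b, r — r exactly once
  expect_setequal(closed$term_id, c("bottom", "a", "b", "r"))
})

test_that("malformed ontologies are rejected", {
  expect_error(build_ontology(tibble::tibble(term_id = c("a", "b")),
                              list(a = "b", b = "a")),
               "exactly one root")
  expect_error(build_ontology(tibble::tibble(term_id = c("r", "a", "b")),
                              list(r = character(0), a = "b", b = "a")),
               "cycle")
  onto <- chain_ontology()
  expect_warning(
    propagate_annotations(onto, tibble::tibble(gene_id = "g",
                                               term_id = "nope")),
    "unknown")
})

test_that("the minimal OBO reader round-trips a hand-written file", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0001", "name: root process", "",
    "[Term]", "id: GO:0002", "name: middle", "is_a: GO:0001 ! root process", "",
    "[Term]", "id: GO:0003", "name: leaf", "is_a: GO:0002", "",
    "[Term]", "id: GO:0004", "name: gone", "is_obsolete: true", "",
    "[Typedef]", "id: part_of"
  ), path)
  onto <- read_obo(path)
  expect_equal(nrow(onto$terms), 3)
  expect_equal(onto$root, "GO:0001")
  expect_equal(onto$parents[["GO:0003"]], "GO:0002")
  expect_equal(onto$terms$name[onto$terms$term_id == "GO:0002"], "middle")
})

test_that("parent-child-union counts match hand enumeration on a chain", {
  onto <- chain_ontology()
  genes <- sprintf("g%02d", 1:10)
  # genes 1..6 at mid, of which 1..3 also at leaf; all genes reach root
  ann <- dplyr::bind_rows(
    tibble::tibble(gene_id = genes, term_id = "root"),
    tibble::tibble(gene_id = genes[1:6], term_id = "mid"),
    tibble::tibble(gene_id = genes[1:3], term_id = "leaf")
  )
  closed <- propagate_annotations(onto, ann)
  study <- c("g01", "g02", "g04", "g09")
  ora <- parent_child_union_ora(study, genes, onto, closed)
  leaf <- ora[ora$term_id == "leaf", ]
  expect_equal(leaf$n_pop_parents, 6) # genes under mid
  expect_equal(leaf$n_pop_term, 3)
  expect_equal(leaf$n_study_parents, 3) # g01 g02 g04
  expect_equal(leaf$n_study_term, 2)    # g01 g02
  expect_equal(leaf$p_value, hyper_tail_oracle(2, 3, 6, 3))
  mid <- ora[ora$term_id == "mid", ]
  expect_equal(mid$n_pop_parents, 10)
  expect_equal(mid$p_value, hyper_tail_oracle(3, 6, 10, 4))
})

test_that("p-values equal the exhaustive tail-sum oracle on random toys", {
  for (seed in 1:4) {
    toy <- simulate_toy_ontology(n_terms = 10, n_genes = 18,
                                 planted_enrichment = 3, seed = seed)
    closed <- propagate_annotations(toy$ontology, toy$annotations)
    ora <- parent_child_union_ora(toy$study_set, toy$reference,
                                  toy$ontology, closed)
    for (i in seq_len(nrow(ora))) {
      oracle <- ora_oracle_term(ora$term_id[i], toy$study_set,
                                toy$reference, toy$ontology, closed)
      expect_equal(ora$p_value[i], oracle$p, tolerance = 1e-12)
      expect_equal(ora$n_pop_parents[i], oracle$n_pop_parents)
      expect_equal(ora$n_study_term[i], oracle$n_study_term)
    }
  }
})

test_that("a study equal to a term's universe gives p = 1", {
  onto <- chain_ontology()
  genes <- sprintf("g%d", 1:8)
  ann <- dplyr::bind_rows(
    tibble::tibble(gene_id = genes, term_id = "root"),
    tibble::tibble(gene_id = genes[1:4], term_id = "mid")
  )
  closed <- propagate_annotations(onto, ann)
  ora <- parent_child_union_ora(genes, genes, onto, closed)
  expect_equal(ora$p_value[ora$term_id == "mid"], 1)
  expect_error(parent_child_union_ora(c(genes, "zz"), genes, onto, closed),
               "subset")
})

test_that("p-values under uniform study sets are conservative or exact", {
  toy <- simulate_toy_ontology(n_terms = 12, n_genes = 40,
                               planted_enrichment = 0, seed = 6)
  closed <- propagate_annotations(toy$ontology, toy$annotations)
  term <- toy$planted_term
  ps <- withr::with_seed(61, replicate(400, {
    study <- sample(toy$reference, 10)
    ora <- parent_child_union_ora(study, toy$reference, toy$ontology, closed)
    p <- ora$p_value[ora$term_id == term]
    if (length(p) == 0) NA_real_ else p
  }))
  ps <- ps[!is.na(ps)]
  for (alpha in c(0.05, 0.1, 0.25)) {
    expect_lte(mean(ps <= alpha), alpha + 3 * sqrt(alpha * (1 - alpha) / length(ps)))
  }
})

test_that("ORA is invariant to relabeling genes", {
  toy <- simulate_toy_ontology(n_terms = 10, n_genes = 20, seed = 7)
  closed <- propagate_annotations(toy$ontology, toy$annotations)
  relabel <- setNames(sprintf("x%02d", seq_along(toy$reference)),
                      toy$reference)
  closed2 <- dplyr::mutate(closed, gene_id = unname(relabel[gene_id]))
  attr(closed2, "closed") <- TRUE
  a <- parent_child_union_ora(toy$study_set, toy$reference,
                              toy$ontology, closed)
  b <- parent_child_union_ora(unname(relabel[toy$study_set]),
                              unname(relabel[toy$reference]),
                              toy$ontology, closed2)
  expect_equal(a$p_value, b$p_value)
})

test_that("category summaries reflect which categories fire", {
  records <- tibble::tibble(term_id = c("t1", "t2", "t3"),
                            p_value = c(0.01, 0.2, 0.04))
  cmap <- tibble::tibble(term_id = c("t1", "t2", "t3"),
                         category = c("F_a", "F_p", "F_a"))
  out <- categorize_terms(records, cmap)
  expect_equal(out$category, "F_a")
  expect_equal(out$n_terms, 2L)
  expect_equal(out$min_p, 0.01)
  none <- categorize_terms(dplyr::mutate(records, p_value = 0.5), cmap)
  expect_equal(nrow(none), 0)
})
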