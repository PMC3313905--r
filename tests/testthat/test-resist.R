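set_label_of <- function(a, b) paste0(a, "∩", b)

test_that("U/D/S sets partition the gene universe per experiment", {
  de <- tidyr::expand_grid(gene_id = sprintf("g%02d", 1:12),
                           experiment_id = as.character(1:5))
  withr::with_seed(51, {
    de$label <- sample(c("U", "D", "S"), nrow(de), replace = TRUE,
                       prob = c(0.2, 0.2, 0.6))
  })
  sets <- build_sets(de)
  for (e in unique(sets$experiment_id)) {
    sub <- sets[sets$experiment_id == e, ]
    expect_setequal(sub$gene_id, sprintf("g%02d", 1:12))
    expect_equal(anyDuplicated(sub$gene_id), 0L)
  }
  de$label[1] <- NA
  expect_error(build_sets(de), "missing label")
})

test_that("the named intersections follow set algebra", {
  de <- tidyr::expand_grid(gene_id = c("a", "b", "c", "d"),
                           experiment_id = as.character(1:5))
  de$label <- "S"
  de$label[de$gene_id == "a" & de$experiment_id %in% c("1", "3")] <- "D"
  de$label[de$gene_id == "b" & de$experiment_id == "1"] <- "U"
  de$label[de$gene_id == "b" & de$experiment_id == "3"] <- "U"
  de$label[de$gene_id == "c" & de$experiment_id == "4"] <- "U"
  de$label[de$gene_id == "c" & de$experiment_id == "5"] <- "D"
  inter <- intersect_sets(build_sets(de))
  get <- function(lbl) inter$genes[[which(inter$set_label == lbl)]]
  expect_equal(get(set_label_of("D1", "D3")), "a")
  expect_equal(get(set_label_of("U1", "U3")), "b")
  expect_equal(get(set_label_of("U4", "D5")), "c")
  expect_equal(get(set_label_of("U1", "D3")), character(0))
  expect_equal(get(set_label_of("S1", "S3")), c("c", "d"))
  expect_true(all(inter$n_genes <= 4))
  expect_equal(nrow(inter), 10)
})

test_that("the rule engine reproduces the published verdict rows", {
  rows <- list(
    list(set_label_of("D1", "D3"), "F_a", "inherent", FALSE),  # DAPK1
    list(set_label_of("U4", "D5"), "F_p", "acquired", FALSE),  # KIT
    list("U1", "F_p", "inherent", FALSE),                      # BCL2L2
    list("U3", c("F_p", "F_m"), "inherent", FALSE),
    list("D1", "F_a", "inherent", FALSE),                      # DAP, CASP1
    list("D1", "F_p", "acquired", FALSE),                      # CDC25
    list("D3", "F_a", "inherent", FALSE),                      # IL24
    list("U4", "F_p", "acquired", FALSE),                      # BCL2
    list("U5", "F_p", "acquired", FALSE),                      # BIRC5
    list("D4", "F_p", "acquired", FALSE),                      # BCL2L2
    list("D5", c("F_a", "F_i"), "inherent", TRUE)              # IKBKE, PPP3CC
  )
  for (r in rows) {
    v <- classify_resistance(r[[1]], r[[2]])
    hit <- v[!is.na(v$category) &
               v$category %in% intersect(r[[2]], c("F_p", "F_a")), ]
    expect_equal(unique(hit$resistance), r[[3]], label = r[[1]])
    expect_equal(unique(hit$qualified), r[[4]], label = r[[1]])
  }
  # rows where no relevant category fires are undefined ("n/d")
  expect_equal(classify_resistance(set_label_of("S1", "S3"),
                                   "F_i")$resistance, "undefined")
  expect_equal(classify_resistance(set_label_of("S1", "S3"),
                                   character(0))$resistance, "undefined")
  expect_equal(classify_resistance(set_label_of("S4", "S5"),
                                   c("F_a", "F_m"))$resistance, "undefined")
})

test_that("the rule engine is pure and rejects unknown labels", {
  a <- classify_resistance("U1", c("F_p", "F_a"))
  b <- classify_resistance("U1", c("F_p", "F_a"))
  expect_identical(a, b)
  expect_equal(nrow(a), 2) # mixed enrichment: both sub-verdicts reported
  expect_setequal(a$resistance, c("inherent", "acquired"))
  expect_error(classify_resistance("Q9", "F_p"), "unknown set label")
})

test_that("cluster mean profiles map to behavioural set labels", {
  thresholds <- tibble::tibble(experiment_id = as.character(1:5),
                               threshold = 0.5)
  means <- tidyr::expand_grid(cluster = 1:3,
                              experiment_id = as.character(1:5))
  means$mean_M <- 0
  means$mean_M[means$cluster == 2 & means$experiment_id == "5"] <- -1
  means$mean_M[means$cluster == 3 & means$experiment_id == "5"] <- 1
  out <- map_cluster_to_set(means, thresholds)
  expect_equal(out$set_label, c("~S all", "~D5", "~U5"))
  expect_equal(out$profile[2], "S,S,S,S,D")
})

test_that("classify_gene_sets wires enrichment to verdicts", {
  onto <- chain_ontology()
  genes <- sprintf("g%02d", 1:20)
  ann <- dplyr::bind_rows(
    tibble::tibble(gene_id = genes, term_id = "root"),
    tibble::tibble(gene_id = genes[1:12], term_id = "mid"),
    tibble::tibble(gene_id = genes[1:5], term_id = "leaf")
  )
  cmap <- tibble::tibble(term_id = "leaf", category = "F_a")
  sets <- tibble::tibble(
    set_label = c(set_label_of("D1", "D3"), "U1"),
    genes = list(genes[1:4], character(0)) # all four under the leaf term
  )
  out <- classify_gene_sets(sets, genes, onto,
                            propagate_annotations(onto, ann), cmap)
  # leaf enrichment: drawing 4 leaf genes among 4 draws from the 12-gene
  # mid universe with 5 leaf genes: p = choose(5,4)/choose(12,4) < 0.05
  expect_equal(out$resistance, c("inherent", "not_applicable"))
  expect_equal(out$categories[1], "F_a")
  expect_equal(out$n_genes, c(4L, 0L))
})
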