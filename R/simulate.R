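# Synthetic-data generator: two-channel slides with a known truth table,
# platform pairs with a reporter->gene mapping, cluster-structured profile
# matrices, and toy ontologies with a planted enriched term. Every
# downstream stage of the pipeline can be exercised against ground truth
# without any external download.

#' Simulation configuration
#'
#' Bundles and validates the parameters of the two-channel slide generator.
#' All "logarithmic" quantities are log2. The generative model is
#' multiplicative on the raw scale: the observed log2 foreground is the true
#' log2 signal plus a background contamination term with mean `Bl(signal)`
#' (a linear trend by default) and standard deviation `background_noise_sd`;
#' the recorded log2 background channel is `Bl(signal)` plus noise of the
#' same magnitude. Dye bias is injected as a polynomial in the mean
#' log-intensity A added to the red channel, so that an intensity-dependent
#' loess normalization can remove it exactly in the noiseless limit.
#'
#' @param n_features Number of features (spots) per slide, at least 50.
#' @param n_replicates Replicate slides per loop experiment (default 3).
#' @param dye_bias_coefficients Polynomial coefficients (increasing degree)
#'   of the M-vs-A dye-bias trend added to the red channel.
#' @param background_noise_sd SD (log2 units) of the multiplicative
#'   background noise on each channel.
#' @param background_coefficients Coefficients (intercept, slope) of the
#'   linear log2 background trend `Bl(F)`.
#' @param de_fraction Proportion of features planted as differentially
#'   expressed per experiment.
#' @param de_effect Planted log2 fold-change magnitude.
#' @param outlier_fraction Proportion of features spiked with an extreme
#'   intensity to exercise outlier exclusion.
#' @param intensity_range Log2 range of the true green-channel abundances
#'   (raw dynamic range defaults to 2^6..2^16).
#' @param seed Integer seed; a fixed seed makes all generator output
#'   reproducible.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_features = 1000,
                       n_replicates = 3,
                       dye_bias_coefficients = c(0, 0, 0),
                       background_noise_sd = 0.1,
                       background_coefficients = c(4, 0.25),
                       de_fraction = 0.05,
                       de_effect = 1.5,
                       outlier_fraction = 0,
                       intensity_range = c(6, 16),
                       seed = 1L) {
  if (!is.numeric(n_features) || n_features < 50) {
    abort("`n_features` must be at least 50.")
  }
  if (!is.numeric(n_replicates) || n_replicates < 1) {
    abort("`n_replicates` must be a positive integer.")
  }
  for (p in c(de_fraction = de_fraction, outlier_fraction = outlier_fraction)) {
    if (!is_proportion(p)) abort("proportions must lie in [0, 1].")
  }
  if (!is.numeric(background_noise_sd) || background_noise_sd < 0) {
    abort("`background_noise_sd` must be non-negative.")
  }
  if (!is.numeric(de_effect) || de_effect < 0) {
    abort("`de_effect` must be non-negative.")
  }
  if (length(intensity_range) != 2L || diff(intensity_range) <= 0) {
    abort("`intensity_range` must be an increasing pair of log2 bounds.")
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single integer.")
  }
  structure(
    list(
      n_features = as.integer(n_features),
      n_replicates = as.integer(n_replicates),
      dye_bias_coefficients = as.numeric(dye_bias_coefficients),
      background_noise_sd = background_noise_sd,
      background_coefficients = as.numeric(background_coefficients),
      de_fraction = de_fraction,
      de_effect = de_effect,
      outlier_fraction = outlier_fraction,
      intensity_range = as.numeric(intensity_range),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Planted truth for one experiment: per-feature log2 fold change and labels.
make_truth <- function(feature_id, m_true, experiment_id) {
  tibble(
    experiment_id = experiment_id,
    feature_id = feature_id,
    true_log_ratio = m_true,
    is_de = m_true != 0,
    true_direction = dplyr::case_when(
      m_true > 0 ~ "U",
      m_true < 0 ~ "D",
      TRUE ~ "S"
    )
  )
}

# Draw a planted DE vector: de_fraction of features at +/- de_effect.
draw_de <- function(n, de_fraction, de_effect) {
  m <- rep(0, n)
  n_de <- round(de_fraction * n)
  if (n_de > 0) {
    idx <- sample.int(n, n_de)
    m[idx] <- sample(c(-1, 1), n_de, replace = TRUE) * de_effect
  }
  m
}

# Generate the replicate slides of one experiment given its per-feature
# truth. Returns log2-scale slide rows (one per feature x replicate).
make_slides <- function(feature_id, m_true, config, experiment_id,
                        n_replicates) {
  n <- length(feature_id)
  s_g <- runif(n, config$intensity_range[1], config$intensity_range[2])
  s_r0 <- s_g + m_true
  a0 <- (s_r0 + s_g) / 2
  s_r <- s_r0 + polyval_asc(config$dye_bias_coefficients, a0)

  n_out <- round(config$outlier_fraction * n)
  if (n_out > 0) {
    spike <- sample.int(n, n_out)
    s_r[spike] <- s_r[spike] + 8
    s_g[spike] <- s_g[spike] + 8
  }

  bl <- function(s) polyval_asc(config$background_coefficients, s)
  sdv <- config$background_noise_sd
  purrr::map(seq_len(n_replicates), function(r) {
    tibble(
      experiment_id = experiment_id,
      replicate_index = r,
      feature_id = feature_id,
      F_R = s_r + rnorm(n, bl(s_r), sdv),
      B_R = bl(s_r) + rnorm(n, 0, sdv),
      F_G = s_g + rnorm(n, bl(s_g), sdv),
      B_G = bl(s_g) + rnorm(n, 0, sdv)
    )
  }) |> purrr::list_rbind()
}

#' Simulate a loop-design experiment triple
#'
#' Generates replicate two-channel slides for the loop experiments '1'
#' (control vs low dose), '2' (low vs high dose) and '3' (control vs high
#' dose). The noiseless truth satisfies the loop identity feature-wise:
#' the planted log ratios obey `M1 + M2 = M3`, so the loop discrepancy
#' `LdF = M1 + M2 - M3` of the truth is exactly zero. Noise, dye bias and
#' multiplicative background are added on top.
#'
#' @param config A [sim_config()].
#' @param feature_id Optional character vector of feature identifiers; by
#'   default `FT00001..` of length `n_features`.
#' @return A list with `slides` (one tibble of log2 slide rows across the
#'   three experiments and all replicates) and `truth` (per experiment and
#'   feature: `true_log_ratio`, `is_de`, `true_direction`).
#' @export
simulate_loop_experiment <- function(config, feature_id = NULL) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n <- if (is.null(feature_id)) config$n_features else length(feature_id)
    if (is.null(feature_id)) feature_id <- sprintf("FT%05d", seq_len(n))
    m1 <- draw_de(n, config$de_fraction, config$de_effect)
    m2 <- draw_de(n, config$de_fraction, config$de_effect)
    m3 <- m1 + m2
    slides <- purrr::list_rbind(list(
      make_slides(feature_id, m1, config, "1", config$n_replicates),
      make_slides(feature_id, m2, config, "2", config$n_replicates),
      make_slides(feature_id, m3, config, "3", config$n_replicates)
    ))
    truth <- purrr::list_rbind(list(
      make_truth(feature_id, m1, "1"),
      make_truth(feature_id, m2, "2"),
      make_truth(feature_id, m3, "3")
    ))
    list(slides = slides, truth = truth)
  })
}

#' Simulate single-slide late-treatment experiments
#'
#' Generates one slide per experiment (default the 72 h experiments '4' and
#' '5') with independently planted differential expression.
#'
#' @inheritParams simulate_loop_experiment
#' @param experiments Character experiment identifiers.
#' @return A list with `slides` and `truth`, as for
#'   [simulate_loop_experiment()].
#' @export
simulate_single_experiments <- function(config, experiments = c("4", "5"),
                                        feature_id = NULL) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 1L, {
    n <- if (is.null(feature_id)) config$n_features else length(feature_id)
    if (is.null(feature_id)) feature_id <- sprintf("FT%05d", seq_len(n))
    out <- purrr::map(experiments, function(e) {
      m <- draw_de(n, config$de_fraction, config$de_effect)
      list(slides = make_slides(feature_id, m, config, e, 1L),
           truth = make_truth(feature_id, m, e))
    })
    list(slides = purrr::list_rbind(purrr::map(out, "slides")),
         truth = purrr::list_rbind(purrr::map(out, "truth")))
  })
}

#' Simulate a pair of overlapping microarray platforms
#'
#' Emulates two platforms from the same manufacturer with overlapping gene
#' content (the study's 1.2 k / 4.8 k situation, scaled down) and the
#' reporter-to-gene mapping table. The mapping is one-to-one on the overlap;
#' a configurable number of reporters is left out of the mapping entirely
#' (unmappable) and a group of reporters is made many-to-one (they share a
#' single decoy gene) so that downstream one-to-one validation has
#' something to drop.
#'
#' @param config A [sim_config()] (only the seed is used).
#' @param overlap_fraction Fraction of the smaller platform's genes shared
#'   with the larger platform; must be in (0, 1].
#' @param n_genes_a,n_genes_b Number of mappable genes per platform.
#' @param n_unmapped Reporters per platform absent from the mapping.
#' @param n_many_to_one Reporters (on platform A) sharing one decoy gene.
#' @return A list with `platform_a` and `platform_b` (tibbles of
#'   `reporter_id`, `gene_id`), `mapping` (the reporter-to-gene table as a
#'   pipeline input, including the planted violations), `cgs_true` (the
#'   gene overlap) and `many_to_one_reporters`.
#' @export
simulate_platform_pair <- function(config, overlap_fraction = 0.8,
                                   n_genes_a = 120, n_genes_b = 480,
                                   n_unmapped = 5, n_many_to_one = 5) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.numeric(overlap_fraction) || overlap_fraction <= 0 ||
      overlap_fraction > 1) {
    abort("`overlap_fraction` must lie in (0, 1]; 0 would leave an empty common gene set.")
  }
  withr::with_seed(config$seed + 2L, {
    n_overlap <- round(overlap_fraction * min(n_genes_a, n_genes_b))
    if (n_overlap < 1) abort("overlap too small: no shared genes.")
    n_total <- n_genes_a + n_genes_b - n_overlap
    genes <- sprintf("GN%04d", seq_len(n_total))
    shared <- genes[seq_len(n_overlap)]
    only_a <- genes[seq_len(n_genes_a - n_overlap) + n_overlap]
    only_b <- setdiff(genes, c(shared, only_a))

    genes_a <- sample(c(shared, only_a))
    genes_b <- sample(c(shared, only_b))
    platform_a <- tibble(
      reporter_id = sprintf("A_RPT%04d", seq_along(genes_a)),
      gene_id = genes_a
    )
    platform_b <- tibble(
      reporter_id = sprintf("B_RPT%04d", seq_along(genes_b)),
      gene_id = genes_b
    )

    mapping <- dplyr::bind_rows(platform_a, platform_b)
    # unmappable reporters: present on the slides, absent from the mapping
    unmapped_a <- sprintf("A_RPT%04d", nrow(platform_a) + seq_len(n_unmapped))
    unmapped_b <- sprintf("B_RPT%04d", nrow(platform_b) + seq_len(n_unmapped))
    platform_a <- dplyr::bind_rows(
      platform_a, tibble(reporter_id = unmapped_a, gene_id = NA_character_))
    platform_b <- dplyr::bind_rows(
      platform_b, tibble(reporter_id = unmapped_b, gene_id = NA_character_))
    # many-to-one reporters: all mapped to one decoy gene on platform A
    m2o <- character(0)
    if (n_many_to_one > 0) {
      m2o <- sprintf("A_RPT%04d",
                     nrow(platform_a) + seq_len(n_many_to_one))
      decoy <- sprintf("GN%04d", n_total + 1L)
      platform_a <- dplyr::bind_rows(
        platform_a, tibble(reporter_id = m2o, gene_id = decoy))
      mapping <- dplyr::bind_rows(
        mapping, tibble(reporter_id = m2o, gene_id = decoy))
    }
    list(platform_a = platform_a, platform_b = platform_b,
         mapping = mapping, cgs_true = sort(shared),
         many_to_one_reporters = m2o)
  })
}

#' Simulate cluster-structured expression profiles
#'
#' Draws gene profiles around `k_true` centroid profiles with isotropic
#' Gaussian noise. Centroid coordinates are drawn from
#' `N(0, (separation * noise_sd)^2)` and redrawn until every pairwise
#' centroid distance is at least `separation * noise_sd`, so `separation`
#' is a guaranteed lower bound on the centroid separation in noise-SD
#' units.
#'
#' @param n_genes Number of genes (rows).
#' @param n_experiments Number of profile dimensions (columns).
#' @param k_true Number of planted clusters (>= 2).
#' @param separation Minimum centroid separation in units of `noise_sd`.
#' @param noise_sd Within-cluster SD per dimension.
#' @param seed Integer seed.
#' @return A list with `profiles` (tibble: `gene_id` plus one numeric
#'   column per experiment) and `assignment` (tibble: `gene_id`,
#'   `cluster`).
#' @export
simulate_cluster_profiles <- function(n_genes, n_experiments = 5, k_true,
                                      separation, noise_sd = 1, seed = 1L) {
  if (k_true < 2) abort("`k_true` must be at least 2.")
  if (k_true > n_genes) abort("`k_true` cannot exceed `n_genes`.")
  if (separation <= 0) abort("`separation` must be positive.")
  withr::with_seed(as.integer(seed), {
    repeat {
      centroids <- matrix(rnorm(k_true * n_experiments, 0,
                                separation * noise_sd),
                          nrow = k_true)
      if (k_true == 1 ||
          min(dist(centroids)) >= separation * noise_sd) break
    }
    cluster <- sample(rep(seq_len(k_true), length.out = n_genes))
    x <- centroids[cluster, , drop = FALSE] +
      matrix(rnorm(n_genes * n_experiments, 0, noise_sd), nrow = n_genes)
    gene_id <- sprintf("GN%04d", seq_len(n_genes))
    profiles <- as_tibble(x, .name_repair = ~ as.character(seq_len(n_experiments)))
    profiles <- dplyr::bind_cols(tibble(gene_id = gene_id), profiles)
    list(profiles = profiles,
         assignment = tibble(gene_id = gene_id, cluster = cluster))
  })
}

#' Simulate a toy ontology with a planted enriched term
#'
#' Builds a random single-root DAG of terms, annotates genes to random
#' terms, and draws a study set that over-samples genes annotated (after
#' true-path propagation) to a planted term.
#'
#' @param n_terms Number of terms including the root.
#' @param n_genes Number of genes in the reference universe.
#' @param planted_term Term to enrich; by default the non-root term with
#'   the most propagated annotations covering at most 60% of genes.
#' @param planted_enrichment Sampling-weight multiplier for genes under the
#'   planted term (0 gives a uniform study set).
#' @param study_fraction Study-set size as a fraction of `n_genes`.
#' @param seed Integer seed.
#' @return A list with `ontology` (a [build_ontology()] object),
#'   `annotations` (direct gene-term tibble), `study_set`, `reference`
#'   (all genes) and `planted_term`.
#' @export
simulate_toy_ontology <- function(n_terms = 20, n_genes = 50,
                                  planted_term = NULL,
                                  planted_enrichment = 5,
                                  study_fraction = 0.2, seed = 1L) {
  if (n_terms < 2) abort("`n_terms` must be at least 2.")
  withr::with_seed(as.integer(seed), {
    term_id <- sprintf("T%03d", seq_len(n_terms))
    parents <- c(list(character(0)), purrr::map(2:n_terms, function(i) {
      k <- sample(1:min(2L, i - 1L), 1)
      term_id[sample.int(i - 1L, k)]
    }))
    names(parents) <- term_id
    onto <- build_ontology(tibble(term_id = term_id,
                                  name = paste("term", term_id)),
                           parents)
    gene_id <- sprintf("GN%04d", seq_len(n_genes))
    annotations <- purrr::map(gene_id, function(g) {
      tibble(gene_id = g,
             term_id = sample(term_id[-1], sample(1:3, 1)))
    }) |> purrr::list_rbind()

    closed <- propagate_annotations(onto, annotations)
    by_term <- split(closed$gene_id, closed$term_id)
    if (is.null(planted_term)) {
      sizes <- lengths(by_term)
      sizes <- sizes[names(sizes) != onto$root &
                       sizes <= 0.6 * n_genes & sizes >= 3]
      if (length(sizes) == 0) abort("no suitable term to plant; increase n_genes.")
      planted_term <- names(sizes)[which.max(sizes)]
    }
    under <- gene_id %in% by_term[[planted_term]]
    w <- 1 + planted_enrichment * under
    n_study <- max(2L, round(study_fraction * n_genes))
    study_set <- sample(gene_id, n_study, prob = w)
    list(ontology = onto, annotations = annotations,
         study_set = sort(study_set), reference = gene_id,
         planted_term = planted_term)
  })
}

#' Simulate a gene-to-chromosome map
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param n_chromosomes Number of chromosomes to spread the genes over.
#' @param seed Integer seed.
#' @return A tibble with `gene_id` and `chromosome`.
#' @export
simulate_chromosome_map <- function(gene_ids, n_chromosomes = 23, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    tibble(gene_id = gene_ids,
           chromosome = sample(paste0("chr", seq_len(n_chromosomes)),
                               length(gene_ids), replace = TRUE))
  })
}

#' Simulate a complete two-platform study
#'
#' Composes the generator pieces into a full pipeline input bundle: a
#' platform pair with its reporter mapping, triplicate loop slides
#' (experiments '1', '2', '3') measured on platform A, single slides for
#' the late experiments '4' and '5' on platform B, a chromosome map, a toy
#' ontology with annotations and a term-to-functional-category map.
#'
#' @param config A [sim_config()].
#' @param overlap_fraction,n_genes_a,n_genes_b Passed to
#'   [simulate_platform_pair()].
#' @return A list with `slides`, `truth`, `mapping`, `platforms`,
#'   `chromosome_map`, `ontology`, `annotations`, `category_map`,
#'   `cgs_true` and the `config`.
#' @export
simulate_study <- function(config, overlap_fraction = 0.8,
                           n_genes_a = 120, n_genes_b = 480) {
  stopifnot(inherits(config, "sim_config"))
  pair <- simulate_platform_pair(config, overlap_fraction,
                                 n_genes_a, n_genes_b)
  loop <- simulate_loop_experiment(config,
                                   feature_id = pair$platform_a$reporter_id)
  late <- simulate_single_experiments(config,
                                      feature_id = pair$platform_b$reporter_id)
  genes <- sort(unique(na.omit(c(pair$platform_a$gene_id,
                                 pair$platform_b$gene_id))))
  chrom <- simulate_chromosome_map(genes, seed = config$seed + 3L)
  toy <- simulate_toy_ontology(n_terms = 25, n_genes = length(genes),
                               seed = config$seed + 4L)
  toy$annotations$gene_id <- genes[match(toy$annotations$gene_id,
                                         sprintf("GN%04d", seq_along(genes)))]
  # annotate the planted up/down genes of the early experiments under two
  # dedicated terms mapped to the F_p / F_a functional categories, so the
  # resistance logic has signal to detect
  reporter_gene <- setNames(pair$platform_a$gene_id,
                            pair$platform_a$reporter_id)
  dir1 <- loop$truth[loop$truth$experiment_id == "1", ]
  up_genes <- na.omit(unname(reporter_gene[
    dir1$feature_id[dir1$true_direction == "U"]]))
  down_genes <- na.omit(unname(reporter_gene[
    dir1$feature_id[dir1$true_direction == "D"]]))
  non_root <- setdiff(toy$ontology$terms$term_id, toy$ontology$root)
  term_fp <- non_root[length(non_root) - 1L]
  term_fa <- non_root[length(non_root)]
  toy$annotations <- dplyr::bind_rows(
    toy$annotations,
    tibble(gene_id = up_genes, term_id = term_fp),
    tibble(gene_id = down_genes, term_id = term_fa)
  ) |> dplyr::distinct()
  category_map <- withr::with_seed(config$seed + 5L, {
    extras <- setdiff(non_root, c(term_fp, term_fa))
    n_cat <- min(length(extras), 8L)
    dplyr::bind_rows(
      tibble(term_id = c(term_fp, term_fa), category = c("F_p", "F_a")),
      tibble(term_id = sample(extras, n_cat),
             category = sample(c("F_m", "F_i"), n_cat, replace = TRUE))
    )
  })
  list(
    slides = dplyr::bind_rows(loop$slides, late$slides),
    truth = dplyr::bind_rows(loop$truth, late$truth),
    mapping = pair$mapping,
    platforms = pair[c("platform_a", "platform_b")],
    chromosome_map = chrom,
    ontology = toy$ontology,
    annotations = toy$annotations,
    category_map = category_map,
    cgs_true = pair$cgs_true,
    config = config
  )
}
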