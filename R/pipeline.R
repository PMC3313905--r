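# End-to-end orchestration: preprocess -> loop filter -> integrate ->
# DE calling -> {sets, clustering} -> enrichment -> verdicts ->
# chromosome aggregation, with a manifest tying outputs to parameters.

#' Pipeline parameters
#'
#' Collects every tunable of the pipeline with the study's defaults.
#'
#' @param span_bg Loess span of the background regression.
#' @param span_ma Loess span of the M-A normalization (10%).
#' @param iqr_k IQR multiplier of the outlier filter (3).
#' @param loop_n_sd Loop-filter band width in SDs (2).
#' @param reference_experiments MRS reference experiments.
#' @param window_frac Sliding-window width for DE calling (20%).
#' @param confidence DE confidence level (95%).
#' @param sd_top_n Genes kept for clustering by SD ranking (100).
#' @param k_min,k_max Cluster-number scan range (2..30).
#' @param n_init_select Restarts per k during model selection (1000).
#' @param n_init_final Restarts of the final clustering (100).
#' @param alpha Enrichment significance threshold (0.05).
#' @param seed Master seed, split per stage.
#' @return A named list of class `gc_params`.
#' @export
pipeline_params <- function(span_bg = 0.3, span_ma = 0.10, iqr_k = 3,
                            loop_n_sd = 2,
                            reference_experiments = c("4", "5"),
                            window_frac = 0.20, confidence = 0.95,
                            sd_top_n = 100, k_min = 2, k_max = 30,
                            n_init_select = 1000, n_init_final = 100,
                            alpha = 0.05, seed = 1L) {
  structure(as.list(environment()), class = "gc_params")
}

#' Run the full analysis pipeline
#'
#' Executes every stage on an input bundle (as produced by
#' [simulate_study()] or [load_pipeline_inputs()]): per-experiment
#' preprocessing, the loop-design filter over experiments '1'-'3',
#' reporter mapping and MRS integration over the common gene set,
#' sliding-window DE calling, U/D/S set construction with the named
#' intersections, SD-ranked clustering with silhouette-based selection of
#' k, parent-child-union enrichment with resistance verdicts, and
#' chromosome-level aggregation. Re-running with the same inputs and
#' parameters reproduces identical results.
#'
#' @param inputs List with `slides`, `mapping`, `ontology`, `annotations`,
#'   `category_map`, `chromosome_map`.
#' @param params A [pipeline_params()] list.
#' @param out_dir Optional directory; when given, every result table is
#'   written as TSV together with a `manifest.json` recording parameters,
#'   seed and per-file checksums.
#' @return An object of class `gc_pipeline` with elements `unified`,
#'   `cgs`, `de`, `sets`, `intersections`, `kselect`, `clustering`,
#'   `cluster_profiles`, `cluster_behaviour`, `verdicts`, `chromosome`,
#'   `manifest`.
#' @export
run_pipeline <- function(inputs, params = pipeline_params(),
                         out_dir = NULL) {
  for (nm in c("slides", "mapping", "ontology", "annotations",
               "category_map", "chromosome_map")) {
    if (is.null(inputs[[nm]])) abort(sprintf("inputs$%s is missing.", nm))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  profiles <- stage("preprocess", {
    inputs$slides |>
      dplyr::group_by(.data$experiment_id) |>
      dplyr::group_map(~ preprocess_experiment(
        .x, span_bg = params$span_bg, span_ma = params$span_ma,
        iqr_k = params$iqr_k), .keep = TRUE) |>
      setNames(sort(unique(inputs$slides$experiment_id)))
  })
  # group_map drops the grouping column; restore names from group order
  exp_ids <- sort(unique(inputs$slides$experiment_id))
  names(profiles) <- exp_ids

  loop <- stage("loop_filter", {
    loop_design_filter(profiles[["1"]], profiles[["2"]], profiles[["3"]],
                       n_sd = params$loop_n_sd)
  })
  kept <- loop$feature_id[loop$keep]
  for (e in c("1", "2", "3")) {
    profiles[[e]] <- dplyr::filter(profiles[[e]],
                                   .data$feature_id %in% kept, .data$mask)
  }
  for (e in setdiff(exp_ids, c("1", "2", "3"))) {
    profiles[[e]] <- dplyr::filter(profiles[[e]], .data$mask)
  }

  gene_profiles <- stage("integrate", {
    purrr::imap(profiles, function(p, e) {
      map_reporters(dplyr::select(p, "feature_id", "M", "A"),
                    inputs$mapping) |>
        dplyr::mutate(experiment_id = e)
    }) |> purrr::list_rbind()
  })
  unified <- stage("integrate", {
    integrate_experiments(gene_profiles,
                          reference_experiments = params$reference_experiments)
  })
  cgs <- attr(unified, "cgs")

  de <- stage("de_detect", {
    call_de(unified, window_frac = params$window_frac,
            confidence = params$confidence)
  })
  sets <- stage("sets", build_sets(de))
  intersections <- stage("sets", intersect_sets(sets))

  seeds <- split_seed(params$seed, 2)
  wide <- unified_wide(unified)
  top <- stage("cluster", {
    select_high_variance(wide, n = min(params$sd_top_n, nrow(wide)))
  })
  kselect <- stage("cluster", {
    select_optimal_k(top, k_min = params$k_min,
                     k_max = min(params$k_max, nrow(top) - 1),
                     n_init = params$n_init_select, seed = seeds[1])
  })
  clustering <- stage("cluster", {
    kmeans_best_of(top, k = kselect$k_star,
                   n_init = params$n_init_final, seed = seeds[2])
  })
  cluster_profiles <- cluster_mean_profiles(top, clustering$assignment)
  behaviour <- map_cluster_to_set(cluster_profiles, de_thresholds(de))

  annotations_closed <- stage("enrich", {
    propagate_annotations(inputs$ontology, inputs$annotations)
  })
  individual <- sets |>
    dplyr::filter(.data$label %in% c("U", "D")) |>
    dplyr::group_by(set_label = paste0(.data$label, .data$experiment_id)) |>
    dplyr::summarise(genes = list(sort(.data$gene_id)), .groups = "drop")
  cluster_sets <- clustering$assignment |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(genes = list(sort(.data$gene_id)), .groups = "drop") |>
    dplyr::left_join(behaviour, by = "cluster")
  mappable <- grepl("^~[UD][0-9]$", cluster_sets$set_label)
  cluster_sets$rule_label <- ifelse(mappable,
                                    sub("^~", "", cluster_sets$set_label),
                                    NA_character_)

  verdicts <- stage("classify", {
    v1 <- classify_gene_sets(
      dplyr::select(intersections, "set_label", "genes"),
      cgs, inputs$ontology, annotations_closed, inputs$category_map,
      alpha = params$alpha)
    v2 <- classify_gene_sets(individual, cgs, inputs$ontology,
                             annotations_closed, inputs$category_map,
                             alpha = params$alpha)
    v3 <- cluster_sets |>
      dplyr::filter(!is.na(.data$rule_label)) |>
      dplyr::transmute(set_label = .data$rule_label, genes = .data$genes) |>
      classify_gene_sets(cgs, inputs$ontology, annotations_closed,
                         inputs$category_map, alpha = params$alpha)
    if (nrow(v3) > 0) {
      v3$set_label <- paste0(
        "C", cluster_sets$cluster[!is.na(cluster_sets$rule_label)],
        " (", v3$set_label, ")")
    }
    dplyr::bind_rows(v1, v2, v3)
  })

  chromosome <- stage("chromo", {
    list(
      profiles = purrr::list_rbind(purrr::map(
        c("all", "4h", "72h"),
        ~ chromosome_means(unified, inputs$chromosome_map, .x))),
      correlations = correlate_counts_expression(unified,
                                                 inputs$chromosome_map)
    )
  })

  result <- structure(
    list(unified = unified, cgs = cgs, loop_filter = loop, de = de,
         sets = sets, intersections = intersections, kselect = kselect,
         clustering = clustering, cluster_profiles = cluster_profiles,
         cluster_behaviour = behaviour, verdicts = verdicts,
         chromosome = chromosome, params = params),
    class = "gc_pipeline"
  )
  result$manifest <- build_manifest(result, params)

  if (!is.null(out_dir)) {
    result$manifest <- write_pipeline_outputs(result, out_dir)
  }
  result
}

flatten_verdicts <- function(verdicts) {
  dplyr::select(verdicts, "set_label", "n_genes", "categories",
                "resistance", "qualified")
}

build_manifest <- function(result, params, files = NULL) {
  list(
    package = "gcresist",
    created = "run",
    seed = params$seed,
    parameters = unclass(params),
    n_cgs = length(result$cgs),
    k_star = result$kselect$k_star,
    files = files
  )
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(df, path, progress = FALSE)
    path
  }
  paths <- c(
    w(as_tibble(result$unified), "unified_matrix.tsv"),
    w(result$loop_filter, "loop_filter.tsv"),
    w(as_tibble(result$de), "de_labels.tsv"),
    w(as_tibble(result$sets), "sets.tsv"),
    w(dplyr::mutate(result$intersections,
                    genes = purrr::map_chr(.data$genes, paste,
                                           collapse = ",")),
      "intersections.tsv"),
    w(result$kselect$curve, "silhouette_curve.tsv"),
    w(result$clustering$assignment, "cluster_assignment.tsv"),
    w(result$cluster_profiles, "cluster_profiles.tsv"),
    w(result$cluster_behaviour, "cluster_behaviour.tsv"),
    w(flatten_verdicts(result$verdicts), "verdicts.tsv"),
    w(result$chromosome$profiles, "chromosome_profiles.tsv"),
    w(result$chromosome$correlations$pairs, "chromosome_correlations.tsv")
  )
  manifest <- build_manifest(
    result, result$params,
    files = lapply(setNames(paths, basename(paths)),
                   function(p) list(md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

#' @export
print.gc_pipeline <- function(x, ...) {
  cat(sprintf(
    "gcresist pipeline result\n  common gene set: %d genes\n  optimal k: %d (mean silhouette %.3f)\n  verdicts: %s\n",
    length(x$cgs), x$kselect$k_star, x$clustering$mean_silhouette,
    paste(sprintf("%s=%d", names(table(x$verdicts$resistance)),
                  table(x$verdicts$resistance)), collapse = ", ")))
  invisible(x)
}
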