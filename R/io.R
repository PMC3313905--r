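# Readers and writers for the pipeline's tab-delimited dialects. Slide
# files store raw linear intensities; log2 is taken on load and undone on
# write, so write(read(x)) round-trips.

slide_columns <- c("feature_id", "F_R", "B_R", "F_G", "B_G")

read_tsv_strict <- function(path, what) {
  if (!file.exists(path)) abort(sprintf("%s file not found: %s", what, path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed %s file %s: first problem at line %d (%s).",
                  what, path, probs$row[1] + 1L, probs$expected[1]))
  }
  df
}

#' Read a two-channel slide table
#'
#' Reads a tab-delimited feature table with header columns `feature_id`,
#' `F_R`, `B_R`, `F_G`, `B_G` holding raw linear median intensities.
#' Intensities are converted to log2 on load; missing or non-positive raw
#' values become `NA` and are counted in a log message.
#'
#' @param path Path to the TSV file.
#' @param experiment_id,replicate_index Optional identifiers attached as
#'   columns (kept from the file when present there).
#' @return A log2-scale slide tibble.
#' @export
read_slide_table <- function(path, experiment_id = NULL,
                             replicate_index = NULL) {
  df <- read_tsv_strict(path, "slide")
  missing <- setdiff(slide_columns, names(df))
  if (length(missing) > 0) {
    abort(sprintf("slide file %s is missing column(s): %s.",
                  path, paste(missing, collapse = ", ")))
  }
  n_bad <- 0L
  for (col in setdiff(slide_columns, "feature_id")) {
    raw <- as.numeric(df[[col]])
    bad <- !is.finite(raw) | raw <= 0
    n_bad <- n_bad + sum(bad)
    raw[bad] <- NA_real_
    df[[col]] <- log2(raw)
  }
  if (n_bad > 0) {
    inform(sprintf("read_slide_table: %d missing/non-positive intensity value(s) in %s set to NA.",
                   n_bad, basename(path)))
  }
  if (!is.null(experiment_id)) df$experiment_id <- as.character(experiment_id)
  if (!is.null(replicate_index)) df$replicate_index <- as.integer(replicate_index)
  as_tibble(df)
}

#' Write a two-channel slide table
#'
#' Inverse of [read_slide_table()]: log2 intensities are written back on
#' the raw linear scale.
#'
#' @param slide Log2-scale slide tibble.
#' @param path Output path.
#' @export
write_slide_table <- function(slide, path) {
  assert_columns(slide, slide_columns, "slide")
  out <- slide[slide_columns]
  for (col in setdiff(slide_columns, "feature_id")) {
    out[[col]] <- 2^out[[col]]
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a reporter-to-gene mapping table
#'
#' @param path TSV with columns `reporter_id`, `gene_id`.
#' @return A tibble.
#' @export
read_mapping_table <- function(path) {
  df <- read_tsv_strict(path, "mapping")
  assert_columns(df, c("reporter_id", "gene_id"), sprintf("mapping file %s", path))
  df
}

#' Read a two-column annotation-style table
#'
#' Generic loader for the small TSV inputs: gene-term annotations
#' (`gene_id`, `term_id`), term categories (`term_id`, `category`) and
#' gene chromosomes (`gene_id`, `chromosome`).
#'
#' @param path TSV path.
#' @param columns Required column names.
#' @return A tibble.
#' @export
read_pairs_table <- function(path, columns) {
  df <- read_tsv_strict(path, "table")
  assert_columns(df, columns, sprintf("file %s", path))
  df
}

#' Read a pipeline configuration file
#'
#' A YAML file naming the input files (slides grouped by experiment, the
#' mapping table, ontology, annotation, category and chromosome tables)
#' and any parameter overrides. Every referenced file must exist.
#'
#' @param path YAML path.
#' @return The configuration list with a `base_dir` for relative paths.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  cfg$base_dir <- cfg$base_dir %||% dirname(path)
  refs <- c(unlist(cfg$slides, use.names = FALSE),
            cfg$mapping, cfg$ontology, cfg$annotations,
            cfg$category_map, cfg$chromosome_map)
  refs <- file.path(cfg$base_dir, refs)
  missing <- refs[!file.exists(refs)]
  if (length(missing) > 0) {
    abort(sprintf("config references missing file(s): %s",
                  paste(missing, collapse = ", ")))
  }
  cfg
}

#' Load pipeline inputs from a configuration
#'
#' Materializes the input bundle [run_pipeline()] consumes from the files
#' referenced by a configuration (see [read_pipeline_config()]).
#'
#' @param cfg Configuration list or path to a YAML file.
#' @return A named list with `slides`, `mapping`, `ontology`,
#'   `annotations`, `category_map`, `chromosome_map`.
#' @export
load_pipeline_inputs <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  slides <- purrr::imap(cfg$slides, function(paths, exp) {
    purrr::imap(paths, function(p, i) {
      read_slide_table(file.path(cfg$base_dir, p),
                       experiment_id = exp,
                       replicate_index = as.integer(i))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  list(
    slides = slides,
    mapping = read_mapping_table(file.path(cfg$base_dir, cfg$mapping)),
    ontology = read_obo(file.path(cfg$base_dir, cfg$ontology)),
    annotations = read_pairs_table(file.path(cfg$base_dir, cfg$annotations),
                                   c("gene_id", "term_id")),
    category_map = read_pairs_table(file.path(cfg$base_dir, cfg$category_map),
                                    c("term_id", "category")),
    chromosome_map = read_pairs_table(
      file.path(cfg$base_dir, cfg$chromosome_map),
      c("gene_id", "chromosome"))
  )
}

#' Write a simulated study as pipeline input files
#'
#' Serializes a [simulate_study()] bundle into the on-disk dialect the
#' configuration-driven pipeline consumes: one slide TSV per experiment
#' and replicate (raw linear intensities), the mapping / annotation /
#' category / chromosome tables, a minimal OBO ontology, and a
#' `config.yaml` tying them together. The ground-truth table is written
#' separately (`truth.tsv`) and is never referenced by the configuration,
#' so pipeline stages cannot read it.
#'
#' @param study A [simulate_study()] bundle.
#' @param dir Output directory (created if needed).
#' @return The path of the written `config.yaml`.
#' @export
write_study_inputs <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  slide_files <- list()
  groups <- dplyr::group_split(study$slides,
                               .data$experiment_id, .data$replicate_index)
  for (g in groups) {
    e <- g$experiment_id[1]
    r <- g$replicate_index[1]
    fname <- sprintf("slide_exp%s_rep%d.tsv", e, r)
    write_slide_table(g, file.path(dir, fname))
    slide_files[[e]] <- c(slide_files[[e]], fname)
  }
  readr::write_tsv(study$mapping, file.path(dir, "mapping.tsv"),
                   progress = FALSE)
  readr::write_tsv(study$annotations, file.path(dir, "annotations.tsv"),
                   progress = FALSE)
  readr::write_tsv(study$category_map, file.path(dir, "category_map.tsv"),
                   progress = FALSE)
  readr::write_tsv(study$chromosome_map,
                   file.path(dir, "chromosome_map.tsv"), progress = FALSE)
  readr::write_tsv(study$truth, file.path(dir, "truth.tsv"),
                   progress = FALSE)
  write_obo(study$ontology, file.path(dir, "ontology.obo"))
  cfg <- list(slides = slide_files, mapping = "mapping.tsv",
              ontology = "ontology.obo", annotations = "annotations.tsv",
              category_map = "category_map.tsv",
              chromosome_map = "chromosome_map.tsv")
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  file.path(dir, "config.yaml")
}
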