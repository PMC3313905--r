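# A minimal ontology container: terms, is-a parent links forming a
# single-root DAG, and true-path propagation of gene annotations.

#' Build an ontology from terms and parent links
#'
#' Validates that the is-a graph is acyclic with a single root and
#' precomputes each term's ancestor set.
#'
#' @param terms Tibble with `term_id` and optionally `name`.
#' @param parents Named list: for each term, the character vector of its
#'   parent term ids (empty for the root).
#' @return An object of class `gc_ontology` with elements `terms`,
#'   `parents`, `ancestors` (exclusive of the term itself) and `root`.
#' @export
build_ontology <- function(terms, parents) {
  assert_columns(terms, "term_id", "terms")
  if (!"name" %in% names(terms)) terms$name <- terms$term_id
  ids <- terms$term_id
  if (anyDuplicated(ids)) abort("duplicate term ids.")
  parents <- parents[ids]
  names(parents) <- ids
  parents <- purrr::map(parents, ~ if (is.null(.x)) character(0) else .x)
  unknown <- setdiff(unlist(parents), ids)
  if (length(unknown) > 0) {
    abort(sprintf("parent term(s) not in the term list: %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  roots <- unname(ids[lengths(parents) == 0])
  if (length(roots) != 1) {
    abort(sprintf("the ontology must have exactly one root; found %d (%s).",
                  length(roots), paste(head(roots, 5), collapse = ", ")))
  }
  # Kahn topological sort; leftovers indicate a cycle
  n_par <- lengths(parents)
  children <- split(
    rep(ids, lengths(parents)), unlist(parents))
  order <- character(0)
  queue <- roots
  remaining <- setNames(n_par, ids)
  while (length(queue) > 0) {
    t <- queue[1]
    queue <- queue[-1]
    order <- c(order, t)
    for (ch in children[[t]] %||% character(0)) {
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) != length(ids)) {
    abort("the term graph contains a cycle; an ontology must be acyclic.")
  }
  ancestors <- setNames(vector("list", length(ids)), ids)
  for (t in order) {
    ancestors[[t]] <- unique(c(
      parents[[t]], unlist(ancestors[parents[[t]]], use.names = FALSE)))
  }
  structure(
    list(terms = as_tibble(terms), parents = parents,
         ancestors = ancestors, root = roots),
    class = "gc_ontology"
  )
}

#' @export
print.gc_ontology <- function(x, ...) {
  cat(sprintf("ontology: %d terms, root %s\n", nrow(x$terms), x$root))
  invisible(x)
}

#' Read a minimal OBO file
#'
#' Parses `[Term]` stanzas for `id`, `name` and `is_a` tags only (comments
#' after `!` are stripped; obsolete terms are skipped) and builds a
#' validated ontology.
#'
#' @param path Path to an OBO file.
#' @return A `gc_ontology`.
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  terms <- list()
  cur <- NULL
  flush <- function(cur, terms) {
    if (!is.null(cur) && !isTRUE(cur$obsolete) && !is.null(cur$id)) {
      terms[[cur$id]] <- cur
    }
    terms
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(parents = character(0))
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      terms <- flush(cur, terms)
      cur <- NULL
      in_term <- FALSE
    } else if (in_term && nzchar(ln)) {
      tag <- sub(":.*$", "", ln)
      val <- trimws(sub("^[^:]+:", "", ln))
      val <- trimws(sub("!.*$", "", val))
      if (tag == "id") cur$id <- val
      else if (tag == "name") cur$name <- val
      else if (tag == "is_a") cur$parents <- c(cur$parents, val)
      else if (tag == "is_obsolete" && val == "true") cur$obsolete <- TRUE
    }
  }
  terms <- flush(cur, terms)
  if (length(terms) == 0) abort(sprintf("no [Term] stanzas found in %s.", path))
  build_ontology(
    tibble(term_id = unname(purrr::map_chr(terms, "id")),
           name = unname(purrr::map_chr(terms, ~ .x$name %||% .x$id))),
    purrr::map(terms, "parents")
  )
}

#' True-path propagation of gene annotations
#'
#' Closes a direct gene-term annotation table over the ontology: a gene
#' annotated to a term becomes annotated to every ancestor of that term.
#' The operation is idempotent. Annotations to unknown terms are dropped
#' with a warning.
#'
#' @param ontology A `gc_ontology`.
#' @param annotations Tibble with `gene_id`, `term_id`.
#' @return The closed annotation tibble (distinct gene-term pairs), with
#'   attribute `closed = TRUE`.
#' @export
propagate_annotations <- function(ontology, annotations) {
  stopifnot(inherits(ontology, "gc_ontology"))
  assert_columns(annotations, c("gene_id", "term_id"), "annotations")
  known <- annotations$term_id %in% ontology$terms$term_id
  if (any(!known)) {
    warn(sprintf("propagate_annotations: dropping %d annotation(s) to unknown terms.",
                 sum(!known)))
    annotations <- annotations[known, ]
  }
  closed <- annotations |>
    dplyr::mutate(term_id = purrr::map(.data$term_id, function(t) {
      c(t, ontology$ancestors[[t]])
    })) |>
    tidyr::unnest("term_id") |>
    dplyr::distinct(.data$gene_id, .data$term_id) |>
    dplyr::arrange(.data$gene_id, .data$term_id)
  attr(closed, "closed") <- TRUE
  closed
}

#' Write an ontology as a minimal OBO file
#'
#' Emits `[Term]` stanzas with `id`, `name` and `is_a` tags, the subset
#' [read_obo()] parses.
#'
#' @param ontology A `gc_ontology`.
#' @param path Output path.
#' @export
write_obo <- function(ontology, path) {
  stopifnot(inherits(ontology, "gc_ontology"))
  lines <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(ontology$terms))) {
    id <- ontology$terms$term_id[i]
    pars <- ontology$parents[[id]]
    lines <- c(lines, "[Term]", paste0("id: ", id),
               paste0("name: ", ontology$terms$name[i]),
               if (length(pars) > 0) paste0("is_a: ", pars), "")
  }
  writeLines(lines, path)
  invisible(path)
}
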