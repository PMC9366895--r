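#' Build an annotation corpus from an entity-to-phenotype table
#'
#' An annotation corpus maps entities (genes or diseases) to sets of
#' phenotype classes and carries both the direct assignments and their
#' true-path propagation: the union of ancestor closures of every directly
#' assigned class, expressed in canonical ids so equivalence bridges are
#' honored.
#'
#' Rows whose class id is unknown to the graph are dropped with a warning; if
#' more than `max_unknown_frac` of rows are unknown the corpus is rejected,
#' which guards against annotating against the wrong ontology build.
#'
#' @param x Data frame whose first two columns are `entity_id` and `class_id`
#'   (extra columns ignored).
#' @param graph A [phenont] ontology.
#' @param kind `"gene"` or `"disease"`.
#' @param species Species tag of the annotated entities.
#' @param entities Optional character vector of entity ids that must be
#'   present even with zero annotations (they then have empty sets and score
#'   zero everywhere downstream).
#' @param max_unknown_frac Maximum tolerated fraction of rows with unknown
#'   class ids (default 0.05).
#' @return An `annotation_corpus` object.
#' @export
annotation_corpus <- function(x, graph, kind = c("gene", "disease"),
                              species = "integrated", entities = NULL,
                              max_unknown_frac = 0.05) {
  kind <- match.arg(kind)
  stopifnot(inherits(graph, "phenont"))
  x <- as_tibble(x)
  check_two_cols(x, "annotation table")
  x <- tibble(entity_id = as.character(x[[1L]]), class_id = as.character(x[[2L]]))
  if (nrow(x) == 0L && is.null(entities)) abort("empty annotation table")

  known <- x$class_id %in% names(graph$canonical)
  if (any(!known)) {
    frac <- mean(!known)
    offenders <- unique(x$class_id[!known])
    if (frac > max_unknown_frac) {
      abort(sprintf(
        "%.1f%% of annotation rows reference unknown classes (threshold %.1f%%): %s",
        100 * frac, 100 * max_unknown_frac,
        paste(head(offenders, 10L), collapse = ", ")))
    }
    warn(sprintf("dropped %d annotation row(s) with unknown class id(s): %s",
                 sum(!known), paste(head(offenders, 5L), collapse = ", ")))
    x <- x[known, ]
  }
  x <- distinct(x)

  direct <- lapply(split(x$class_id, x$entity_id), unique)
  if (!is.null(entities)) {
    missing <- setdiff(entities, names(direct))
    direct <- c(direct, setNames(replicate(length(missing), character(0L),
                                           simplify = FALSE), missing))
  }
  direct <- direct[order(names(direct))]
  anc <- ancestor_sets(graph)
  direct_canonical <- lapply(direct, function(cls) {
    if (!length(cls)) character(0L) else
      sort(unique(unname(graph$canonical[cls])))
  })
  propagated <- lapply(direct_canonical, function(cls) {
    if (!length(cls)) return(character(0L))
    sort(unique(unlist(anc[cls], use.names = FALSE)))
  })
  structure(list(kind = kind, species = species,
                 direct = direct, direct_canonical = direct_canonical,
                 propagated = propagated),
            class = "annotation_corpus")
}

#' Read an annotation corpus from a TSV file
#'
#' Two-column TSV (`entity_id`, `class_id`), no header by default; gzip input
#' is accepted transparently.
#'
#' @inheritParams annotation_corpus
#' @param path TSV path (optionally gzipped).
#' @param header Whether the file has a header row.
#' @return An `annotation_corpus`.
#' @export
read_annotations <- function(path, graph, kind = c("gene", "disease"),
                             species = "integrated", header = FALSE,
                             entities = NULL, max_unknown_frac = 0.05) {
  x <- readr::read_tsv(path, col_names = header, show_col_types = FALSE,
                       progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  if (nrow(x) == 0L) abort(sprintf("empty annotation file: %s", path))
  annotation_corpus(x, graph, kind = kind, species = species,
                    entities = entities, max_unknown_frac = max_unknown_frac)
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat(sprintf("<annotation_corpus> %s/%s: %d entities, %d direct annotations\n",
              x$kind, x$species, length(x$direct),
              sum(lengths(x$direct))))
  invisible(x)
}

#' @export
tidy.annotation_corpus <- function(x, ...) {
  tibble(entity_id = rep(names(x$direct), lengths(x$direct)),
         class_id = unlist(x$direct, use.names = FALSE))
}

#' @export
glance.annotation_corpus <- function(x, ...) {
  tibble(kind = x$kind, species = x$species,
         n_entities = length(x$direct),
         n_direct = sum(lengths(x$direct)),
         n_propagated = sum(lengths(x$propagated)))
}

corpus_entities <- function(corpus) names(corpus$direct)

#' Read an orthology map
#'
#' Two-column TSV of orthologous gene id pairs; duplicates removed.
#'
#' @param path TSV path.
#' @param header Whether the file has a header row.
#' @return A tibble with columns `gene_a`, `gene_b`.
#' @export
read_orthology <- function(path, header = FALSE) {
  x <- readr::read_tsv(path, col_names = header, show_col_types = FALSE,
                       progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  check_two_cols(x, "orthology table")
  distinct(tibble(gene_a = as.character(x[[1L]]), gene_b = as.character(x[[2L]])))
}

#' Read gene-disease associations
#'
#' @param path Two-column TSV (`gene_id`, `disease_id`).
#' @param header Whether the file has a header row.
#' @return A tibble with columns `gene_id`, `disease_id`.
#' @export
read_gene_disease <- function(path, header = FALSE) {
  x <- readr::read_tsv(path, col_names = header, show_col_types = FALSE,
                       progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  check_two_cols(x, "association table")
  distinct(tibble(gene_id = as.character(x[[1L]]), disease_id = as.character(x[[2L]])))
}

#' Pool phenotype annotations across organisms via orthology
#'
#' For each gene of the anchor species, unions its phenotype sets with those
#' of all its orthologs in the other corpora (all orthologs are used when the
#' mapping is not one-to-one, which maximizes phenotype coverage). Genes
#' without orthologs keep their own annotations. All corpora must be gene
#' corpora over one integrated ontology.
#'
#' @param corpora List of gene `annotation_corpus` objects; exactly one must
#'   carry `anchor_species`.
#' @param orthology A tibble (or list of tibbles, parallel to the non-anchor
#'   corpora) with columns `gene_a` (anchor gene id) and `gene_b` (other
#'   species' gene id), as from [read_orthology()].
#' @param anchor_species Species tag of the corpus whose gene ids key the
#'   result.
#' @return An `annotation_corpus` keyed by anchor-species gene ids.
#' @export
combine_organism_annotations <- function(corpora, orthology, anchor_species) {
  stopifnot(is.list(corpora), all(vapply(corpora, inherits, logical(1L),
                                         "annotation_corpus")))
  species <- vapply(corpora, function(x) x$species, character(1L))
  if (!anchor_species %in% species) {
    abort(sprintf("anchor species '%s' absent from corpora (%s)",
                  anchor_species, paste(species, collapse = ", ")))
  }
  anchor <- corpora[[match(anchor_species, species)]]
  others <- corpora[species != anchor_species]
  if (inherits(orthology, "data.frame")) orthology <- list(orthology)
  if (length(others) && length(orthology) != length(others)) {
    abort("need one orthology map per non-anchor corpus")
  }

  direct <- anchor$direct
  direct_canonical <- anchor$direct_canonical
  propagated <- anchor$propagated
  for (i in seq_along(others)) {
    oc <- others[[i]]
    om <- orthology[[i]]
    hits <- om[om$gene_a %in% names(direct) & om$gene_b %in% names(oc$direct), ]
    for (j in seq_len(nrow(hits))) {
      a <- hits$gene_a[[j]]; b <- hits$gene_b[[j]]
      direct[[a]] <- unique(c(direct[[a]], oc$direct[[b]]))
      direct_canonical[[a]] <- sort(unique(c(direct_canonical[[a]],
                                             oc$direct_canonical[[b]])))
      propagated[[a]] <- sort(unique(c(propagated[[a]], oc$propagated[[b]])))
    }
  }
  structure(list(kind = "gene", species = anchor_species,
                 direct = direct, direct_canonical = direct_canonical,
                 propagated = propagated),
            class = "annotation_corpus")
}
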