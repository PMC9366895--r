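#' Read an ontology from an OBO flat file (subset)
#'
#' Parses the OBO 1.2 subset the pipeline consumes: `[Term]` stanzas with
#' `id`, `name`, `is_a`, `relationship` and `equivalent_to` tags. Trailing
#' `! comment` text after ids is stripped. `equivalent_to` is not part of
#' standard OBO 1.2; it is the dialect tag this package writes for
#' cross-species equivalence bridges. Paired reciprocal `is_a` assertions
#' (`X is_a Y` together with `Y is_a X`) are accepted as a fallback
#' equivalence encoding and converted to an equivalence pair.
#'
#' @param path Path to an OBO file.
#' @param species_map Named character vector mapping CURIE prefixes to species
#'   tags (e.g. `c(HP = "human", MP = "mouse")`). Prefixes not mapped get
#'   `default_species`.
#' @param default_species Species tag for unmapped prefixes.
#' @return A [phenont] ontology.
#' @export
parse_obo <- function(path, species_map = NULL, default_species = "integrated") {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  term_starts <- which(lines == "[Term]")
  if (!length(term_starts)) abort("no [Term] stanzas found")
  other_starts <- which(grepl("^\\[", lines) & lines != "[Term]")
  bounds <- sort(c(term_starts, other_starts, length(lines) + 1L))

  strip <- function(x) sub("\\s*(!.*)?$", "", x)
  tag_val <- function(stanza, tag) {
    hits <- grep(sprintf("^%s:", tag), stanza, value = TRUE)
    strip(sub(sprintf("^%s:\\s*", tag), "", hits))
  }

  ids <- character(0L); labels <- character(0L)
  sub_child <- character(0L); sub_parent <- character(0L)
  rel_s <- character(0L); rel_r <- character(0L); rel_o <- character(0L)
  eq_a <- character(0L); eq_b <- character(0L)

  for (s in term_starts) {
    end <- min(bounds[bounds > s]) - 1L
    stanza <- lines[(s + 1L):end]
    id <- tag_val(stanza, "id")
    if (length(id) != 1L || !nzchar(id)) abort("stanza without a single id tag")
    if (id %in% ids) abort(sprintf("duplicate class id: %s", id))
    nm <- tag_val(stanza, "name")
    ids <- c(ids, id)
    labels <- c(labels, if (length(nm)) nm[[1L]] else id)
    for (p in tag_val(stanza, "is_a")) {
      sub_child <- c(sub_child, id); sub_parent <- c(sub_parent, p)
    }
    for (e in tag_val(stanza, "equivalent_to")) {
      eq_a <- c(eq_a, id); eq_b <- c(eq_b, e)
    }
    for (r in tag_val(stanza, "relationship")) {
      parts <- strsplit(trimws(r), "\\s+")[[1L]]
      if (length(parts) != 2L) abort(sprintf("malformed relationship line in %s: %s", id, r))
      rel_s <- c(rel_s, id); rel_r <- c(rel_r, parts[[1L]]); rel_o <- c(rel_o, parts[[2L]])
    }
  }

  unknown <- setdiff(c(sub_parent, rel_o, eq_b), ids)
  if (length(unknown)) {
    abort(sprintf("is_a/relationship/equivalent_to references unknown id(s): %s",
                  paste(head(unknown, 10L), collapse = ", ")))
  }

  # reciprocal is_a fallback: X is_a Y and Y is_a X encode an equivalence
  key <- paste(sub_child, sub_parent)
  rev_key <- paste(sub_parent, sub_child)
  recip <- key %in% rev_key
  if (any(recip)) {
    first_dir <- recip & sub_child < sub_parent
    eq_a <- c(eq_a, sub_child[first_dir]); eq_b <- c(eq_b, sub_parent[first_dir])
    sub_child <- sub_child[!recip]; sub_parent <- sub_parent[!recip]
  }

  prefixes <- curie_prefix(ids)
  species <- rep(default_species, length(ids))
  if (!is.null(species_map)) {
    hit <- prefixes %in% names(species_map)
    species[hit] <- unname(species_map[prefixes[hit]])
  }

  phenont(
    classes = tibble(id = ids, label = labels, species = species),
    subclass_edges = tibble(child = sub_child, parent = sub_parent),
    relation_edges = tibble(subject = rel_s, relation = rel_r, object = rel_o),
    equivalence_pairs = if (length(eq_a)) tibble(a = eq_a, b = eq_b) else NULL)
}

#' Write an ontology to the OBO flat-file subset
#'
#' Serializes a [phenont] so that `parse_obo(write_obo(g, f))` reconstructs an
#' isomorphic graph (class set, subclass and relation edges, and equivalence
#' structure are preserved; species tags travel separately via `species_map`).
#'
#' @param graph A [phenont] ontology.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(graph, path) {
  stopifnot(inherits(graph, "phenont"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  sub_by <- split(graph$subclass_edges$parent, graph$subclass_edges$child)
  rel_by <- split(paste(graph$relation_edges$relation, graph$relation_edges$object),
                  graph$relation_edges$subject)
  eq_by <- split(graph$equivalence_pairs$b, graph$equivalence_pairs$a)
  for (i in seq_len(nrow(graph$classes))) {
    id <- graph$classes$id[[i]]
    out <- c("[Term]",
             sprintf("id: %s", id),
             sprintf("name: %s", graph$classes$label[[i]]),
             sprintf("is_a: %s", sort(sub_by[[id]] %||% character(0L))),
             sprintf("relationship: %s", sort(rel_by[[id]] %||% character(0L))),
             sprintf("equivalent_to: %s", sort(eq_by[[id]] %||% character(0L))),
             "")
    writeLines(out, con)
  }
  invisible(path)
}

#' Export the ontology edge list as TSV
#'
#' Debugging export: one row per edge, columns `child`, `relation`, `parent`.
#'
#' @param graph A [phenont] ontology.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  readr::write_tsv(tidy(graph), path)
  invisible(path)
}
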