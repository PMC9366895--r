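#' Construct an integrated phenotype ontology graph
#'
#' `phenont()` builds the package's central data structure: a directed acyclic
#' multigraph of phenotype classes carrying subclass (`is_a`) edges, labeled
#' relation edges (`part-of`, `results-from`, ...), and equivalence sets that
#' bridge species-specific vocabularies (e.g. declaring the fly and zebrafish
#' nervous systems interchangeable). Equivalent classes are merged onto a
#' canonical representative (the lexicographically smallest member id), so
#' ancestor queries and most-informative-common-ancestor lookups are well
#' defined across species.
#'
#' Only the subclass hierarchy (after canonicalization) participates in
#' ancestor closure; relation edges are retained for export to the embedding
#' graphs but never contribute to subsumption.
#'
#' @param classes Data frame with columns `id`, `label`, `species` (one of
#'   `"human"`, `"mouse"`, `"fish"`, `"fly"`, `"yeast"`, `"integrated"`).
#'   Optional columns `entity` and `quality` record the abnormality design
#'   pattern for classes constructed with [add_phenotype_class()].
#' @param subclass_edges Data frame with columns `child`, `parent`.
#' @param relation_edges Data frame with columns `subject`, `relation`,
#'   `object`; may be empty.
#' @param equivalence_pairs Data frame with columns `a`, `b`; each row declares
#'   two class ids equivalent. Pairs are closed into disjoint sets.
#' @return An object of class `phenont`.
#' @export
phenont <- function(classes,
                    subclass_edges = NULL,
                    relation_edges = NULL,
                    equivalence_pairs = NULL) {
  classes <- as_tibble(classes)
  if (!all(c("id", "label", "species") %in% names(classes))) {
    abort("`classes` needs columns id, label, species")
  }
  if (!"entity" %in% names(classes)) classes$entity <- NA_character_
  if (!"quality" %in% names(classes)) classes$quality <- NA_character_
  classes <- classes[, c("id", "label", "species", "entity", "quality")]
  dup <- classes$id[duplicated(classes$id)]
  if (length(dup)) {
    abort(sprintf("duplicate class id(s): %s", paste(unique(dup), collapse = ", ")))
  }
  bad_sp <- setdiff(unique(classes$species), ontology_species())
  if (length(bad_sp)) {
    abort(sprintf("unknown species tag(s): %s", paste(bad_sp, collapse = ", ")))
  }

  empty_edges <- tibble(child = character(), parent = character())
  subclass_edges <- if (is.null(subclass_edges)) empty_edges else
    distinct(as_tibble(subclass_edges)[, c("child", "parent")])
  relation_edges <- if (is.null(relation_edges))
    tibble(subject = character(), relation = character(), object = character()) else
    distinct(as_tibble(relation_edges)[, c("subject", "relation", "object")])
  equivalence_pairs <- if (is.null(equivalence_pairs))
    tibble(a = character(), b = character()) else
    distinct(as_tibble(equivalence_pairs)[, c("a", "b")])

  known <- classes$id
  refd <- c(subclass_edges$child, subclass_edges$parent,
            relation_edges$subject, relation_edges$object,
            equivalence_pairs$a, equivalence_pairs$b)
  unknown <- setdiff(refd, known)
  if (length(unknown)) {
    abort(sprintf("edge references unknown class id(s): %s",
                  paste(head(unknown, 10L), collapse = ", ")))
  }

  canonical <- canonicalize_ids(known, equivalence_pairs)
  g <- structure(
    list(classes = classes,
         subclass_edges = subclass_edges,
         relation_edges = relation_edges,
         equivalence_pairs = equivalence_pairs,
         canonical = canonical,
         cache = new.env(parent = emptyenv())),
    class = "phenont")
  # forces a topological order; errors with an explicit cycle if there is one
  canonical_topo_order(g)
  g
}

ontology_species <- function() {
  c("human", "mouse", "fish", "fly", "yeast", "integrated")
}

# union-find over equivalence pairs; canonical representative is the
# lexicographically smallest member of each set
canonicalize_ids <- function(ids, pairs) {
  parent <- setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs$a[[i]])
      rb <- find(pairs$b[[i]])
      if (ra != rb) parent[[max(ra, rb)]] <- min(ra, rb)
    }
  }
  vapply(ids, find, character(1L))
}

#' @export
print.phenont <- function(x, ...) {
  n_eq <- sum(table(x$canonical) > 1L)
  cat(sprintf(
    "<phenont> %d classes (%d canonical), %d subclass edges, %d relation edges, %d equivalence sets\n",
    nrow(x$classes), length(unique(x$canonical)),
    nrow(x$subclass_edges), nrow(x$relation_edges), n_eq))
  sp <- table(x$classes$species)
  cat("  species:", paste(sprintf("%s=%d", names(sp), sp), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as_tibble.phenont <- function(x, ...) x$classes

#' Tidy an ontology graph into its subclass edge list
#'
#' Returns one row per subclass edge with the species of either end, the
#' format also used by the TSV edge-list export.
#'
#' @param x A `phenont` object.
#' @param ... Unused.
#' @return A tibble with columns `child`, `relation`, `parent`.
#' @export
tidy.phenont <- function(x, ...) {
  bind_rows(
    tibble(child = x$subclass_edges$child, relation = "is_a",
           parent = x$subclass_edges$parent),
    tibble(child = x$relation_edges$subject, relation = x$relation_edges$relation,
           parent = x$relation_edges$object),
    tibble(child = x$equivalence_pairs$a, relation = "equivalent_to",
           parent = x$equivalence_pairs$b))
}

canonical_of <- function(graph, ids) {
  unknown <- setdiff(ids, names(graph$canonical))
  if (length(unknown)) {
    abort(sprintf("unknown class id(s): %s", paste(head(unknown, 10L), collapse = ", ")))
  }
  unname(graph$canonical[ids])
}

# canonical subclass edge list with self-loops (from merged trivial edges) removed
canonical_edges <- function(graph) {
  ch <- unname(graph$canonical[graph$subclass_edges$child])
  pa <- unname(graph$canonical[graph$subclass_edges$parent])
  keep <- ch != pa
  distinct(tibble(child = ch[keep], parent = pa[keep]))
}

# Kahn topological order over the canonical DAG (parents before children);
# errors listing one explicit cycle when the subclass relation is not acyclic
canonical_topo_order <- function(graph) {
  if (!is.null(graph$cache$topo)) return(graph$cache$topo)
  nodes <- unique(unname(graph$canonical))
  ed <- canonical_edges(graph)
  idx <- setNames(seq_along(nodes), nodes)
  n <- length(nodes)
  parents_of <- split(idx[ed$parent], idx[ed$child])   # child -> its parents
  children_of <- split(idx[ed$child], idx[ed$parent])  # parent -> its children
  unprocessed_parents <- integer(n)
  tab <- table(idx[ed$child])
  unprocessed_parents[as.integer(names(tab))] <- as.integer(tab)
  queue <- which(unprocessed_parents == 0L)
  order <- integer(0L)
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    order <- c(order, v)
    for (c in children_of[[as.character(v)]] %||% integer(0L)) {
      unprocessed_parents[c] <- unprocessed_parents[c] - 1L
      if (unprocessed_parents[c] == 0L) queue <- c(queue, c)
    }
  }
  if (length(order) < n) {
    left <- setdiff(seq_len(n), order)
    cyc <- find_cycle(nodes, parents_of, left)
    abort(sprintf("subclass relation contains a cycle: %s",
                  paste(cyc, collapse = " -> ")))
  }
  graph$cache$topo <- nodes[order]
  graph$cache$topo
}

find_cycle <- function(nodes, parents_of, left) {
  start <- left[[1L]]
  seen <- integer(0L)
  v <- start
  repeat {
    seen <- c(seen, v)
    nxt <- intersect(parents_of[[as.character(v)]] %||% integer(0L), left)
    v <- nxt[[1L]]
    if (v %in% seen) {
      cyc <- c(seen[which(seen == v):length(seen)], v)
      return(nodes[cyc])
    }
  }
}

# all-ancestor closure (reflexive, transitive) per canonical id; memoised
ancestor_sets <- function(graph) {
  if (!is.null(graph$cache$anc)) return(graph$cache$anc)
  topo <- canonical_topo_order(graph)
  ed <- canonical_edges(graph)
  parents_of <- split(ed$parent, ed$child)
  anc <- vector("list", length(topo))
  names(anc) <- topo
  for (v in topo) {
    ps <- parents_of[[v]]
    anc[[v]] <- if (is.null(ps)) v else
      unique(c(v, unlist(anc[ps], use.names = FALSE)))
  }
  graph$cache$anc <- anc
  anc
}

#' Ancestor closure of a phenotype class
#'
#' Returns the reflexive-transitive superclass closure of a class over the
#' canonicalized subclass hierarchy. Equivalence is honored: all members of an
#' equivalence set share one ancestor set, expressed in canonical ids.
#'
#' @param graph A [phenont] ontology.
#' @param class_id A class id known to the graph (any member of an
#'   equivalence set may be given).
#' @return Character vector of canonical ancestor ids, including the class's
#'   own canonical id.
#' @examples
#' g <- phenont(
#'   classes = tibble::tibble(id = c("R:1", "A:1"), label = c("root", "a"),
#'                            species = "integrated"),
#'   subclass_edges = tibble::tibble(child = "A:1", parent = "R:1"))
#' ancestors(g, "A:1")
#' @export
ancestors <- function(graph, class_id) {
  stopifnot(inherits(graph, "phenont"), length(class_id) == 1L)
  can <- canonical_of(graph, class_id)
  sort(ancestor_sets(graph)[[can]])
}

# species tags attached to each canonical id (a merged class carries every
# member's tag)
canonical_species_map <- function(graph) {
  if (!is.null(graph$cache$can_sp)) return(graph$cache$can_sp)
  can <- unname(graph$canonical[graph$classes$id])
  graph$cache$can_sp <- split(graph$classes$species, can)
  graph$cache$can_sp
}

#' Count direct and inferred cross-species subsumptions
#'
#' For two species tags, counts ordered pairs of classes `(sub, super)` where
#' `sub` carries one tag, `super` the other, and `super` lies in the ancestor
#' closure of `sub`. Pairs connected by an asserted subclass edge (after
#' canonical merging) are `direct`; the remainder — those only derivable
#' through the closure, including via equivalence bridges — are `inferred`.
#'
#' @param graph A [phenont] ontology.
#' @param species_a,species_b Species tags present in the graph.
#' @return A tibble with one row per direction (`species_sub` is the species
#'   of the subclass end) and columns `direct`, `inferred`, `total`.
#' @export
cross_species_subsumption_counts <- function(graph, species_a, species_b) {
  stopifnot(inherits(graph, "phenont"))
  for (sp in c(species_a, species_b)) {
    if (!sp %in% ontology_species()) abort(sprintf("unknown species tag: %s", sp))
  }
  anc <- ancestor_sets(graph)
  ed <- canonical_edges(graph)
  direct_key <- paste(ed$child, ed$parent)
  ids_of <- function(sp) graph$classes$id[graph$classes$species == sp]

  count_dir <- function(sp_sub, sp_super) {
    subs <- ids_of(sp_sub)
    supers <- ids_of(sp_super)
    super_can <- unname(graph$canonical[supers])
    n_direct <- 0L; n_total <- 0L
    for (s in subs) {
      cs <- unname(graph$canonical[[s]])
      hits <- supers[super_can %in% anc[[cs]] & supers != s]
      n_total <- n_total + length(hits)
      if (length(hits)) {
        n_direct <- n_direct +
          sum(paste(cs, unname(graph$canonical[hits])) %in% direct_key)
      }
    }
    tibble(species_sub = sp_sub, species_super = sp_super,
           direct = n_direct, inferred = n_total - n_direct, total = n_total)
  }
  bind_rows(count_dir(species_a, species_b), count_dir(species_b, species_a))
}

#' Deterministic id of the abnormality class derived from an entity
#'
#' Anatomy-derived phenotype classes follow the pattern
#' `<PREFIX>AB:<local id>`, mirroring how abnormal-anatomy classes are minted
#' from an anatomy vocabulary (e.g. a fly `wing` class yields
#' `FBbtAB:<wing local id>` labeled "phenotypic abnormality of wing").
#'
#' @param entity_id The anatomy/process class id the abnormality is about.
#' @return The derived class id (a string).
#' @export
abnormality_class_id <- function(entity_id) {
  sprintf("%sAB:%s", curie_prefix(entity_id), curie_local(entity_id))
}

abnormality_root_id <- function(prefix) sprintf("%sAB:ROOT", prefix)

#' Mint an abnormality phenotype class from an entity
#'
#' Implements the anatomical-abnormality design pattern: given an entity class
#' (anatomy or process), adds a new phenotype class "phenotypic abnormality of
#' <entity>" with a structural definition pattern `(entity, quality,
#' Abnormal)`. The new class is placed under the abnormality classes of the
#' entity's direct parents when those exist, otherwise directly under the
#' species' abnormality root (created on demand). Re-invocation with the same
#' entity is a no-op, so minting is idempotent.
#'
#' @param graph A [phenont] ontology containing `entity_id`.
#' @param entity_id Class id of the underlying entity.
#' @param species Species tag for the new phenotype class.
#' @param quality Quality class id; defaults to the generic `"Quality"`.
#' @return The updated `phenont`; the new class id is
#'   `abnormality_class_id(entity_id)`.
#' @export
add_phenotype_class <- function(graph, entity_id, species, quality = "Quality") {
  stopifnot(inherits(graph, "phenont"))
  if (!entity_id %in% graph$classes$id) {
    abort(sprintf("unknown entity id: %s", entity_id))
  }
  new_id <- abnormality_class_id(entity_id)
  if (new_id %in% graph$classes$id) return(graph)

  prefix <- curie_prefix(entity_id)
  root_id <- abnormality_root_id(prefix)
  classes <- graph$classes
  sub <- graph$subclass_edges
  if (!root_id %in% classes$id) {
    classes <- bind_rows(classes, tibble(
      id = root_id, label = "phenotypic abnormality of organism",
      species = species, entity = NA_character_, quality = NA_character_))
  }
  ent_label <- classes$label[classes$id == entity_id][[1L]]
  classes <- bind_rows(classes, tibble(
    id = new_id, label = sprintf("phenotypic abnormality of %s", ent_label),
    species = species, entity = entity_id, quality = quality))

  parent_entities <- sub$parent[sub$child == entity_id]
  parent_ab <- abnormality_class_id(parent_entities)
  parent_ab <- parent_ab[parent_ab %in% classes$id]
  parents <- if (length(parent_ab)) parent_ab else root_id
  sub <- bind_rows(sub, tibble(child = new_id, parent = parents))
  phenont(classes, sub, graph$relation_edges, graph$equivalence_pairs)
}
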