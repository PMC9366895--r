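#' Information content of phenotype classes from annotation corpora
#'
#' The probability of a class is its propagated annotation frequency: the
#' number of entities whose propagated (true-path closed) annotation set
#' contains the class, divided by the total number of entities across the
#' supplied corpora (each entity counted once). Information content is
#' \eqn{-\log_2 p(c)} in bits: a class annotating every entity has IC 0, and
#' rarer (deeper) classes have higher IC. Classes with zero annotation
#' frequency do not appear in the table and are excluded from
#' most-informative-common-ancestor candidacy downstream.
#'
#' For cross-species similarity the corpora should jointly cover both sides
#' being compared (model-organism genes and human diseases), so shared
#' ancestors bridging species get a nonzero frequency from both sides.
#'
#' @param corpora A single `annotation_corpus` or list of them, over one
#'   integrated ontology.
#' @param corpus_id Provenance string stored on the table.
#' @return An `ic_table`: a tibble with columns `class_id` (canonical),
#'   `n_entities`, `p`, `ic`, plus attributes `total_entities` and
#'   `corpus_id`.
#' @export
compute_ic <- function(corpora, corpus_id = "corpus") {
  if (inherits(corpora, "annotation_corpus")) corpora <- list(corpora)
  if (!length(corpora)) abort("empty corpus list")
  stopifnot(all(vapply(corpora, inherits, logical(1L), "annotation_corpus")))

  sets <- list()
  for (co in corpora) {
    keys <- sprintf("%s/%s/%s", co$kind, co$species, names(co$propagated))
    for (i in seq_along(keys)) {
      k <- keys[[i]]
      sets[[k]] <- unique(c(sets[[k]], co$propagated[[i]]))
    }
  }
  total <- length(sets)
  if (total == 0L) abort("corpora contain no entities")
  counts <- table(unlist(sets, use.names = FALSE))
  out <- tibble(class_id = names(counts),
                n_entities = as.integer(counts)) |>
    mutate(p = .data$n_entities / total, ic = -log2(.data$p)) |>
    arrange(.data$class_id)
  structure(out, total_entities = total, corpus_id = corpus_id,
            class = c("ic_table", class(out)))
}

ic_vector <- function(ic) {
  stopifnot(inherits(ic, "ic_table"))
  setNames(ic$ic, ic$class_id)
}

#' Resnik similarity of two phenotype classes
#'
#' The information content of the most informative common ancestor (MICA):
#' the maximum IC over the intersection of the two classes' ancestor
#' closures, restricted to classes present in the IC table. Returns 0 when
#' the classes share only zero-frequency ancestors.
#'
#' @param ic An [compute_ic()] table.
#' @param graph A [phenont] ontology.
#' @param c1,c2 Class ids known to the graph.
#' @return A non-negative number (bits).
#' @export
resnik_pair <- function(ic, graph, c1, c2) {
  common <- intersect(ancestors(graph, c1), ancestors(graph, c2))
  vals <- ic_vector(ic)[common]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) 0 else max(vals)
}

#' Best-match-average similarity of two phenotype sets
#'
#' Symmetric best match average: each class in one set is matched to its
#' best Resnik partner in the other set; the two directional means are
#' averaged. Either set being empty yields 0 with a warning (an entity
#' without informative phenotypes).
#'
#' @param set_a,set_b Character vectors of class ids (direct annotation
#'   sets; ancestor information enters through the Resnik term).
#' @inheritParams resnik_pair
#' @return A non-negative number (bits).
#' @export
bma_similarity <- function(set_a, set_b, ic, graph) {
  if (!length(set_a) || !length(set_b)) {
    warn("empty phenotype set in best-match-average; similarity is 0")
    return(0)
  }
  m <- matrix(0, length(set_a), length(set_b))
  for (i in seq_along(set_a)) {
    for (j in seq_along(set_b)) {
      m[i, j] <- resnik_pair(ic, graph, set_a[[i]], set_b[[j]])
    }
  }
  0.5 * (mean(apply(m, 1L, max)) + mean(apply(m, 2L, max)))
}

new_similarity_matrix <- function(values, method) {
  structure(values, method = method, class = c("similarity_matrix", class(values)))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> method=%s: %d genes x %d diseases\n",
              attr(x, "method"), nrow(x), ncol(x)))
  invisible(x)
}

#' Tidy a similarity matrix into long form
#'
#' @param x A `similarity_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `disease_id`, `score`, `method`.
#' @export
tidy.similarity_matrix <- function(x, ...) {
  tibble(gene_id = rep(rownames(x), times = ncol(x)),
         disease_id = rep(colnames(x), each = nrow(x)),
         score = as.vector(unclass(x)),
         method = attr(x, "method"))
}

#' Gene-by-disease Resnik best-match-average similarity matrix
#'
#' Scores every gene against every disease by the best-match-average of
#' Resnik similarities between their direct annotation sets. Entities with
#' no annotations receive 0 against everything.
#'
#' @param gene_corpus,disease_corpus `annotation_corpus` objects over
#'   `graph`.
#' @inheritParams resnik_pair
#' @return A `similarity_matrix` (genes in rows, diseases in columns) with
#'   method `"resnik_bma"`.
#' @export
similarity_matrix_resnik <- function(gene_corpus, disease_corpus, ic, graph) {
  stopifnot(inherits(gene_corpus, "annotation_corpus"),
            inherits(disease_corpus, "annotation_corpus"),
            inherits(ic, "ic_table"), inherits(graph, "phenont"))
  gsets <- lapply(gene_corpus$direct, function(x)
    unique(unname(graph$canonical[x])))
  dsets <- lapply(disease_corpus$direct, function(x)
    unique(unname(graph$canonical[x])))
  ug <- sort(unique(unlist(gsets, use.names = FALSE)))
  ud <- sort(unique(unlist(dsets, use.names = FALSE)))

  anc <- ancestor_sets(graph)
  anc_idx <- function(cls) {
    lapply(cls, function(cc) {
      ix <- match(anc[[cc]], ic$class_id)
      as.integer(ix[!is.na(ix)])
    })
  }
  R <- resnik_class_matrix(anc_idx(ug), anc_idx(ud), ic$ic)
  g_idx <- lapply(gsets, function(x) match(x, ug))
  d_idx <- lapply(dsets, function(x) match(x, ud))
  vals <- bma_from_class_matrix(g_idx, d_idx, R)
  rownames(vals) <- names(gsets)
  colnames(vals) <- names(dsets)
  new_similarity_matrix(vals, "resnik_bma")
}
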