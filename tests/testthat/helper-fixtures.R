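# Shared fixtures: a tiny two-species ontology with one equivalence bridge,
# random DAG generators with brute-force oracles, and a separable embedding
# construction for the supervised model.

# Root R; human A with child A1, human B; mouse A' (equivalent to A) with
# child A1'. Annotating e1..e4 with {A1, A1', A, B} gives p(A) = 3/4 and
# p(A1) = p(A1') = p(B) = 1/4.
toy_graph <- function() {
  phenont(
    classes = tibble::tibble(
      id = c("ROOT:1", "HP:0000001", "HP:0000002", "HP:0000003",
             "MP:0000001", "MP:0000002"),
      label = c("root", "A", "A1", "B", "A prime", "A1 prime"),
      species = c("integrated", "human", "human", "human", "mouse", "mouse")),
    subclass_edges = tibble::tibble(
      child = c("HP:0000001", "HP:0000002", "HP:0000003",
                "MP:0000001", "MP:0000002"),
      parent = c("ROOT:1", "HP:0000001", "ROOT:1", "ROOT:1", "MP:0000001")),
    equivalence_pairs = tibble::tibble(a = "MP:0000001", b = "HP:0000001"))
}

toy_corpus <- function(graph = toy_graph()) {
  annotation_corpus(
    tibble::tibble(entity_id = c("e1", "e2", "e3", "e4"),
                   class_id = c("HP:0000002", "MP:0000002",
                                "HP:0000001", "HP:0000003")),
    graph)
}

# random DAG over n nodes: node i gets one parent among 1..i-1 plus extra
# forward edges, optionally a few equivalence merges between non-adjacent nodes
random_dag <- function(n, seed, p_extra = 0.08, n_equiv = 0L) {
  withr::with_seed(seed, {
    ids <- sprintf("N:%03d", seq_len(n))
    parent <- c(NA, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1L)))
    edges <- tibble::tibble(child = ids[-1L], parent = ids[parent[-1L]])
    for (i in 3:n) {
      extra <- which(runif(i - 1L) < p_extra)
      extra <- setdiff(extra, parent[i])
      if (length(extra)) {
        edges <- rbind(edges, tibble::tibble(child = ids[i], parent = ids[extra]))
      }
    }
    eq <- NULL
    if (n_equiv > 0L) {
      # merge sibling-ish pairs: pick pairs where neither reaches the other
      reach <- brute_closure(ids, edges)
      cand <- list()
      for (k in seq_len(50L)) {
        ab <- sample(ids, 2L)
        if (!(ab[2L] %in% reach[[ab[1L]]]) && !(ab[1L] %in% reach[[ab[2L]]])) {
          cand[[length(cand) + 1L]] <- ab
          if (length(cand) >= n_equiv) break
        }
      }
      if (length(cand)) {
        eq <- tibble::tibble(a = vapply(cand, `[`, character(1L), 1L),
                             b = vapply(cand, `[`, character(1L), 2L))
      }
    }
    g <- try(phenont(tibble::tibble(id = ids, label = ids, species = "integrated"),
                     edges, equivalence_pairs = eq), silent = TRUE)
    if (inherits(g, "try-error")) {
      # an equivalence merge may induce a cycle; retry without merges
      g <- phenont(tibble::tibble(id = ids, label = ids, species = "integrated"),
                   edges)
    }
    g
  })
}

# independent reachability oracle: repeated one-step expansion over an edge
# table, no use of the package's closure code
brute_closure <- function(ids, edges) {
  parents_of <- split(edges$parent, edges$child)
  out <- list()
  for (id in ids) {
    acc <- id
    repeat {
      nxt <- unique(c(acc, unlist(parents_of[acc], use.names = FALSE)))
      if (length(nxt) == length(acc)) break
      acc <- nxt
    }
    out[[id]] <- sort(acc)
  }
  out
}

# the same oracle on the canonicalized graph of a phenont
brute_canonical_closure <- function(graph) {
  ed <- dplyr::distinct(tibble::tibble(
    child = unname(graph$canonical[graph$subclass_edges$child]),
    parent = unname(graph$canonical[graph$subclass_edges$parent])))
  ed <- ed[ed$child != ed$parent, ]
  brute_closure(unique(unname(graph$canonical)), ed)
}

# brute-force Resnik: enumerate both ancestor closures, intersect, max IC
brute_resnik <- function(ic, graph, c1, c2) {
  clo <- brute_canonical_closure(graph)
  common <- intersect(clo[[unname(graph$canonical[c1])]],
                      clo[[unname(graph$canonical[c2])]])
  vals <- ic$ic[match(common, ic$class_id)]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) 0 else max(vals)
}

# separable supervised fixture: disease vector = its gene's vector plus a
# constant offset; genes recur across diseases (many-to-one truth)
separable_embeddings <- function(seed, n_genes = 40L, n_diseases = 200L,
                                 dim = 10L, offset = 3) {
  withr::with_seed(seed, {
    G <- matrix(rnorm(n_genes * dim), n_genes)
    rownames(G) <- sprintf("GENE:%03d", seq_len(n_genes))
    assoc <- sample(n_genes, n_diseases, replace = TRUE)
    D <- G[assoc, ] + matrix(offset, n_diseases, dim)
    rownames(D) <- sprintf("OMIM:%03d", seq_len(n_diseases))
    list(embeddings = rbind(G, D),
         genes = rownames(G),
         truth = tibble::tibble(gene_id = rownames(G)[assoc],
                                disease_id = rownames(D)))
  })
}

# wrap a plain score matrix as a similarity_matrix for ranking tests
new_sim_for_tests <- function(m, method = "test") {
  structure(m, method = method, class = c("similarity_matrix", class(m)))
}

# restrict a corpus to a subset of entities (test-local re-implementation)
corpus_subset_for_tests <- function(corpus, ids) {
  structure(list(kind = corpus$kind, species = corpus$species,
                 direct = corpus$direct[ids],
                 direct_canonical = corpus$direct_canonical[ids],
                 propagated = corpus$propagated[ids]),
            class = "annotation_corpus")
}

# a disease_rankings tibble from a score matrix and truth, bypassing
# rank_genes (used when the oracle must stay independent of it)
rankings_of <- function(scores, truth) {
  rank_genes(tidyr::crossing(gene_id = rownames(scores),
                             disease_id = colnames(scores)) |>
               dplyr::mutate(score = scores[cbind(gene_id, disease_id)]),
             truth = truth)
}
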