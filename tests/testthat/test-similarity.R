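# IC values on the toy corpus, computed by hand: 4 entities, class A in 3
# propagated sets (-log2(3/4) ~ 0.4150), leaves in 1 of 4 (2 bits), root in
# all (0 bits).

test_that("information content follows propagated annotation frequency", {
  g <- toy_graph()
  ic <- compute_ic(toy_corpus(g))
  icv <- setNames(ic$ic, ic$class_id)
  expect_equal(unname(icv["HP:0000001"]), -log2(3 / 4), tolerance = 1e-12)
  expect_equal(unname(icv["ROOT:1"]), 0)
  expect_equal(unname(icv["HP:0000002"]), 2)
  expect_equal(unname(icv["MP:0000002"]), 2)
  expect_equal(attr(ic, "total_entities"), 4L)
  expect_error(compute_ic(list()), "empty")
})

test_that("ic is antitone along subclass edges", {
  g <- random_dag(40, seed = 21)
  ids <- g$classes$id
  ann <- withr::with_seed(3, tibble::tibble(
    entity_id = rep(sprintf("e%d", 1:25), each = 2L),
    class_id = sample(ids, 50L, replace = TRUE)))
  ic <- compute_ic(annotation_corpus(ann, g))
  icv <- setNames(ic$ic, ic$class_id)
  ed <- g$subclass_edges
  for (i in seq_len(nrow(ed))) {
    child_ic <- icv[unname(g$canonical[ed$child[i]])]
    parent_ic <- icv[unname(g$canonical[ed$parent[i]])]
    if (!is.na(child_ic) && !is.na(parent_ic)) {
      expect_gte(child_ic, parent_ic)
    }
  }
})

test_that("Resnik similarity is the IC of the most informative common ancestor", {
  g <- toy_graph()
  ic <- compute_ic(toy_corpus(g))
  # human A1 vs mouse A1': MICA is the merged A/A-prime class
  expect_equal(resnik_pair(ic, g, "HP:0000002", "MP:0000002"), -log2(3 / 4),
               tolerance = 1e-12)
  # self-similarity is the class's own IC
  expect_equal(resnik_pair(ic, g, "HP:0000002", "HP:0000002"), 2)
  # only the universally annotated root shared: similarity 0
  expect_equal(resnik_pair(ic, g, "HP:0000003", "MP:0000002"), 0)
  expect_error(resnik_pair(ic, g, "HP:0000002", "XX:9"), "unknown class")
})

test_that("resnik_pair equals brute-force enumeration on random DAGs", {
  for (seed in 1:20) {
    g <- random_dag(n = sample(8:40, 1L), seed = seed, n_equiv = sample(0:2, 1L))
    ids <- g$classes$id
    ann <- withr::with_seed(seed + 500, tibble::tibble(
      entity_id = rep(sprintf("e%d", 1:10), each = 2L),
      class_id = sample(ids, 20L, replace = TRUE)))
    ic <- compute_ic(annotation_corpus(ann, g))
    pairs <- withr::with_seed(seed + 900,
                              matrix(sample(ids, 10L, replace = TRUE), ncol = 2L))
    for (i in seq_len(nrow(pairs))) {
      expect_equal(resnik_pair(ic, g, pairs[i, 1L], pairs[i, 2L]),
                   brute_resnik(ic, g, pairs[i, 1L], pairs[i, 2L]))
    }
  }
})

test_that("best-match-average matches the hand-worked example and is symmetric", {
  g <- toy_graph()
  ic <- compute_ic(toy_corpus(g))
  a <- -log2(3 / 4)
  # gene {A1'} vs disease {A1, B}: row mean a, column mean (a + 0)/2
  expect_equal(bma_similarity("MP:0000002", c("HP:0000002", "HP:0000003"), ic, g),
               0.5 * (a + a / 2), tolerance = 1e-12)
  expect_equal(bma_similarity("HP:0000002", "HP:0000002", ic, g), 2)
  expect_warning(z <- bma_similarity(character(0L), "HP:0000002", ic, g), "empty")
  expect_equal(z, 0)

  g2 <- random_dag(25, seed = 77)
  ids <- g2$classes$id
  ann <- withr::with_seed(8, tibble::tibble(
    entity_id = rep(sprintf("e%d", 1:12), each = 2L),
    class_id = sample(ids, 24L, replace = TRUE)))
  ic2 <- compute_ic(annotation_corpus(ann, g2))
  withr::with_seed(123, {
    for (k in 1:30) {
      sa <- sample(ids, sample(1:4, 1L))
      sb <- sample(ids, sample(1:4, 1L))
      expect_equal(bma_similarity(sa, sb, ic2, g2),
                   bma_similarity(sb, sa, ic2, g2), tolerance = 1e-12)
    }
  })
})

test_that("the similarity matrix agrees with per-cell recomputation", {
  b <- generate_bundle(synthetic_config(n_human_classes = 40, n_model_classes = 40,
                                        n_genes = 20, n_diseases = 10, seed = 31))
  gc <- combine_organism_annotations(b$gene_corpora, list(b$orthology), "human")
  ic <- compute_ic(list(gc, b$disease_corpus))
  sim <- similarity_matrix_resnik(gc, b$disease_corpus, ic, b$ontology)
  expect_s3_class(sim, "similarity_matrix")
  expect_equal(dim(sim), c(20L, 10L))

  withr::with_seed(4, {
    for (k in 1:25) {
      gi <- sample(rownames(sim), 1L)
      di <- sample(colnames(sim), 1L)
      expected <- bma_similarity(gc$direct[[gi]], b$disease_corpus$direct[[di]],
                                 ic, b$ontology)
      expect_equal(unclass(sim)[gi, di], expected, tolerance = 1e-10)
    }
  })

  # single-cell matrix degenerates to bma_similarity itself
  g1 <- corpus_subset_for_tests(gc, rownames(sim)[1L])
  d1 <- corpus_subset_for_tests(b$disease_corpus, colnames(sim)[1L])
  s11 <- similarity_matrix_resnik(g1, d1, ic, b$ontology)
  expect_equal(as.numeric(s11), unclass(sim)[1L, 1L])
})

test_that("tidying a similarity matrix yields one row per gene-disease pair", {
  b <- generate_bundle(synthetic_config(n_human_classes = 30, n_model_classes = 30,
                                        n_genes = 6, n_diseases = 4, seed = 9))
  gc <- combine_organism_annotations(b$gene_corpora, list(b$orthology), "human")
  ic <- compute_ic(list(gc, b$disease_corpus))
  sim <- similarity_matrix_resnik(gc, b$disease_corpus, ic, b$ontology)
  td <- tidy(sim)
  expect_equal(nrow(td), 24L)
  expect_equal(td$score[td$gene_id == rownames(sim)[2L] &
                          td$disease_id == colnames(sim)[3L]],
               unclass(sim)[2L, 3L])
})
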