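test_that("entity-graph flavors differ exactly in direction and equivalence", {
  g <- toy_graph()
  co <- toy_corpus(g)

  und <- axioms_to_graph(g, co, flavor = "dl2vec")
  dir <- axioms_to_graph(g, co, flavor = "owl2vec")
  expect_false(attr(und, "directed"))
  expect_true(attr(dir, "directed"))
  expect_true(any(und$label == "equivalent_to"))
  expect_false(any(dir$label == "equivalent_to"))
  expect_error(axioms_to_graph(g, co, flavor = "word2vec"), "arg")

  # edge count: subclass + relations + direct annotations (+ equivalences)
  n_ann <- sum(lengths(co$direct))
  expect_equal(nrow(dir), nrow(g$subclass_edges) + nrow(g$relation_edges) + n_ann)
  expect_equal(nrow(und), nrow(dir) + nrow(g$equivalence_pairs))

  # empty corpus: ontology edges only
  bare <- axioms_to_graph(g, list(), flavor = "owl2vec")
  expect_equal(nrow(bare), nrow(g$subclass_edges) + nrow(g$relation_edges))
})

test_that("random walks truncate at sinks and follow forced paths", {
  g <- phenont(tibble::tibble(id = c("A:1", "B:1", "C:1"),
                              label = c("a", "b", "c"),
                              species = "integrated"),
               tibble::tibble(child = "A:1", parent = "B:1"))
  eg <- axioms_to_graph(g, list(), flavor = "owl2vec")
  w <- generate_walks(eg, num_walks = 4L, walk_length = 3L, seed = 5L)
  sents <- w$sentences
  # C:1 is isolated: all its walks are the single-token sentence
  from_c <- Filter(function(s) s[[1L]] == "C:1", sents)
  expect_length(from_c, 4L)
  expect_true(all(lengths(from_c) == 1L))
  # A:1 -> B:1 is the only directed path; every walk from A is forced
  from_a <- Filter(function(s) s[[1L]] == "A:1", sents)
  expect_true(all(vapply(from_a, function(s)
    identical(s, c("A:1", "is_a", "B:1")), logical(1L))))
  # B:1 is a sink in the directed graph
  from_b <- Filter(function(s) s[[1L]] == "B:1", sents)
  expect_true(all(lengths(from_b) == 1L))
})

test_that("walk corpora are reproducible under a fixed seed", {
  b <- generate_bundle(synthetic_config(n_human_classes = 30, n_model_classes = 30,
                                        n_genes = 15, n_diseases = 6, seed = 3))
  eg <- axioms_to_graph(b$ontology, b$gene_corpora, flavor = "dl2vec")
  w1 <- generate_walks(eg, 5L, 8L, seed = 11L)
  w2 <- generate_walks(eg, 5L, 8L, seed = 11L)
  w3 <- generate_walks(eg, 5L, 8L, seed = 12L)
  expect_identical(w1$sentences, w2$sentences)
  expect_false(identical(w1$sentences, w3$sentences))
  # every node with at least one edge appears in some sentence
  tokens <- unique(unlist(w1$sentences))
  linked <- unique(c(eg$from, eg$to))
  expect_true(all(linked %in% tokens))
})

test_that("undirected walks can traverse edges in both directions", {
  g <- phenont(tibble::tibble(id = c("A:1", "B:1"), label = c("a", "b"),
                              species = "integrated"),
               tibble::tibble(child = "A:1", parent = "B:1"))
  eg <- axioms_to_graph(g, list(), flavor = "dl2vec")
  w <- generate_walks(eg, 3L, 2L, seed = 2L)
  from_b <- Filter(function(s) s[[1L]] == "B:1", w$sentences)
  expect_true(all(lengths(from_b) > 1L))  # B can walk back to A
})

test_that("axiom sentences propagate annotations over the hierarchy", {
  g <- toy_graph()
  co <- annotation_corpus(tibble::tibble(entity_id = "e1",
                                         class_id = "HP:0000002"), g)
  w <- generate_axiom_sentences(g, co, labels = FALSE)
  ann <- Filter(function(s) s[[1L]] == "e1", w$sentences)
  # one sentence per ancestor of the annotated class: A1, A, root
  expect_length(ann, 3L)
  expect_setequal(vapply(ann, `[`, character(1L), 3L),
                  c("HP:0000002", "HP:0000001", "ROOT:1"))

  # no annotations: no entity sentences
  w0 <- generate_axiom_sentences(g, list(), labels = FALSE)
  expect_false(any(vapply(w0$sentences, function(s)
    s[[1L]] == "e1", logical(1L))))

  # label sentences are exactly the difference between the two modes
  wl <- generate_axiom_sentences(g, co, labels = TRUE)
  expect_equal(length(wl$sentences) - length(w$sentences), nrow(g$classes))
})

test_that("skip-gram embeds co-occurring tokens closer than strangers", {
  # g1/p1 co-occur (and share walk contexts), g2/p2 likewise, never across;
  # cosine similarity in the word space must respect the pairing
  sent <- c(replicate(40, c("g1", "p1", "g1", "p1"), simplify = FALSE),
            replicate(40, c("g2", "p2", "g2", "p2"), simplify = FALSE))
  corpus <- structure(list(sentences = sent, seed = 1L, params = list()),
                      class = "walk_corpus")
  for (seed in 1:5) {
    emb <- train_skipgram(corpus, dim = 16L, window = 2L, mincount = 1L,
                          negatives = 3L, epochs = 30L, seed = seed)
    cm <- cosine_similarity_matrix(emb, c("g1", "g2"), c("p1", "p2"))
    expect_gt(unclass(cm)["g1", "p1"], unclass(cm)["g1", "p2"])
    expect_gt(unclass(cm)["g2", "p2"], unclass(cm)["g2", "p1"])
  }
})

test_that("a gene embeds closer to its own phenotypes than to random classes", {
  b <- generate_bundle(synthetic_config(n_human_classes = 50, n_model_classes = 50,
                                        n_genes = 30, n_diseases = 10, seed = 17))
  sp <- b$config$model_species
  eg <- axioms_to_graph(b$ontology, b$gene_corpora[[sp]], flavor = "dl2vec")
  genes <- names(b$gene_corpora[[sp]]$direct)
  wins <- 0L
  total <- 0L
  for (seed in 1:5) {
    w <- generate_walks(eg, 10L, 10L, seed = seed)
    emb <- train_skipgram(w, dim = 32L, window = 5L, epochs = 5L, seed = seed,
                          required_tokens = genes)
    all_classes <- intersect(b$ontology$classes$id, rownames(emb))
    for (g in genes[1:10]) {
      own <- intersect(b$gene_corpora[[sp]]$direct[[g]], rownames(emb))
      other <- withr::with_seed(seed + 1000L,
                                sample(setdiff(all_classes, own), length(own)))
      cm <- unclass(cosine_similarity_matrix(emb, g, c(own, other)))
      wins <- wins + (mean(cm[, own]) > mean(cm[, other]))
      total <- total + 1L
    }
  }
  expect_gt(wins / total, 0.8)
})

test_that("skip-gram vocabulary handling enforces mincount and required tokens", {
  corpus <- structure(list(sentences = list(c("a", "b"), c("a", "c")),
                           seed = 1L, params = list()),
                      class = "walk_corpus")
  expect_error(train_skipgram(corpus, dim = 4L, mincount = 5L,
                              required_tokens = "b"),
               "required token")
  emb <- train_skipgram(corpus, dim = 100L, mincount = 0L, epochs = 1L)
  expect_equal(ncol(emb), 100L)
  expect_setequal(rownames(emb), c("a", "b", "c"))
  # identical seeds give identical vectors
  emb2 <- train_skipgram(corpus, dim = 100L, mincount = 0L, epochs = 1L)
  expect_identical(unclass(emb), unclass(emb2))
})

test_that("cosine similarity matches the direct formula", {
  v <- matrix(c(1, 0, 0, 1, 1, 1), 3L, 2L, byrow = TRUE,
              dimnames = list(c("x", "y", "z"), NULL))
  cm <- cosine_similarity_matrix(v, c("x", "z"), c("x", "y"))
  expect_equal(unclass(cm)["x", "x"], 1)
  expect_equal(unclass(cm)["x", "y"], 0)
  expect_equal(unclass(cm)["z", "x"], 1 / sqrt(2))

  # zero vector scores 0 by convention
  v0 <- rbind(v, w = c(0, 0))
  expect_equal(unname(unclass(cosine_similarity_matrix(v0, "w", "x"))[1L, 1L]), 0)
  expect_error(cosine_similarity_matrix(v, "x", "missing"), "missing")

  withr::with_seed(7, {
    m <- matrix(rnorm(100), 10L)
    rownames(m) <- sprintf("t%d", 1:10)
    cm2 <- unclass(cosine_similarity_matrix(m, rownames(m)[1:5], rownames(m)[6:10]))
    for (i in 1:5) for (j in 1:5) {
      u <- m[i, ]; w <- m[5 + j, ]
      expect_equal(cm2[i, j], sum(u * w) / sqrt(sum(u^2) * sum(w^2)),
                   tolerance = 1e-12)
    }
  })
})
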