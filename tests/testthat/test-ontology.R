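write_obo_text <- function(...) {
  f <- withr::local_tempfile(fileext = ".obo", .local_envir = parent.frame())
  writeLines(c("format-version: 1.2", "", ...), f)
  f
}

test_that("a minimal OBO file parses into classes and subclass edges", {
  f <- write_obo_text(
    "[Term]", "id: X:1", "name: root", "",
    "[Term]", "id: X:2", "name: a", "is_a: X:1 ! root")
  g <- parse_obo(f)
  expect_s3_class(g, "phenont")
  expect_equal(nrow(g$classes), 2L)
  expect_equal(g$subclass_edges,
               tibble::tibble(child = "X:2", parent = "X:1"))
})

test_that("equivalent_to merges ids onto one canonical representative", {
  f <- write_obo_text(
    "[Term]", "id: FBbt:00005093", "name: nervous system (fly)", "",
    "[Term]", "id: ZFA:0000396", "name: nervous system (fish)",
    "equivalent_to: FBbt:00005093")
  g <- parse_obo(f)
  expect_equal(unname(g$canonical[["ZFA:0000396"]]),
               unname(g$canonical[["FBbt:00005093"]]))
})

test_that("reciprocal is_a pairs are accepted as equivalence fallback", {
  f <- write_obo_text(
    "[Term]", "id: X:1", "name: a", "is_a: X:2", "",
    "[Term]", "id: X:2", "name: b", "is_a: X:1")
  g <- parse_obo(f)
  expect_equal(unname(g$canonical[["X:2"]]), "X:1")
  expect_equal(nrow(g$subclass_edges), 0L)
})

test_that("malformed ontologies are rejected with informative errors", {
  dup <- write_obo_text("[Term]", "id: X:1", "name: a", "",
                        "[Term]", "id: X:1", "name: b")
  expect_error(parse_obo(dup), "duplicate class id: X:1")

  dangling <- write_obo_text("[Term]", "id: X:1", "name: a", "is_a: X:9")
  expect_error(parse_obo(dangling), "unknown id")

  cyc <- write_obo_text(
    "[Term]", "id: X:1", "name: a", "is_a: X:2", "",
    "[Term]", "id: X:2", "name: b", "is_a: X:3", "",
    "[Term]", "id: X:3", "name: c", "is_a: X:1")
  expect_error(parse_obo(cyc), "cycle")
})

test_that("a cycle created by equivalence merging is caught after canonicalization", {
  # A <= B and C <= D with B ~ C and D ~ A closes a loop among canonical ids
  expect_error(
    phenont(tibble::tibble(id = c("X:1", "X:2", "X:3", "X:4"),
                           label = letters[1:4], species = "integrated"),
            tibble::tibble(child = c("X:1", "X:3"), parent = c("X:2", "X:4")),
            equivalence_pairs = tibble::tibble(a = c("X:2", "X:4"),
                                               b = c("X:3", "X:1"))),
    "cycle")
})

test_that("ancestors honors equivalence and includes the class itself", {
  g <- toy_graph()
  expect_equal(ancestors(g, "ROOT:1"), "ROOT:1")
  # A1' (mouse) climbs through the merged A/A' class to the root
  expect_equal(ancestors(g, "MP:0000002"),
               c("HP:0000001", "MP:0000002", "ROOT:1"))
  # canonicalization is a congruence: both members share one ancestor set
  expect_equal(ancestors(g, "MP:0000001"), ancestors(g, "HP:0000001"))
  expect_error(ancestors(g, "HP:9999999"), "unknown class")
})

test_that("ancestors equals brute-force reachability on random DAGs", {
  for (seed in 1:40) {
    g <- random_dag(n = sample(5:50, 1L), seed = seed,
                    n_equiv = sample(0:2, 1L))
    clo <- brute_canonical_closure(g)
    for (id in sample(g$classes$id, min(8L, nrow(g$classes)))) {
      expect_equal(ancestors(g, id), clo[[unname(g$canonical[id])]])
    }
  }
})

test_that("parse -> write -> parse round-trips an isomorphic graph", {
  g <- random_dag(30, seed = 99, n_equiv = 2L)
  f <- withr::local_tempfile(fileext = ".obo")
  write_obo(g, f)
  g2 <- parse_obo(f)
  expect_setequal(g2$classes$id, g$classes$id)
  expect_equal(dplyr::arrange(g2$subclass_edges, child, parent),
               dplyr::arrange(g$subclass_edges, child, parent))
  expect_equal(g2$canonical[sort(names(g2$canonical))],
               g$canonical[sort(names(g$canonical))])
  expect_equal(ancestors(g2, g$classes$id[[15L]]),
               ancestors(g, g$classes$id[[15L]]))
})

test_that("abnormality classes are minted idempotently under the right parents", {
  g <- phenont(
    classes = tibble::tibble(
      id = c("FBbt:00000001", "FBbt:00004729"),
      label = c("organism", "wing"),
      species = "fly"),
    subclass_edges = tibble::tibble(child = "FBbt:00004729",
                                    parent = "FBbt:00000001"))
  g1 <- add_phenotype_class(g, "FBbt:00000001", species = "fly")
  # the anatomy root's abnormality class sits directly under the species root
  root_ab <- abnormality_class_id("FBbt:00000001")
  expect_true(root_ab %in% g1$classes$id)
  expect_equal(g1$subclass_edges$parent[g1$subclass_edges$child == root_ab],
               "FBbtAB:ROOT")

  g2 <- add_phenotype_class(g1, "FBbt:00004729", species = "fly")
  wing_ab <- abnormality_class_id("FBbt:00004729")
  expect_equal(g2$classes$label[g2$classes$id == wing_ab],
               "phenotypic abnormality of wing")
  # wing abnormality nests under the organism abnormality, mirroring anatomy
  expect_equal(g2$subclass_edges$parent[g2$subclass_edges$child == wing_ab],
               root_ab)
  expect_equal(g2$classes$entity[g2$classes$id == wing_ab], "FBbt:00004729")

  # idempotent: minting again changes nothing
  g3 <- add_phenotype_class(g2, "FBbt:00004729", species = "fly")
  expect_equal(g3$classes, g2$classes)
  expect_error(add_phenotype_class(g2, "FBbt:0999999", species = "fly"),
               "unknown entity")
})

test_that("cross-species subsumption counts match pair enumeration", {
  # two disjoint single-species trees: no cross counts
  g0 <- phenont(
    classes = tibble::tibble(
      id = c("HP:0000001", "HP:0000002", "MP:0000001", "MP:0000002"),
      label = letters[1:4],
      species = c("human", "human", "mouse", "mouse")),
    subclass_edges = tibble::tibble(child = c("HP:0000002", "MP:0000002"),
                                    parent = c("HP:0000001", "MP:0000001")))
  t0 <- cross_species_subsumption_counts(g0, "mouse", "human")
  expect_equal(t0$total, c(0L, 0L))

  # one mid-level bridge: counts equal subtree size x superpath size
  g1 <- toy_graph()
  t1 <- cross_species_subsumption_counts(g1, "mouse", "human")
  # oracle: enumerate all ordered cross-species pairs directly
  oracle <- function(g, sp_sub, sp_super) {
    subs <- g$classes$id[g$classes$species == sp_sub]
    supers <- g$classes$id[g$classes$species == sp_super]
    clo <- brute_canonical_closure(g)
    sum(vapply(subs, function(s) sum(
      unname(g$canonical[supers]) %in% clo[[unname(g$canonical[s])]]),
      integer(1L)))
  }
  expect_equal(t1$total[t1$species_sub == "mouse"], oracle(g1, "mouse", "human"))
  expect_equal(t1$total[t1$species_sub == "human"], oracle(g1, "human", "mouse"))
  # mouse A' ~ A and A1' below it see human A (self-pair) and nothing above
  # except via A; human A1 sees mouse A'
  expect_true(all(t1$total > 0L))
  expect_error(cross_species_subsumption_counts(g1, "mouse", "martian"),
               "unknown species")
})

test_that("adding an equivalence bridge never decreases cross-species counts", {
  g_before <- phenont(
    classes = tibble::tibble(
      id = c("R:1", "HP:0000001", "HP:0000002", "MP:0000001", "MP:0000002"),
      label = letters[1:5],
      species = c("integrated", "human", "human", "mouse", "mouse")),
    subclass_edges = tibble::tibble(
      child = c("HP:0000001", "HP:0000002", "MP:0000001", "MP:0000002"),
      parent = c("R:1", "HP:0000001", "R:1", "MP:0000001")))
  g_after <- phenont(g_before$classes, g_before$subclass_edges,
                     equivalence_pairs = tibble::tibble(a = "MP:0000001",
                                                        b = "HP:0000001"))
  before <- cross_species_subsumption_counts(g_before, "mouse", "human")
  after <- cross_species_subsumption_counts(g_after, "mouse", "human")
  expect_true(all(after$total >= before$total))
  expect_gt(sum(after$total), sum(before$total))
})
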