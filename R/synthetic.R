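#' Configuration of the synthetic benchmark generator
#'
#' Describes the statistical structure the analysis assumes in real
#' cross-species data: two species-specific phenotype vocabularies joined
#' under one root with equivalence bridges; diseases annotated with human
#' phenotype classes; a one-to-one orthology between human and
#' model-organism genes; and an association signal in which the model
#' ortholog of a disease gene mirrors (through the bridges) part of the
#' disease's phenotype profile. Two bias knobs reproduce the study bias seen
#' in curated databases: `bias_multiplier` inflates how many annotations
#' disease-gene orthologs receive, and `depth_bias` draws their annotations
#' from deeper (more specific, higher-IC) classes.
#'
#' @param n_human_classes,n_model_classes Classes per species subtree
#'   (including each subtree root).
#' @param branching Mean children per class during tree growth.
#' @param bridge_fraction Fraction of model classes given a human equivalent,
#'   in `[0, 1]`.
#' @param n_genes,n_diseases Gene and disease counts.
#' @param pheno_per_disease,pheno_per_gene Mean annotation counts.
#' @param fidelity Probability that a disease phenotype is mirrored, via its
#'   bridged class, into the associated gene's model ortholog.
#' @param bias_multiplier Annotation-count inflation (>= 1) for
#'   disease-gene orthologs.
#' @param depth_bias Draw disease-gene annotations depth-weighted (deeper
#'   classes more likely) instead of uniformly.
#' @param model_species Species tag of the model organism subtree.
#' @param seed Integer seed; a fixed seed gives byte-identical bundles.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_human_classes = 150L, n_model_classes = 150L,
                             branching = 2, bridge_fraction = 0.8,
                             n_genes = 300L, n_diseases = 100L,
                             pheno_per_disease = 6, pheno_per_gene = 6,
                             fidelity = 0.9, bias_multiplier = 1,
                             depth_bias = FALSE, model_species = "mouse",
                             seed = 1L) {
  stopifnot(n_human_classes >= 2L, n_model_classes >= 2L, branching > 0,
            bridge_fraction >= 0, bridge_fraction <= 1,
            n_genes >= 1L, n_diseases >= 1L,
            pheno_per_disease > 0, pheno_per_gene > 0,
            fidelity >= 0, fidelity <= 1, bias_multiplier >= 1,
            is.logical(depth_bias),
            model_species %in% setdiff(ontology_species(), c("human", "integrated")))
  structure(list(n_human_classes = as.integer(n_human_classes),
                 n_model_classes = as.integer(n_model_classes),
                 branching = branching, bridge_fraction = bridge_fraction,
                 n_genes = as.integer(n_genes), n_diseases = as.integer(n_diseases),
                 pheno_per_disease = pheno_per_disease,
                 pheno_per_gene = pheno_per_gene,
                 fidelity = fidelity, bias_multiplier = bias_multiplier,
                 depth_bias = depth_bias, model_species = model_species,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

model_prefixes <- c(mouse = "MP", fish = "ZP", fly = "FBbtAB", yeast = "FYPO")

# breadth-first tree growth with Poisson(branching) children per node until
# exactly n nodes exist; returns parent index per node (NA for the root)
grow_tree <- function(n, branching) {
  parent <- rep(NA_integer_, n)
  count <- 1L
  queue <- 1L
  while (count < n) {
    if (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      k <- rpois(1L, branching)
    } else {
      v <- sample.int(count, 1L)
      k <- max(1L, rpois(1L, branching))
    }
    k <- min(k, n - count)
    if (k > 0L) {
      kids <- count + seq_len(k)
      parent[kids] <- v
      count <- count + k
      queue <- c(queue, kids)
    }
  }
  parent
}

#' Generate a synthetic cross-species phenotype ontology
#'
#' Grows a human subtree and a model-organism subtree under one shared root
#' by breadth-first branching (Poisson children per class), then declares a
#' `bridge_fraction` share of the model classes equivalent to depth-matched
#' human classes. Whenever any bridging is requested the two subtree roots
#' are bridged as well, the way integrated phenotype ontologies always align
#' their top-level "phenotypic abnormality" classes. Additional bridges are
#' sampled shallow-weighted (curated equivalences concentrate on major
#' structures near the top of each vocabulary) and each bridge's human
#' target is drawn from the descendants of the nearest bridged ancestor's
#' target, so bridging preserves subsumption order and can never create a
#' cycle.
#'
#' @param config A [synthetic_config()].
#' @return A [phenont] with species tags assigned.
#' @export
generate_ontology <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$bridge_fraction > 0 && config$n_human_classes == 0L) {
    abort("bridge_fraction > 0 requires human classes")
  }
  prefix <- model_prefixes[[config$model_species]]
  with_seed(fan_seed(config$seed, 11L), {
    root <- "PHENO:0000000"
    hids <- sprintf("HP:%07d", seq_len(config$n_human_classes))
    mids <- sprintf("%s:%07d", prefix, seq_len(config$n_model_classes))

    hparent <- grow_tree(config$n_human_classes, config$branching)
    h_edges <- tibble(child = hids[-1L], parent = hids[hparent[-1L]])
    hdepth <- integer(config$n_human_classes)
    hdepth[1L] <- 1L
    for (i in seq_len(config$n_human_classes)[-1L]) {
      hdepth[i] <- hdepth[hparent[i]] + 1L
    }

    n_mirror_max <- config$n_model_classes - 1L
    n_mirror <- round(config$bridge_fraction * n_mirror_max)
    if (n_mirror > config$n_human_classes - 1L) {
      abort("not enough human classes to bridge this many model classes")
    }
    # bridge targets are sampled shallow-weighted: curated cross-species
    # equivalences concentrate on major structures near the top of each
    # vocabulary, while annotations reach much deeper
    mirror_targets <- if (n_mirror > 0L)
      sort(sample(hids[-1L], n_mirror, prob = 1 / hdepth[-1L]^2)) else character(0L)

    # bridged model classes mirror the induced human topology (the mirror's
    # parent is the mirror of the nearest bridged human ancestor), so the
    # merged subclass relation stays acyclic and bridge depths match
    mirror_of <- setNames(mids[1L + seq_len(n_mirror)], mirror_targets)
    h_parent_of <- setNames(c(NA_character_, hids[hparent[-1L]]), hids)
    m_edges_child <- character(0L); m_edges_parent <- character(0L)
    for (h in mirror_targets[order(match(mirror_targets, hids))]) {
      anc <- h_parent_of[[h]]
      while (!is.na(anc) && !anc %in% mirror_targets) anc <- h_parent_of[[anc]]
      m_edges_child <- c(m_edges_child, mirror_of[[h]])
      m_edges_parent <- c(m_edges_parent,
                          if (is.na(anc)) mids[[1L]] else mirror_of[[anc]])
    }
    # species-specific classes grow breadth-first with Poisson(branching)
    # children off the bridged skeleton, keeping the subtree bushy so class
    # frequency (and hence IC) falls with depth as in real ontologies
    n_free <- config$n_model_classes - 1L - n_mirror
    if (n_free > 0L) {
      free_ids <- mids[(1L + n_mirror + 1L):config$n_model_classes]
      queue <- sample(mids[seq_len(n_mirror + 1L)])
      placed <- 0L
      while (placed < n_free) {
        if (length(queue)) {
          v <- queue[[1L]]
          queue <- queue[-1L]
          k <- rpois(1L, config$branching)
        } else {
          v <- sample(mids[seq_len(n_mirror + 1L + placed)], 1L)
          k <- max(1L, rpois(1L, config$branching))
        }
        k <- min(k, n_free - placed)
        if (k > 0L) {
          kids <- free_ids[placed + seq_len(k)]
          m_edges_child <- c(m_edges_child, kids)
          m_edges_parent <- c(m_edges_parent, rep(v, k))
          placed <- placed + k
          queue <- c(queue, kids)
        }
      }
    }
    m_edges <- tibble(child = m_edges_child, parent = m_edges_parent)

    eq <- tibble(a = unname(mirror_of), b = names(mirror_of))
    if (config$bridge_fraction > 0) {
      # integrated phenotype ontologies always align the two top-level
      # "phenotypic abnormality" classes, whatever else is bridged
      eq <- bind_rows(eq, tibble(a = mids[[1L]], b = hids[[1L]]))
    }

    classes <- bind_rows(
      tibble(id = root, label = "phenotypic abnormality",
             species = "integrated"),
      tibble(id = hids,
             label = c("human phenotypic abnormality",
                       sprintf("human phenotype %d", seq_len(config$n_human_classes - 1L))),
             species = "human"),
      tibble(id = mids,
             label = c(sprintf("%s phenotypic abnormality", config$model_species),
                       sprintf("%s phenotype %d", config$model_species,
                               seq_len(config$n_model_classes - 1L))),
             species = config$model_species))
    edges <- bind_rows(
      tibble(child = c(hids[[1L]], mids[[1L]]), parent = root),
      h_edges,
      m_edges)
    phenont(classes, edges, equivalence_pairs = if (nrow(eq)) eq else NULL)
  })
}

class_depths <- function(graph) {
  anc <- ancestor_sets(graph)
  setNames(lengths(anc) - 1L, names(anc))
}

#' Generate annotations, orthology and truth over a synthetic ontology
#'
#' Emulates curated genotype-phenotype resources: diseases receive
#' depth-weighted human phenotype profiles; each disease is assigned one
#' associated human gene whose model ortholog mirrors each disease phenotype
#' (through its bridged class or that class's nearest bridged ancestor, and
#' sometimes a child of the bridge for extra specificity) with probability
#' `fidelity`; all other annotations are random model classes. Disease-gene
#' orthologs get `bias_multiplier` times more annotations, drawn
#' depth-weighted when `depth_bias` is on. A one-to-one orthology table and
#' the gene-disease truth complete the bundle. When `fidelity > 0`, disease
#' phenotypes are drawn from human classes that have a bridged
#' self-or-ancestor, so the mirroring mechanism is always well defined.
#'
#' @param ontology A [generate_ontology()] result.
#' @param config The same [synthetic_config()].
#' @return A `benchmark_bundle`: list with `ontology`, `gene_corpora` (model
#'   corpus plus an annotation-less human anchor corpus), `disease_corpus`,
#'   `orthology`, `truth` and `config`.
#' @export
generate_annotations <- function(ontology, config) {
  stopifnot(inherits(ontology, "phenont"), inherits(config, "synthetic_config"))
  if (config$fidelity > 0 && config$bridge_fraction == 0) {
    abort("fidelity > 0 requires bridge_fraction > 0 (no mirror possible)")
  }
  prefix <- model_prefixes[[config$model_species]]
  sp <- config$model_species

  human_genes <- sprintf("GENE:%05d", seq_len(config$n_genes))
  model_genes <- sprintf("%sGENE:%05d", prefix, seq_len(config$n_genes))
  diseases <- sprintf("OMIM:%06d", 100000L + seq_len(config$n_diseases))
  ortho_of <- setNames(model_genes, human_genes)

  cls <- ontology$classes
  hids <- cls$id[cls$species == "human"]
  mids <- cls$id[cls$species == sp]
  h_root <- hids[[1L]]; m_root <- mids[[1L]]
  # depth within the species' own subtree (edges up to the shared root)
  parent_vec <- setNames(ontology$subclass_edges$parent,
                         ontology$subclass_edges$child)
  depth_of <- function(ids) {
    vapply(ids, function(x) {
      d <- 0L
      cur <- x
      while (cur %in% names(parent_vec)) {
        cur <- parent_vec[[match(cur, names(parent_vec))]]
        d <- d + 1L
      }
      d
    }, integer(1L), USE.NAMES = FALSE)
  }

  eq <- ontology$equivalence_pairs
  is_model_side <- curie_prefix(eq$a) == prefix
  mirror_to_model <- setNames(ifelse(is_model_side, eq$a, eq$b),
                              ifelse(is_model_side, eq$b, eq$a))
  bridged_canon <- unique(unname(ontology$canonical[names(mirror_to_model)]))

  h_pool <- setdiff(hids, h_root)
  if (config$fidelity > 0) {
    anc <- ancestor_sets(ontology)
    has_bridge <- vapply(unname(ontology$canonical[h_pool]), function(cc)
      any(anc[[cc]] %in% bridged_canon), logical(1L))
    h_pool <- h_pool[has_bridge]
    if (!length(h_pool)) abort("no bridgeable human classes to annotate diseases with")
  }
  m_pool <- setdiff(mids, m_root)
  m_children_of <- split(ontology$subclass_edges$child[
    ontology$subclass_edges$child %in% m_pool],
    ontology$subclass_edges$parent[ontology$subclass_edges$child %in% m_pool])

  # nearest bridged self-or-ancestor of a human class, mapped to model side
  h_parent_of <- setNames(ontology$subclass_edges$parent,
                          ontology$subclass_edges$child)
  mirror_for <- function(h) {
    cur <- h
    while (!is.na(cur)) {
      if (cur %in% names(mirror_to_model)) return(mirror_to_model[[cur]])
      cur <- if (cur %in% names(h_parent_of)) h_parent_of[[cur]] else NA_character_
    }
    NA_character_
  }

  with_seed(fan_seed(config$seed, 23L), {
    d_counts <- pmax(1L, rpois(config$n_diseases, config$pheno_per_disease))
    h_w <- depth_of(h_pool)
    disease_sets <- lapply(d_counts, function(k)
      sample(h_pool, min(k, length(h_pool)), prob = h_w))
    names(disease_sets) <- diseases

    assoc_gene <- if (config$n_diseases <= config$n_genes)
      sample(human_genes, config$n_diseases) else
      sample(human_genes, config$n_diseases, replace = TRUE)
    truth <- tibble(gene_id = assoc_gene, disease_id = diseases)
    diseases_of <- split(truth$disease_id, truth$gene_id)

    # depth-biased draws double in weight per level: class frequency roughly
    # halves per level in a branching hierarchy, so this tilt is what moves
    # annotations decisively into rare, high-IC leaves
    m_w_uniform <- rep(1, length(m_pool))
    m_w_deep <- 2^depth_of(m_pool)
    gene_rows <- purrr::map(seq_len(config$n_genes), function(i) {
      hg <- human_genes[[i]]
      associated <- hg %in% names(diseases_of)
      mirrored <- character(0L)
      if (associated && config$fidelity > 0) {
        for (d in diseases_of[[hg]]) {
          for (h in disease_sets[[d]]) {
            if (runif(1L) < config$fidelity) {
              m <- mirror_for(h)
              if (!is.na(m)) {
                kids <- m_children_of[[m]]
                if (length(kids) && runif(1L) < 0.5) m <- sample(kids, 1L)
                mirrored <- c(mirrored, m)
              }
            }
          }
        }
      }
      lam <- config$pheno_per_gene *
        (if (associated) config$bias_multiplier else 1)
      k <- max(1L, rpois(1L, lam))
      n_extra <- max(0L, k - length(unique(mirrored)))
      w <- if (associated && config$depth_bias) m_w_deep else m_w_uniform
      extra <- if (n_extra > 0L)
        sample(m_pool, min(n_extra, length(m_pool)), prob = w) else character(0L)
      cls <- unique(c(mirrored, extra))
      tibble(entity_id = ortho_of[[hg]], class_id = cls)
    })

    gene_tbl <- bind_rows(gene_rows)
    disease_tbl <- tibble(
      entity_id = rep(diseases, lengths(disease_sets)),
      class_id = unlist(disease_sets, use.names = FALSE))

    bundle <- structure(list(
      ontology = ontology,
      gene_corpora = list(
        annotation_corpus(gene_tbl, ontology, kind = "gene", species = sp,
                          entities = model_genes),
        annotation_corpus(tibble(entity_id = character(0L),
                                 class_id = character(0L)),
                          ontology, kind = "gene", species = "human",
                          entities = human_genes)),
      disease_corpus = annotation_corpus(disease_tbl, ontology,
                                         kind = "disease", species = "human"),
      orthology = tibble(gene_a = human_genes, gene_b = model_genes),
      truth = truth,
      config = config), class = "benchmark_bundle")
    names(bundle$gene_corpora) <- c(sp, "human")
    bundle
  })
}

#' Generate a complete synthetic benchmark bundle
#'
#' Convenience wrapper: [generate_ontology()] followed by
#' [generate_annotations()].
#'
#' @param config A [synthetic_config()].
#' @return A `benchmark_bundle`.
#' @export
generate_bundle <- function(config = synthetic_config()) {
  generate_annotations(generate_ontology(config), config)
}

#' @export
print.benchmark_bundle <- function(x, ...) {
  cat(sprintf("<benchmark_bundle> %s: %d classes, %d genes, %d diseases, %d associations\n",
              x$config$model_species, nrow(x$ontology$classes),
              nrow(x$orthology), length(x$disease_corpus$direct),
              nrow(x$truth)))
  invisible(x)
}

#' Write a benchmark bundle to a directory of portable text files
#'
#' Emits `ontology.obo`, per-species gene annotation TSVs,
#' `disease_annotations.tsv`, `orthology.tsv`, `associations.tsv` and a
#' `bundle.yaml` manifest; [read_bundle()] reconstructs the bundle
#' losslessly.
#'
#' @param bundle A `benchmark_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_obo(bundle$ontology, file.path(dir, "ontology.obo"))
  for (sp in names(bundle$gene_corpora)) {
    readr::write_tsv(tidy(bundle$gene_corpora[[sp]]),
                     file.path(dir, sprintf("gene_annotations_%s.tsv", sp)),
                     col_names = FALSE)
  }
  readr::write_tsv(tidy(bundle$disease_corpus),
                   file.path(dir, "disease_annotations.tsv"), col_names = FALSE)
  readr::write_tsv(bundle$orthology, file.path(dir, "orthology.tsv"),
                   col_names = FALSE)
  readr::write_tsv(bundle$truth, file.path(dir, "associations.tsv"),
                   col_names = FALSE)
  meta <- unclass(bundle$config)
  meta$species <- names(bundle$gene_corpora)
  meta$entities <- lapply(bundle$gene_corpora, corpus_entities)
  yaml::write_yaml(meta, file.path(dir, "bundle.yaml"))
  invisible(dir)
}

#' Read a benchmark bundle written by [write_bundle()]
#'
#' @param dir Bundle directory.
#' @return A `benchmark_bundle`.
#' @export
read_bundle <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "bundle.yaml"))
  sp <- meta$model_species
  prefix <- model_prefixes[[sp]]
  species_map <- setNames(c("human", sp, "integrated"),
                          c("HP", prefix, "PHENO"))
  graph <- parse_obo(file.path(dir, "ontology.obo"), species_map = species_map)
  gene_corpora <- lapply(meta$species, function(s) {
    path <- file.path(dir, sprintf("gene_annotations_%s.tsv", s))
    ann <- if (file.size(path) > 0L)
      readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                      progress = FALSE,
                      col_types = readr::cols(.default = readr::col_character()))
    else tibble(entity_id = character(0L), class_id = character(0L))
    annotation_corpus(ann, graph, kind = "gene", species = s,
                      entities = unlist(meta$entities[[s]]))
  })
  names(gene_corpora) <- meta$species
  cfg_fields <- setdiff(names(meta), c("species", "entities"))
  config <- do.call(synthetic_config, meta[cfg_fields])
  structure(list(
    ontology = graph,
    gene_corpora = gene_corpora,
    disease_corpus = read_annotations(file.path(dir, "disease_annotations.tsv"),
                                      graph, kind = "disease", species = "human"),
    orthology = read_orthology(file.path(dir, "orthology.tsv")),
    truth = setNames(read_gene_disease(file.path(dir, "associations.tsv")),
                     c("gene_id", "disease_id")),
    config = config), class = "benchmark_bundle")
}
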