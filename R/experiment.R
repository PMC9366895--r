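experiment_methods <- function() {
  c("resnik_bma", "opa2vec", "dl2vec", "owl2vec", "naive", "supervised")
}

default_experiment_config <- function() {
  list(
    seed = 1L,
    methods = c("resnik_bma", "naive"),
    synthetic = list(),
    data = NULL,
    restrict_common = FALSE,
    plots = TRUE,
    embedding = list(
      dim = 100L, epochs = 10L, learning_rate = 0.025,
      dl2vec = list(num_walks = 50L, walk_length = 30L, window = 10L,
                    mincount = 1L, negatives = 5L),
      owl2vec = list(num_walks = 30L, walk_length = 7L, window = 5L,
                     mincount = 1L, negatives = 5L),
      opa2vec = list(window = 5L, mincount = 0L, negatives = 5L,
                     labels = TRUE)),
    supervised = list(embedding = "dl2vec", folds = 10L,
                      learning_rate = 0.001, max_iterations = 300L,
                      negatives_per_positive = 5L, holdout = "diseases"))
}

# drop entities from a corpus, keeping structure intact
corpus_subset <- function(corpus, ids) {
  keep <- intersect(names(corpus$direct), ids)
  structure(list(kind = corpus$kind, species = corpus$species,
                 direct = corpus$direct[keep],
                 direct_canonical = corpus$direct_canonical[keep],
                 propagated = corpus$propagated[keep]),
            class = "annotation_corpus")
}

#' Run an end-to-end gene-disease prioritization experiment
#'
#' Orchestrates the full protocol from a flat configuration: obtain a
#' benchmark bundle (generated from synthetic parameters, or loaded from a
#' directory written by [write_bundle()]), pool model-organism phenotypes
#' onto the human gene universe via orthology, compute information content,
#' score every requested method, rank genes per disease, evaluate
#' macro-averaged ROC curves, and write all results plus bias diagnostics
#' and a reproducibility manifest into `out_dir`. A single top-level seed is
#' fanned out deterministically to every stage, so reruns with the same
#' configuration are identical.
#'
#' @param config A configuration list or path to a YAML file. Recognized
#'   keys: `seed`, `methods` (subset of `resnik_bma`, `opa2vec`, `dl2vec`,
#'   `owl2vec`, `naive`, `supervised`), `synthetic` (overrides for
#'   [synthetic_config()]), `data$dir` (load a bundle instead of
#'   generating), `restrict_common` (keep only genes annotated in every
#'   model corpus), `plots`, and `embedding`/`supervised` hyperparameter
#'   blocks (pre-filled with the standard settings for each method).
#' @param out_dir Output directory. While the run is in progress it contains
#'   an `INCOMPLETE` marker; the marker is removed on success.
#' @return Invisibly, a list with the AUC summary, per-method `roc_result`s,
#'   the bias report and the bundle.
#' @export
run_experiment <- function(config = list(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(default_experiment_config(), config)
  unknown <- setdiff(cfg$methods, experiment_methods())
  if (length(unknown)) {
    abort(sprintf("unknown method(s): %s (choose from %s)",
                  paste(unknown, collapse = ", "),
                  paste(experiment_methods(), collapse = ", ")))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(out_dir, "INCOMPLETE")
  file.create(marker)

  seed <- as.integer(cfg$seed)
  bundle <- if (!is.null(cfg$data$dir)) read_bundle(cfg$data$dir) else {
    syn <- do.call(synthetic_config,
                   modifyList(cfg$synthetic, list(seed = fan_seed(seed, 1L))))
    generate_bundle(syn)
  }
  write_bundle(bundle, file.path(out_dir, "bundle"))
  graph <- bundle$ontology

  model_corpora <- bundle$gene_corpora[names(bundle$gene_corpora) != "human"]
  anchor <- combine_organism_annotations(
    bundle$gene_corpora, rep(list(bundle$orthology), length(model_corpora)),
    anchor_species = "human")

  annotated <- function(corpus, human_ids) {
    model_ids <- bundle$orthology$gene_b[match(human_ids, bundle$orthology$gene_a)]
    human_ids[model_ids %in% names(corpus$direct)[lengths(corpus$direct) > 0L]]
  }
  universe <- names(anchor$direct)[lengths(anchor$direct) > 0L]
  if (isTRUE(cfg$restrict_common)) {
    for (co in model_corpora) universe <- annotated(co, universe)
  }
  universe <- sort(universe)
  gene_corpus <- corpus_subset(anchor, universe)

  ic <- compute_ic(list(gene_corpus, bundle$disease_corpus),
                   corpus_id = "experiment-union")
  truth <- bundle$truth
  disease_ids <- sort(names(bundle$disease_corpus$direct))

  embeddings_cache <- list()
  get_embeddings <- function(method) {
    if (!is.null(embeddings_cache[[method]])) return(embeddings_cache[[method]])
    ec <- cfg$embedding
    p <- ec[[method]]
    corpus <- if (method == "opa2vec") {
      generate_axiom_sentences(graph, list(gene_corpus, bundle$disease_corpus),
                               labels = isTRUE(p$labels))
    } else {
      eg <- axioms_to_graph(graph, list(gene_corpus, bundle$disease_corpus),
                            flavor = method)
      generate_walks(eg, p$num_walks, p$walk_length, seed = fan_seed(seed, 40L))
    }
    emb <- train_skipgram(corpus, dim = ec$dim, window = p$window,
                          mincount = p$mincount, negatives = p$negatives,
                          epochs = ec$epochs, learning_rate = ec$learning_rate,
                          seed = fan_seed(seed, 50L),
                          required_tokens = c(universe, disease_ids))
    embeddings_cache[[method]] <<- emb
    emb
  }

  rocs <- list()
  summaries <- list()
  for (method in cfg$methods) {
    rankings <- switch(
      method,
      resnik_bma = rank_genes(similarity_matrix_resnik(
        gene_corpus, bundle$disease_corpus, ic, graph), truth = truth),
      naive = naive_rank(ic, gene_corpus, disease_ids, truth = truth),
      supervised = {
        emb <- get_embeddings(cfg$supervised$embedding)
        sc <- do.call(supervised_config,
                      c(cfg$supervised[setdiff(names(cfg$supervised), "embedding")],
                        list(seed = fan_seed(seed, 60L))))
        scores <- supervised_scores(emb, truth, sc, genes = universe)
        rank_genes(scores, truth = truth)
      },
      # dl2vec / owl2vec / opa2vec: cosine over skip-gram vectors
      rank_genes(cosine_similarity_matrix(get_embeddings(method),
                                          universe, disease_ids),
                 truth = truth))
    readr::write_tsv(as_tibble(rankings),
                     file.path(out_dir, sprintf("rankings_%s.tsv", method)))
    roc <- suppressWarnings(roc_from_rankings(rankings))
    rocs[[method]] <- roc
    readr::write_tsv(roc$points, file.path(out_dir, sprintf("roc_%s.tsv", method)))
    summaries[[method]] <- tibble(method = method, auc = roc$auc,
                                  n_diseases = roc$n_diseases,
                                  n_genes = length(universe))
  }

  auc_summary <- bind_rows(summaries)
  readr::write_tsv(auc_summary, file.path(out_dir, "auc_summary.tsv"))

  # bias diagnostics over the model-organism annotations
  totals <- total_ic(gene_corpus, ic)
  bias <- study_bias_test(totals, unique(truth$gene_id))
  gaps <- vapply(gene_corpus$direct, ic_gap, numeric(1L), ic = ic, graph = graph)
  gap_tbl <- tibble(gene_id = names(gaps), ic_gap = unname(gaps),
                    disease_associated = names(gaps) %in% truth$gene_id)
  bias_report <- bind_rows(
    tibble(metric = "total_ic_t", value = bias$statistic),
    tibble(metric = "total_ic_p_one_tailed", value = bias$p.value),
    tibble(metric = "total_ic_mean_disease", value = bias$mean_disease),
    tibble(metric = "total_ic_mean_other", value = bias$mean_other),
    tibble(metric = "ic_gap_mean_disease",
           value = mean(gap_tbl$ic_gap[gap_tbl$disease_associated])),
    tibble(metric = "ic_gap_mean_other",
           value = mean(gap_tbl$ic_gap[!gap_tbl$disease_associated])))
  readr::write_tsv(bias_report, file.path(out_dir, "bias_report.tsv"))

  if (isTRUE(cfg$plots) && length(rocs)) {
    pl <- plot_roc_curves(rocs)
    ggplot2::ggsave(file.path(out_dir, "roc_curves.pdf"), pl,
                    width = 6, height = 5)
  }

  manifest <- list(config = cfg,
                   package_version = as.character(utils::packageVersion("phenosim")),
                   r_version = R.version.string,
                   n_genes_ranked = length(universe),
                   n_diseases = length(disease_ids))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  file.remove(marker)
  invisible(list(auc_summary = auc_summary, rocs = rocs,
                 bias_report = bias_report, bundle = bundle))
}
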