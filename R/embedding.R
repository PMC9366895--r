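#' Convert ontology axioms and annotations into an entity graph
#'
#' Builds the graph the random-walk embedding methods explore. Subclass
#' edges (label `is_a`), labeled relation edges and gene/disease annotation
#' edges (label `has_phenotype`) become graph edges over the raw (uncanonicalized)
#' class ids. The two flavors differ the way the corresponding embedding
#' pipelines do: `dl2vec` graphs are undirected and include one
#' `equivalent_to` edge per equivalence pair, whereas `owl2vec` graphs are
#' directed (child to parent) and omit equivalence axioms.
#'
#' @param graph A [phenont] ontology.
#' @param corpora List of `annotation_corpus` objects contributing
#'   entity-annotation edges (may be empty).
#' @param flavor `"dl2vec"` or `"owl2vec"`.
#' @return An `entity_graph`: a tibble of edges (`from`, `label`, `to`) with
#'   attributes `directed` and `nodes`.
#' @export
axioms_to_graph <- function(graph, corpora = list(), flavor = c("dl2vec", "owl2vec")) {
  flavor <- match.arg(flavor)
  stopifnot(inherits(graph, "phenont"))
  if (inherits(corpora, "annotation_corpus")) corpora <- list(corpora)

  edges <- bind_rows(
    tibble(from = graph$subclass_edges$child, label = "is_a",
           to = graph$subclass_edges$parent),
    tibble(from = graph$relation_edges$subject,
           label = graph$relation_edges$relation,
           to = graph$relation_edges$object))
  if (flavor == "dl2vec" && nrow(graph$equivalence_pairs)) {
    edges <- bind_rows(edges, tibble(from = graph$equivalence_pairs$a,
                                     label = "equivalent_to",
                                     to = graph$equivalence_pairs$b))
  }
  ann <- purrr::map_dfr(corpora, function(co) {
    tibble(from = rep(names(co$direct), lengths(co$direct)),
           label = "has_phenotype",
           to = unlist(co$direct, use.names = FALSE))
  })
  edges <- distinct(bind_rows(edges, ann))
  nodes <- sort(unique(c(graph$classes$id, edges$from, edges$to)))
  structure(edges, directed = flavor == "owl2vec", nodes = nodes,
            flavor = flavor, class = c("entity_graph", class(edges)))
}

#' Generate a random-walk corpus over an entity graph
#'
#' Starts `num_walks` uniform random walks of up to `walk_length` steps from
#' every node (following out-edges only when the graph is directed) and
#' interleaves edge labels as tokens, so a walk reads like
#' `node is_a node has_phenotype node ...`. Walks truncate at sinks; an
#' isolated node yields single-token sentences. Reproducible for a fixed
#' seed.
#'
#' @param entity_graph An [axioms_to_graph()] result.
#' @param num_walks Walks per node (>= 1).
#' @param walk_length Maximum steps per walk (>= 1).
#' @param seed Integer seed.
#' @return A `walk_corpus`: list with `sentences` (list of character token
#'   vectors), `seed`, `params`.
#' @export
generate_walks <- function(entity_graph, num_walks, walk_length, seed = 1L) {
  stopifnot(inherits(entity_graph, "entity_graph"),
            num_walks >= 1L, walk_length >= 1L)
  nodes <- attr(entity_graph, "nodes")
  if (!length(nodes)) abort("empty graph")
  directed <- attr(entity_graph, "directed")
  labels <- sort(unique(entity_graph$label))

  from_i <- match(entity_graph$from, nodes)
  to_i <- match(entity_graph$to, nodes)
  lab_i <- match(entity_graph$label, labels)
  if (!directed) {
    tmp <- from_i
    from_i <- c(from_i, to_i)
    to_i <- c(to_i, tmp)
    lab_i <- c(lab_i, lab_i)
  }
  ord <- order(from_i, to_i, lab_i)
  from_i <- from_i[ord]; to_i <- to_i[ord]; lab_i <- lab_i[ord]
  deg <- tabulate(from_i, nbins = length(nodes))
  offsets <- c(0L, cumsum(deg))

  sent_idx <- random_walks_cpp(offsets, to_i - 1L, lab_i - 1L,
                               length(nodes), as.integer(num_walks),
                               as.integer(walk_length), as.numeric(seed))
  tokens <- c(nodes, labels)
  sentences <- lapply(sent_idx, function(ix) tokens[ix])
  structure(list(sentences = sentences, seed = seed,
                 params = list(num_walks = num_walks, walk_length = walk_length)),
            class = "walk_corpus")
}

#' Generate an axiom-sentence corpus
#'
#' The axiom-and-annotation corpus used by the OPA2Vec-style method: one
#' sentence per subclass/relation/equivalence axiom (`subject relation
#' object`), and one annotation sentence per entity and per ancestor of each
#' annotated class — the annotation signal propagated over the subsumption
#' hierarchy. With `labels = TRUE`, each class also contributes a sentence of
#' its id followed by its label words (the natural-language side of the
#' ontology; full definition text mining is out of scope).
#'
#' @param graph A [phenont] ontology.
#' @param corpora List of `annotation_corpus` objects.
#' @param labels Include class-label word sentences.
#' @return A `walk_corpus`.
#' @export
generate_axiom_sentences <- function(graph, corpora = list(), labels = TRUE) {
  stopifnot(inherits(graph, "phenont"))
  if (inherits(corpora, "annotation_corpus")) corpora <- list(corpora)
  sentences <- c(
    purrr::pmap(list(graph$subclass_edges$child, graph$subclass_edges$parent),
                function(c, p) c(c, "is_a", p)),
    purrr::pmap(list(graph$relation_edges$subject, graph$relation_edges$relation,
                     graph$relation_edges$object),
                function(s, r, o) c(s, r, o)),
    purrr::pmap(list(graph$equivalence_pairs$a, graph$equivalence_pairs$b),
                function(a, b) c(a, "equivalent_to", b)))
  for (co in corpora) {
    for (e in names(co$propagated)) {
      for (cl in co$propagated[[e]]) {
        sentences[[length(sentences) + 1L]] <- c(e, "has_phenotype", cl)
      }
    }
  }
  if (labels) {
    words <- strsplit(tolower(graph$classes$label), "\\s+")
    lab_sent <- purrr::map2(graph$classes$id, words, function(id, w) c(id, w))
    sentences <- c(sentences, lab_sent)
  }
  structure(list(sentences = sentences, seed = NA_integer_,
                 params = list(labels = labels)),
            class = "walk_corpus")
}

#' @export
print.walk_corpus <- function(x, ...) {
  cat(sprintf("<walk_corpus> %d sentences, %d tokens\n",
              length(x$sentences), sum(lengths(x$sentences))))
  invisible(x)
}

#' Train skip-gram embeddings on a token corpus
#'
#' Skip-gram with negative sampling over the corpus sentences (word2vec
#' objective), trained single-threaded so that a fixed seed gives
#' bit-identical vectors. Tokens occurring fewer than `mincount` times are
#' dropped from the vocabulary; `mincount = 0` keeps everything.
#'
#' @param corpus A `walk_corpus`.
#' @param dim Embedding dimensionality.
#' @param window Context window half-width.
#' @param mincount Minimum token frequency kept in the vocabulary.
#' @param negatives Negative samples per positive pair.
#' @param epochs Passes over the corpus.
#' @param learning_rate Initial learning rate (decays linearly).
#' @param seed Integer seed.
#' @param required_tokens Tokens (typically every gene and disease id) that
#'   must survive the `mincount` cut; missing ones raise an error listing
#'   them.
#' @return An `embedding_table`: numeric matrix (tokens in rows) with the
#'   training parameters attached.
#' @export
train_skipgram <- function(corpus, dim = 100L, window = 5L, mincount = 1L,
                           negatives = 5L, epochs = 10L, learning_rate = 0.025,
                           seed = 1L, required_tokens = NULL) {
  stopifnot(inherits(corpus, "walk_corpus"), dim >= 1L, window >= 1L,
            negatives >= 1L, epochs >= 1L)
  if (!length(corpus$sentences)) abort("empty corpus")
  tok <- unlist(corpus$sentences, use.names = FALSE)
  freq <- table(tok)
  vocab <- names(freq)[as.integer(freq) >= max(1L, mincount)]
  if (!is.null(required_tokens)) {
    missing <- setdiff(required_tokens, vocab)
    if (length(missing)) {
      abort(sprintf("required token(s) below mincount or absent: %s",
                    paste(head(missing, 10L), collapse = ", ")))
    }
  }
  vocab <- sort(vocab)
  vfreq <- as.numeric(freq[vocab])
  sent_i <- lapply(corpus$sentences, function(s) {
    ix <- match(s, vocab)
    as.integer(ix[!is.na(ix)] - 1L)
  })
  sent_i <- sent_i[lengths(sent_i) > 0L]
  vec <- sgns_train_cpp(sent_i, length(vocab), vfreq, as.integer(dim),
                        as.integer(window), as.integer(negatives),
                        as.integer(epochs), learning_rate, as.numeric(seed))
  rownames(vec) <- vocab
  structure(vec, training_params = list(dim = dim, window = window,
                                        mincount = mincount,
                                        negatives = negatives, epochs = epochs,
                                        learning_rate = learning_rate,
                                        seed = seed),
            class = c("embedding_table", class(vec)))
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d tokens x %d dims\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Cosine similarity matrix between gene and disease embeddings
#'
#' @param embeddings An `embedding_table` (or any numeric matrix with token
#'   rownames).
#' @param gene_ids,disease_ids Tokens to compare; all must be present.
#' @return A `similarity_matrix` with method `"cosine"`. A zero vector has
#'   similarity 0 against everything by convention.
#' @export
cosine_similarity_matrix <- function(embeddings, gene_ids, disease_ids) {
  missing <- setdiff(c(gene_ids, disease_ids), rownames(embeddings))
  if (length(missing)) {
    abort(sprintf("id(s) missing from embeddings: %s",
                  paste(head(missing, 10L), collapse = ", ")))
  }
  G <- unclass(embeddings)[gene_ids, , drop = FALSE]
  D <- unclass(embeddings)[disease_ids, , drop = FALSE]
  norm_rows <- function(m) {
    n <- sqrt(rowSums(m^2))
    n[n == 0] <- 1  # zero vectors stay zero, giving similarity 0
    m / n
  }
  vals <- norm_rows(G) %*% t(norm_rows(D))
  rownames(vals) <- gene_ids
  colnames(vals) <- disease_ids
  new_similarity_matrix(vals, "cosine")
}
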