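#' Rank genes per disease from a similarity matrix
#'
#' For each requested disease, sorts the full gene universe by descending
#' score, breaking ties by ascending gene id so rankings are deterministic.
#' Positives are marked from the truth table when given.
#'
#' @param sim A `similarity_matrix` (genes x diseases) or a long tibble with
#'   columns `gene_id`, `disease_id`, `score`.
#' @param truth Optional tibble of known associations (`gene_id`,
#'   `disease_id`).
#' @param diseases Diseases to rank; default all in `sim`. Unknown ids error.
#' @return A `disease_rankings` tibble: `disease_id`, `gene_id`, `score`,
#'   `positive`, `rank`, sorted best-first within disease.
#' @export
rank_genes <- function(sim, truth = NULL, diseases = NULL) {
  long <- if (inherits(sim, "similarity_matrix")) tidy(sim)[1:3] else
    as_tibble(sim)[, c("gene_id", "disease_id", "score")]
  have <- unique(long$disease_id)
  diseases <- diseases %||% sort(have)
  unknown <- setdiff(diseases, have)
  if (length(unknown)) {
    abort(sprintf("unknown disease id(s): %s", paste(head(unknown, 5L), collapse = ", ")))
  }
  long <- long[long$disease_id %in% diseases, ]
  key <- if (!is.null(truth)) paste(truth$gene_id, truth$disease_id) else character(0L)
  long$positive <- paste(long$gene_id, long$disease_id) %in% key
  out <- long |>
    arrange(.data$disease_id, dplyr::desc(.data$score), .data$gene_id) |>
    group_by(.data$disease_id) |>
    mutate(rank = dplyr::row_number()) |>
    ungroup()
  structure(out, class = c("disease_rankings", class(out)))
}

#' Disease-independent naive ranking by summed information content
#'
#' The naive classifier scores each gene by the sum of the information
#' content of its direct phenotype annotations and predicts the same ranked
#' list for every disease. It carries no disease-specific signal at all, so
#' any predictive performance it shows measures annotation bias in the
#' corpus: genes annotated with more, and more specific, phenotypes rank
#' higher regardless of the disease asked about.
#'
#' @param ic An [compute_ic()] table (classes absent from it contribute 0).
#' @param gene_corpus A gene `annotation_corpus`.
#' @param disease_ids Diseases to replicate the ranking for.
#' @param truth Optional association tibble for marking positives.
#' @return A `disease_rankings` tibble.
#' @export
naive_rank <- function(ic, gene_corpus, disease_ids, truth = NULL) {
  stopifnot(inherits(gene_corpus, "annotation_corpus"))
  totals <- total_ic(gene_corpus, ic)
  long <- tidyr::crossing(disease_id = disease_ids,
                          tibble(gene_id = totals$gene_id, score = totals$total_ic))
  rank_genes(long, truth = truth, diseases = disease_ids)
}
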