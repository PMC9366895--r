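#' Total information content of each gene's phenotype annotations
#'
#' Sums the IC of each gene's direct (canonicalized) annotation classes;
#' classes absent from the IC table contribute 0, and genes without
#' annotations total 0.
#'
#' @param gene_corpus A gene `annotation_corpus`.
#' @param ic An [compute_ic()] table.
#' @return A tibble (`gene_id`, `n_annotations`, `total_ic`).
#' @export
total_ic <- function(gene_corpus, ic) {
  stopifnot(inherits(gene_corpus, "annotation_corpus"), inherits(ic, "ic_table"))
  icv <- ic_vector(ic)
  sums <- vapply(gene_corpus$direct_canonical, function(cls) {
    vals <- icv[cls]
    sum(vals[!is.na(vals)])
  }, numeric(1L))
  tibble(gene_id = names(sums),
         n_annotations = unname(lengths(gene_corpus$direct_canonical)),
         total_ic = unname(sums))
}

#' Test for study bias in annotation totals
#'
#' Unpaired one-tailed Student's t-test (pooled variance) of whether genes
#' whose (ortholog's) human counterpart is disease-associated carry a higher
#' total annotation information content than the remaining genes. A
#' significant result indicates study bias: disease-gene orthologs are
#' annotated with more, and more specific, phenotypes, which a
#' disease-independent classifier can exploit.
#'
#' @param totals A [total_ic()] table (or any tibble with `gene_id` and
#'   `total_ic`).
#' @param disease_gene_ids Gene ids forming the disease-associated group.
#' @return A one-row tibble: `statistic` (t), `p.value` (one-tailed,
#'   disease group greater), `mean_disease`, `mean_other`, `n_disease`,
#'   `n_other`.
#' @export
study_bias_test <- function(totals, disease_gene_ids) {
  x <- totals$total_ic[totals$gene_id %in% disease_gene_ids]
  y <- totals$total_ic[!totals$gene_id %in% disease_gene_ids]
  if (length(x) < 2L || length(y) < 2L) {
    abort("each group needs at least two genes")
  }
  tt <- t.test(x, y, alternative = "greater", var.equal = TRUE)
  tibble(statistic = unname(tt$statistic), p.value = tt$p.value,
         mean_disease = mean(x), mean_other = mean(y),
         n_disease = length(x), n_other = length(y))
}

#' Information-content gap to the nearest informative human superclass
#'
#' For each model-organism phenotype class of a gene, the gap is the absolute
#' difference between the class's IC and the IC of its most informative
#' human superclass (an ancestor whose canonical class carries a human
#' member, the class itself included when it is bridged to a human class by
#' equivalence). Classes with no human superclass contribute 0, as do classes
#' absent from the IC table. Genes annotated with deep, species-specific
#' classes that connect to humans only through shallow ancestors accumulate
#' large gaps — the structural penalty that distance-based similarity methods
#' convert into spuriously low similarity for heavily annotated genes.
#'
#' @param gene_phenotypes Character vector of model-organism class ids (a
#'   gene's direct annotations).
#' @param ic An [compute_ic()] table over the union corpus.
#' @param graph A [phenont] ontology.
#' @param aggregate `"sum"` (default, matching per-gene total-IC framing) or
#'   `"mean"`.
#' @return A single number; 0 with a warning for an empty phenotype set.
#' @export
ic_gap <- function(gene_phenotypes, ic, graph, aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  if (!length(gene_phenotypes)) {
    warn("empty phenotype set; ic_gap is 0")
    return(0)
  }
  icv <- ic_vector(ic)
  can_sp <- canonical_species_map(graph)
  gaps <- vapply(gene_phenotypes, function(cl) {
    can <- canonical_of(graph, cl)
    ic_c <- unname(icv[can])
    if (is.na(ic_c)) return(0)
    anc <- ancestors(graph, cl)
    human <- anc[vapply(anc, function(a) "human" %in% can_sp[[a]], logical(1L))]
    vals <- icv[human]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) 0 else abs(ic_c - max(vals))
  }, numeric(1L))
  if (aggregate == "sum") sum(gaps) else mean(gaps)
}
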