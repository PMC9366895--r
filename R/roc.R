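#' Macro-averaged ROC from per-disease gene rankings
#'
#' Implements the rank-based protocol: for each disease, true- and
#' false-positive rates are computed at every rank k in 0..n over a shared
#' gene universe of size n; the curves are then averaged pointwise across
#' diseases at each rank and the area taken by the trapezoidal rule. For a
#' single disease this equals the Mann-Whitney statistic
#' (probability that a positive outranks a negative). 0.5 is the level of a
#' random ranking, 1.0 a perfect one.
#'
#' Diseases with no positive in the universe cannot be evaluated and are
#' excluded with a warning; rankings over differently sized universes are an
#' error.
#'
#' @param rankings A `disease_rankings` tibble from [rank_genes()],
#'   [naive_rank()] or scores converted with [rank_genes()].
#' @return A `roc_result`: list with `points` (tibble `rank`, `fpr`, `tpr`),
#'   `auc`, `n_diseases`, `per_disease` (per-disease AUCs) and the per-disease
#'   rate matrices used for bootstrap comparison.
#' @export
roc_from_rankings <- function(rankings) {
  parts <- split(as_tibble(rankings), rankings$disease_id)
  sizes <- unique(vapply(parts, nrow, integer(1L)))
  if (length(sizes) != 1L) {
    abort(sprintf("rankings use different gene universe sizes: %s",
                  paste(sizes, collapse = ", ")))
  }
  n <- sizes
  n_pos <- vapply(parts, function(p) sum(p$positive), integer(1L))
  drop <- n_pos == 0L | n_pos == n
  if (any(drop)) {
    warn(sprintf("excluding %d disease(s) without both positives and negatives",
                 sum(drop)))
    parts <- parts[!drop]
  }
  if (!length(parts)) abort("no evaluable disease rankings")

  tpr_m <- matrix(0, length(parts), n + 1L)
  fpr_m <- matrix(0, length(parts), n + 1L)
  for (i in seq_along(parts)) {
    p <- parts[[i]][order(parts[[i]]$rank), ]
    pos_cum <- c(0L, cumsum(p$positive))
    neg_cum <- c(0L, cumsum(!p$positive))
    tpr_m[i, ] <- pos_cum / pos_cum[[n + 1L]]
    fpr_m[i, ] <- neg_cum / neg_cum[[n + 1L]]
  }
  tpr <- colMeans(tpr_m)
  fpr <- colMeans(fpr_m)
  per_auc <- vapply(seq_along(parts), function(i)
    trapezoid_auc(fpr_m[i, ], tpr_m[i, ]), numeric(1L))

  structure(list(points = tibble(rank = 0:n, fpr = fpr, tpr = tpr),
                 auc = trapezoid_auc(fpr, tpr),
                 n_diseases = length(parts),
                 per_disease = tibble(disease_id = names(parts), auc = per_auc),
                 tpr_matrix = tpr_m, fpr_matrix = fpr_m,
                 disease_ids = names(parts)),
            class = "roc_result")
}

trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (head(tpr, -1L) + tpr[-1L]) / 2)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> macro ROCAUC %.4f over %d diseases (universe %d genes)\n",
              x$auc, x$n_diseases, nrow(x$points) - 1L))
  invisible(x)
}

#' @export
tidy.roc_result <- function(x, ...) x$points

#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, n_diseases = x$n_diseases,
         n_genes = nrow(x$points) - 1L)
}

#' Plot a macro-averaged ROC curve
#'
#' @param object A `roc_result`.
#' @param ... Further `roc_result`s to overlay, named for the legend.
#' @return A ggplot object.
#' @export
autoplot.roc_result <- function(object, ...) {
  extra <- list(...)
  extra <- extra[vapply(extra, inherits, logical(1L), "roc_result")]
  plot_roc_curves(c(list(object), extra))
}

#' Plot several ROC curves together
#'
#' @param curves A (preferably named) list of `roc_result` objects.
#' @return A ggplot object with one curve per method, AUC in the legend.
#' @export
plot_roc_curves <- function(curves) {
  stopifnot(all(vapply(curves, inherits, logical(1L), "roc_result")))
  nms <- names(curves) %||% rep("", length(curves))
  nms[nms == ""] <- sprintf("method %d", which(nms == ""))
  df <- purrr::map2_dfr(curves, nms, function(r, nm)
    mutate(r$points, method = sprintf("%s (AUC %.3f)", nm, r$auc)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$method)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Compare two macro-averaged ROCAUCs by paired bootstrap over diseases
#'
#' Both results must cover the same disease set. Diseases are resampled with
#' replacement; the macro AUC of each method is recomputed on each resample
#' and the two-sided p-value read off the bootstrap distribution of the
#' difference (with the usual +1 small-sample correction). Deterministic for
#' a fixed seed.
#'
#' @param rocs_a,rocs_b `roc_result` objects over the same diseases.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @return A one-row tibble: `auc_a`, `auc_b`, `estimate` (auc_a - auc_b),
#'   `p.value`, `n_boot`, `n_diseases`.
#' @export
compare_auc <- function(rocs_a, rocs_b, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(rocs_a, "roc_result"), inherits(rocs_b, "roc_result"))
  if (!setequal(rocs_a$disease_ids, rocs_b$disease_ids)) {
    abort("the two ROC results cover different disease sets")
  }
  ord <- match(rocs_a$disease_ids, rocs_b$disease_ids)
  nd <- length(rocs_a$disease_ids)
  diffs <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      ix <- sample.int(nd, nd, replace = TRUE)
      a <- trapezoid_auc(colMeans(rocs_a$fpr_matrix[ix, , drop = FALSE]),
                         colMeans(rocs_a$tpr_matrix[ix, , drop = FALSE]))
      bb <- trapezoid_auc(colMeans(rocs_b$fpr_matrix[ord[ix], , drop = FALSE]),
                          colMeans(rocs_b$tpr_matrix[ord[ix], , drop = FALSE]))
      a - bb
    }, numeric(1L))
  })
  p <- min(1, 2 * min((sum(diffs <= 0) + 1) / (n_boot + 1),
                      (sum(diffs >= 0) + 1) / (n_boot + 1)))
  tibble(auc_a = rocs_a$auc, auc_b = rocs_b$auc,
         estimate = rocs_a$auc - rocs_b$auc,
         p.value = p, n_boot = as.integer(n_boot), n_diseases = nd)
}
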