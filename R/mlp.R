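#' Configuration for supervised gene-disease prediction
#'
#' One-hidden-layer perceptron over concatenated gene and disease embedding
#' vectors: the hidden layer is half the input width, the output a sigmoid
#' unit scoring association, trained full-batch with adaptive-moment gradient
#' descent. Defaults follow the standard setup for this task: learning rate
#' 0.001, 300 iterations, five sampled negatives per positive, 10-fold
#' cross-validation stratified by disease.
#'
#' @param hidden_fraction Hidden width as a fraction of the input width.
#' @param learning_rate Adam step size.
#' @param max_iterations Training epochs (passes over the training pairs).
#' @param batch_size Minibatch size; capped at the training-set size.
#' @param negatives_per_positive Negatives sampled per positive pair.
#' @param folds Cross-validation folds (>= 2).
#' @param holdout `"diseases"` (default; whole diseases held out, preventing
#'   any leakage into per-disease ranking) or `"associations"` (association
#'   rows partitioned; diseases may appear on both sides).
#' @param seed Integer seed controlling folds, negative sampling and weight
#'   initialization.
#' @return A `supervised_config` list.
#' @export
supervised_config <- function(hidden_fraction = 0.5, learning_rate = 0.001,
                              max_iterations = 300L, batch_size = 200L,
                              negatives_per_positive = 5L,
                              folds = 10L, holdout = c("diseases", "associations"),
                              seed = 1L) {
  holdout <- match.arg(holdout)
  stopifnot(hidden_fraction > 0, learning_rate > 0, max_iterations >= 1L,
            batch_size >= 1L, negatives_per_positive >= 1L, folds >= 2L)
  structure(list(hidden_fraction = hidden_fraction,
                 learning_rate = learning_rate,
                 max_iterations = as.integer(max_iterations),
                 batch_size = as.integer(batch_size),
                 negatives_per_positive = as.integer(negatives_per_positive),
                 folds = as.integer(folds), holdout = holdout,
                 seed = as.integer(seed)),
            class = "supervised_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# minibatch Adam training of a 1-hidden-layer (ReLU) network with sigmoid
# output and binary cross-entropy loss; max_iterations counts epochs
mlp_fit <- function(X, y, hidden, lr, iters, seed, batch_size = 200L) {
  p <- ncol(X)
  n <- nrow(X)
  batch_size <- min(batch_size, n)
  with_seed(seed, {
    W1 <- matrix(rnorm(p * hidden, sd = sqrt(2 / p)), p, hidden)
    W2 <- matrix(rnorm(hidden, sd = sqrt(1 / hidden)), hidden, 1L)
    perms <- lapply(seq_len(iters), function(i) sample.int(n))
  })
  params <- list(W1 = W1, b1 = matrix(0, 1L, hidden), W2 = W2, b2 = 0)
  m <- lapply(params, function(x) x * 0)
  v <- lapply(params, function(x) x * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  loss <- numeric(iters)
  starts <- seq.int(1L, n, by = batch_size)
  t_adam <- 0L

  for (ep in seq_len(iters)) {
    ord <- perms[[ep]]
    ep_loss <- 0
    for (s in starts) {
      ix <- ord[s:min(s + batch_size - 1L, n)]
      Xb <- X[ix, , drop = FALSE]
      yb <- y[ix]
      nb <- length(ix)
      Z1 <- sweep(Xb %*% params$W1, 2L, -params$b1[1L, ])
      H <- pmax(Z1, 0)
      pr <- sigmoid(drop(H %*% params$W2) + params$b2)
      pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
      ep_loss <- ep_loss - sum(yb * log(pr) + (1 - yb) * log(1 - pr))

      dz2 <- matrix((pr - yb) / nb, nb, 1L)
      gW2 <- t(H) %*% dz2
      gb2 <- sum(dz2)
      dZ1 <- (dz2 %*% t(params$W2)) * (Z1 > 0)
      grads <- list(W1 = t(Xb) %*% dZ1, b1 = matrix(colSums(dZ1), 1L),
                    W2 = gW2, b2 = gb2)
      t_adam <- t_adam + 1L
      for (nm in names(params)) {
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * grads[[nm]]
        v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * grads[[nm]]^2
        mhat <- m[[nm]] / (1 - beta1^t_adam)
        vhat <- v[[nm]] / (1 - beta2^t_adam)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    loss[ep] <- ep_loss / n
  }
  c(params, list(loss = loss))
}

mlp_predict <- function(model, X) {
  H <- pmax(sweep(X %*% model$W1, 2L, -model$b1[1L, ]), 0)
  sigmoid(drop(H %*% model$W2) + model$b2)
}

#' Supervised gene-disease association scores under cross-validation
#'
#' Trains the configured perceptron per fold on the training diseases'
#' positive pairs plus uniformly sampled negatives (genes not associated with
#' the positive's disease, sampled without replacement within a disease and
#' re-sampled per fold), then scores every (gene, held-out disease) pair with
#' the sigmoid output. With the default disease hold-out, no pair involving a
#' held-out disease is ever seen in training; [audit_fold_leakage()] verifies
#' this from the recorded fold bookkeeping.
#'
#' @param embeddings An `embedding_table` (or matrix with token rownames)
#'   containing every gene and disease id.
#' @param associations Tibble of positive pairs (`gene_id`, `disease_id`).
#' @param config A [supervised_config()].
#' @param genes Gene universe to rank; default the genes in `associations`.
#' @return A tibble (`disease_id`, `gene_id`, `score`, `fold`) with
#'   attributes `fold_assignment`, `train_diseases` (per fold) and `loss`
#'   (per-fold training loss traces).
#' @export
supervised_scores <- function(embeddings, associations, config = supervised_config(),
                              genes = NULL) {
  stopifnot(inherits(config, "supervised_config"))
  associations <- distinct(as_tibble(associations)[, c("gene_id", "disease_id")])
  genes <- sort(genes %||% unique(associations$gene_id))
  diseases <- sort(unique(associations$disease_id))
  missing <- setdiff(c(genes, diseases), rownames(embeddings))
  if (length(missing)) {
    abort(sprintf("id(s) missing from embeddings: %s",
                  paste(head(missing, 10L), collapse = ", ")))
  }
  if (length(diseases) < config$folds) {
    abort(sprintf("fewer diseases (%d) than folds (%d)",
                  length(diseases), config$folds))
  }
  E <- unclass(embeddings)

  if (config$holdout == "diseases") {
    fold_of <- with_seed(fan_seed(config$seed, 1L),
                         sample(rep(seq_len(config$folds),
                                    length.out = length(diseases))))
    names(fold_of) <- diseases
  } else {
    row_fold <- with_seed(fan_seed(config$seed, 1L),
                          sample(rep(seq_len(config$folds),
                                     length.out = nrow(associations))))
  }

  pos_genes_of <- split(associations$gene_id, associations$disease_id)
  out <- vector("list", config$folds)
  losses <- vector("list", config$folds)
  train_diseases <- vector("list", config$folds)

  for (f in seq_len(config$folds)) {
    if (config$holdout == "diseases") {
      test_d <- diseases[fold_of[diseases] == f]
      train_pos <- associations[!associations$disease_id %in% test_d, ]
    } else {
      test_rows <- row_fold == f
      test_d <- sort(unique(associations$disease_id[test_rows]))
      train_pos <- associations[!test_rows, ]
    }
    if (nrow(train_pos) == 0L) {
      abort(sprintf("fold %d has zero training positives; use fewer folds", f))
    }
    train_diseases[[f]] <- sort(unique(train_pos$disease_id))

    neg <- with_seed(fan_seed(config$seed, 100L + f), {
      purrr::map_dfr(split(train_pos, train_pos$disease_id), function(tp) {
        d <- tp$disease_id[[1L]]
        pool <- setdiff(genes, pos_genes_of[[d]])
        want <- min(length(pool), config$negatives_per_positive * nrow(tp))
        tibble(gene_id = sample(pool, want), disease_id = d)
      })
    })
    Xtr <- cbind(E[c(train_pos$gene_id, neg$gene_id), , drop = FALSE],
                 E[c(train_pos$disease_id, neg$disease_id), , drop = FALSE])
    ytr <- c(rep(1, nrow(train_pos)), rep(0, nrow(neg)))
    hidden <- max(1L, round(ncol(Xtr) * config$hidden_fraction))
    model <- mlp_fit(Xtr, ytr, hidden, config$learning_rate,
                     config$max_iterations, fan_seed(config$seed, 200L + f),
                     batch_size = config$batch_size)
    losses[[f]] <- model$loss

    grid <- tidyr::crossing(disease_id = test_d, gene_id = genes)
    Xte <- cbind(E[grid$gene_id, , drop = FALSE],
                 E[grid$disease_id, , drop = FALSE])
    out[[f]] <- mutate(grid, score = mlp_predict(model, Xte), fold = f)
  }

  res <- bind_rows(out)
  attr(res, "fold_assignment") <-
    if (config$holdout == "diseases")
      tibble(disease_id = diseases, fold = unname(fold_of[diseases])) else
      distinct(select(res, "disease_id", "fold"))
  attr(res, "train_diseases") <- train_diseases
  attr(res, "loss") <- losses
  attr(res, "config") <- config
  res
}

#' Audit cross-validation fold assignments for leakage
#'
#' Confirms that no disease scored in a fold was part of that fold's training
#' diseases (only meaningful for the disease hold-out mode, where it must
#' hold exactly).
#'
#' @param scores A [supervised_scores()] result.
#' @return `TRUE` if clean; otherwise a tibble of offending
#'   (disease, fold) pairs.
#' @export
audit_fold_leakage <- function(scores) {
  train <- attr(scores, "train_diseases")
  scored <- distinct(as_tibble(scores)[, c("disease_id", "fold")])
  bad <- scored[purrr::map2_lgl(scored$disease_id, scored$fold,
                                function(d, f) d %in% train[[f]]), ]
  if (nrow(bad) == 0L) TRUE else bad
}
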