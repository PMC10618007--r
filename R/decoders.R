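#' Per-trial odor feature matrix
#'
#' Flattens a significance mask's baseline-subtracted response values into
#' the decoder feature representation: one row per (odor, trial), one
#' column per cell, with the odor as the class label.
#'
#' @param mask a [detect_significant()] result (or [activity_mask()]).
#' @return An object of class `odor_features`: numeric matrix `x`
#'   (trials x cells) and factor `odor`.
#' @export
response_features <- function(mask) {
  stopifnot(inherits(mask, "significance_mask"))
  d <- dim(mask$response_values)
  x <- do.call(rbind, lapply(seq_len(d[2]), function(o)
    t(mask$response_values[, o, , drop = TRUE])))
  odor <- factor(rep(mask$labels, each = d[3]), levels = mask$labels)
  colnames(x) <- mask$cell_ids
  structure(list(x = x, odor = odor, labels = mask$labels),
            class = "odor_features")
}

#' Mask features by reliability class
#'
#' For each odor, the trials of that odor keep only the cells belonging to
#' the requested class *for that odor*; all other cells are set to zero. A
#' cell reliable for one odor and unreliable for another is kept in the
#' first odor's trials and zeroed in the second's. Masking is idempotent.
#'
#' @param features an [response_features()] object (or a
#'   `significance_mask`, converted on the fly).
#' @param table the matching [classify_cells()] result.
#' @param class `"reliable"`, `"unreliable"`, or `"all"` (all responsive
#'   cells, i.e. only silent cells zeroed).
#' @return The masked `odor_features`.
#' @export
mask_by_class <- function(features, table, class = c("all", "reliable", "unreliable")) {
  if (inherits(features, "significance_mask"))
    features <- response_features(features)
  stopifnot(inherits(features, "odor_features"),
            inherits(table, "reliability_table"))
  class <- match.arg(class)
  n_cells <- ncol(features$x)
  cls <- matrix(as.character(table$class), n_cells,
                length(features$labels))
  for (o in seq_along(features$labels)) {
    keep <- if (class == "all") cls[, o] != "silent" else cls[, o] == class
    rows <- features$odor == features$labels[o]
    features$x[rows, !keep] <- 0
  }
  features$masked_class <- class
  features
}

# Class-probability matrices for the three decoders; rows sum to one.
decoder_probs <- function(train, test, decoder, knn_k, svm_cost) {
  lv <- levels(train$odor)
  switch(decoder,
    lda = {
      # drop features with zero pooled within-class variance (lda rejects them)
      resid <- train$x - apply(train$x, 2, stats::ave, train$odor)
      keep <- apply(resid, 2, stats::sd) > 1e-10
      if (!any(keep)) stop("no usable features for LDA")
      fit <- suppressWarnings(MASS::lda(train$x[, keep, drop = FALSE],
                                        grouping = train$odor))
      p <- stats::predict(fit, test$x[, keep, drop = FALSE])$posterior
      p[, lv, drop = FALSE]
    },
    knn = {
      fit <- caret::knn3(train$x, train$odor, k = knn_k)
      stats::predict(fit, test$x, type = "prob")[, lv, drop = FALSE]
    },
    svm = {
      keep <- apply(train$x, 2, stats::sd) > 0  # constant columns break scaling
      fit <- e1071::svm(train$x[, keep, drop = FALSE], train$odor,
                        kernel = "linear", cost = svm_cost)
      dv <- attr(stats::predict(fit, test$x[, keep, drop = FALSE],
                                decision.values = TRUE),
                 "decision.values")
      # mean signed pairwise decision value per class, softmax-calibrated
      score <- matrix(0, nrow(test$x), length(lv), dimnames = list(NULL, lv))
      for (cn in colnames(dv)) {
        pair <- strsplit(cn, "/", fixed = TRUE)[[1]]
        score[, pair[1]] <- score[, pair[1]] + dv[, cn]
        score[, pair[2]] <- score[, pair[2]] - dv[, cn]
      }
      score <- score / (length(lv) - 1)
      p <- exp(score - apply(score, 1, max))
      p / rowSums(p)
    })
}

#' Cross-validated odor decoding
#'
#' Stratified k-fold cross-validation (fold size 20% of each odor's trials
#' by default, i.e. 5 folds) of a linear discriminant, k-nearest-neighbour
#' or linear-kernel support-vector decoder. Predictions over all held-out
#' folds are pooled into one prediction matrix.
#'
#' @param features an (optionally class-masked) [response_features()]
#'   object.
#' @param decoder `"lda"`, `"knn"`, or `"svm"`.
#' @param fold_fraction held-out fraction per fold (default 0.2).
#' @param seed integer seed for the fold assignment.
#' @param knn_k neighbours for kNN (default 3).
#' @param svm_cost SVM regularization constant (default 1).
#' @return An object of class `prediction_matrix`: `prob` (pooled test
#'   trials x odor classes, rows sum to 1), `truth`, `accuracy`, and the
#'   decoder metadata.
#' @export
kfold_evaluate <- function(features, decoder = c("lda", "knn", "svm"),
                           fold_fraction = 0.2, seed = 1L,
                           knn_k = 3L, svm_cost = 1) {
  stopifnot(inherits(features, "odor_features"))
  decoder <- match.arg(decoder)
  n_folds <- max(2L, round(1 / fold_fraction))
  per_odor <- table(features$odor)
  if (any(per_odor < 2)) stop("every odor needs at least 2 trials")
  fold <- integer(length(features$odor))
  with_seed_if(seed, {
    for (lv in levels(features$odor)) {
      idx <- sample(which(features$odor == lv))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  probs <- list(); truths <- list()
  for (f in sort(unique(fold))) {
    tr <- list(x = features$x[fold != f, , drop = FALSE],
               odor = droplevels(features$odor[fold != f]))
    if (nlevels(tr$odor) < nlevels(features$odor))
      stop("a fold lost an entire odor class; reduce `fold_fraction`")
    te <- list(x = features$x[fold == f, , drop = FALSE],
               odor = features$odor[fold == f])
    p <- decoder_probs(tr, te, decoder, knn_k, svm_cost)
    probs[[length(probs) + 1L]] <- p
    truths[[length(truths) + 1L]] <- te$odor
  }
  prob <- do.call(rbind, probs)
  truth <- factor(unlist(lapply(truths, as.character)),
                  levels = levels(features$odor))
  predicted <- factor(colnames(prob)[max.col(prob, ties.method = "first")],
                      levels = levels(truth))
  structure(list(prob = prob, truth = truth, predicted = predicted,
                 accuracy = mean(predicted == truth),
                 decoder = decoder, n_folds = n_folds,
                 masked_class = features$masked_class,
                 params = list(knn_k = knn_k, svm_cost = svm_cost)),
            class = "prediction_matrix")
}

#' @export
print.prediction_matrix <- function(x, ...) {
  cat("<prediction_matrix> ", x$decoder,
      if (!is.null(x$masked_class)) paste0(" (", x$masked_class, " cells)"),
      ": accuracy ", signif(x$accuracy, 3), " over ", length(x$truth),
      " test trials\n", sep = "")
  invisible(x)
}

#' Rank-based pairwise AUC
#'
#' For an ordered class pair (i, j): pool the predicted probabilities of
#' being class i for the test trials of classes i and j, rank them
#' (midranks on ties), and with `S_i` the rank sum of the class-i trials
#' compute `AUC(i|j) = (S_i - n_i (n_i + 1) / 2) / (n_i n_j)` -- the
#' Mann-Whitney estimate of the probability that a class-i trial outscores
#' a class-j trial. The unordered pair score `A(i, j)` averages both
#' directions.
#'
#' @param pred a [kfold_evaluate()] prediction matrix.
#' @param i,j class labels or indices.
#' @return A list: `auc_ij` (AUC(i|j)), `auc_ji`, and their mean `A`.
#' @export
pairwise_auc <- function(pred, i, j) {
  stopifnot(inherits(pred, "prediction_matrix"))
  lv <- levels(pred$truth)
  if (is.numeric(i)) i <- lv[i]
  if (is.numeric(j)) j <- lv[j]
  one_dir <- function(a, b) {
    fa <- pred$prob[pred$truth == a, a]
    fb <- pred$prob[pred$truth == b, a]
    na <- length(fa); nb <- length(fb)
    if (na < 1 || nb < 1) stop("need at least one test trial per class")
    r <- rank(c(fa, fb))  # midranks
    (sum(r[seq_len(na)]) - na * (na + 1) / 2) / (na * nb)
  }
  auc_ij <- one_dir(i, j)
  auc_ji <- one_dir(j, i)
  list(auc_ij = auc_ij, auc_ji = auc_ji, A = (auc_ij + auc_ji) / 2)
}

#' All-to-all AUC
#'
#' Unweighted mean of the unordered pair scores `A(i, j)` over all class
#' pairs: the single-number separability summary of a multiclass decoder.
#'
#' @param pred a [kfold_evaluate()] prediction matrix.
#' @return Numeric scalar in [0, 1].
#' @export
a2a_auc <- function(pred) {
  stopifnot(inherits(pred, "prediction_matrix"))
  lv <- levels(pred$truth)
  if (length(lv) < 2) stop("need at least 2 classes")
  vals <- c()
  for (a in seq_along(lv)[-length(lv)])
    for (b in (a + 1):length(lv))
      vals <- c(vals, pairwise_auc(pred, lv[a], lv[b])$A)
  mean(vals)
}
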