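#' Binary pair-feature matrix
#'
#' Encodes each sample by the 0/1 indicators of a fixed pair panel; the
#' representation every benchmark family (LDA, linear SVM, random forest)
#' is trained on, so all of them inherit the rank invariance of the pair
#' indicator.
#'
#' @param dataset an [expr_dataset()].
#' @param pairs a data frame with columns `gene_i`, `gene_j`.
#' @return an object of class `pair_features`: binary `features` matrix
#'   (samples x pairs), `pairs`, `sample_ids`.
#' @export
build_pair_features <- function(dataset, pairs) {
  pairs <- as_tibble(pairs)[, c("gene_i", "gene_j")]
  i <- match(pairs$gene_i, gene_ids(dataset))
  j <- match(pairs$gene_j, gene_ids(dataset))
  if (anyNA(i) || anyNA(j)) {
    missing <- unique(c(pairs$gene_i[is.na(i)], pairs$gene_j[is.na(j)]))
    abort(paste0("pair gene(s) absent from dataset: ", paste(missing, collapse = ", ")))
  }
  v <- dataset$values
  feat <- t((v[i, , drop = FALSE] > v[j, , drop = FALSE]) * 1L)
  colnames(feat) <- paste(pairs$gene_i, pairs$gene_j, sep = ">")
  rownames(feat) <- sample_ids(dataset)
  structure(list(features = feat, pairs = pairs, sample_ids = sample_ids(dataset)),
            class = "pair_features")
}

#' @export
print.pair_features <- function(x, ...) {
  cat(sprintf("<pair_features> %d samples x %d binary pair indicators\n",
              nrow(x$features), ncol(x$features)))
  invisible(x)
}

#' @export
as_tibble.pair_features <- function(x, ...) {
  bind_cols(tibble(sample_id = x$sample_ids),
            as_tibble(as.data.frame(x$features)))
}

# Columns safe for LDA: some within-group variation.
informative_columns <- function(X, y) {
  ok <- vapply(seq_len(ncol(X)), function(c) {
    any(tapply(X[, c], y, function(v) stats::var(v) > 0))
  }, logical(1))
  which(ok)
}

fit_family <- function(X, y, family) {
  switch(family,
    lda = {
      keep <- informative_columns(X, y)
      if (!length(keep)) abort("no informative feature for LDA")
      fit <- suppressWarnings(MASS::lda(X[, keep, drop = FALSE], grouping = y))
      list(fit = fit, keep = keep)
    },
    linear_svm = {
      fit <- e1071::svm(X, y, kernel = "linear", cost = 1, scale = FALSE)
      list(fit = fit, keep = seq_len(ncol(X)))
    },
    random_forest = {
      fit <- randomForest::randomForest(X, y, ntree = 300, importance = FALSE)
      list(fit = fit, keep = seq_len(ncol(X)))
    }
  )
}

# Decision scores oriented toward the positive class "KD".
family_scores <- function(fitted, X, family) {
  X <- X[, fitted$keep, drop = FALSE]
  switch(family,
    lda = as.numeric(stats::predict(fitted$fit, X)$posterior[, "KD"]),
    linear_svm = {
      pr <- stats::predict(fitted$fit, X, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      s <- as.numeric(dv[, 1])
      if (!startsWith(colnames(dv)[1], "KD")) s <- -s
      s
    },
    random_forest = as.numeric(stats::predict(fitted$fit, X, type = "prob")[, "KD"])
  )
}

family_labels <- function(fitted, X, family) {
  X <- X[, fitted$keep, drop = FALSE]
  switch(family,
    lda = as.character(stats::predict(fitted$fit, X)$class),
    linear_svm = as.character(stats::predict(fitted$fit, X)),
    random_forest = as.character(stats::predict(fitted$fit, X))
  )
}

# Feature importance ranking (column indices, most important first).
family_importance <- function(X, y, family) {
  switch(family,
    lda = {
      keep <- informative_columns(X, y)
      fit <- suppressWarnings(MASS::lda(X[, keep, drop = FALSE], grouping = y))
      w <- abs(fit$scaling[, 1])
      ranked <- keep[order(-w, seq_along(w))]
      c(ranked, setdiff(seq_len(ncol(X)), ranked))
    },
    linear_svm = {
      fit <- e1071::svm(X, y, kernel = "linear", cost = 1, scale = FALSE)
      w <- abs(as.numeric(crossprod(fit$coefs, fit$SV)))
      order(-w, seq_len(ncol(X)))
    },
    random_forest = {
      fit <- randomForest::randomForest(X, y, ntree = 300, importance = FALSE)
      imp <- randomForest::importance(fit)[, "MeanDecreaseGini"]
      order(-imp, seq_len(ncol(X)))
    }
  )
}

stratified_folds <- function(y, n_folds, seed) {
  with_seed_(seed, {
    fold <- integer(length(y))
    for (lev in levels(y)) {
      idx <- which(y == lev)
      fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
    fold
  })
}

#' Cross-validated feature selection and fit for a benchmark family
#'
#' Stratified n-fold cross-validation over prefix sizes of a per-fold
#' importance ranking (absolute discriminant coefficients for LDA,
#' absolute linear weights for the SVM, Gini impurity importance for the
#' random forest). The subset size with the highest mean CV balanced
#' accuracy (smallest size on ties) is refit on all data using the
#' full-data ranking.
#'
#' @param features a [build_pair_features()] object.
#' @param labels truth labels (`KD`/`DB`/`DV` or `KD`/`FI`), aligned with
#'   the feature rows.
#' @param family `"lda"`, `"linear_svm"` or `"random_forest"`.
#' @param n_folds number of CV folds (default 10).
#' @param seed integer seed.
#' @param size_grid candidate subset sizes (default: a coarse grid up to
#'   the number of pairs).
#' @return an object of class `benchmark_model`.
#' @export
cv_select_and_fit <- function(features, labels,
                              family = c("lda", "linear_svm", "random_forest"),
                              n_folds = 10, seed = 1L, size_grid = NULL) {
  family <- match.arg(family)
  stopifnot(inherits(features, "pair_features"))
  X <- features$features
  y <- factor(ifelse(labels == "KD", "KD", "FI"), levels = c("FI", "KD"))
  if (min(table(y)) < n_folds) {
    abort(sprintf("cannot build %d stratified folds: smallest class has %d samples",
                  n_folds, min(table(y))))
  }
  P <- ncol(X)
  size_grid <- sort(unique(pmin(
    size_grid %||% c(1, 2, 3, 5, 7, 10, 15, 20, 30, 40, 50, 60), P
  )))
  fold <- stratified_folds(y, n_folds, seed)
  ba <- matrix(NA_real_, nrow = n_folds, ncol = length(size_grid))
  for (f in seq_len(n_folds)) {
    tr <- fold != f; te <- !tr
    ranking <- family_importance(X[tr, , drop = FALSE], y[tr], family)
    for (s in seq_along(size_grid)) {
      cols <- ranking[seq_len(size_grid[s])]
      fitted <- fit_family(X[tr, cols, drop = FALSE], y[tr], family)
      pred <- family_labels(fitted, X[te, cols, drop = FALSE], family)
      ba[f, s] <- confusion_metrics(pred, as.character(y[te]), "KD")$balanced_accuracy
    }
  }
  cv <- tibble(size = size_grid, balanced_accuracy = colMeans(ba))
  best_size <- cv$size[which.max(cv$balanced_accuracy)]
  full_ranking <- family_importance(X, y, family)
  cols <- full_ranking[seq_len(best_size)]
  fitted <- fit_family(X[, cols, drop = FALSE], y, family)
  structure(
    list(family = family, fitted = fitted, columns = cols,
         feature_names = colnames(X)[cols],
         pairs = features$pairs[cols, , drop = FALSE],
         cv = cv, best_size = best_size, seed = seed),
    class = "benchmark_model"
  )
}

#' @export
print.benchmark_model <- function(x, ...) {
  cat(sprintf("<benchmark_model> %s over %d pair features (CV-selected)\n",
              x$family, x$best_size))
  invisible(x)
}

#' Evaluate a benchmark model on a pair-feature matrix
#'
#' @param model a [cv_select_and_fit()] model.
#' @param features a [build_pair_features()] object built over the same
#'   pair panel the model was trained on.
#' @param labels truth labels aligned with the feature rows.
#' @return a one-row tibble: confusion metrics plus `auroc` and
#'   `n_features`.
#' @export
evaluate_benchmark <- function(model, features, labels) {
  stopifnot(inherits(model, "benchmark_model"), inherits(features, "pair_features"))
  if (!all(model$feature_names %in% colnames(features$features))) {
    abort("feature columns do not match the model's training pairs")
  }
  X <- features$features[, model$feature_names, drop = FALSE]
  truth <- ifelse(labels == "KD", "KD", "FI")
  pred <- family_labels(model$fitted, X, model$family)
  scores <- family_scores(model$fitted, X, model$family)
  cm <- confusion_metrics(pred, truth, "KD")
  mutate(cm, auroc = roc_auc(scores, truth, "KD")$auroc,
         n_features = model$best_size, family = model$family)
}
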