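#' Train a k-TSP majority-vote classifier
#'
#' Takes a sorted candidate pair-score list (as produced by
#' [select_top_pairs()]), forms the greedy gene-disjoint prefix, and for
#' each odd `k` in `k_grid` evaluates the apparent (training-data) balanced
#' accuracy of the majority vote over the first `k` disjoint pairs. The
#' model with the highest apparent balanced accuracy is returned; ties go
#' to the largest `k`: inside the resampling framework the classifier's
#' pair set is the stability-selection counting statistic, so among
#' training-equivalent panels the largest harvests the most evidence per
#' run (and its majority vote has the lowest held-out variance).
#'
#' @param dataset an [expr_dataset()] (the training data).
#' @param candidates a sorted pair-score tibble.
#' @param class1 positive class (default `"KD"`).
#' @param class2 negative class set (default `"FI"` = DB + DV).
#' @param k_grid odd candidate panel sizes.
#' @return an object of class `ktsp_model`: pairs, `k`, vote classes and
#'   the apparent balanced accuracy of each `k` tried.
#' @export
train_ktsp <- function(dataset, candidates, class1 = "KD", class2 = "FI",
                       k_grid = c(1, 3, 5, 7, 9)) {
  candidates <- as_tibble(candidates)
  if (!nrow(candidates)) abort("empty candidate pair list")
  if (any(!is_odd(k_grid))) abort("k_grid must contain odd integers only")
  disjoint <- greedy_disjoint(candidates)
  k_grid <- sort(unique(as.integer(k_grid[k_grid <= nrow(disjoint)])))
  if (!length(k_grid)) k_grid <- 1L

  truth <- sample_classes(dataset)$group
  grid <- tibble(k = k_grid, balanced_accuracy = NA_real_)
  best <- NULL
  for (r in seq_along(k_grid)) {
    k <- k_grid[r]
    model <- new_ktsp(disjoint[seq_len(k), ], k)
    pred <- predict(model, dataset)$predicted
    ba <- confusion_metrics(pred, truth, positive_class = "KD")$balanced_accuracy
    grid$balanced_accuracy[r] <- ba
    if (is.null(best) || ba >= best$ba - 1e-12) best <- list(model = model, ba = ba)
  }
  best$model$k_selection <- grid
  best$model
}

new_ktsp <- function(pairs, k) {
  structure(
    list(pairs = as_tibble(pairs)[, c("gene_i", "gene_j")], k = as.integer(k),
         positive_class = "KD", negative_class = "FI"),
    class = "ktsp_model"
  )
}

#' @export
print.ktsp_model <- function(x, ...) {
  cat(sprintf("<ktsp_model> k = %d majority vote for %s vs %s\n",
              x$k, x$positive_class, x$negative_class))
  print(x$pairs, n = x$k)
  invisible(x)
}

# Vote counts (number of pairs with gene_i > gene_j) per sample.
ktsp_votes <- function(model, values) {
  i <- match(model$pairs$gene_i, rownames(values))
  j <- match(model$pairs$gene_j, rownames(values))
  if (anyNA(i) || anyNA(j)) {
    missing <- unique(c(model$pairs$gene_i[is.na(i)], model$pairs$gene_j[is.na(j)]))
    abort(paste0("model gene(s) absent from data: ", paste(missing, collapse = ", ")))
  }
  colSums(values[i, , drop = FALSE] > values[j, , drop = FALSE])
}

#' Predict with a k-TSP model
#'
#' Majority vote: a sample is called `KD` when more than `k/2` of the
#' model's pair indicators are 1 (since `k` is odd there is no vote tie).
#' The per-sample `score` is the fraction of KD votes.
#'
#' @param object a `ktsp_model`.
#' @param newdata an [expr_dataset()] or a named numeric vector
#'   (one sample, gene -> value).
#' @param ... unused.
#' @return a tibble with `sample_id`, `votes`, `score`, `predicted`.
#' @export
predict.ktsp_model <- function(object, newdata, ...) {
  if (is.numeric(newdata) && !is.null(names(newdata))) {
    values <- matrix(newdata, ncol = 1, dimnames = list(names(newdata), "sample"))
  } else if (inherits(newdata, "expr_dataset")) {
    values <- newdata$values
  } else {
    abort("newdata must be an expr_dataset or a named numeric vector")
  }
  v <- ktsp_votes(object, values)
  tibble(
    sample_id = colnames(values),
    votes = as.integer(v),
    score = unname(v / object$k),
    predicted = unname(ifelse(v > object$k / 2, object$positive_class,
                              object$negative_class))
  )
}

#' @rdname predict.ktsp_model
#' @param model a `ktsp_model`.
#' @param sample a named numeric vector of expression values.
#' @return `predict_ktsp` returns the predicted label for one sample.
#' @export
predict_ktsp <- function(model, sample) {
  predict(model, sample)$predicted[[1]]
}
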