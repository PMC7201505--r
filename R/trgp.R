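#' Top-ranked gene-pair (TRGP) voting classifier
#'
#' An unweighted single-sample classifier over an ordered panel of N gene
#' pairs. Each pair votes +1 for KD when `gene_i > gene_j` and -1 for FI
#' otherwise (ties vote -1, consistent with the 0-branch of the binary
#' indicator). The classification score is the mean vote, so it lives on
#' the lattice `(2v - N)/N` for `v = 0..N` KD votes; a sample is called KD
#' exactly when its score is strictly greater than the fixed threshold 0.
#'
#' @param pairs an ordered data frame with columns `gene_i`, `gene_j`
#'   (discovery ranking order).
#' @param positive_class label voted for by `gene_i > gene_j`.
#' @return an object of class `trgp_model` with fixed `threshold = 0`.
#' @export
trgp_model <- function(pairs, positive_class = "KD") {
  pairs <- as_tibble(pairs)[, c("gene_i", "gene_j")]
  if (!nrow(pairs)) abort("a TRGP model needs at least one pair")
  if (any(pairs$gene_i == pairs$gene_j)) abort("pair with gene_i == gene_j")
  structure(
    list(pairs = pairs, n_pairs = nrow(pairs), positive_class = positive_class,
         negative_class = "FI", threshold = 0),
    class = "trgp_model"
  )
}

#' @export
print.trgp_model <- function(x, ...) {
  cat(sprintf("<trgp_model> %d-pair mean-vote classifier (%s if score > 0)\n",
              x$n_pairs, x$positive_class))
  print(x$pairs, n = min(x$n_pairs, 10))
  invisible(x)
}

trgp_values <- function(newdata) {
  if (is.numeric(newdata) && !is.null(names(newdata))) {
    matrix(newdata, ncol = 1, dimnames = list(names(newdata), "sample"))
  } else if (inherits(newdata, "expr_dataset")) {
    newdata$values
  } else {
    abort("expected an expr_dataset or a named numeric vector")
  }
}

#' TRGP classification score
#'
#' Mean of the N pair votes: `score = (#KD votes - #FI votes) / N`.
#'
#' @param model a [trgp_model()].
#' @param sample a named numeric vector (one sample) or an
#'   [expr_dataset()].
#' @return a numeric vector of scores in `[-1, 1]`, named by sample.
#' @export
trgp_score <- function(model, sample) {
  values <- trgp_values(sample)
  i <- match(model$pairs$gene_i, rownames(values))
  j <- match(model$pairs$gene_j, rownames(values))
  if (anyNA(i) || anyNA(j)) {
    missing <- unique(c(model$pairs$gene_i[is.na(i)], model$pairs$gene_j[is.na(j)]))
    abort(paste0("model gene(s) absent from data: ", paste(missing, collapse = ", ")))
  }
  votes <- colSums(values[i, , drop = FALSE] > values[j, , drop = FALSE])
  stats::setNames((2 * votes - model$n_pairs) / model$n_pairs, colnames(values))
}

#' Classify samples with a TRGP model
#'
#' @param model a [trgp_model()].
#' @param dataset an [expr_dataset()].
#' @return a tibble with `sample_id`, `score`, `predicted`
#'   (`KD` iff `score > 0`, FI otherwise — a score of exactly 0 is FI).
#' @export
trgp_classify <- function(model, dataset) {
  s <- trgp_score(model, dataset)
  tibble(
    sample_id = names(s),
    score = unname(s),
    predicted = unname(ifelse(s > model$threshold, model$positive_class,
                              model$negative_class))
  )
}

#' @export
predict.trgp_model <- function(object, newdata, ...) trgp_classify(object, newdata)

#' Sweep the TRGP panel size
#'
#' Builds TRGP models from the first N = 1..`n_max` discovery-ranked pairs
#' and evaluates balanced accuracy and AUROC of each on `dataset`. The
#' best N is the smallest panel attaining the maximum balanced accuracy,
#' with AUROC as secondary tie-break.
#'
#' @param ranked_pairs an ordered pair data frame (e.g. from
#'   [rank_top_pairs()]).
#' @param dataset an [expr_dataset()] with KD and FI samples.
#' @param n_max largest panel size to try (capped at `nrow(ranked_pairs)`).
#' @return an object of class `panel_sweep`: `sweep` (tibble of `n_pairs`,
#'   `balanced_accuracy`, `auroc`) and `best_n`.
#' @export
select_panel_size <- function(ranked_pairs, dataset, n_max = 60) {
  ranked_pairs <- as_tibble(ranked_pairs)
  if (!nrow(ranked_pairs)) abort("ranked_pairs is empty")
  n_max <- min(n_max, nrow(ranked_pairs))
  truth <- sample_classes(dataset)$group
  sweep <- tibble(n_pairs = seq_len(n_max), balanced_accuracy = NA_real_,
                  auroc = NA_real_)
  for (N in seq_len(n_max)) {
    model <- trgp_model(ranked_pairs[seq_len(N), ])
    res <- trgp_classify(model, dataset)
    sweep$balanced_accuracy[N] <-
      confusion_metrics(res$predicted, truth, "KD")$balanced_accuracy
    sweep$auroc[N] <- roc_auc(res$score, truth, "KD")$auroc
  }
  best_ba <- max(sweep$balanced_accuracy)
  cand <- sweep[sweep$balanced_accuracy >= best_ba - 1e-12, ]
  cand <- cand[cand$auroc >= max(cand$auroc) - 1e-12, ]
  best_n <- min(cand$n_pairs)
  structure(list(sweep = sweep, best_n = best_n, pairs = ranked_pairs),
            class = "panel_sweep")
}

#' @export
print.panel_sweep <- function(x, ...) {
  cat(sprintf("<panel_sweep> best N = %d of %d panel sizes tried\n",
              x$best_n, nrow(x$sweep)))
  print(x$sweep, n = 10)
  invisible(x)
}
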