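#' Destroy gene-class association by shuffling
#'
#' Default (`mode = "per_gene"`): each gene row's values are independently
#' permuted across samples, and the gene-id-to-row assignment is permuted,
#' so every per-row value multiset is preserved while all association with
#' the class labels (which are untouched) is destroyed. `mode = "pooled"`
#' permutes the entire value matrix instead (only the global multiset is
#' preserved).
#'
#' @param dataset an [expr_dataset()].
#' @param seed integer seed.
#' @param mode `"per_gene"` (default) or `"pooled"`.
#' @return a shuffled `expr_dataset` with the original labels.
#' @export
shuffle_dataset <- function(dataset, seed = 1L, mode = c("per_gene", "pooled")) {
  mode <- match.arg(mode)
  v <- dataset$values
  shuffled <- with_seed_(seed, {
    if (mode == "per_gene") {
      out <- t(apply(v, 1, sample))
      rownames(out) <- sample(rownames(v))
      colnames(out) <- colnames(v)
      out[order(match(rownames(out), rownames(v))), , drop = FALSE]
    } else {
      out <- matrix(sample(as.vector(v)), nrow = nrow(v), dimnames = dimnames(v))
      out
    }
  })
  expr_dataset(shuffled, dataset$labels)
}

#' Permutation null for the discovery pipeline
#'
#' Runs `n_permutations` discovery runs on label-destroyed (shuffled)
#' copies of the cohort and the same number on the real cohort, each on an
#' independent stratified 80/20 split. Per run it records the top (maximum)
#' pair score of the run's final candidate list, the selected classifier
#' size k, and train/test AUROC of the run's k-TSP model; a two-sample
#' Kolmogorov-Smirnov test then compares the real and null top-score
#' samples. Real-data top scores should sit well above the null and
#' held-out null AUROC should hover around 0.5.
#'
#' @param dataset an [expr_dataset()] with all three classes.
#' @param n_permutations number of shuffled (and of real) runs.
#' @param seed master seed.
#' @param mode shuffling granularity, see [shuffle_dataset()].
#' @inheritParams run_discovery
#' @return an object of class `permutation_summary`: tibbles `real` and
#'   `null` (per-run `top_delta`, `k`, `train_auroc`, `test_auroc`), and
#'   `ks_statistic`, `ks_p_value` comparing the two top-score samples.
#' @export
permutation_study <- function(dataset, n_permutations = 50, seed = 1L,
                              train_fraction = 0.8, top_m_per_comparison = 100,
                              top_m_final = 100, k_grid = c(1, 3, 5, 7, 9),
                              n_filter_genes = 100,
                              mode = c("per_gene", "pooled")) {
  stopifnot(n_permutations >= 1)
  mode <- match.arg(mode)
  seeds <- derive_seeds(seed, 2L * n_permutations)

  one_run <- function(data, run_seed, label) {
    sp <- stratified_split(data$labels, train_fraction, seed = run_seed)
    train <- subset_samples(data, sp$train)
    test <- subset_samples(data, sp$test)
    dr <- discovery_run(train, top_m_per_comparison = top_m_per_comparison,
                        top_m_final = top_m_final, k_grid = k_grid,
                        n_filter_genes = n_filter_genes)
    truth_tr <- sample_classes(train)$group
    truth_te <- sample_classes(test)$group
    tibble(
      top_delta = max(dr$candidates$delta),
      k = dr$model$k,
      train_auroc = roc_auc(predict(dr$model, train)$score, truth_tr, "KD")$auroc,
      test_auroc = roc_auc(predict(dr$model, test)$score, truth_te, "KD")$auroc
    )
  }

  real <- vector("list", n_permutations)
  null <- vector("list", n_permutations)
  for (p in seq_len(n_permutations)) {
    real[[p]] <- tryCatch(
      one_run(dataset, seeds[p], "real"),
      error = function(e) abort(sprintf("real run %d failed: %s", p,
                                        conditionMessage(e)))
    )
    null[[p]] <- tryCatch({
      shuffled <- shuffle_dataset(dataset, seed = seeds[n_permutations + p],
                                  mode = mode)
      one_run(shuffled, seeds[n_permutations + p], "null")
    }, error = function(e) abort(sprintf("permutation %d failed: %s", p,
                                         conditionMessage(e))))
  }
  real <- bind_rows(real); null <- bind_rows(null)
  ks <- ks_two_sample(real$top_delta, null$top_delta)
  structure(
    list(real = real, null = null, n_permutations = n_permutations,
         ks_statistic = ks$statistic, ks_p_value = ks$p_value, mode = mode),
    class = "permutation_summary"
  )
}

#' @export
print.permutation_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<permutation_summary> %d real vs %d shuffled runs\n",
           "  top score: real %.3f vs null %.3f (KS D = %.3f, p = %.2g)\n",
           "  held-out AUROC: real %.3f vs null %.3f\n"),
    nrow(x$real), nrow(x$null),
    mean(x$real$top_delta), mean(x$null$top_delta),
    x$ks_statistic, x$ks_p_value,
    mean(x$real$test_auroc), mean(x$null$test_auroc)
  ))
  invisible(x)
}
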