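#' Stratified train/test split
#'
#' Per class c, `round(train_fraction * n_c)` samples go to the training
#' side; the split is stratified on the three-way class (KD/DB/DV) so both
#' infection subclasses are present in every training set, which the
#' two-branch candidate construction requires.
#'
#' @param labels a data frame with `sample_id` and `class`, or a named
#'   character vector.
#' @param train_fraction fraction of each class assigned to training.
#' @param seed integer seed.
#' @return a list with character vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_fraction = 0.8, seed = 1L) {
  if (!is.data.frame(labels)) {
    labels <- tibble(sample_id = names(labels), class = unname(labels))
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must lie strictly between 0 and 1")
  }
  split_ids <- with_seed_(seed, {
    lapply(split(labels$sample_id, labels$class), function(ids) {
      n <- length(ids)
      if (n < 2) abort("every class needs at least 2 samples to split")
      n_train <- round(train_fraction * n)
      if (n_train < 1 || n_train >= n) {
        abort(sprintf(
          "train_fraction %.2f empties one side of a class with %d samples",
          train_fraction, n
        ))
      }
      tr <- sample(ids, n_train)
      list(train = tr, test = setdiff(ids, tr))
    })
  })
  train <- unlist(lapply(split_ids, `[[`, "train"), use.names = FALSE)
  test <- unlist(lapply(split_ids, `[[`, "test"), use.names = FALSE)
  list(train = labels$sample_id[labels$sample_id %in% train],
       test = labels$sample_id[labels$sample_id %in% test])
}

#' One discovery run: restricted-pair two-stage selection + k-TSP
#'
#' Stage 1 selects the top `top_m_per_comparison` score pairs of KD vs DB
#' and of KD vs DV (Wilcoxon prefilter, orientations collapsed, not
#' gene-disjoint so the union genuinely holds ~2m restricted pairs).
#' Stage 2 re-scores the union as a restricted candidate set against
#' KD vs FI and keeps the top `top_m_final` gene-disjoint pairs.
#' Stage 3 trains a k-TSP majority-vote classifier on those candidates.
#'
#' @param train an [expr_dataset()] containing all three classes.
#' @param top_m_per_comparison,top_m_final stage sizes (defaults 100).
#' @param k_grid odd k-TSP panel sizes tried.
#' @param n_filter_genes Wilcoxon prefilter size.
#' @param rank_matrix optional precomputed rank matrix for `train`.
#' @return a list with `model` (a `ktsp_model`) and `candidates`
#'   (the stage-2 pair-score tibble).
#' @export
discovery_run <- function(train, top_m_per_comparison = 100, top_m_final = 100,
                          k_grid = c(1, 3, 5, 7, 9), n_filter_genes = 100,
                          rank_matrix = NULL) {
  present <- unique(train$labels$class)
  missing <- setdiff(c("KD", "DB", "DV"), present)
  if (length(missing)) {
    abort(paste0("class(es) absent from training data: ",
                 paste(missing, collapse = ", ")))
  }
  if (is.null(rank_matrix)) rank_matrix <- rank_matrix(train$values)
  top_db <- select_top_pairs(train, "KD", "DB", m = top_m_per_comparison,
                             disjoint = FALSE, n_filter_genes = n_filter_genes,
                             rank_matrix = rank_matrix)
  top_dv <- select_top_pairs(train, "KD", "DV", m = top_m_per_comparison,
                             disjoint = FALSE, n_filter_genes = n_filter_genes,
                             rank_matrix = rank_matrix)
  restricted <- distinct(bind_rows(top_db[c("gene_i", "gene_j")],
                                   top_dv[c("gene_i", "gene_j")]))
  candidates <- select_top_pairs(train, "KD", "FI", m = top_m_final,
                                 candidates = restricted, disjoint = TRUE,
                                 rank_matrix = rank_matrix)
  model <- train_ktsp(train, candidates, k_grid = k_grid)
  list(model = model, candidates = candidates)
}

#' Resampling discovery of stable gene pairs
#'
#' The stability-selection engine: `n_runs` independent stratified 80/20
#' splits of the cohort; per run, [discovery_run()] on the training side
#' and held-out evaluation of the run's k-TSP classifier on the test side.
#' Pairs are counted across runs — by default the pairs of each run's
#' final classifier (`count_mode = "classifier_pairs"`); alternatively the
#' full stage-2 candidate list (`"final_pairs"`). A pair's repetition rate
#' is its count divided by `n_runs`.
#'
#' @param dataset an [expr_dataset()] with all three classes.
#' @param n_runs number of resampling runs (study scale: 10,000;
#'   desk scale: 100-500).
#' @param train_fraction per-class training fraction.
#' @param count_mode what to count per run (see above).
#' @param seed master seed; per-run seeds are derived by run index.
#' @inheritParams discovery_run
#' @return an object of class `pair_discovery`: `pair_counts` (tibble
#'   `gene_i`, `gene_j`, `count`, `rate`, `mean_delta`), `run_metrics`
#'   (per-run `k`, held-out `auroc`, `balanced_accuracy`, `accuracy`),
#'   `n_runs`, `count_mode`.
#' @export
run_discovery <- function(dataset, n_runs = 10000, train_fraction = 0.8,
                          top_m_per_comparison = 100, top_m_final = 100,
                          k_grid = c(1, 3, 5, 7, 9),
                          count_mode = c("classifier_pairs", "final_pairs"),
                          seed = 1L, n_filter_genes = 100) {
  count_mode <- match.arg(count_mode)
  stopifnot(n_runs >= 1)
  seeds <- derive_seeds(seed, n_runs)
  rkm <- rank_matrix(dataset$values)
  counted <- vector("list", n_runs)
  metrics <- vector("list", n_runs)
  for (run in seq_len(n_runs)) {
    res <- tryCatch({
      sp <- stratified_split(dataset$labels, train_fraction, seed = seeds[run])
      train <- subset_samples(dataset, sp$train)
      test <- subset_samples(dataset, sp$test)
      dr <- discovery_run(train,
                          top_m_per_comparison = top_m_per_comparison,
                          top_m_final = top_m_final, k_grid = k_grid,
                          n_filter_genes = n_filter_genes,
                          rank_matrix = rkm[, sp$train, drop = FALSE])
      pred <- predict(dr$model, test)
      truth <- sample_classes(test)$group
      cm <- confusion_metrics(pred$predicted, truth, "KD")
      au <- roc_auc(pred$score, truth, "KD")$auroc
      pairs <- if (count_mode == "classifier_pairs") {
        scored <- dr$candidates
        semi_join(scored, dr$model$pairs, by = c("gene_i", "gene_j"))
      } else {
        dr$candidates
      }
      list(
        pairs = pairs[c("gene_i", "gene_j", "delta")],
        metrics = tibble(run = run, k = dr$model$k, auroc = au,
                         balanced_accuracy = cm$balanced_accuracy,
                         accuracy = cm$accuracy)
      )
    }, error = function(e) {
      abort(sprintf("discovery run %d failed: %s", run, conditionMessage(e)))
    })
    counted[[run]] <- res$pairs
    metrics[[run]] <- res$metrics
  }
  pair_counts <- bind_rows(counted) |>
    group_by(.data$gene_i, .data$gene_j) |>
    summarise(count = dplyr::n(), mean_delta = mean(.data$delta),
              .groups = "drop") |>
    mutate(rate = .data$count / n_runs) |>
    select("gene_i", "gene_j", "count", "rate", "mean_delta")
  structure(
    list(pair_counts = pair_counts, run_metrics = bind_rows(metrics),
         n_runs = n_runs, count_mode = count_mode, seed = seed),
    class = "pair_discovery"
  )
}

#' @export
print.pair_discovery <- function(x, ...) {
  cat(sprintf(
    "<pair_discovery> %d runs (%s): %d distinct pairs, mean held-out AUROC %.3f\n",
    x$n_runs, x$count_mode, nrow(x$pair_counts), mean(x$run_metrics$auroc)
  ))
  print(head(arrange(x$pair_counts, desc(.data$rate)), 10))
  invisible(x)
}

#' Extract the top-ranked (stable) pairs
#'
#' Pairs whose repetition rate strictly exceeds `threshold`, sorted by
#' descending rate, then descending mean training delta, then
#' lexicographically.
#'
#' @param result a `pair_discovery` object.
#' @param threshold repetition-rate cutoff in (0, 1] (default 0.1).
#' @return a tibble `gene_i`, `gene_j`, `count`, `rate`, `mean_delta`
#'   (possibly empty).
#' @export
rank_top_pairs <- function(result, threshold = 0.1) {
  stopifnot(inherits(result, "pair_discovery"), threshold > 0, threshold <= 1)
  result$pair_counts |>
    filter(.data$rate > threshold) |>
    arrange(desc(.data$rate), desc(.data$mean_delta), .data$gene_i, .data$gene_j)
}
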