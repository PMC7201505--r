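#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a discovery result
#'
#' One row per pair seen across the resampling runs, with its count,
#' repetition rate and mean training delta, sorted by rate.
#' @param x a `pair_discovery` object.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.pair_discovery <- function(x, ...) {
  arrange(x$pair_counts, desc(.data$rate), desc(.data$mean_delta),
          .data$gene_i, .data$gene_j)
}

#' @rdname tidy.pair_discovery
#' @exportS3Method generics::glance
glance.pair_discovery <- function(x, ...) {
  tibble(
    n_runs = x$n_runs,
    n_pairs_seen = nrow(x$pair_counts),
    count_mode = x$count_mode,
    mean_k = mean(x$run_metrics$k),
    mean_test_auroc = mean(x$run_metrics$auroc),
    mean_test_balanced_accuracy = mean(x$run_metrics$balanced_accuracy)
  )
}

#' @exportS3Method generics::tidy
tidy.ktsp_model <- function(x, ...) x$pairs

#' @exportS3Method generics::glance
glance.ktsp_model <- function(x, ...) {
  tibble(k = x$k, positive_class = x$positive_class)
}

#' @exportS3Method generics::tidy
tidy.trgp_model <- function(x, ...) {
  mutate(x$pairs, rank = dplyr::row_number(), .before = 1)
}

#' @exportS3Method generics::glance
glance.trgp_model <- function(x, ...) {
  tibble(n_pairs = x$n_pairs, threshold = x$threshold,
         positive_class = x$positive_class)
}

#' @exportS3Method generics::tidy
tidy.panel_sweep <- function(x, ...) x$sweep

#' @exportS3Method generics::glance
glance.panel_sweep <- function(x, ...) {
  best <- x$sweep[x$sweep$n_pairs == x$best_n, ]
  tibble(best_n = x$best_n,
         balanced_accuracy = best$balanced_accuracy,
         auroc = best$auroc)
}

#' @exportS3Method generics::tidy
tidy.permutation_summary <- function(x, ...) {
  bind_rows(
    mutate(x$real, source = "real"),
    mutate(x$null, source = "null")
  ) |> select("source", dplyr::everything())
}

#' @exportS3Method generics::glance
glance.permutation_summary <- function(x, ...) {
  tibble(
    n_permutations = x$n_permutations,
    real_mean_top_delta = mean(x$real$top_delta),
    null_mean_top_delta = mean(x$null$top_delta),
    real_mean_test_auroc = mean(x$real$test_auroc),
    null_mean_test_auroc = mean(x$null$test_auroc),
    ks_statistic = x$ks_statistic,
    ks_p_value = x$ks_p_value
  )
}

#' @exportS3Method generics::tidy
tidy.roc_result <- function(x, ...) x$curve

#' @exportS3Method generics::glance
glance.roc_result <- function(x, ...) {
  tibble(auroc = x$auroc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @exportS3Method generics::tidy
tidy.benchmark_model <- function(x, ...) {
  mutate(x$pairs, feature = x$feature_names, rank = dplyr::row_number())
}

#' @exportS3Method generics::glance
glance.benchmark_model <- function(x, ...) {
  tibble(family = x$family, n_features = x$best_size,
         cv_balanced_accuracy = max(x$cv$balanced_accuracy))
}
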