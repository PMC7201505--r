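#' @import ggplot2
NULL

#' Repetition rate vs mean score of discovered pairs
#'
#' One point per pair seen across the resampling runs; the dashed line
#' marks the stability threshold separating top-ranked pairs from the
#' unstable bulk.
#'
#' @param object a `pair_discovery` object.
#' @param threshold repetition-rate cutoff drawn as a reference line.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.pair_discovery <- function(object, threshold = 0.1, ...) {
  ggplot(object$pair_counts, aes(x = .data$rate, y = .data$mean_delta)) +
    geom_point(alpha = 0.6) +
    geom_vline(xintercept = threshold, linetype = "dashed", colour = "red") +
    labs(x = "Repetition rate", y = "Mean pair score (delta)",
         title = sprintf("Pair stability over %d resampling runs", object$n_runs)) +
    theme_minimal()
}

#' Panel-size sweep of the TRGP classifier
#'
#' Balanced accuracy and AUROC against the number of top-ranked pairs in
#' the panel; the dotted line marks the selected panel size.
#'
#' @param object a `panel_sweep` object.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.panel_sweep <- function(object, ...) {
  long <- pivot_longer(object$sweep, c("balanced_accuracy", "auroc"),
                       names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$n_pairs, y = .data$value, colour = .data$metric)) +
    geom_line() +
    geom_point(size = 1) +
    geom_vline(xintercept = object$best_n, linetype = "dotted") +
    labs(x = "Number of gene pairs", y = "Metric value", colour = NULL,
         title = sprintf("TRGP panel-size sweep (best N = %d)", object$best_n)) +
    theme_minimal()
}

#' ROC curve
#'
#' @param object a `roc_result` from [roc_auc()].
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.roc_result <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    geom_step() +
    coord_equal() +
    labs(x = "False positive rate", y = "True positive rate",
         title = sprintf("ROC (AUROC = %.3f)", object$auroc)) +
    theme_minimal()
}

#' Real vs permutation-null top pair scores
#'
#' @param object a `permutation_summary`.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.permutation_summary <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$top_delta, fill = .data$source)) +
    geom_histogram(alpha = 0.6, position = "identity", bins = 30) +
    labs(x = "Top pair score per run", y = "Runs", fill = NULL,
         title = sprintf("Real vs shuffled discovery (KS p = %.2g)",
                         object$ks_p_value)) +
    theme_minimal()
}

#' Classification score strip plot by true group
#'
#' The score distribution of a TRGP (or k-TSP) classification result by
#' true class, with the decision threshold at 0.
#'
#' @param scored a data frame with `score` and a truth column.
#' @param truth a vector of true labels aligned with `scored`.
#' @export
plot_scores <- function(scored, truth) {
  d <- mutate(as_tibble(scored), truth = ifelse(truth == "KD", "KD", "FI"))
  ggplot(d, aes(x = .data$truth, y = .data$score)) +
    geom_hline(yintercept = 0, linetype = "dotted") +
    geom_jitter(width = 0.15, alpha = 0.6) +
    geom_boxplot(alpha = 0.2, outlier.shape = NA) +
    labs(x = "True group", y = "Classification score") +
    theme_minimal()
}
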