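#' Confusion-matrix derived metrics
#'
#' Sensitivity is KD recall (correct KD calls over all true KD),
#' specificity is FI recall, accuracy the overall fraction correct,
#' balanced accuracy the mean of sensitivity and specificity, precision
#' the fraction of KD calls that are true KD (NA when no KD is called).
#' Truth labels other than `positive_class` (e.g. DB/DV) count as the
#' negative (FI) class.
#'
#' @param predicted,truth equal-length label vectors.
#' @param positive_class the positive label (default `"KD"`).
#' @return a one-row tibble with `tp, fp, tn, fn` and the derived metrics.
#' @export
confusion_metrics <- function(predicted, truth, positive_class = "KD") {
  if (!length(predicted) || length(predicted) != length(truth)) {
    abort("predicted and truth must be nonempty and of equal length")
  }
  pos_true <- truth == positive_class
  if (!any(pos_true)) abort("positive class absent from truth labels")
  pos_pred <- predicted == positive_class
  tp <- sum(pos_pred & pos_true)
  fp <- sum(pos_pred & !pos_true)
  fn <- sum(!pos_pred & pos_true)
  tn <- sum(!pos_pred & !pos_true)
  sens <- tp / (tp + fn)
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = sens,
    specificity = spec,
    accuracy = (tp + tn) / length(truth),
    balanced_accuracy = mean(c(sens, spec), na.rm = TRUE),
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_
  )
}

#' ROC curve and AUROC
#'
#' AUROC is computed as the Mann-Whitney statistic — the probability that a
#' random positive scores above a random negative, ties counting 1/2 —
#' via the rank formula. The curve holds (FPR, TPR) at every distinct
#' score threshold.
#'
#' @param scores numeric classification scores (higher = more KD-like).
#' @param truth label vector; `positive_class` vs the rest.
#' @param positive_class positive label.
#' @return an object of class `roc_result`: `auroc` and `curve`
#'   (tibble `threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, truth, positive_class = "KD") {
  pos <- truth == positive_class
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0 || n2 == 0) abort("need at least one positive and one negative")
  r <- rank(scores)
  auroc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  thr <- sort(unique(scores), decreasing = TRUE)
  curve <- tibble(
    threshold = c(Inf, thr),
    tpr = vapply(c(Inf, thr), function(t) mean(scores[pos] >= t), double(1)),
    fpr = vapply(c(Inf, thr), function(t) mean(scores[!pos] >= t), double(1))
  )
  structure(list(auroc = auroc, curve = curve, n_pos = n1, n_neg = n2),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUROC = %.4f (%d positives, %d negatives)\n",
              x$auroc, x$n_pos, x$n_neg))
  invisible(x)
}

#' DeLong 95% confidence interval for the AUROC
#'
#' Delegates to the DeLong variance estimator (as implemented in pROC),
#' clipping to `[0, 1]`. When the score distribution is degenerate (zero
#' variance, e.g. all scores tied) the interval collapses to the point
#' AUROC and `degenerate` is flagged.
#'
#' @inheritParams roc_auc
#' @return a one-row tibble: `auroc`, `conf_low`, `conf_high`, `degenerate`.
#' @export
auroc_ci_delong <- function(scores, truth, positive_class = "KD") {
  point <- roc_auc(scores, truth, positive_class)$auroc
  resp <- factor(ifelse(truth == positive_class, "pos", "neg"),
                 levels = c("neg", "pos"))
  ci <- tryCatch({
    r <- pROC::roc(response = resp, predictor = scores, quiet = TRUE,
                   direction = "<", levels = c("neg", "pos"))
    suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  }, error = function(e) NULL)
  if (is.null(ci) || anyNA(ci) || isTRUE(all.equal(ci[1], ci[3]))) {
    warn("degenerate score distribution: AUROC CI collapsed to the point estimate")
    return(tibble(auroc = point, conf_low = point, conf_high = point,
                  degenerate = TRUE))
  }
  tibble(auroc = point,
         conf_low = max(0, ci[1]), conf_high = min(1, ci[3]),
         degenerate = FALSE)
}

#' Stratified bootstrap confidence interval for a confusion metric
#'
#' Resamples cases within the true-positive and true-negative strata,
#' recomputes the metric, and reports the percentile 2.5/97.5 interval.
#' Resamples where the metric is undefined (e.g. precision with no
#' positive call) are redrawn, up to a cap.
#'
#' @param scored a data frame with columns `predicted` and `truth`.
#' @param metric one of `sensitivity`, `specificity`, `accuracy`,
#'   `balanced_accuracy`, `precision`.
#' @param n_boot number of bootstrap draws (>= 100).
#' @param seed integer seed.
#' @param positive_class positive label.
#' @return a one-row tibble: `metric`, `estimate`, `conf_low`, `conf_high`.
#' @export
bootstrap_metric_ci <- function(scored, metric = "sensitivity", n_boot = 2000,
                                seed = 1L, positive_class = "KD") {
  stopifnot(n_boot >= 100)
  metric <- match.arg(metric, c("sensitivity", "specificity", "accuracy",
                                "balanced_accuracy", "precision"))
  scored <- as_tibble(scored)
  est <- confusion_metrics(scored$predicted, scored$truth, positive_class)[[metric]]
  pos_idx <- which(scored$truth == positive_class)
  neg_idx <- which(scored$truth != positive_class)
  pred_pos <- scored$predicted == positive_class
  draws <- with_seed_(seed, {
    out <- double(n_boot); got <- 0L; attempts <- 0L
    while (got < n_boot && attempts < 10L * n_boot) {
      attempts <- attempts + 1L
      pp <- pred_pos[sample(pos_idx, length(pos_idx), replace = TRUE)]
      pn <- pred_pos[sample(neg_idx, length(neg_idx), replace = TRUE)]
      v <- metric_value(sum(pp), length(pp) - sum(pp), sum(pn),
                        length(pn) - sum(pn), metric)
      if (!is.na(v)) { got <- got + 1L; out[got] <- v }
    }
    out[seq_len(got)]
  })
  if (!length(draws)) abort("metric undefined in every bootstrap resample")
  q <- unname(stats::quantile(draws, c(0.025, 0.975), type = 7))
  tibble(metric = metric, estimate = est, conf_low = q[1], conf_high = q[2])
}

# Scalar metric from stratified counts: tp/fn from the positive stratum,
# fp/tn from the negative one. NA where undefined.
metric_value <- function(tp, fn, fp, tn, metric) {
  switch(metric,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / (tp + fn + fp + tn),
    balanced_accuracy = (tp / (tp + fn) + tn / (tn + fp)) / 2,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_
  )
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_a - ECDF_b|` with the asymptotic p-value.
#'
#' @param sample_a,sample_b nonempty numeric vectors.
#' @return a one-row tibble: `statistic`, `p_value`.
#' @export
ks_two_sample <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b)) abort("both samples must be nonempty")
  kt <- suppressWarnings(stats::ks.test(sample_a, sample_b, exact = FALSE))
  tibble(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}
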