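test_that("confusion metrics satisfy their defining identities", {
  pred <- rep(c("KD", "FI", "KD", "FI"), c(73, 5, 33, 113))
  truth <- rep(c("KD", "KD", "FI", "FI"), c(73, 5, 33, 113))
  m <- confusion_metrics(pred, truth)
  expect_equal(unlist(m[c("tp", "fn", "fp", "tn")], use.names = FALSE),
               c(73, 5, 33, 113))
  expect_equal(m$sensitivity, m$tp / (m$tp + m$fn))
  expect_equal(m$specificity, m$tn / (m$tn + m$fp))
  expect_equal(m$accuracy, (m$tp + m$tn) / 224)
  expect_equal(m$balanced_accuracy, (m$sensitivity + m$specificity) / 2)
  expect_equal(m$precision, m$tp / (m$tp + m$fp))
})

test_that("degenerate predictions hit the documented edge values", {
  perfect <- confusion_metrics(c("KD", "FI"), c("KD", "DB"))
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "accuracy",
                                "balanced_accuracy", "precision")],
                      use.names = FALSE),
               rep(1, 5))
  all_neg <- confusion_metrics(rep("FI", 4), c("KD", "KD", "DB", "DV"))
  expect_equal(all_neg$sensitivity, 0)
  expect_equal(all_neg$specificity, 1)
  expect_equal(all_neg$balanced_accuracy, 0.5)
  expect_true(is.na(all_neg$precision))
  expect_error(confusion_metrics(character(0), character(0)), "nonempty")
  expect_error(confusion_metrics("FI", "DB"), "positive class absent")
})

test_that("roc_auc equals the brute-force positive-negative pair count", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3),
                       c("KD", "KD", "DB", "DV"))$auroc, 1)
  expect_equal(roc_auc(rep(0.5, 6), rep(c("KD", "DB"), 3))$auroc, 0.5)
  expect_equal(roc_auc(c(0.9, 0.35, 0.4, 0.3),
                       c("KD", "KD", "DB", "DB"))$auroc, 0.75)
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(10:50, 1)
    truth <- sample(c("KD", "DB", "DV"), n, replace = TRUE)
    if (!any(truth == "KD") || all(truth == "KD")) next
    scores <- round(rnorm(n), 1) # coarse grid to exercise ties
    expect_equal(roc_auc(scores, truth)$auroc, brute_auroc(scores, truth))
  }
  expect_error(roc_auc(1:3, rep("KD", 3)), "at least one")
})

test_that("AUROC is antisymmetric under score negation", {
  set.seed(10)
  truth <- rep(c("KD", "DB"), c(12, 15))
  scores <- rnorm(27)
  expect_equal(roc_auc(scores, truth)$auroc, 1 - roc_auc(-scores, truth)$auroc)
})

test_that("DeLong interval brackets the point AUROC and clips at 1", {
  set.seed(4)
  truth <- rep(c("KD", "DB"), each = 40)
  scores <- c(rnorm(40, 1), rnorm(40, 0))
  ci <- auroc_ci_delong(scores, truth)
  expect_lte(ci$conf_low, ci$auroc)
  expect_gte(ci$conf_high, ci$auroc)
  sep <- c(rnorm(40, 10), rnorm(40, 0))
  expect_equal(suppressWarnings(auroc_ci_delong(sep, truth))$conf_high, 1)
  # degenerate scores collapse with a warning
  expect_warning(flat <- auroc_ci_delong(rep(1, 80), truth), "degenerate")
  expect_equal(flat$conf_low, flat$auroc)
  expect_true(flat$degenerate)
})

test_that("DeLong width shrinks as the sample doubles", {
  width <- function(n, seed) {
    set.seed(seed)
    truth <- rep(c("KD", "DB"), each = n)
    scores <- c(rnorm(n, 1), rnorm(n))
    ci <- auroc_ci_delong(scores, truth)
    ci$conf_high - ci$conf_low
  }
  w_small <- mean(vapply(1:5, function(s) width(40, s), double(1)))
  w_big <- mean(vapply(1:5, function(s) width(160, s), double(1)))
  expect_lt(w_big, w_small)
})

test_that("bootstrap CI is deterministic, degenerate-safe and ~95% calibrated", {
  df <- data.frame(predicted = rep(c("KD", "FI"), c(20, 30)),
                   truth = rep(c("KD", "FI"), c(20, 30)))
  ci <- bootstrap_metric_ci(df, "sensitivity", n_boot = 200, seed = 1)
  expect_equal(c(ci$conf_low, ci$conf_high), c(1, 1))
  ci2 <- bootstrap_metric_ci(df, "sensitivity", n_boot = 200, seed = 1)
  expect_identical(ci, ci2)

  p_true <- 0.85
  cover <- 0; n_sim <- 200
  for (s in seq_len(n_sim)) {
    set.seed(s + 1000)
    truth <- rep(c("KD", "FI"), c(60, 60))
    correct <- c(rbinom(60, 1, p_true) == 1, rbinom(60, 1, 0.8) == 1)
    pred <- ifelse((truth == "KD") == correct, "KD", "FI")
    ci <- bootstrap_metric_ci(data.frame(predicted = pred, truth = truth),
                              "sensitivity", n_boot = 200, seed = s)
    if (ci$conf_low <= p_true && ci$conf_high >= p_true) cover <- cover + 1
  }
  expect_gte(cover / n_sim, 0.90)
  expect_lte(cover / n_sim, 1.00)
})

test_that("two-sample KS statistic matches ECDF enumeration", {
  expect_equal(ks_two_sample(1:5, 1:5)$statistic, 0)
  expect_equal(ks_two_sample(1:5, 11:15)$statistic, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(2, 3, 4))$statistic, 1 / 3)
  expect_error(ks_two_sample(numeric(0), 1:3), "nonempty")
})
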