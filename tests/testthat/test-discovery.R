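test_that("stratified split applies per-class rounding and is reproducible", {
  labels <- data.frame(
    sample_id = sprintf("s%03d", 1:224),
    class = rep(c("KD", "DB", "DV"), c(78, 52, 94))
  )
  sp <- stratified_split(labels, 0.8, seed = 5)
  train_tab <- table(labels$class[labels$sample_id %in% sp$train])
  test_tab <- table(labels$class[labels$sample_id %in% sp$test])
  expect_equal(as.vector(train_tab[c("KD", "DB", "DV")]), c(62L, 42L, 75L))
  expect_equal(as.vector(test_tab[c("KD", "DB", "DV")]), c(16L, 10L, 19L))
  expect_setequal(c(sp$train, sp$test), labels$sample_id)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(stratified_split(labels, 0.8, seed = 5), sp)
  expect_false(identical(stratified_split(labels, 0.8, seed = 6), sp))
})

test_that("splits that would empty a side are rejected", {
  labels <- data.frame(sample_id = sprintf("s%d", 1:6),
                       class = rep(c("KD", "DB", "DV"), each = 2))
  expect_error(stratified_split(labels, 0.9, seed = 1), "empties")
  labels$class[2] <- "DB"
  expect_error(stratified_split(labels, 0.5, seed = 1), "at least 2")
})

test_that("discovery_run routes comparison-specific pairs through the union stage", {
  # one pair flips only KD-vs-DB, another flips both comparisons
  planted <- rbind(
    planted_pairs(1, p_kd = 0.95, p_db = 0.05, p_dv = 0.95),
    dplyr::mutate(planted_pairs(1, p_kd = 0.95, p_db = 0.05, p_dv = 0.05),
                  gene_i = "QQ01_i", gene_j = "QQ01_j")
  )
  ds <- generate_cohort(cohort_config(40, 30, 30, n_background_genes = 60,
                                      planted = planted, seed = 77))
  dr <- discovery_run(ds, top_m_per_comparison = 50, top_m_final = 50,
                      n_filter_genes = 40)
  keys <- paste(dr$candidates$gene_i, dr$candidates$gene_j)
  # the DB-only flipper enters via the DB branch; the double flipper
  # survives reselection with a high KD-vs-FI delta
  expect_true("PP01_i PP01_j" %in% keys)
  expect_true("QQ01_i QQ01_j" %in% keys)
  both <- dr$candidates[keys == "QQ01_i QQ01_j", ]
  expect_gt(both$delta, 0.7)
  # stage-2 candidates are bounded by the stage-1 union
  expect_lte(nrow(dr$candidates), 100)
  keep <- ds$labels$class != "DV"
  no_dv <- expr_dataset(expr_values(ds)[, keep], ds$labels[keep, ])
  expect_error(discovery_run(no_dv), "absent")
})

test_that("repetition counts are bounded and maximal for ubiquitous pairs", {
  ds <- standard_cohort(seed = 31, n_pairs = 2, n_genes = 40, n_kd = 20,
                        n_db = 12, n_dv = 12)
  disc <- run_discovery(ds, n_runs = 25, seed = 9, n_filter_genes = 20,
                        top_m_per_comparison = 30, top_m_final = 30)
  expect_true(all(disc$pair_counts$count >= 1 & disc$pair_counts$count <= 25))
  expect_true(all(disc$pair_counts$rate > 0 & disc$pair_counts$rate <= 1))
  top <- rank_top_pairs(disc, 0.9)
  expect_true(all(paste(top$gene_i, top$gene_j) %in%
                    c("PP01_i PP01_j", "PP02_i PP02_j")))
  expect_equal(nrow(disc$run_metrics), 25L)
})

test_that("rank_top_pairs applies a strict threshold and the ranking order", {
  disc <- structure(
    list(pair_counts = tibble::tibble(
      gene_i = c("A1", "B1", "C1"), gene_j = c("A2", "B2", "C2"),
      count = c(66, 10, 40), rate = c(0.66, 0.10, 0.40),
      mean_delta = c(0.9, 0.5, 0.7)
    ), n_runs = 100, run_metrics = tibble::tibble(), count_mode = "classifier_pairs"),
    class = "pair_discovery"
  )
  out <- rank_top_pairs(disc, 0.1)
  expect_equal(out$gene_i, c("A1", "C1")) # B at exactly 0.10 excluded
  expect_equal(out$rate, c(0.66, 0.40))   # descending-rate convention
  expect_equal(nrow(rank_top_pairs(disc, 1.0)), 0L)
})

test_that("planted pairs dominate background pairs in repetition rate", {
  ds <- standard_cohort(seed = 41)
  disc <- run_discovery(ds, n_runs = 100, seed = 17)
  tab <- tidy(disc)
  planted <- grepl("^PP", tab$gene_i)
  expect_gt(min(tab$rate[planted]), max(c(tab$rate[!planted], 0)))
  top <- rank_top_pairs(disc, 0.1)
  expect_gte(sum(grepl("^PP", top$gene_i)), 6)        # >= 80% of 7 planted
  expect_gte(mean(disc$run_metrics$auroc), 0.9)
})

test_that("discovery is reproducible from the master seed", {
  ds <- standard_cohort(seed = 51, n_pairs = 2, n_genes = 30, n_kd = 16,
                        n_db = 10, n_dv = 10)
  a <- run_discovery(ds, n_runs = 8, seed = 3, n_filter_genes = 20,
                     top_m_per_comparison = 20, top_m_final = 20)
  b <- run_discovery(ds, n_runs = 8, seed = 3, n_filter_genes = 20,
                     top_m_per_comparison = 20, top_m_final = 20)
  expect_identical(a$pair_counts, b$pair_counts)
  expect_identical(a$run_metrics, b$run_metrics)
})

test_that("an all-background cohort yields chance-level held-out performance", {
  ds <- generate_cohort(cohort_config(30, 20, 20, n_background_genes = 60,
                                      seed = 61))
  disc <- run_discovery(ds, n_runs = 40, seed = 7, n_filter_genes = 30,
                        top_m_per_comparison = 50, top_m_final = 50)
  expect_gte(mean(disc$run_metrics$auroc), 0.35)
  expect_lte(mean(disc$run_metrics$auroc), 0.65)
})
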