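test_that("pair_indicator implements the strict-inequality rule", {
  expect_identical(pair_indicator(5.2, 3.1), 1L)
  expect_identical(pair_indicator(3.1, 5.2), 0L)
  expect_identical(pair_indicator(2.0, 2.0), 0L) # tie falls in the else-branch
  expect_error(pair_indicator(Inf, 1), "finite")
  expect_error(pair_indicator(1, NA), "finite")
})

test_that("pair_score matches the constructed worked example", {
  values <- rbind(
    gi = c(3, 1, 4, 1, 1, 2),
    gj = c(1, 2, 2, 2, 3, 1)
  )
  ds <- dataset_from(values, c("KD", "KD", "KD", "DB", "DB", "DB"))
  s <- pair_score(ds, "gi", "gj", class1 = "KD", class2 = "DB")
  expect_equal(s$p1, 2 / 3)
  expect_equal(s$p2, 1 / 3)
  expect_equal(s$delta, 1 / 3)
})

test_that("pair_score equals the brute-force counter on every pair", {
  for (seed in 1:4) {
    ds <- rand_dataset(n_genes = 6, n_kd = 5, n_db = 4, n_dv = 4, seed = seed)
    genes <- gene_ids(ds)
    for (i in 1:5) for (j in (i + 1):6) {
      got <- pair_score(ds, genes[i], genes[j])
      want <- brute_pair_score(ds, genes[i], genes[j])
      expect_equal(got$p1, unname(want["p1"]))
      expect_equal(got$p2, unname(want["p2"]))
      expect_equal(got$delta, unname(want["delta"]))
    }
  }
})

test_that("delta is symmetric in class order and orientation", {
  ds <- rand_dataset(n_genes = 5, seed = 33)
  a <- pair_score(ds, "G01", "G02", class1 = "KD", class2 = "FI")
  b <- pair_score(ds, "G01", "G02", class1 = "FI", class2 = "KD")
  flipped <- pair_score(ds, "G02", "G01")
  expect_equal(a$delta, b$delta)
  expect_equal(a$delta, flipped$delta)
  expect_equal(a$rank_gamma, -flipped$rank_gamma)
})

test_that("pair_score errors on empty class or unknown gene", {
  ds <- rand_dataset(n_kd = 3, n_db = 3, n_dv = 0, seed = 2)
  expect_error(pair_score(ds, "G01", "G02", class2 = "DV"), "no samples")
  expect_error(pair_score(ds, "G01", "nope"), "absent")
})

test_that("wilcoxon_filter retains extreme genes and matches rank-sum enumeration", {
  # gene with complete class separation is always retained
  values <- matrix(rnorm(6 * 8, 8), 6, 8,
                   dimnames = list(sprintf("g%d", 1:6), NULL))
  values[1, 1:4] <- values[1, 1:4] + 100
  ds <- dataset_from(values, rep(c("KD", "DB"), each = 4))
  expect_true("g1" %in% wilcoxon_filter(ds, "KD", "DB", n_genes = 2))

  # top-2 match an exact standardized rank-sum computation (oracle: by hand)
  set.seed(7)
  values <- matrix(rnorm(6 * 8, 8), 6, 8,
                   dimnames = list(sprintf("g%d", 1:6), NULL))
  ds <- dataset_from(values, rep(c("KD", "DB"), each = 4))
  z <- apply(values, 1, function(x) {
    r <- rank(x)
    W <- sum(r[1:4])
    (W - 4 * 9 / 2) / sqrt(4 * 4 * 9 / 12) # no ties: plain variance
  })
  want <- c(names(sort(z, decreasing = TRUE))[1], names(sort(z))[1])
  expect_setequal(wilcoxon_filter(ds, "KD", "DB", n_genes = 2), want)

  # degenerate: asking for >= all genes returns everything
  expect_setequal(wilcoxon_filter(ds, "KD", "DB", n_genes = 10), gene_ids(ds))
  expect_error(wilcoxon_filter(ds, "KD", "DB", n_genes = 3), "even")
})

test_that("select_top_pairs ranks a planted perfect pair first", {
  cfg <- cohort_config(20, 10, 10, n_background_genes = 30,
                       planted = planted_pairs(1, p_kd = 1, p_db = 0, p_dv = 0),
                       seed = 44)
  ds <- generate_cohort(cfg)
  top <- select_top_pairs(ds, "KD", "FI", m = 10, n_filter_genes = 20)
  expect_equal(top$gene_i[1], "PP01_i")
  expect_equal(top$gene_j[1], "PP01_j")
  expect_equal(top$delta[1], 1)
  # orientation collapse: p1 >= p2 everywhere
  expect_true(all(top$p1 >= top$p2))
})

test_that("candidate restriction, tie-breaks and disjointness behave as specified", {
  # restriction: output is a subset of the candidate set even when better
  # pairs exist outside it
  cfg <- cohort_config(15, 8, 8, n_background_genes = 10,
                       planted = planted_pairs(2, p_kd = 1, p_db = 0, p_dv = 0),
                       seed = 45)
  ds <- generate_cohort(cfg)
  cand <- tibble::tibble(gene_i = "BG0001", gene_j = "BG0002")
  out <- select_top_pairs(ds, "KD", "FI", m = 5, candidates = cand)
  expect_equal(nrow(out), 1L)
  expect_equal(out$gene_i, "BG0001")

  # equal-delta pairs sharing gene A: larger |rank_gamma| wins, disjointness
  # then blocks the second
  values <- rbind(
    A = c(9, 9, 9, 1, 1, 1),
    B = c(1, 1, 1, 9, 9, 9),
    C = c(2, 2, 2, 8, 8, 8),
    D = c(0, 0, 0, 0.5, 0.5, 0.5)
  )
  ds2 <- dataset_from(values, rep(c("KD", "DB"), each = 3))
  out2 <- select_top_pairs(ds2, "KD", "DB", m = 4, n_filter_genes = 4,
                           disjoint = TRUE)
  # (A,B) and (A,C) both have delta 1; |gamma(A,B)| > |gamma(A,C)|
  expect_equal(out2$gene_i[1], "A")
  expect_equal(out2$gene_j[1], "B")
  expect_false(any(duplicated(c(out2$gene_i, out2$gene_j))))
  out3 <- select_top_pairs(ds2, "KD", "DB", m = 10, n_filter_genes = 4,
                           disjoint = FALSE)
  expect_gt(nrow(out3), nrow(out2))
  expect_error(select_top_pairs(ds2, "KD", "DB", m = 0), "positive")
})

test_that("fixed-pair scores are invariant under every monotone transform", {
  for (seed in 1:3) {
    ds <- rand_dataset(n_genes = 12, n_kd = 6, n_db = 5, n_dv = 5, seed = seed)
    genes <- gene_ids(ds)
    base <- pair_score(ds, genes[1], genes[2])
    for (tr in monotone_transforms) {
      expect_equal(pair_score(apply_monotone_transform(ds, tr),
                              genes[1], genes[2]),
                   base)
    }
  }
})

test_that("filtering and selection are invariant under global monotone transforms", {
  # the Wilcoxon prefilter compares a gene across samples, so only
  # transforms applied identically to every sample leave it unchanged
  for (seed in 1:3) {
    ds <- rand_dataset(n_genes = 12, n_kd = 6, n_db = 5, n_dv = 5, seed = seed)
    base <- select_top_pairs(ds, "KD", "FI", m = 20, n_filter_genes = 8)
    base_f <- wilcoxon_filter(ds, "KD", "FI", n_genes = 6)
    for (tr in c("exp", "affine_pos")) {
      tds <- apply_monotone_transform(ds, tr)
      expect_equal(select_top_pairs(tds, "KD", "FI", m = 20, n_filter_genes = 8),
                   base)
      expect_identical(wilcoxon_filter(tds, "KD", "FI", n_genes = 6), base_f)
    }
  }
})
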