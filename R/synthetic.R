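#' Planted order-reversal pairs
#'
#' Describes the ground-truth signal planted by [generate_cohort()]: for a
#' sample of class c the indicator `gene_i > gene_j` is drawn
#' Bernoulli(p_c), and the two expression values are set to `(u + gap, u)`
#' or `(u, u + gap)` accordingly, with `u` drawn from the background
#' baseline. A diagnostic pair reverses ordering between classes, e.g.
#' `p_kd = 0.95` with `p_db = p_dv = 0.05`.
#'
#' @param n_pairs number of planted pairs.
#' @param p_kd,p_db,p_dv per-class probabilities that `gene_i > gene_j`.
#'   Scalars are recycled across pairs.
#' @param gap positive expression offset enforcing the sampled ordering.
#' @return a tibble with columns `gene_i`, `gene_j`, `p_kd`, `p_db`,
#'   `p_dv`, `gap`.
#' @export
planted_pairs <- function(n_pairs = 7, p_kd = 0.95, p_db = 0.05, p_dv = 0.05,
                          gap = 1) {
  stopifnot(n_pairs >= 0)
  tibble(
    gene_i = sprintf("PP%02d_i", seq_len(n_pairs)),
    gene_j = sprintf("PP%02d_j", seq_len(n_pairs)),
    p_kd = rep_len(p_kd, n_pairs),
    p_db = rep_len(p_db, n_pairs),
    p_dv = rep_len(p_dv, n_pairs),
    gap = rep_len(gap, n_pairs)
  )
}

#' Cohort generator configuration
#'
#' @param n_kd,n_db,n_dv sample counts per class.
#' @param n_background_genes number of signal-free background genes.
#' @param planted a tibble of planted pairs as produced by [planted_pairs()]
#'   (may have zero rows for an all-background cohort).
#' @param baseline_mean,baseline_sd background log-intensity distribution:
#'   each gene g gets a mean `mu_g ~ N(baseline_mean, baseline_sd)` and its
#'   values are `N(mu_g, baseline_sd)` independent of class.
#' @param seed integer seed fixing all randomness.
#' @export
cohort_config <- function(n_kd, n_db, n_dv, n_background_genes,
                          planted = planted_pairs(0),
                          baseline_mean = 8, baseline_sd = 1, seed = 1L) {
  planted <- as_tibble(planted)
  stopifnot(
    n_kd >= 0, n_db >= 0, n_dv >= 0, n_background_genes >= 0,
    baseline_sd > 0
  )
  if (nrow(planted)) {
    probs <- c(planted$p_kd, planted$p_db, planted$p_dv)
    if (any(probs < 0 | probs > 1)) abort("planted probabilities must lie in [0,1]")
    if (any(planted$gap <= 0)) abort("planted gap must be positive")
    if (any(planted$gene_i == planted$gene_j)) abort("planted pair with gene_i == gene_j")
    ids <- c(planted$gene_i, planted$gene_j)
    if (anyDuplicated(ids)) abort("planted gene ids must be distinct across pairs")
  }
  structure(
    list(
      n_kd = as.integer(n_kd), n_db = as.integer(n_db), n_dv = as.integer(n_dv),
      n_background_genes = as.integer(n_background_genes), planted = planted,
      baseline_mean = baseline_mean, baseline_sd = baseline_sd,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Generate a labeled synthetic cohort with planted pairs
#'
#' Produces an [expr_dataset()] in which background genes carry no class
#' signal (class-independent gene-specific Gaussians) and each planted pair
#' realises a configured per-class order-reversal probability exactly, via
#' an explicit expression gap. Fully reproducible from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return an `expr_dataset`; the planted truth is attached as
#'   `attr(, "truth")` (the planted-pair tibble).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- c(KD = config$n_kd, DB = config$n_db, DV = config$n_dv)
  n_samp <- sum(n)
  if (n_samp == 0L) abort("cohort has no samples")
  classes <- rep(names(n), n)
  samp_ids <- sprintf("S%03d_%s", seq_len(n_samp), classes)
  planted <- config$planted

  bg_ids <- if (config$n_background_genes)
    sprintf("BG%04d", seq_len(config$n_background_genes)) else character(0)
  if (nrow(planted) && length(intersect(bg_ids, c(planted$gene_i, planted$gene_j)))) {
    abort("planted gene id collides with a background gene id")
  }

  with_seed_(config$seed, {
    mu <- stats::rnorm(length(bg_ids), config$baseline_mean, config$baseline_sd)
    bg <- matrix(
      stats::rnorm(length(bg_ids) * n_samp, mean = rep(mu, times = n_samp),
                   sd = config$baseline_sd),
      nrow = length(bg_ids), ncol = n_samp,
      dimnames = list(bg_ids, samp_ids)
    )
    rows <- list(bg)
    for (r in seq_len(nrow(planted))) {
      p_by_class <- c(KD = planted$p_kd[r], DB = planted$p_db[r], DV = planted$p_dv[r])
      p <- unname(p_by_class[classes])
      ind <- stats::rbinom(n_samp, 1L, p)
      u <- stats::rnorm(n_samp, config$baseline_mean, config$baseline_sd)
      xi <- u + ifelse(ind == 1L, planted$gap[r], 0)
      xj <- u + ifelse(ind == 1L, 0, planted$gap[r])
      pm <- rbind(xi, xj)
      dimnames(pm) <- list(c(planted$gene_i[r], planted$gene_j[r]), samp_ids)
      rows[[r + 1L]] <- pm
    }
    values <- do.call(rbind, rows)
  })

  ds <- expr_dataset(values, tibble(sample_id = samp_ids, class = classes))
  attr(ds, "truth") <- planted
  ds
}

#' The package's reference planted cohort
#'
#' A cohort of 60 KD / 40 DB / 60 DV samples over 200 genes, 7 of the
#' 100 gene pairs planted with order-reversal probability 0.95 in KD and
#' 0.05 in both infection subclasses (186 exchangeable background genes).
#' This is the ground-truth test bed used throughout the documentation and
#' tests.
#'
#' @param seed integer seed.
#' @param n_kd,n_db,n_dv,n_pairs,p_kd,p_fi,n_genes overridable condition
#'   parameters; `n_genes` counts planted and background genes together.
#' @return an `expr_dataset` with a `truth` attribute.
#' @export
standard_cohort <- function(seed = 1L, n_kd = 60, n_db = 40, n_dv = 60,
                            n_pairs = 7, p_kd = 0.95, p_fi = 0.05,
                            n_genes = 200) {
  n_bg <- n_genes - 2L * n_pairs
  stopifnot(n_bg >= 0)
  generate_cohort(cohort_config(
    n_kd = n_kd, n_db = n_db, n_dv = n_dv, n_background_genes = n_bg,
    planted = planted_pairs(n_pairs, p_kd = p_kd, p_db = p_fi, p_dv = p_fi),
    seed = seed
  ))
}

#' Apply a strictly increasing within-sample transform
#'
#' Pair indicators depend only on within-sample orderings, so every score,
#' filter and classifier in the package is invariant under these maps. Used
#' to assert that rank invariance in tests and examples.
#'
#' @param dataset an [expr_dataset()].
#' @param transform one of `"exp"`, `"affine_pos"` (x -> 3x + 7), `"rank"`
#'   (within-sample ranks).
#' @export
apply_monotone_transform <- function(dataset,
                                     transform = c("exp", "affine_pos", "rank")) {
  transform <- match.arg(transform)
  v <- dataset$values
  v2 <- switch(transform,
    exp = exp(v),
    affine_pos = 3 * v + 7,
    rank = rank_matrix(v)
  )
  dimnames(v2) <- dimnames(v)
  out <- expr_dataset(v2, dataset$labels)
  attr(out, "truth") <- attr(dataset, "truth")
  out
}

#' Probe-level fixture with a known collapsing answer
#'
#' Builds a probe matrix plus annotation table in which the probe that
#' should survive [collapse_probes()] for each gene is known by
#' construction (probe means are spaced by construction, widest mean last),
#' together with the expected gene-level matrix.
#'
#' @param genes character vector of gene ids.
#' @param probes_per_gene number of probes mapped to each gene.
#' @param n_unannotated,n_multi counts of unannotated and multi-gene probes
#'   to add (both must be filtered out by collapsing).
#' @param n_samples number of samples.
#' @param seed integer seed.
#' @return a list with `probe_data`, `annotation`, `expected` (the gene
#'   matrix collapsing must reproduce) and `survivors` (gene -> probe id).
#' @export
generate_probe_fixture <- function(genes = c("G1", "G2", "G3"),
                                   probes_per_gene = 3, n_unannotated = 2,
                                   n_multi = 2, n_samples = 6, seed = 1L) {
  stopifnot(probes_per_gene >= 1, n_samples >= 1)
  with_seed_(seed, {
    rows <- list(); ann <- list(); survivors <- character(0)
    expected <- list()
    for (g in genes) {
      for (k in seq_len(probes_per_gene)) {
        pid <- sprintf("%s_p%d", g, k)
        vals <- stats::rnorm(n_samples, mean = 4 + k, sd = 0.1)
        rows[[pid]] <- vals
        ann[[pid]] <- g
      }
      surv <- sprintf("%s_p%d", g, probes_per_gene)
      survivors[g] <- surv
      expected[[g]] <- rows[[surv]]
    }
    for (k in seq_len(n_unannotated)) {
      pid <- sprintf("UNANN_p%d", k)
      rows[[pid]] <- stats::rnorm(n_samples, 6, 0.1)
      ann[[pid]] <- ""
    }
    for (k in seq_len(n_multi)) {
      pid <- sprintf("MULTI_p%d", k)
      rows[[pid]] <- stats::rnorm(n_samples, 6, 0.1)
      ann[[pid]] <- paste(genes[c(1, min(2, length(genes)))], collapse = ";")
    }
  })
  samp <- sprintf("S%02d", seq_len(n_samples))
  probe_data <- bind_cols(
    tibble(probe_id = names(rows)),
    as_tibble(stats::setNames(as.data.frame(do.call(rbind, rows)), samp))
  )
  annotation <- tibble(probe_id = names(ann), gene_symbols = unname(unlist(ann)))
  expected_mat <- bind_cols(
    tibble(gene_id = names(expected)),
    as_tibble(stats::setNames(as.data.frame(do.call(rbind, expected)), samp))
  )
  list(probe_data = probe_data, annotation = annotation,
       expected = expected_mat, survivors = survivors)
}
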