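#' Binary gene-pair indicator
#'
#' The elementary rank feature: 1 when the expression of gene i strictly
#' exceeds that of gene j within a sample, else 0. Ties fall in the 0 (non
#' KD-voting) branch.
#'
#' @param x_i,x_j finite numeric vectors (recycled elementwise).
#' @return an integer vector of 0/1 indicators.
#' @export
pair_indicator <- function(x_i, x_j) {
  if (any(!is.finite(x_i)) || any(!is.finite(x_j))) {
    abort("pair_indicator requires finite inputs")
  }
  as.integer(x_i > x_j)
}

# --- internal scoring engines ------------------------------------------------

# Score explicitly oriented candidate pairs. values: genes x samples matrix;
# pairs: tibble(gene_i, gene_j); idx1/idx2: class column indices;
# rankmat: within-sample rank matrix over ALL genes of the dataset.
score_candidate_pairs <- function(values, pairs, idx1, idx2, rankmat = NULL) {
  ids <- rownames(values)
  i <- match(pairs$gene_i, ids)
  j <- match(pairs$gene_j, ids)
  if (anyNA(i) || anyNA(j)) {
    missing <- unique(c(pairs$gene_i[is.na(i)], pairs$gene_j[is.na(j)]))
    abort(paste0("pair gene(s) absent from dataset: ", paste(missing, collapse = ", ")))
  }
  if (is.null(rankmat)) rankmat <- rank_matrix(values)
  p1 <- rowMeans(values[i, idx1, drop = FALSE] > values[j, idx1, drop = FALSE])
  p2 <- rowMeans(values[i, idx2, drop = FALSE] > values[j, idx2, drop = FALSE])
  g1 <- rowMeans(rankmat[i, idx1, drop = FALSE] - rankmat[j, idx1, drop = FALSE])
  g2 <- rowMeans(rankmat[i, idx2, drop = FALSE] - rankmat[j, idx2, drop = FALSE])
  tibble(
    gene_i = pairs$gene_i, gene_j = pairs$gene_j,
    p1 = unname(p1), p2 = unname(p2), delta = unname(abs(p1 - p2)),
    rank_gamma = unname(g1 - g2)
  )
}

# Enumerate and score all unordered pairs among `genes`, collapsing the two
# orientations to the one with p1 >= p2.
score_all_pairs <- function(values, genes, idx1, idx2, rankmat = NULL) {
  sub <- values[genes, , drop = FALSE]
  if (is.null(rankmat)) rankmat <- rank_matrix(values)
  rk <- rankmat[genes, , drop = FALSE]
  G <- nrow(sub)
  if (G < 2) return(tibble(gene_i = character(0), gene_j = character(0),
                           p1 = double(0), p2 = double(0),
                           delta = double(0), rank_gamma = double(0)))
  n1 <- length(idx1); n2 <- length(idx2)
  out <- vector("list", G - 1L)
  for (i in seq_len(G - 1L)) {
    J <- (i + 1L):G
    xi1 <- matrix(sub[i, idx1], nrow = length(J), ncol = n1, byrow = TRUE)
    xi2 <- matrix(sub[i, idx2], nrow = length(J), ncol = n2, byrow = TRUE)
    Xj1 <- sub[J, idx1, drop = FALSE]
    Xj2 <- sub[J, idx2, drop = FALSE]
    p1 <- rowMeans(xi1 > Xj1)          # P_class1(x_i > x_j)
    p2 <- rowMeans(xi2 > Xj2)
    q1 <- rowMeans(Xj1 > xi1)          # flipped orientation (differs under ties)
    q2 <- rowMeans(Xj2 > xi2)
    gamma <- (mean(rk[i, idx1]) - rowMeans(rk[J, idx1, drop = FALSE])) -
             (mean(rk[i, idx2]) - rowMeans(rk[J, idx2, drop = FALSE]))
    flip <- unname(p1 < p2)
    out[[i]] <- tibble(
      gene_i = unname(ifelse(flip, genes[J], genes[i])),
      gene_j = unname(ifelse(flip, genes[i], genes[J])),
      p1 = unname(ifelse(flip, q1, p1)),
      p2 = unname(ifelse(flip, q2, p2)),
      rank_gamma = unname(ifelse(flip, -gamma, gamma))
    )
  }
  bind_rows(out) |> mutate(delta = abs(.data$p1 - .data$p2)) |>
    select("gene_i", "gene_j", "p1", "p2", "delta", "rank_gamma")
}

greedy_disjoint <- function(scores) {
  used <- character(0)
  keep <- logical(nrow(scores))
  for (r in seq_len(nrow(scores))) {
    gi <- scores$gene_i[r]; gj <- scores$gene_j[r]
    if (!(gi %in% used) && !(gj %in% used)) {
      keep[r] <- TRUE
      used <- c(used, gi, gj)
    }
  }
  scores[keep, , drop = FALSE]
}

sort_pair_scores <- function(scores) {
  arrange(scores, desc(.data$delta), desc(abs(.data$rank_gamma)),
          .data$gene_i, .data$gene_j)
}

#' Score one gene pair between two classes
#'
#' `p1` and `p2` are the class-conditional frequencies of the indicator
#' `gene_i > gene_j`; the pair score is `delta = |p1 - p2|`, the TSP
#' statistic. `rank_gamma` is the k-TSP secondary statistic: the between
#' class difference of the mean within-sample rank difference of the two
#' genes (ranks taken across all genes of the dataset).
#'
#' @param dataset an [expr_dataset()].
#' @param gene_i,gene_j gene ids; orientation means "`gene_i > gene_j`
#'   votes for `class1`".
#' @param class1,class2 class label sets; `"FI"` expands to `c("DB","DV")`.
#' @return a one-row tibble: `gene_i, gene_j, p1, p2, delta, rank_gamma`.
#' @export
pair_score <- function(dataset, gene_i, gene_j, class1 = "KD", class2 = "FI") {
  idx1 <- class_index(dataset, class1)
  idx2 <- class_index(dataset, class2)
  score_candidate_pairs(dataset$values, tibble(gene_i = gene_i, gene_j = gene_j),
                        idx1, idx2)
}

#' Wilcoxon rank-sum gene prefilter
#'
#' Standardizes the two-sample rank-sum statistic of every gene
#' (`class1` vs `class2`, tie-corrected) and keeps the `n_genes/2` most
#' up-regulated and `n_genes/2` most down-regulated genes, the usual
#' k-TSP filtering step that makes pair enumeration tractable.
#'
#' @inheritParams pair_score
#' @param n_genes even number of genes to keep; if the dataset has fewer
#'   genes they are all returned.
#' @return a character vector of gene ids.
#' @export
wilcoxon_filter <- function(dataset, class1 = "KD", class2 = "FI",
                            n_genes = 100) {
  if (n_genes < 2 || n_genes %% 2 != 0) abort("n_genes must be an even integer >= 2")
  idx1 <- class_index(dataset, class1)
  idx2 <- class_index(dataset, class2)
  genes <- gene_ids(dataset)
  if (n_genes >= length(genes)) return(genes)
  z <- wilcoxon_z(dataset$values, idx1, idx2)
  half <- n_genes / 2
  ord_up <- genes[order(-z, genes)]
  ord_dn <- genes[order(z, genes)]
  unique(c(ord_up[seq_len(half)], ord_dn[seq_len(half)]))
}

wilcoxon_z <- function(values, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2); N <- n1 + n2
  sub <- values[, c(idx1, idx2), drop = FALSE]
  rk <- t(apply(sub, 1, rank))
  W <- rowSums(rk[, seq_len(n1), drop = FALSE])
  mu <- n1 * (N + 1) / 2
  tie <- apply(sub, 1, function(x) {
    t <- tabulate(match(x, unique(x)))
    sum(t^3 - t)
  })
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie / (N * (N - 1)))
  (W - mu) / sqrt(pmax(sigma2, .Machine$double.eps))
}

#' Select the top-scoring gene pairs between two classes
#'
#' Without `candidates`, pairs are enumerated among the Wilcoxon-filtered
#' genes with the two orientations of each pair collapsed to the one whose
#' indicator frequency is higher in `class1`. With `candidates`, scoring is
#' restricted to exactly that oriented pair set (the restricted-pair stage).
#' Pairs are ordered by descending `delta`, then descending `|rank_gamma|`,
#' then lexicographically; with `disjoint = TRUE` any pair sharing a gene
#' with an already selected pair is greedily skipped.
#'
#' @inheritParams pair_score
#' @param m maximum number of pairs returned.
#' @param candidates optional tibble with columns `gene_i`, `gene_j`.
#' @param disjoint logical; greedily enforce gene-disjointness.
#' @param n_filter_genes size of the Wilcoxon prefilter (ignored when
#'   `candidates` is given).
#' @param rank_matrix optional precomputed within-sample rank matrix.
#' @return a pair-score tibble (at most `m` rows), sorted.
#' @export
select_top_pairs <- function(dataset, class1 = "KD", class2 = "FI", m = 100,
                             candidates = NULL, disjoint = TRUE,
                             n_filter_genes = 100, rank_matrix = NULL) {
  if (m <= 0) abort("m must be positive")
  idx1 <- class_index(dataset, class1)
  idx2 <- class_index(dataset, class2)
  scores <- if (is.null(candidates)) {
    genes <- wilcoxon_filter(dataset, class1, class2, n_genes = n_filter_genes)
    score_all_pairs(dataset$values, genes, idx1, idx2, rank_matrix)
  } else {
    cand <- distinct(as_tibble(candidates)[c("gene_i", "gene_j")])
    score_candidate_pairs(dataset$values, cand, idx1, idx2, rank_matrix)
  }
  scores <- sort_pair_scores(scores)
  if (disjoint) scores <- greedy_disjoint(scores)
  head(scores, m)
}
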