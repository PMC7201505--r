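# Fixtures built in code and brute-force oracles kept deliberately
# independent of the package's vectorized implementations.

# A random dataset with exchangeable (signal-free) genes.
rand_dataset <- function(n_genes = 8, n_kd = 5, n_db = 3, n_dv = 4, seed = 1) {
  set.seed(seed)
  n <- n_kd + n_db + n_dv
  values <- matrix(rnorm(n_genes * n, mean = 8), nrow = n_genes,
                   dimnames = list(sprintf("G%02d", seq_len(n_genes)),
                                   sprintf("S%02d", seq_len(n))))
  labels <- data.frame(
    sample_id = colnames(values),
    class = rep(c("KD", "DB", "DV"), c(n_kd, n_db, n_dv))
  )
  expr_dataset(values, labels)
}

# Dataset from an explicit genes x samples value table.
dataset_from <- function(values, classes) {
  colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("G%02d", seq_len(nrow(values)))
  }
  expr_dataset(values, data.frame(sample_id = colnames(values), class = classes))
}

# Brute-force pair score: explicit double loop over samples.
brute_pair_score <- function(ds, gi, gj, class1 = "KD", class2 = c("DB", "DV")) {
  v <- expr_values(ds)
  cls <- ds$labels$class
  count1 <- 0; n1 <- 0; count2 <- 0; n2 <- 0
  for (s in seq_len(ncol(v))) {
    ind <- if (v[gi, s] > v[gj, s]) 1 else 0
    if (cls[s] %in% class1) { count1 <- count1 + ind; n1 <- n1 + 1 }
    if (cls[s] %in% class2) { count2 <- count2 + ind; n2 <- n2 + 1 }
  }
  p1 <- count1 / n1; p2 <- count2 / n2
  c(p1 = p1, p2 = p2, delta = abs(p1 - p2))
}

# Brute-force Mann-Whitney AUROC: loop over positive-negative pairs.
brute_auroc <- function(scores, truth, positive = "KD") {
  pos <- scores[truth == positive]
  neg <- scores[truth != positive]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# All within-sample strictly increasing transforms under test.
monotone_transforms <- c("exp", "affine_pos", "rank")
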