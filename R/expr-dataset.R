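#' Expression dataset container
#'
#' An `expr_dataset` bundles a genes-by-samples matrix of (log-scale)
#' expression values with a per-sample class label in `{KD, DB, DV}`.
#' KD is Kawasaki disease; DB and DV are defined bacterial and defined viral
#' febrile infection, pooled as the febrile-infection (FI) control class by
#' every two-class operation in the package.
#'
#' @param values either a numeric matrix (genes x samples, unique rownames =
#'   gene ids, colnames = sample ids) or a data frame whose first column is
#'   `gene_id` and remaining columns are one numeric column per sample.
#' @param labels a data frame with columns `sample_id` and `class`
#'   (values in `KD`, `DB`, `DV`), or a named character vector.
#' @return an object of class `expr_dataset`.
#' @export
expr_dataset <- function(values, labels) {
  if (is.data.frame(values)) {
    df <- as_tibble(values)
    if (names(df)[1] != "gene_id") {
      abort("first column of an expression data frame must be 'gene_id'")
    }
    mat <- as.matrix(df[-1])
    if (!is.numeric(mat)) abort("expression values must be numeric")
    rownames(mat) <- as.character(df$gene_id)
    values <- mat
  }
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("'values' must be a numeric matrix or a gene_id-keyed data frame")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    abort("expression values must be finite with no missing entries")
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    abort("gene ids (rownames) must be present and unique")
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    abort("sample ids (colnames) must be present and unique")
  }
  if (!is.data.frame(labels)) {
    labels <- tibble(sample_id = names(labels), class = unname(labels))
  }
  labels <- as_tibble(labels)[c("sample_id", "class")]
  labels$sample_id <- as.character(labels$sample_id)
  labels$class <- as.character(labels$class)
  if (anyDuplicated(labels$sample_id)) abort("duplicated sample_id in labels")
  bad <- setdiff(labels$class, c("KD", "DB", "DV"))
  if (length(bad)) {
    abort(paste0("unknown class label(s): ", paste(unique(bad), collapse = ", ")))
  }
  missing_lab <- setdiff(colnames(values), labels$sample_id)
  extra_lab <- setdiff(labels$sample_id, colnames(values))
  if (length(missing_lab) || length(extra_lab)) {
    abort(paste0(
      "sample ids of matrix and labels disagree",
      if (length(missing_lab)) paste0("; unlabeled: ", paste(missing_lab, collapse = ", ")),
      if (length(extra_lab)) paste0("; labels without columns: ", paste(extra_lab, collapse = ", "))
    ))
  }
  labels <- labels[match(colnames(values), labels$sample_id), ]
  structure(list(values = values, labels = labels), class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  tab <- table(factor(x$labels$class, levels = c("KD", "DB", "DV")))
  cat(sprintf(
    "<expr_dataset> %d genes x %d samples (KD=%d, DB=%d, DV=%d)\n",
    nrow(x$values), ncol(x$values), tab["KD"], tab["DB"], tab["DV"]
  ))
  invisible(x)
}

#' @rdname expr_dataset
#' @param x an `expr_dataset`.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname expr_dataset
#' @export
sample_ids <- function(x) colnames(x$values)

#' @rdname expr_dataset
#' @export
expr_values <- function(x) x$values

#' Per-sample class labels as a tibble
#'
#' Returns `sample_id`, the three-way `class`, and the pooled two-way
#' `group` (KD vs FI = DB + DV).
#' @param x an `expr_dataset`.
#' @export
sample_classes <- function(x) {
  mutate(x$labels, group = ifelse(.data$class == "KD", "KD", "FI"))
}

# Column indices for a set of class labels ("FI" expands to DB+DV).
class_index <- function(x, classes) {
  classes <- unique(unlist(lapply(classes, function(cl) {
    if (identical(cl, "FI")) c("DB", "DV") else cl
  })))
  idx <- which(x$labels$class %in% classes)
  if (!length(idx)) abort(paste0("no samples with class in {", paste(classes, collapse = ","), "}"))
  idx
}

# Subset samples by id, keeping labels aligned.
subset_samples <- function(x, ids) {
  expr_dataset(x$values[, ids, drop = FALSE],
               x$labels[match(ids, x$labels$sample_id), ])
}

#' Express an expression dataset as a tibble
#'
#' One row per gene: `gene_id` followed by one numeric column per sample.
#' @param x an `expr_dataset`.
#' @param ... unused.
#' @export
as_tibble.expr_dataset <- function(x, ...) {
  bind_cols(tibble(gene_id = rownames(x$values)), as_tibble(x$values))
}

#' Collapse a probe-level matrix to one row per gene
#'
#' Probe-level array data is reduced to gene level by (i) dropping probes
#' with no gene annotation, (ii) dropping probes annotated to more than one
#' gene, and (iii) for each gene with several surviving probes, keeping the
#' probe whose mean intensity across all samples is highest. Ties on the
#' mean are broken toward the lexicographically smallest probe id.
#'
#' @param probe_data a data frame whose first column is `probe_id` and whose
#'   remaining columns are numeric sample intensities.
#' @param annotation a data frame with columns `probe_id` and `gene_symbols`;
#'   `gene_symbols` is a `;`-separated string (empty = unannotated). Probes
#'   absent from the table count as unannotated.
#' @param labels optional per-sample labels; when supplied the result is an
#'   [expr_dataset()], otherwise a gene-keyed tibble.
#' @return a tibble (`gene_id` + sample columns) or an `expr_dataset`.
#' @export
collapse_probes <- function(probe_data, annotation, labels = NULL) {
  probe_data <- as_tibble(probe_data)
  if (names(probe_data)[1] != "probe_id") abort("first column must be 'probe_id'")
  if (anyDuplicated(probe_data$probe_id)) abort("duplicated probe_id in probe matrix")
  annotation <- as_tibble(annotation)
  if (anyDuplicated(annotation$probe_id)) abort("duplicated probe_id in annotation")

  symbols <- strsplit(as.character(annotation$gene_symbols), ";", fixed = TRUE)
  symbols <- lapply(symbols, function(s) s[nzchar(s)])
  single <- lengths(symbols) == 1L
  map <- tibble(
    probe_id = as.character(annotation$probe_id)[single],
    gene_id = vapply(symbols[single], identity, character(1))
  )

  kept <- inner_join(probe_data, map, by = "probe_id")
  if (nrow(kept) == 0L) {
    abort("no annotated single-gene probe survives collapsing: empty dataset")
  }
  value_cols <- setdiff(names(probe_data), "probe_id")
  means <- rowMeans(as.matrix(kept[value_cols]))
  kept <- kept |>
    mutate(.mean = means) |>
    arrange(.data$gene_id, desc(.data$.mean), .data$probe_id) |>
    distinct(.data$gene_id, .keep_all = TRUE) |>
    select("gene_id", all_of(value_cols))

  if (is.null(labels)) kept else expr_dataset(kept, labels)
}

#' Restrict datasets to their common genes
#'
#' Each dataset is reduced to the sorted intersection of gene ids across all
#' inputs, in identical row order, so pair features are comparable between
#' cohorts.
#'
#' @param datasets a list of [expr_dataset()] objects.
#' @return a list of `expr_dataset` objects over the same sorted gene set.
#' @export
intersect_common_genes <- function(datasets) {
  if (!length(datasets)) abort("need at least one dataset")
  gene_sets <- lapply(datasets, gene_ids)
  common <- Reduce(intersect, gene_sets)
  if (!length(common)) {
    sizes <- vapply(gene_sets, length, integer(1))
    abort(paste0(
      "empty gene intersection across datasets (gene counts: ",
      paste(sizes, collapse = ", "), ")"
    ))
  }
  common <- sort(common)
  lapply(datasets, function(d) {
    expr_dataset(d$values[common, , drop = FALSE], d$labels)
  })
}

#' Read / write an expression dataset as TSV
#'
#' The matrix file is tab-separated with a `gene_id` first column and one
#' column per sample; the labels file has columns `sample_id` and `class`.
#' Values are written at full precision so a write/read round trip is exact.
#'
#' @param matrix_path,labels_path file paths.
#' @return `read_expr_dataset` returns an [expr_dataset()];
#'   `write_expr_dataset` invisibly returns the input.
#' @export
read_expr_dataset <- function(matrix_path, labels_path) {
  raw <- readr::read_tsv(matrix_path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (names(raw)[1] != "gene_id") abort("matrix file must start with a 'gene_id' column")
  if (anyDuplicated(raw$gene_id)) {
    dup <- raw$gene_id[duplicated(raw$gene_id)][1]
    abort(paste0("duplicated gene_id in matrix: ", dup))
  }
  num <- raw
  for (col in names(raw)[-1]) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad)) {
      abort(sprintf("non-numeric value '%s' at row %d, column '%s'",
                    raw[[col]][bad[1]], bad[1], col))
    }
    num[[col]] <- v
  }
  labels <- readr::read_tsv(labels_path,
                            col_types = readr::cols(.default = "c"),
                            progress = FALSE)
  expr_dataset(num, labels)
}

#' @rdname read_expr_dataset
#' @param dataset an [expr_dataset()].
#' @export
write_expr_dataset <- function(dataset, matrix_path, labels_path) {
  readr::write_tsv(as_tibble(dataset), matrix_path, progress = FALSE)
  readr::write_tsv(dataset$labels, labels_path, progress = FALSE)
  invisible(dataset)
}
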