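# Model and pair-list serialization (JSON / TSV side formats).

#' Write / read a classifier model as JSON
#'
#' k-TSP models serialize as `{pairs, k, positive_class}`, TRGP models as
#' `{pairs, n_pairs, positive_class, threshold}`.
#'
#' @param model a `ktsp_model` or `trgp_model`.
#' @param path file path.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "ktsp_model")) {
    obj <- list(type = "ktsp", pairs = model$pairs, k = model$k,
                positive_class = model$positive_class)
  } else if (inherits(model, "trgp_model")) {
    obj <- list(type = "trgp", pairs = model$pairs, n_pairs = model$n_pairs,
                positive_class = model$positive_class, threshold = model$threshold)
  } else {
    abort("write_model supports ktsp_model and trgp_model objects")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(model)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pairs <- as_tibble(obj$pairs)
  switch(obj$type,
    ktsp = new_ktsp(pairs, obj$k),
    trgp = trgp_model(pairs, positive_class = obj$positive_class),
    abort(paste0("unknown model type: ", obj$type))
  )
}

#' Write / read a scored pair list as TSV
#'
#' Columns: `gene_i`, `gene_j`, and any score columns present
#' (`p1`, `p2`, `delta`, `rank_gamma`, `rate`, ...).
#'
#' @param pairs a pair tibble.
#' @param path file path.
#' @export
write_pairs <- function(pairs, path) {
  readr::write_tsv(as_tibble(pairs), path, progress = FALSE)
  invisible(pairs)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
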