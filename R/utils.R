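# Internal helpers shared across the package.

#' @importFrom rlang abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer
#' @importFrom purrr map map_dbl map_chr
NULL

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream. Restores (or removes) .Random.seed on exit.
with_seed_ <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Counter-style seed derivation: one child seed per index, reproducible from
# the master seed and independent of the order in which children are consumed.
derive_seeds <- function(seed, n) {
  with_seed_(seed, sample.int(2147483646L, n, replace = FALSE))
}

is_odd <- function(x) x %% 2L == 1L

# Within-sample ranks across all genes (genes x samples in, same shape out).
rank_matrix <- function(values) {
  rk <- apply(values, 2, rank)
  dimnames(rk) <- dimnames(values)
  rk
}

`%||%` <- function(x, y) if (is.null(x)) y else x
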