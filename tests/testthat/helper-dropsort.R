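# shared fixtures built in code

`%||%` <- function(a, b) if (is.null(a)) b else a

# ground-truth status -> expected classifier call
truth_to_call <- c(intact = "cell", damaged = "damaged", empty = "empty")

# library with a given empty/damaged composition (remainder intact)
make_library <- function(n_barcodes, p_empty, p_damaged, seed, ...) {
  n_empty <- round(n_barcodes * p_empty)
  n_damaged <- round(n_barcodes * p_damaged)
  generate_counts(synth_config(
    n_intact = n_barcodes - n_empty - n_damaged,
    n_damaged = n_damaged,
    n_empty = n_empty,
    seed = seed,
    ...
  ))
}

# tiny deterministic count matrix from dense layers
dense_cm <- function(spliced, unspliced = NULL, species = NULL, mito = NULL) {
  s <- as.matrix(spliced)
  if (is.null(rownames(s))) rownames(s) <- sprintf("g%02d", seq_len(nrow(s)))
  if (is.null(colnames(s))) colnames(s) <- sprintf("bc%02d", seq_len(ncol(s)))
  u <- if (is.null(unspliced)) {
    matrix(0, nrow(s), ncol(s), dimnames = dimnames(s))
  } else {
    u <- as.matrix(unspliced); dimnames(u) <- dimnames(s); u
  }
  genes <- tibble::tibble(
    gene = rownames(s),
    species = species %||% rep(NA_character_, nrow(s)),
    is_mito = mito %||% rep(FALSE, nrow(s))
  )
  count_matrix(s, u, genes = genes)
}
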