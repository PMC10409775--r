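#' Barcode x gene UMI count container with spliced/unspliced layers
#'
#' Lightweight container for droplet scRNA-seq counts: two sparse integer
#' layers of identical shape (genes in rows, barcodes in columns, the usual
#' market-matrix orientation), a gene annotation tibble carrying species and
#' mitochondrial flags, and an optional per-barcode ground-truth tibble when
#' the matrix came from the synthetic generator.
#'
#' @param spliced,unspliced Sparse (or dense) non-negative integer matrices,
#'   genes x barcodes, same dimnames.
#' @param genes Tibble with columns `gene`, `species`, `is_mito` (missing
#'   columns are filled with defaults).
#' @param truth Optional per-barcode tibble with columns `barcode`, `status`
#'   (`intact` / `damaged` / `empty`), `type`, `is_doublet`, `species_mix`.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(spliced, unspliced, genes = NULL, truth = NULL) {
  as_sparse <- function(m) {
    m <- Matrix::Matrix(m, sparse = TRUE)
    methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  }
  spliced <- as_sparse(spliced)
  unspliced <- as_sparse(unspliced)
  if (!identical(dim(spliced), dim(unspliced))) {
    stop("`spliced` and `unspliced` must have identical dimensions.",
         call. = FALSE)
  }
  if (is.null(rownames(spliced)) || is.null(colnames(spliced))) {
    stop("Layers must carry gene rownames and barcode colnames.", call. = FALSE)
  }
  if (min(spliced@x, 0) < 0 || min(unspliced@x, 0) < 0) {
    stop("Counts must be non-negative.", call. = FALSE)
  }
  if (is.null(genes)) {
    genes <- tibble::tibble(gene = rownames(spliced))
  }
  if (is.null(genes$species)) genes$species <- NA_character_
  if (is.null(genes$is_mito)) genes$is_mito <- FALSE
  stopifnot(identical(genes$gene, rownames(spliced)))
  if (!is.null(truth)) {
    stopifnot(setequal(truth$barcode, colnames(spliced)),
              !anyDuplicated(truth$barcode))
    truth <- truth[match(colnames(spliced), truth$barcode), ]
  }
  structure(
    list(spliced = spliced, unspliced = unspliced,
         genes = genes, truth = truth),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d barcodes\n",
              nrow(x$spliced), ncol(x$spliced)))
  cat(sprintf("  spliced UMIs:   %.0f\n", sum(x$spliced)))
  cat(sprintf("  unspliced UMIs: %.0f\n", sum(x$unspliced)))
  if (!is.null(x$truth)) {
    tab <- table(x$truth$status)
    cat("  truth: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$spliced)

assert_count_matrix <- function(x) {
  if (!inherits(x, "count_matrix")) {
    stop("Expected a `count_matrix`; see `count_matrix()` or ",
         "`generate_counts()`.", call. = FALSE)
  }
  invisible(x)
}

#' Barcode identifiers of a count matrix
#' @param x A `count_matrix`.
#' @return Character vector of barcodes.
#' @export
barcodes <- function(x) {
  assert_count_matrix(x)
  colnames(x$spliced)
}

#' Per-barcode total UMI counts (spliced + unspliced)
#' @param x A `count_matrix`.
#' @return A tibble with columns `barcode`, `spliced`, `unspliced`, `total`.
#' @export
barcode_totals <- function(x) {
  assert_count_matrix(x)
  s <- unname(Matrix::colSums(x$spliced))
  u <- unname(Matrix::colSums(x$unspliced))
  tibble::tibble(
    barcode = colnames(x$spliced),
    spliced = s,
    unspliced = u,
    total = s + u
  )
}

#' Write a count matrix as Matrix Market layers with TSV sidecars
#'
#' Writes `spliced.mtx`, `unspliced.mtx`, `barcodes.tsv`, `genes.tsv` (with
#' `species` and `is_mito` columns) and, when ground truth is present,
#' `truth.csv` into `dir`.
#'
#' @param x A `count_matrix`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(x, dir) {
  assert_count_matrix(x)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$spliced, file.path(dir, "spliced.mtx"))
  Matrix::writeMM(x$unspliced, file.path(dir, "unspliced.mtx"))
  writeLines(colnames(x$spliced), file.path(dir, "barcodes.tsv"))
  utils::write.table(x$genes, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(x$truth)) {
    utils::write.csv(x$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' @param dir Directory holding `spliced.mtx` / `unspliced.mtx` (an
#'   `unspliced` layer of zeros is assumed when the file is absent),
#'   `barcodes.tsv`, `genes.tsv` and optionally `truth.csv`.
#' @return A `count_matrix`.
#' @export
read_count_matrix <- function(dir) {
  bc <- readLines(file.path(dir, "barcodes.tsv"))
  genes <- tibble::as_tibble(
    utils::read.table(file.path(dir, "genes.tsv"), sep = "\t", header = TRUE,
                      colClasses = c(gene = "character"))
  )
  spliced <- methods::as(Matrix::readMM(file.path(dir, "spliced.mtx")),
                         "CsparseMatrix")
  dimnames(spliced) <- list(genes$gene, bc)
  unspliced_path <- file.path(dir, "unspliced.mtx")
  unspliced <- if (file.exists(unspliced_path)) {
    u <- methods::as(Matrix::readMM(unspliced_path), "CsparseMatrix")
    dimnames(u) <- list(genes$gene, bc)
    u
  } else {
    Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                         dims = dim(spliced), dimnames = dimnames(spliced))
  }
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) {
    tibble::as_tibble(utils::read.csv(truth_path,
                                      colClasses = c(barcode = "character")))
  }
  count_matrix(spliced, unspliced, genes = genes, truth = truth)
}
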