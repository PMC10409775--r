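#' Mean normalized expression profile per group of barcodes
#'
#' Normalizes every barcode to 10,000 total UMIs (counts-per-10k), applies
#' `log1p`, and averages within groups. Spliced and unspliced layers are
#' summed before normalization. The result is the per-cluster (or
#' per-label) profile matrix that label transfer correlates.
#'
#' @param x A [count_matrix()].
#' @param groups Either a named character vector (names = barcodes) or a
#'   tibble/data.frame with columns `barcode` and `group`; every barcode of
#'   `x` must be covered.
#' @return A `profile_matrix`: numeric matrix, groups x genes, with the
#'   normalization recorded in the `normalization` attribute.
#' @export
mean_profiles <- function(x, groups) {
  assert_count_matrix(x)
  if (is.data.frame(groups)) {
    stopifnot(all(c("barcode", "group") %in% names(groups)))
    g <- stats::setNames(as.character(groups$group), groups$barcode)
  } else {
    g <- groups
  }
  bcs <- barcodes(x)
  if (!all(bcs %in% names(g))) {
    stop("Every barcode needs a group label.", call. = FALSE)
  }
  g <- g[bcs]
  counts <- x$spliced + x$unspliced
  tot <- Matrix::colSums(counts)
  if (any(tot == 0)) {
    stop("Zero-count barcodes cannot be normalized; drop them first.",
         call. = FALSE)
  }
  norm <- log1p(counts %*% Matrix::Diagonal(x = 10000 / tot))
  levels_g <- sort(unique(g))
  prof <- matrix(0, length(levels_g), nrow(counts),
                 dimnames = list(levels_g, rownames(counts)))
  for (lv in levels_g) {
    sel <- which(g == lv)
    if (length(sel) == 0L) stop("Group `", lv, "` has zero barcodes.",
                                call. = FALSE)
    prof[lv, ] <- Matrix::rowMeans(norm[, sel, drop = FALSE])
  }
  structure(prof, class = c("profile_matrix", "matrix", "array"),
            normalization = "CP10K+log1p")
}

#' Transfer reference labels to clusters by maximum Pearson correlation
#'
#' Correlates every cluster's mean expression profile with every reference
#' label's profile over the genes shared by the two matrices (set
#' intersection; at least two genes required) and assigns each cluster the
#' reference label with the highest Pearson correlation. Zero-variance
#' profiles give undefined correlations, which are recorded as `NA` and
#' excluded from the argmax; ties are broken by lexical label order with a
#' warning.
#'
#' @param cluster_profiles,reference_profiles `profile_matrix` objects from
#'   [mean_profiles()] (any numeric matrix with row and column names works).
#' @param genes Optional character vector restricting the correlation to a
#'   gene list (e.g. highly variable genes); default uses all shared genes.
#' @return A list of class `transfer_result`: `mapping` tibble (`cluster`,
#'   `label`, `r`), the full `correlations` matrix (clusters x labels) and
#'   `shared_genes`.
#' @export
transfer_labels <- function(cluster_profiles, reference_profiles,
                            genes = NULL) {
  cl <- as.matrix(cluster_profiles)
  ref <- as.matrix(reference_profiles)
  shared <- intersect(colnames(cl), colnames(ref))
  if (!is.null(genes)) shared <- intersect(shared, genes)
  if (length(shared) < 2L) {
    stop("Need at least 2 shared genes to correlate profiles (found ",
         length(shared), ").", call. = FALSE)
  }
  cl <- cl[, shared, drop = FALSE]
  ref <- ref[, shared, drop = FALSE]
  suppressWarnings(cors <- stats::cor(t(cl), t(ref), method = "pearson"))
  # zero-variance rows/cols produce NA (sd = 0); excluded from the argmax
  mapping <- purrr::map_dfr(seq_len(nrow(cors)), function(i) {
    r <- cors[i, ]
    if (all(is.na(r))) {
      stop("Cluster `", rownames(cors)[i], "` has no defined correlation ",
           "with any reference label (zero-variance profile).", call. = FALSE)
    }
    best <- max(r, na.rm = TRUE)
    hits <- sort(colnames(cors)[!is.na(r) & r == best])
    if (length(hits) > 1L) {
      warning("Cluster `", rownames(cors)[i], "`: correlation tie between ",
              paste(hits, collapse = ", "), "; keeping `", hits[1L], "`.")
    }
    tibble::tibble(cluster = rownames(cors)[i], label = hits[1L], r = best)
  })
  structure(list(mapping = mapping, correlations = cors,
                 shared_genes = shared),
            class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat(sprintf("<transfer_result> %d cluster(s), %d reference label(s), %d shared genes\n",
              nrow(x$correlations), ncol(x$correlations),
              length(x$shared_genes)))
  print(x$mapping)
  invisible(x)
}

#' Convenience k-means clustering on log-normalized counts
#'
#' Simple cluster labels for exercising [transfer_labels()] when no external
#' clustering is available: k-means on the CP10K + `log1p` matrix. This is a
#' helper, not a replacement for graph-based clustering of real data.
#'
#' @param x A [count_matrix()].
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @return A tibble with `barcode`, `group` (`"c1"`, `"c2"`, ...).
#' @export
cluster_kmeans <- function(x, k, seed = 0) {
  assert_count_matrix(x)
  counts <- x$spliced + x$unspliced
  tot <- Matrix::colSums(counts)
  keep <- tot > 0
  m <- t(as.matrix(log1p(counts[, keep, drop = FALSE] %*%
                           Matrix::Diagonal(x = 10000 / tot[keep]))))
  km <- with_stream_seed(seed, "occupancy",
                         stats::kmeans(m, centers = k, nstart = 5))
  tibble::tibble(barcode = colnames(counts)[keep],
                 group = paste0("c", km$cluster))
}
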