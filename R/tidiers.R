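#' Turn a dropsort result object into a tidy tibble
#'
#' Broom-style generics: `tidy()` returns the per-unit table of a result
#' (category fractions, per-barcode QC rows, cluster mapping), `glance()` a
#' one-row summary.
#'
#' @param x A dropsort result object.
#' @param ... Passed to methods.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Tidy a composition table into a plain tibble
#'
#' @param x A `composition_table` from [predicted_composition()] or
#'   [empirical_composition()].
#' @param ... Unused.
#' @return A tibble with the category fractions plus `conditioning` and
#'   `source` columns.
#' @export
tidy.composition_table <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(conditioning = attr(x, "conditioning"),
                  source = attr(x, "source"))
}

#' One-row summary of a composition table
#' @param x A `composition_table`.
#' @param ... Unused.
#' @return A one-row tibble: singlet/multiplet fractions and the population.
#' @export
glance.composition_table <- function(x, ...) {
  f <- stats::setNames(x$fraction, x$category)
  tibble::tibble(
    conditioning = attr(x, "conditioning"),
    source = attr(x, "source"),
    empty = f[["empty"]],
    single_live = f[["single_live"]],
    singlet = f[["single_live"]] + f[["single_dead"]],
    multiplet = f[["live_dead_pair"]] + f[["multi_live"]] +
      f[["multi_dead"]] + f[["mixed_multiplet"]]
  )
}

#' Tidy the per-barcode table of a QC report
#' @param x A `qc_report`.
#' @param ... Unused.
#' @return The per-barcode tibble.
#' @export
tidy.qc_report <- function(x, ...) x$per_barcode

#' One-row summary of a QC report
#' @param x A `qc_report`.
#' @param ... Unused.
#' @return The summary tibble (cells called, knee, fraction of reads in
#'   cells, status proportions).
#' @export
glance.qc_report <- function(x, ...) x$summary

#' Tidy a label-transfer result into the cluster-to-label mapping
#' @param x A `transfer_result`.
#' @param ... Unused.
#' @return Tibble with `cluster`, `label`, `r`.
#' @export
tidy.transfer_result <- function(x, ...) x$mapping

#' One-row summary of a label-transfer result
#' @param x A `transfer_result`.
#' @param ... Unused.
#' @return One-row tibble: cluster/label counts, shared genes, mean and
#'   minimum mapped correlation.
#' @export
glance.transfer_result <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x$correlations),
    n_labels = ncol(x$correlations),
    n_shared_genes = length(x$shared_genes),
    mean_r = mean(x$mapping$r),
    min_r = min(x$mapping$r)
  )
}

#' Tidy barnyard statistics into the per-barcode table
#' @param x A `barnyard_stats` object.
#' @param ... Unused.
#' @return The per-barcode purity tibble.
#' @export
tidy.barnyard_stats <- function(x, ...) x$per_barcode

#' One-row summary of barnyard statistics
#' @param x A `barnyard_stats` object.
#' @param ... Unused.
#' @return The summary tibble (species fractions, observed cross-species
#'   rate, inferred multiplet rate).
#' @export
glance.barnyard_stats <- function(x, ...) x$summary
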