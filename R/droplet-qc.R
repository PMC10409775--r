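#' Rank barcodes by descending total UMI count
#'
#' The first stage of the ranked-barcode ("knee") plot: barcodes sorted by
#' total counts (spliced + unspliced), ties broken stably by barcode
#' identifier so ranks are reproducible.
#'
#' @param x A [count_matrix()].
#' @return A tibble with columns `rank` (1-based), `barcode`, `total`,
#'   sorted by rank; class `ranked_barcodes`.
#' @export
rank_barcodes <- function(x) {
  assert_count_matrix(x)
  tot <- barcode_totals(x)
  if (all(tot$total == 0)) {
    stop("All barcodes have zero counts; nothing to rank.", call. = FALSE)
  }
  out <- tot |>
    dplyr::arrange(dplyr::desc(.data$total), .data$barcode) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("rank", "barcode", "total")
  structure(out, class = c("ranked_barcodes", class(tibble::tibble())))
}

#' Detect the knee of a ranked-barcode curve
#'
#' Finds the inflection separating cell-containing barcodes from the
#' ambient/empty background as the point of maximum perpendicular distance
#' between the log-rank / log-total curve and the chord joining its
#' endpoints. Working in log-log space makes the result invariant to uniform
#' rescaling of the totals. A confidence score — maximum chord distance
#' divided by chord length — flags curves with no real plateau structure:
#' below `min_confidence` the result is reported as "no inflection", the
#' behaviour of a near power-law library where cells and background are not
#' separable by rank.
#'
#' @param ranked A `ranked_barcodes` tibble from [rank_barcodes()] (any
#'   tibble with `rank` and `total` columns works).
#' @param min_confidence Confidence below which no knee is called
#'   (default 0.05).
#' @return A one-row tibble with `knee_rank`, `n_cells_called`, `confidence`
#'   and `no_inflection`; `knee_rank`/`n_cells_called` are `NA` when no knee
#'   is called.
#' @export
detect_knee <- function(ranked, min_confidence = 0.05) {
  if (!all(c("rank", "total") %in% names(ranked))) {
    stop("`ranked` must have `rank` and `total` columns; see `rank_barcodes()`.",
         call. = FALSE)
  }
  pos <- ranked[ranked$total > 0, ]
  no_knee <- tibble::tibble(knee_rank = NA_integer_,
                            n_cells_called = NA_integer_,
                            confidence = 0,
                            no_inflection = TRUE)
  if (nrow(pos) < 10L) {
    # too few points to support an inflection; degenerate, not an error
    return(no_knee)
  }
  x <- log10(pos$rank)
  y <- log10(pos$total)
  x1 <- x[1L]; y1 <- y[1L]
  x2 <- x[length(x)]; y2 <- y[length(y)]
  chord_len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  if (chord_len == 0) return(no_knee)  # all totals equal at one rank span
  # signed distance; the knee bulges above the chord (curve is concave-up in
  # the drop region), take absolute distance
  dist <- abs((y2 - y1) * x - (x2 - x1) * y + x2 * y1 - y2 * x1) / chord_len
  conf <- max(dist) / chord_len
  if (max(dist) == 0 || conf < min_confidence) {
    no_knee$confidence <- conf
    return(no_knee)
  }
  knee <- pos$rank[which.max(dist)]
  tibble::tibble(knee_rank = as.integer(knee),
                 n_cells_called = as.integer(knee),
                 confidence = conf,
                 no_inflection = FALSE)
}

#' Fraction of reads captured by the called cell barcodes
#'
#' Exact ratio of total UMIs in the called set to total UMIs in the library;
#' the library-level figure of merit that sorting empty droplets away is
#' meant to raise.
#'
#' @param x A [count_matrix()].
#' @param called Character vector of called cell barcodes (subset of
#'   `barcodes(x)`).
#' @return A single proportion in \[0, 1\].
#' @export
fraction_reads_in_cells <- function(x, called) {
  assert_count_matrix(x)
  if (!all(called %in% barcodes(x))) {
    stop("`called` contains barcodes not present in the matrix.", call. = FALSE)
  }
  if (length(called) == 0L) {
    warning("Empty called set; fraction of reads in cells is 0.")
    return(0)
  }
  tot <- barcode_totals(x)
  sum(tot$total[tot$barcode %in% called]) / sum(tot$total)
}

#' Downsample every barcode to a fixed total UMI count
#'
#' Barcodes whose total exceeds `target_per_barcode` are subsampled without
#' replacement across all (gene, layer) cells — a multivariate
#' hypergeometric draw — so post-hoc totals equal `min(total, target)`
#' exactly; smaller barcodes pass through unchanged. This is the UMI-level
#' analogue of normalising libraries to a fixed read depth before comparing
#' sensitivity.
#'
#' @param x A [count_matrix()].
#' @param target_per_barcode Target total per barcode, >= 0.
#' @param seed Integer seed.
#' @return A [count_matrix()] with downsampled layers (truth carried over).
#' @export
downsample_counts <- function(x, target_per_barcode, seed) {
  assert_count_matrix(x)
  if (length(target_per_barcode) != 1L || is.na(target_per_barcode) ||
      target_per_barcode < 0) {
    stop("`target_per_barcode` must be a single non-negative count.",
         call. = FALSE)
  }
  target <- as.integer(target_per_barcode)
  s <- methods::as(x$spliced, "TsparseMatrix")
  u <- methods::as(x$unspliced, "TsparseMatrix")
  # one triplet table across both layers; layer tagged 0/1
  tri <- tibble::tibble(
    i = c(s@i, u@i), j = c(s@j, u@j),
    layer = rep(c(0L, 1L), c(length(s@x), length(u@x))),
    count = as.integer(c(s@x, u@x))
  ) |> dplyr::filter(.data$count > 0)
  totals <- Matrix::colSums(x$spliced) + Matrix::colSums(x$unspliced)
  over <- which(totals > target) - 1L  # 0-based to match @j
  set.seed(seed)
  if (length(over)) {
    keep_rows <- tri$j %in% over
    done <- tri[!keep_rows, ]
    todo <- tri[keep_rows, ] |> dplyr::arrange(.data$j)
    new_counts <- integer(nrow(todo))
    split_idx <- split(seq_len(nrow(todo)), todo$j)
    for (rows in split_idx) {
      cnt <- todo$count[rows]
      tot <- sum(cnt)
      # sample `target` of the tot UMIs without replacement; map the sampled
      # positions back to their (gene, layer) cells via cumulative bins
      picked <- sample.int(tot, target)
      bins <- findInterval(picked, cumsum(cnt) - cnt + 1L)
      tabs <- tabulate(bins, nbins = length(cnt))
      new_counts[rows] <- tabs
    }
    todo$count <- new_counts
    tri <- dplyr::bind_rows(done, todo) |> dplyr::filter(.data$count > 0)
  }
  mk <- function(layer_id) {
    sel <- tri$layer == layer_id
    Matrix::sparseMatrix(i = tri$i[sel] + 1L, j = tri$j[sel] + 1L,
                         x = tri$count[sel], dims = dim(x$spliced),
                         dimnames = dimnames(x$spliced))
  }
  count_matrix(mk(0L), mk(1L), genes = x$genes, truth = x$truth)
}

#' Per-barcode nuclear fraction
#'
#' The unspliced share of each barcode's UMIs,
#' `nf = unspliced / (unspliced + spliced)`, bounded in \[0, 1\]. Near-zero
#' values indicate ambient-RNA-dominated empty droplets (ambient transcripts
#' are overwhelmingly spliced), high values indicate damaged cells or bare
#' nuclei. Zero-count barcodes get `NA` and are flagged `undefined`.
#'
#' @param x A [count_matrix()].
#' @return A tibble with columns `barcode`, `spliced`, `unspliced`,
#'   `nuclear_fraction`, `undefined`.
#' @export
nuclear_fraction <- function(x) {
  assert_count_matrix(x)
  tot <- barcode_totals(x)
  tot |>
    dplyr::mutate(
      nuclear_fraction = dplyr::if_else(.data$total > 0,
                                        .data$unspliced / .data$total,
                                        NA_real_),
      undefined = .data$total == 0
    ) |>
    dplyr::select("barcode", "spliced", "unspliced", "nuclear_fraction",
                  "undefined")
}

# 1-D k-means++ initial centres
kmeanspp_centers <- function(v, k) {
  centers <- numeric(k)
  centers[1L] <- v[sample.int(length(v), 1L)]
  for (j in 2:k) {
    d2 <- vapply(v, function(p) min((p - centers[seq_len(j - 1L)])^2),
                 numeric(1))
    if (all(d2 == 0)) {
      centers[j:k] <- centers[1L] + stats::runif(k - j + 1L, -1e-9, 1e-9)
      break
    }
    centers[j] <- v[sample.int(length(v), 1L, prob = d2)]
  }
  centers
}

#' Classify barcodes as empty droplets, cells or damaged cells
#'
#' Status call from the per-barcode nuclear fraction. Two methods:
#' `"fixed"` thresholds (`empty` below `cutoffs[1]`, `damaged` above
#' `cutoffs[2]`, `cell` between), or `"kmeans3"` — 1-D k-means with k = 3
#' (k-means++ seeding under a fixed seed) on the defined nuclear fractions,
#' clusters ordered by centre and labelled empty / cell / damaged from
#' lowest to highest. Barcodes with undefined nuclear fraction (zero counts)
#' are excluded from clustering and labelled `empty`.
#'
#' @param nf A tibble from [nuclear_fraction()] (columns `barcode`,
#'   `nuclear_fraction`, `undefined`).
#' @param method `"kmeans3"` (default) or `"fixed"`.
#' @param cutoffs Length-2 numeric `(low, high)` for `method = "fixed"`.
#' @param seed Seed for the k-means initialisation (default 0).
#' @return A tibble with `barcode`, `nuclear_fraction`, `status_call`;
#'   the thresholds or cluster centres used are stored in the `thresholds`
#'   attribute.
#' @export
classify_status <- function(nf, method = c("kmeans3", "fixed"),
                            cutoffs = c(0.1, 0.5), seed = 0) {
  method <- match.arg(method)
  if (!all(c("barcode", "nuclear_fraction") %in% names(nf))) {
    stop("`nf` must come from `nuclear_fraction()`.", call. = FALSE)
  }
  if (is.null(nf$undefined)) nf$undefined <- is.na(nf$nuclear_fraction)
  defined <- !nf$undefined
  status <- rep("empty", nrow(nf))
  if (method == "fixed") {
    if (length(cutoffs) != 2L || cutoffs[1] >= cutoffs[2]) {
      stop("`cutoffs` must be an increasing pair (low, high).", call. = FALSE)
    }
    v <- nf$nuclear_fraction[defined]
    status[defined] <- dplyr::case_when(
      v < cutoffs[1] ~ "empty",
      v > cutoffs[2] ~ "damaged",
      TRUE ~ "cell"
    )
    thresholds <- list(method = "fixed", low = cutoffs[1], high = cutoffs[2])
  } else {
    v <- nf$nuclear_fraction[defined]
    if (length(v) < 3L) {
      stop("`kmeans3` needs at least 3 barcodes with defined nuclear fraction.",
           call. = FALSE)
    }
    km <- with_stream_seed(seed, "occupancy", {
      init <- sort(kmeanspp_centers(v, 3L))
      suppressWarnings(stats::kmeans(v, centers = matrix(init, ncol = 1)))
    })
    ord <- order(km$centers[, 1L])
    labels <- c("empty", "cell", "damaged")[match(seq_len(3L), ord)]
    status[defined] <- labels[km$cluster]
    thresholds <- list(method = "kmeans3",
                       centers = sort(as.numeric(km$centers)))
  }
  out <- tibble::tibble(
    barcode = nf$barcode,
    nuclear_fraction = nf$nuclear_fraction,
    status_call = status
  )
  attr(out, "thresholds") <- thresholds
  out
}

#' Per-barcode mitochondrial UMI fraction
#'
#' Exact share of each barcode's UMIs (both layers) on mitochondrial genes;
#' a standard damage/stress covariate alongside the nuclear fraction.
#'
#' @param x A [count_matrix()].
#' @param mito_genes Character vector of mitochondrial gene identifiers;
#'   defaults to the `is_mito` annotation of the matrix.
#' @return A tibble with `barcode`, `mito`, `total`, `mito_fraction`
#'   (`NA` for zero-count barcodes).
#' @export
mito_fraction <- function(x, mito_genes = NULL) {
  assert_count_matrix(x)
  if (is.null(mito_genes)) mito_genes <- x$genes$gene[x$genes$is_mito]
  if (length(mito_genes) == 0L) {
    stop("Empty mitochondrial gene set.", call. = FALSE)
  }
  if (!all(mito_genes %in% x$genes$gene)) {
    stop("`mito_genes` contains genes absent from the matrix.", call. = FALSE)
  }
  sel <- x$genes$gene %in% mito_genes
  mito <- unname(Matrix::colSums(x$spliced[sel, , drop = FALSE]) +
                   Matrix::colSums(x$unspliced[sel, , drop = FALSE]))
  tot <- unname(Matrix::colSums(x$spliced) + Matrix::colSums(x$unspliced))
  tibble::tibble(
    barcode = colnames(x$spliced),
    mito = mito,
    total = tot,
    mito_fraction = ifelse(tot > 0, mito / tot, NA_real_)
  )
}

#' Species-mixing (barnyard) doublet statistics
#'
#' For a two-species library, computes each barcode's species purity
#' `max(species A counts, species B counts) / total` and calls barcodes
#' below `purity_threshold` cross-species doublets. Because only
#' hetero-species doublets are visible, the observed rate is scaled to an
#' inferred total multiplet rate with the standard correction
#' `observed / (2 * fA * fB)`, where `fA`, `fB` are the species fractions
#' estimated from each barcode's majority species (an estimator that assumes
#' co-encapsulation is independent of species).
#'
#' @param x A [count_matrix()] whose genes carry species annotations.
#' @param purity_threshold Purity below which a barcode is called a
#'   cross-species doublet; in (0.5, 1\].
#' @return A list of class `barnyard_stats`: `per_barcode` tibble (`barcode`,
#'   counts per species, `purity`, `majority_species`, `is_cross_doublet`)
#'   and `summary` one-row tibble (`n_barcodes`, `f_a`, `f_b`,
#'   `observed_cross_rate`, `inferred_multiplet_rate`).
#' @export
barnyard_stats <- function(x, purity_threshold = 0.9) {
  assert_count_matrix(x)
  sp <- x$genes$species
  if (all(is.na(sp))) {
    stop("Genes carry no species annotation; not a barnyard matrix.",
         call. = FALSE)
  }
  if (purity_threshold <= 0.5 || purity_threshold > 1) {
    stop("`purity_threshold` must lie in (0.5, 1].", call. = FALSE)
  }
  species <- sort(unique(stats::na.omit(sp)))
  if (length(species) != 2L) {
    stop("Exactly two species are required; found ", length(species), ".",
         call. = FALSE)
  }
  tot_by <- function(keep) {
    unname(Matrix::colSums(x$spliced[keep, , drop = FALSE]) +
             Matrix::colSums(x$unspliced[keep, , drop = FALSE]))
  }
  a <- tot_by(!is.na(sp) & sp == species[1L])
  b <- tot_by(!is.na(sp) & sp == species[2L])
  tot <- a + b
  if (any(tot == 0)) {
    warning(sum(tot == 0), " zero-count barcode(s) excluded from barnyard ",
            "statistics.")
  }
  per <- tibble::tibble(
    barcode = colnames(x$spliced),
    count_a = a, count_b = b,
    purity = ifelse(tot > 0, pmax(a, b) / tot, NA_real_),
    majority_species = ifelse(tot == 0, NA_character_,
                              ifelse(a >= b, species[1L], species[2L])),
    is_cross_doublet = ifelse(tot > 0, pmax(a, b) / tot < purity_threshold, NA)
  )
  ok <- per[!is.na(per$purity), ]
  f_a <- mean(ok$majority_species == species[1L])
  f_b <- 1 - f_a
  if (f_a == 0 || f_b == 0) {
    stop("Single-species library (species fractions ", round(f_a, 3), "/",
         round(f_b, 3), "); cross-species doublet inference is undefined.",
         call. = FALSE)
  }
  observed <- mean(ok$is_cross_doublet)
  summary <- tibble::tibble(
    n_barcodes = nrow(ok),
    f_a = f_a, f_b = f_b,
    observed_cross_rate = observed,
    inferred_multiplet_rate = observed / (2 * f_a * f_b)
  )
  structure(list(per_barcode = per, summary = summary),
            class = "barnyard_stats")
}

#' @export
print.barnyard_stats <- function(x, ...) {
  cat("<barnyard_stats>\n")
  print(x$summary)
  invisible(x)
}

#' Full barcode-level QC report
#'
#' One call chaining the QC stages: barcode ranking, knee detection and cell
#' calling, fraction of reads in cells, nuclear and mitochondrial fractions
#' and the nuclear-fraction status classification.
#'
#' @param x A [count_matrix()].
#' @param method,cutoffs,seed Passed to [classify_status()].
#' @param min_confidence Passed to [detect_knee()].
#' @return An object of class `qc_report`: `per_barcode` tibble (rank,
#'   totals, nuclear/mito fraction, status call) and `summary` one-row
#'   tibble (`n_barcodes`, `n_cells_called`, `knee_rank`, `knee_confidence`,
#'   `fraction_reads_in_cells`, recovered status proportions), plus the
#'   classifier thresholds used.
#' @export
qc_report <- function(x, method = "kmeans3", cutoffs = c(0.1, 0.5), seed = 0,
                      min_confidence = 0.05) {
  assert_count_matrix(x)
  ranked <- rank_barcodes(x)
  knee <- detect_knee(ranked, min_confidence = min_confidence)
  called <- if (!knee$no_inflection) {
    ranked$barcode[seq_len(knee$n_cells_called)]
  } else {
    character(0)
  }
  fric <- if (length(called)) fraction_reads_in_cells(x, called) else NA_real_
  nf <- nuclear_fraction(x)
  cls <- classify_status(nf, method = method, cutoffs = cutoffs, seed = seed)
  mito <- tryCatch(mito_fraction(x), error = function(e) NULL)
  per <- ranked |>
    dplyr::left_join(nf, by = "barcode") |>
    dplyr::left_join(dplyr::select(cls, "barcode", "status_call"),
                     by = "barcode")
  if (!is.null(mito)) {
    per <- dplyr::left_join(per,
                            dplyr::select(mito, "barcode", "mito_fraction"),
                            by = "barcode")
  }
  props <- prop.table(table(factor(per$status_call,
                                   levels = c("cell", "empty", "damaged"))))
  summary <- tibble::tibble(
    n_barcodes = nrow(per),
    n_cells_called = knee$n_cells_called,
    knee_rank = knee$knee_rank,
    knee_confidence = knee$confidence,
    no_inflection = knee$no_inflection,
    fraction_reads_in_cells = fric,
    prop_cell = as.numeric(props["cell"]),
    prop_empty = as.numeric(props["empty"]),
    prop_damaged = as.numeric(props["damaged"])
  )
  structure(list(per_barcode = per, summary = summary,
                 thresholds = attr(cls, "thresholds")),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  print(x$summary)
  invisible(x)
}
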