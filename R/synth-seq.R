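#' Configuration for the synthetic droplet scRNA-seq generator
#'
#' Defines the statistical structure of a simulated droplet library: planted
#' cell types with Dirichlet expression profiles, lognormal library sizes,
#' ambient RNA mixing, empty droplets drawing from the ambient pool only,
#' damaged cells with elevated unspliced (nuclear) fraction, reduced library
#' size and elevated mitochondrial content, optional two-cell doublets, and
#' optional two-species (barnyard) gene blocks.
#'
#' The default unspliced-fraction means (0.02 empty / 0.25 intact / 0.60
#' damaged) place the three barcode populations at the well-separated modes
#' that nuclear-fraction QC assumes: ambient RNA is overwhelmingly spliced,
#' intact whole cells carry a moderate intronic load, and damaged cells that
#' lost cytoplasmic RNA are dominated by nuclear transcripts.
#'
#' @param n_genes Number of genes (split evenly across species when
#'   `species_split` is set).
#' @param n_types Number of planted cell types.
#' @param type_profiles Optional `n_types` x `n_genes` matrix of gene
#'   probabilities (rows sum to 1). Drawn from a symmetric Dirichlet with
#'   concentration `dirichlet_concentration` when `NULL`.
#' @param dirichlet_concentration Concentration of the symmetric Dirichlet
#'   used to draw type profiles; values below 1 give distinct, sparse-ish
#'   profiles that separate types.
#' @param n_intact,n_damaged,n_empty Barcode counts per ground-truth status.
#' @param library_size_log_mu,library_size_log_sigma Lognormal parameters of
#'   intact-cell total UMIs (defaults: median 5000, sigma 0.35).
#' @param damaged_scale Multiplier on library size for damaged cells
#'   (default 0.5: damaged material captures fewer transcripts).
#' @param empty_scale Multiplier on the library-size median for empty
#'   droplets (default 0.02: ambient-only droplets sit ~50x below cells,
#'   producing the knee of a ranked-barcode plot).
#' @param empty_log_sigma Lognormal sigma of empty-droplet totals (default
#'   0.6; ambient capture is more dispersed than cell capture).
#' @param ambient_fraction Fraction of every cell barcode's UMIs drawn from
#'   the ambient pool profile instead of its own type profile.
#' @param nf_empty,nf_intact,nf_damaged Mean unspliced (nuclear) fraction per
#'   status.
#' @param nf_concentration Beta concentration of per-barcode nuclear
#'   fractions around the status mean (larger = tighter modes).
#' @param mito_gene_count Number of mitochondrial genes (per species block
#'   when species are set).
#' @param mito_fraction_intact,mito_fraction_damaged Expected fraction of a
#'   barcode's UMIs on mitochondrial genes.
#' @param doublet_rate Fraction of intact cell barcodes that are two-cell
#'   doublets (each sums two independently drawn cells).
#' @param species_split Optional fraction of cell types tagged species A
#'   (the rest are species B); `NULL` disables barnyard structure.
#' @param seed Integer seed; generation is fully reproducible.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_genes = 1000,
                         n_types = 3,
                         type_profiles = NULL,
                         dirichlet_concentration = 0.5,
                         n_intact = 1000,
                         n_damaged = 100,
                         n_empty = 10000,
                         library_size_log_mu = log(5000),
                         library_size_log_sigma = 0.35,
                         damaged_scale = 0.5,
                         empty_scale = 0.02,
                         empty_log_sigma = 0.6,
                         ambient_fraction = 0.05,
                         nf_empty = 0.02,
                         nf_intact = 0.25,
                         nf_damaged = 0.6,
                         nf_concentration = 150,
                         mito_gene_count = 10,
                         mito_fraction_intact = 0.05,
                         mito_fraction_damaged = 0.2,
                         doublet_rate = 0,
                         species_split = NULL,
                         seed = 1) {
  fracs <- c(ambient_fraction, nf_empty, nf_intact, nf_damaged,
             mito_fraction_intact, mito_fraction_damaged, doublet_rate)
  if (any(fracs < 0) || any(fracs > 1)) {
    stop("All fractions must lie in [0, 1].", call. = FALSE)
  }
  if (any(c(n_genes, n_types, n_intact, n_damaged, n_empty,
            mito_gene_count) < 0)) {
    stop("Counts must be non-negative.", call. = FALSE)
  }
  if (!is.null(species_split) &&
      (species_split <= 0 || species_split >= 1)) {
    stop("`species_split` must be strictly inside (0, 1): both species need ",
         "at least one type.", call. = FALSE)
  }
  if (!is.null(type_profiles)) {
    type_profiles <- as.matrix(type_profiles)
    if (nrow(type_profiles) != n_types || ncol(type_profiles) != n_genes) {
      stop("`type_profiles` must be `n_types` x `n_genes`.", call. = FALSE)
    }
    if (any(type_profiles < 0) ||
        any(abs(rowSums(type_profiles) - 1) > 1e-8)) {
      stop("`type_profiles` rows must be probability vectors.", call. = FALSE)
    }
  }
  structure(mget(names(formals()), environment()), class = "synth_config")
}

rdirichlet_rows <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

# draw `size[i]` gene indices for each unit i, units grouped by a shared
# probability profile; returns aggregated sparse genes x barcodes counts
draw_multinomial_counts <- function(n_genes, n_barcodes, unit_barcode,
                                    unit_profile_id, unit_size, profiles) {
  gene_out <- integer(0)
  bc_out <- integer(0)
  for (pid in sort(unique(unit_profile_id))) {
    sel <- unit_profile_id == pid
    total <- sum(unit_size[sel])
    if (total == 0) next
    draws <- sample.int(n_genes, total, replace = TRUE, prob = profiles[pid, ])
    gene_out <- c(gene_out, draws)
    bc_out <- c(bc_out, rep.int(unit_barcode[sel], unit_size[sel]))
  }
  if (length(gene_out) == 0L) {
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n_genes, n_barcodes)))
  }
  Matrix::sparseMatrix(i = gene_out, j = bc_out, x = 1,
                       dims = c(n_genes, n_barcodes))
}

#' Generate a synthetic droplet UMI count matrix with ground truth
#'
#' Simulates a droplet library barcode by barcode. Each barcode gets a
#' ground-truth status (`intact`, `damaged`, `empty`), a total UMI count
#' (lognormal; scaled down for damaged cells and empties), and gene counts
#' drawn multinomially from a mixture
#' `(1 - ambient_fraction) * type_profile + ambient_fraction * ambient`,
#' where the ambient profile is the library-size-weighted mean of the cell
#' profiles (empties draw from ambient alone). Each UMI lands in the
#' unspliced layer with a per-barcode probability drawn around the
#' status-specific nuclear-fraction mean. Doublet barcodes sum two
#' independently drawn cells. Everything is reproducible under the config
#' seed.
#'
#' @param config A [synth_config()].
#' @return A [count_matrix()] whose `truth` tibble records per-barcode
#'   `status`, `type`, `is_doublet`, `species_mix`, the drawn `library_size`
#'   and nuclear fraction `nf`. The realized type profiles and the ambient
#'   profile are attached as `$type_profiles` and `$ambient_profile` so a
#'   second library can be generated from the same ground truth (pass the
#'   profiles back through `synth_config(type_profiles = )`).
#' @examples
#' cm <- generate_counts(synth_config(n_intact = 50, n_damaged = 5,
#'                                    n_empty = 100, n_genes = 200, seed = 7))
#' cm
#' @export
generate_counts <- function(config) {
  if (!inherits(config, "synth_config")) {
    stop("`config` must come from `synth_config()`.", call. = FALSE)
  }
  cfg <- config
  set.seed(cfg$seed)

  two_species <- !is.null(cfg$species_split)
  n_genes <- cfg$n_genes
  genes <- tibble::tibble(
    gene = sprintf("gene%05d", seq_len(n_genes)),
    species = NA_character_,
    is_mito = FALSE
  )
  if (two_species) {
    half <- n_genes %/% 2
    genes$species <- rep(c("A", "B"), c(half, n_genes - half))
    genes$gene <- paste0(genes$species, "_", genes$gene)
    mito_idx <- c(seq_len(min(cfg$mito_gene_count, half)),
                  half + seq_len(min(cfg$mito_gene_count, n_genes - half)))
  } else {
    mito_idx <- seq_len(min(cfg$mito_gene_count, n_genes))
  }
  genes$is_mito[mito_idx] <- TRUE
  genes$gene[mito_idx] <- sub("gene", "mt-gene", genes$gene[mito_idx])

  # species assignment of types, and type profiles restricted to the type's
  # own species block (barnyard structure) over non-mito genes
  type_species <- if (two_species) {
    n_a <- max(1L, round(cfg$species_split * cfg$n_types))
    n_a <- min(n_a, cfg$n_types - 1L)
    rep(c("A", "B"), c(n_a, cfg$n_types - n_a))
  } else {
    rep(NA_character_, cfg$n_types)
  }

  base_profiles <- matrix(0, cfg$n_types, n_genes)
  if (!is.null(cfg$type_profiles)) {
    base_profiles <- cfg$type_profiles
  } else {
    for (k in seq_len(cfg$n_types)) {
      support <- if (two_species) {
        which(genes$species == type_species[k] & !genes$is_mito)
      } else {
        which(!genes$is_mito)
      }
      base_profiles[k, support] <-
        rdirichlet_rows(1, rep(cfg$dirichlet_concentration, length(support)))
    }
  }

  # fold status-specific mitochondrial load into the full gene profile:
  # (1 - m) on the type's non-mito profile, m uniform over its mito genes
  with_mito <- function(profile, m, species) {
    midx <- if (two_species && !is.na(species)) {
      which(genes$is_mito & genes$species == species)
    } else {
      which(genes$is_mito)
    }
    out <- profile * (1 - m)
    out[midx] <- out[midx] + m / length(midx)
    out
  }

  n_cells <- cfg$n_intact + cfg$n_damaged
  statuses <- rep(c("intact", "damaged", "empty"),
                  c(cfg$n_intact, cfg$n_damaged, cfg$n_empty))
  n_bc <- length(statuses)
  if (n_bc == 0L) stop("Config generates zero barcodes.", call. = FALSE)
  barcode_ids <- sprintf("BC%06d", seq_len(n_bc))

  type_of <- rep(NA_integer_, n_bc)
  if (n_cells > 0) {
    type_of[seq_len(n_cells)] <- sample.int(cfg$n_types, n_cells, replace = TRUE)
  }

  # library sizes: lognormal, scaled by status
  size_mu <- cfg$library_size_log_mu +
    ifelse(statuses == "damaged", log(cfg$damaged_scale),
           ifelse(statuses == "empty", log(cfg$empty_scale), 0))
  size_sigma <- ifelse(statuses == "empty", cfg$empty_log_sigma,
                       cfg$library_size_log_sigma)
  lib_size <- pmax(1L, as.integer(round(stats::rlnorm(n_bc, size_mu, size_sigma))))

  # doublets among intact barcodes: an extra, independently drawn cell
  is_doublet <- rep(FALSE, n_bc)
  if (cfg$doublet_rate > 0 && cfg$n_intact > 0) {
    n_dbl <- round(cfg$doublet_rate * cfg$n_intact)
    is_doublet[sample.int(cfg$n_intact, n_dbl)] <- TRUE
  }
  partner_type <- rep(NA_integer_, n_bc)
  partner_size <- rep(0L, n_bc)
  if (any(is_doublet)) {
    idx <- which(is_doublet)
    partner_type[idx] <- sample.int(cfg$n_types, length(idx), replace = TRUE)
    partner_size[idx] <- pmax(1L, as.integer(round(
      stats::rlnorm(length(idx), cfg$library_size_log_mu,
                    cfg$library_size_log_sigma))))
  }

  # ambient pool: library-size-weighted mean of the cell profiles actually
  # present (expected mass per status x type), mito folded in
  full_profile <- function(k, status) {
    m <- if (status == "damaged") cfg$mito_fraction_damaged else cfg$mito_fraction_intact
    with_mito(base_profiles[k, ], m, type_species[k])
  }
  exp_size <- exp(cfg$library_size_log_mu + cfg$library_size_log_sigma^2 / 2)
  ambient <- rep(0, n_genes)
  wsum <- 0
  for (k in seq_len(cfg$n_types)) {
    w_int <- sum(type_of == k & statuses == "intact", na.rm = TRUE) * exp_size
    w_dam <- sum(type_of == k & statuses == "damaged", na.rm = TRUE) *
      exp_size * cfg$damaged_scale
    if (w_int > 0) ambient <- ambient + w_int * full_profile(k, "intact")
    if (w_dam > 0) ambient <- ambient + w_dam * full_profile(k, "damaged")
    wsum <- wsum + w_int + w_dam
  }
  if (wsum > 0) {
    ambient <- ambient / wsum
  } else {
    ambient <- with_mito(rep(1 / sum(!genes$is_mito), n_genes) *
                           as.numeric(!genes$is_mito),
                         cfg$mito_fraction_intact, NA_character_)
  }

  # enumerate mixture profiles: one per (status, type) plus pure ambient
  profile_list <- list()
  profile_key <- character(0)
  get_profile_id <- function(status, k) {
    key <- if (status == "empty") "empty" else paste(status, k, sep = ":")
    hit <- match(key, profile_key)
    if (!is.na(hit)) return(hit)
    prof <- if (status == "empty") {
      ambient
    } else {
      (1 - cfg$ambient_fraction) * full_profile(k, status) +
        cfg$ambient_fraction * ambient
    }
    profile_list[[length(profile_list) + 1L]] <<- prof
    profile_key[length(profile_key) + 1L] <<- key
    length(profile_key)
  }

  # draw units: every barcode is one unit; doublets contribute a second
  unit_barcode <- seq_len(n_bc)
  unit_status <- statuses
  unit_type <- type_of
  unit_size <- lib_size
  if (any(is_doublet)) {
    idx <- which(is_doublet)
    unit_barcode <- c(unit_barcode, idx)
    unit_status <- c(unit_status, rep("intact", length(idx)))
    unit_type <- c(unit_type, partner_type[idx])
    unit_size <- c(unit_size, partner_size[idx])
  }
  unit_pid <- vapply(seq_along(unit_barcode), function(i) {
    get_profile_id(unit_status[i], unit_type[i])
  }, integer(1))
  profiles <- do.call(rbind, profile_list)

  counts <- draw_multinomial_counts(n_genes, n_bc, unit_barcode, unit_pid,
                                    unit_size, profiles)

  # per-barcode nuclear fraction around the status mean; per-UMI Bernoulli
  # assignment to the unspliced layer == binomial thinning of each count
  nf_mean <- c(intact = cfg$nf_intact, damaged = cfg$nf_damaged,
               empty = cfg$nf_empty)[statuses]
  nf_bc <- nf_mean
  nd <- nf_mean > 0 & nf_mean < 1
  nf_bc[nd] <- stats::rbeta(sum(nd), nf_mean[nd] * cfg$nf_concentration,
                            (1 - nf_mean[nd]) * cfg$nf_concentration)
  counts_t <- methods::as(counts, "TsparseMatrix")
  u_x <- stats::rbinom(length(counts_t@x), size = as.integer(counts_t@x),
                       prob = nf_bc[counts_t@j + 1L])
  unspliced <- Matrix::sparseMatrix(i = counts_t@i + 1L, j = counts_t@j + 1L,
                                    x = u_x, dims = dim(counts))
  spliced <- counts - unspliced

  dimnames(spliced) <- list(genes$gene, barcode_ids)
  dimnames(unspliced) <- list(genes$gene, barcode_ids)

  species_mix <- rep(NA_character_, n_bc)
  if (two_species) {
    own <- type_species[type_of]
    partner <- type_species[partner_type]
    species_mix <- ifelse(
      statuses == "empty", "ambient",
      ifelse(is_doublet & !is.na(partner) & partner != own,
             "A+B", own)
    )
  }

  truth <- tibble::tibble(
    barcode = barcode_ids,
    status = statuses,
    type = ifelse(is.na(type_of), NA_character_, paste0("type", type_of)),
    is_doublet = is_doublet,
    species_mix = species_mix,
    library_size = lib_size + partner_size,
    nf = nf_bc
  )

  out <- count_matrix(spliced, unspliced, genes = genes, truth = truth)
  rownames(base_profiles) <- paste0("type", seq_len(cfg$n_types))
  colnames(base_profiles) <- genes$gene
  out$type_profiles <- base_profiles  # realized profiles (non-mito support)
  out$ambient_profile <- stats::setNames(ambient, genes$gene)
  out
}

#' Generate a two-species (barnyard) synthetic count matrix
#'
#' Same generator as [generate_counts()] with the two-species structure
#' required: genes split into species-A and species-B blocks, each planted
#' type expressed from a single species' block, and doublets mixing two
#' independently sampled cells so cross-species barcodes reveal the doublet
#' rate. Requires `species_split` to be set in the config.
#'
#' @param config A [synth_config()] with non-`NULL` `species_split`.
#' @return A [count_matrix()] with species-annotated genes and per-barcode
#'   `species_mix` truth (`"A"`, `"B"`, `"A+B"` or `"ambient"`).
#' @export
generate_barnyard <- function(config) {
  if (!inherits(config, "synth_config")) {
    stop("`config` must come from `synth_config()`.", call. = FALSE)
  }
  if (is.null(config$species_split)) {
    stop("Barnyard generation requires `species_split` to be set ",
         "(fraction of types from species A).", call. = FALSE)
  }
  if (config$n_types < 2) {
    stop("Barnyard generation needs at least two types (one per species).",
         call. = FALSE)
  }
  generate_counts(config)
}
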