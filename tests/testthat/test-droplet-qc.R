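test_that("barcode ranking sorts by total with a stable tie rule", {
  cm <- dense_cm(matrix(c(5, 2, 9), nrow = 1,
                        dimnames = list("g1", c("x", "y", "z"))))
  rk <- rank_barcodes(cm)
  expect_equal(rk$barcode, c("z", "x", "y"))
  expect_equal(rk$total, c(9, 5, 2))
  # equal totals ordered by barcode identifier
  tie <- dense_cm(matrix(c(4, 4, 4), nrow = 1,
                         dimnames = list("g1", c("c", "a", "b"))))
  expect_equal(rank_barcodes(tie)$barcode, c("a", "b", "c"))
  zero <- dense_cm(matrix(0, 2, 3))
  expect_error(rank_barcodes(zero), "zero")
})

test_that("knee detection finds the plateau break and flags kneeless curves", {
  # two-plateau library: clear drop between cells and empties
  cm <- generate_counts(synth_config(n_intact = 500, n_damaged = 0,
                                     n_empty = 10000, n_genes = 300,
                                     library_size_log_sigma = 0.05,
                                     empty_log_sigma = 0.05, seed = 10))
  k <- detect_knee(rank_barcodes(cm))
  expect_false(k$no_inflection)
  expect_true(k$n_cells_called >= 450 && k$n_cells_called <= 550)
  # scale invariance: multiplying totals by a constant moves nothing
  rk <- rank_barcodes(cm)
  rk7 <- dplyr::mutate(rk, total = total * 7)
  expect_equal(detect_knee(rk7)$knee_rank, k$knee_rank)
  # all-equal totals: no inflection, not a crash
  flat <- tibble::tibble(rank = 1:50, total = rep(100, 50))
  expect_true(detect_knee(flat)$no_inflection)
  # pure power law: log-log straight line, no knee to call
  power <- tibble::tibble(rank = 1:2000,
                          total = round(1e5 * (1:2000)^-1.2) + 1)
  expect_true(detect_knee(power)$no_inflection)
  # degenerate tiny input
  two <- tibble::tibble(rank = 1:2, total = c(10, 1))
  expect_true(detect_knee(two)$no_inflection)
})

test_that("fraction of reads in cells is an exact ratio with sane edges", {
  cm <- dense_cm(matrix(c(10, 0, 5, 5, 1, 0), nrow = 2))
  bcs <- barcodes(cm)
  expect_equal(fraction_reads_in_cells(cm, bcs), 1.0)
  expect_warning(f0 <- fraction_reads_in_cells(cm, character(0)), "Empty")
  expect_equal(f0, 0)
  expect_equal(fraction_reads_in_cells(cm, bcs[1]), 10 / 21)
  expect_error(fraction_reads_in_cells(cm, "nope"), "not present")
  # synthetic library planting ~85% of reads in cell barcodes
  big <- generate_counts(synth_config(n_intact = 500, n_damaged = 0,
                                      n_empty = 4400, n_genes = 300,
                                      library_size_log_sigma = 0.03,
                                      empty_log_sigma = 0.03, seed = 30))
  truth_frac <- sum(big$truth$library_size[big$truth$status == "intact"]) /
    sum(big$truth$library_size)
  k <- detect_knee(rank_barcodes(big))
  called <- rank_barcodes(big)$barcode[seq_len(k$n_cells_called)]
  expect_lt(abs(fraction_reads_in_cells(big, called) - truth_frac), 0.03)
})

test_that("downsampling conserves min(total, target) exactly", {
  cm <- generate_counts(synth_config(n_intact = 80, n_damaged = 10,
                                     n_empty = 100, n_genes = 150, seed = 11))
  before <- barcode_totals(cm)$total
  ds <- downsample_counts(cm, 500, seed = 1)
  expect_equal(barcode_totals(ds)$total, pmin(before, 500))
  # identity when the target is above every total
  same <- downsample_counts(cm, max(before), seed = 1)
  expect_equal(as.matrix(same$spliced), as.matrix(cm$spliced))
  expect_equal(as.matrix(same$unspliced), as.matrix(cm$unspliced))
  # target zero empties the matrix
  none <- downsample_counts(cm, 0, seed = 1)
  expect_equal(sum(none$spliced) + sum(none$unspliced), 0)
  expect_error(downsample_counts(cm, -5, seed = 1), "non-negative")
})

test_that("downsampling draws are hypergeometric across gene cells", {
  # one barcode with counts {a: 80, b: 20}; sampling 50 leaves E[a] = 40
  cm <- dense_cm(matrix(c(80, 20), ncol = 1,
                        dimnames = list(c("a", "b"), "bc1")))
  reps <- 2000
  totals <- numeric(reps)
  a_counts <- vapply(seq_len(reps), function(i) {
    ds <- downsample_counts(cm, 50, seed = i)
    totals[i] <<- sum(ds$spliced)
    as.numeric(ds$spliced["a", 1])
  }, numeric(1))
  expect_true(all(totals == 50))
  # hypergeometric sd: sqrt(n p q (N-n)/(N-1))
  hyper_sd <- sqrt(50 * 0.8 * 0.2 * (100 - 50) / 99)
  expect_lt(abs(mean(a_counts) - 40), 3 * hyper_sd / sqrt(reps))
})

test_that("nuclear fraction is the bounded unspliced share", {
  s <- matrix(c(10, 0, 3, 0, 0, 0), nrow = 2)
  u <- matrix(c(0, 0, 1, 4, 0, 0), nrow = 2)
  cm <- dense_cm(s, u)
  nf <- nuclear_fraction(cm)
  expect_equal(nf$nuclear_fraction, c(0, 5 / 8, NA))
  expect_equal(nf$undefined, c(FALSE, FALSE, TRUE))
  all_u <- dense_cm(matrix(0, 1, 1), matrix(7, 1, 1))
  expect_equal(nuclear_fraction(all_u)$nuclear_fraction, 1)
})

test_that("status classification separates three planted nf modes", {
  cm <- generate_counts(synth_config(n_intact = 500, n_damaged = 500,
                                     n_empty = 500, n_genes = 300, seed = 12))
  cls <- classify_status(nuclear_fraction(cm))
  acc <- mean(cls$status_call == truth_to_call[cm$truth$status])
  expect_gte(acc, 0.95)
  th <- attr(cls, "thresholds")
  expect_equal(th$method, "kmeans3")
  expect_equal(length(th$centers), 3)
  # centres sit near the planted modes, in order
  expect_true(all(abs(th$centers - c(0.02, 0.25, 0.60)) < 0.05))
})

test_that("classification labels follow cluster centres, not cluster indices", {
  # values supplied in an order that shuffles k-means cluster indices
  set.seed(99)
  vals <- sample(c(rnorm(50, 0.6, 0.02), rnorm(50, 0.02, 0.005),
                   rnorm(50, 0.25, 0.02)))
  vals <- pmin(pmax(vals, 0), 1)
  nf <- tibble::tibble(barcode = sprintf("b%03d", seq_along(vals)),
                       nuclear_fraction = vals, undefined = FALSE)
  cls <- classify_status(nf)
  expect_true(all(cls$status_call[vals > 0.5] == "damaged"))
  expect_true(all(cls$status_call[vals < 0.1] == "empty"))
  expect_true(all(cls$status_call[vals > 0.15 & vals < 0.35] == "cell"))
})

test_that("fixed-cutoff classification and undefined-nf conventions hold", {
  nf <- tibble::tibble(barcode = c("a", "b", "c"),
                       nuclear_fraction = c(0.25, 0.25, NA),
                       undefined = c(FALSE, FALSE, TRUE))
  cls <- classify_status(nf, method = "fixed", cutoffs = c(0.1, 0.5))
  expect_equal(cls$status_call, c("cell", "cell", "empty"))
  expect_error(classify_status(nf, method = "fixed", cutoffs = c(0.5, 0.1)),
               "increasing")
  expect_error(classify_status(nf[3, ], method = "kmeans3"), "at least 3")
})

test_that("mitochondrial fraction is exact with validated gene sets", {
  s <- matrix(c(6, 4, 0, 10), nrow = 2,
              dimnames = list(c("mt-1", "g1"), c("b1", "b2")))
  cm <- dense_cm(s, mito = c(TRUE, FALSE))
  mf <- mito_fraction(cm)
  expect_equal(mf$mito_fraction, c(0.6, 0))
  all_mito <- mito_fraction(cm, mito_genes = c("mt-1", "g1"))
  expect_equal(all_mito$mito_fraction, c(1, 1))
  no_anno <- dense_cm(s)
  expect_error(mito_fraction(no_anno), "Empty mitochondrial")
  expect_error(mito_fraction(cm, mito_genes = "absent"), "absent")
})

test_that("barnyard statistics recover a planted doublet rate", {
  cm <- generate_barnyard(synth_config(n_intact = 2000, n_damaged = 0,
                                       n_empty = 0, n_genes = 600, n_types = 4,
                                       species_split = 0.5, doublet_rate = 0.05,
                                       ambient_fraction = 0, seed = 13))
  bs <- barnyard_stats(cm, purity_threshold = 0.9)
  se <- sqrt(0.025 * 0.975 / 2000)
  expect_lt(abs(bs$summary$observed_cross_rate - 0.025), 3 * se)
  expect_lt(abs(bs$summary$inferred_multiplet_rate - 0.05), 6 * se)
  # detection agrees with planted cross-species truth
  expect_equal(bs$per_barcode$is_cross_doublet,
               cm$truth$species_mix == "A+B")
})

test_that("degenerate barnyard inputs are rejected", {
  s <- matrix(c(5, 0, 7, 0), nrow = 2,
              dimnames = list(c("a1", "b1"), c("x", "y")))
  cm_ab <- dense_cm(s, species = c("A", "B"))
  # every barcode pure species A: species fractions degenerate
  expect_error(barnyard_stats(cm_ab), "undefined")
  mixed <- dense_cm(matrix(c(5, 0, 0, 7), nrow = 2,
                           dimnames = list(c("a1", "b1"), c("x", "y"))),
                    species = c("A", "B"))
  bs <- barnyard_stats(mixed)
  expect_equal(bs$summary$observed_cross_rate, 0)
  expect_error(barnyard_stats(mixed, purity_threshold = 0.4), "\\(0.5, 1\\]")
  no_sp <- dense_cm(s)
  expect_error(barnyard_stats(no_sp), "species")
})

test_that("qc_report chains the stages into per-barcode and summary tables", {
  cm <- generate_counts(synth_config(n_intact = 300, n_damaged = 50,
                                     n_empty = 2000, n_genes = 300, seed = 14))
  rep <- qc_report(cm)
  per <- tidy(rep)
  expect_equal(sort(per$rank), seq_len(nrow(per)))
  expect_equal(nrow(per), ncol(cm$spliced))
  expect_true(all(per$status_call %in% c("cell", "empty", "damaged")))
  g <- glance(rep)
  expect_equal(g$prop_cell + g$prop_empty + g$prop_damaged, 1)
  expect_false(g$no_inflection)
})
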