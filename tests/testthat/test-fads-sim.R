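test_that("droplet simulation is seeded, sized and validated", {
  m <- loading_model(0.3, 0.5)
  d1 <- simulate_droplets(m, 5000, seed = 42)
  d2 <- simulate_droplets(m, 5000, seed = 42)
  expect_identical(tibble::as_tibble(d1), tibble::as_tibble(d2))
  expect_equal(nrow(simulate_droplets(m, 0, seed = 1)), 0L)
  expect_error(simulate_droplets(m, -1, seed = 1), "non-negative")
  expect_error(simulate_droplets(list(), 10, seed = 1), "loading_model")
})

test_that("empirical occupancy fractions track the Poisson closed forms", {
  # single live at lambda = 0.1, v = 0.5: 4.52% within 3 binomial SE
  n <- 1e6
  d <- simulate_droplets(loading_model(0.1, 0.5), n, seed = 7)
  p <- dpois(1, 0.05) * dpois(0, 0.05)
  expect_lt(abs(mean(d$n_live == 1 & d$n_dead == 0) - p),
            3 * sqrt(p * (1 - p) / n))
  # exactly one cell at lambda = 0.5, v = 1: 30.3%
  d2 <- simulate_droplets(loading_model(0.5, 1), n, seed = 8)
  p2 <- dpois(1, 0.5)
  expect_lt(abs(mean(d2$n_live + d2$n_dead == 1) - p2),
            3 * sqrt(p2 * (1 - p2) / n))
})

test_that("signals are additive with exact degenerate cases", {
  m <- loading_model(0.5, 0.5)
  d <- simulate_droplets(m, 2000, seed = 3)
  # deterministic background only
  sm0 <- signal_model(background_mu = 0.2, background_sd = 0,
                      live_intensity_sigma = 0)
  s0 <- compute_signals(d, sm0, seed = 3)
  none <- s0$n_live == 0 & s0$n_dead == 0
  expect_equal(s0$signal[none], rep(0.2, sum(none)))
  # unit live intensity, zero noise: signal counts live cells exactly
  sm1 <- signal_model(live_intensity_mu = 0, live_intensity_sigma = 0,
                      background_mu = 0, background_sd = 0)
  s1 <- compute_signals(d, sm1, seed = 3)
  expect_equal(s1$signal, as.numeric(s1$n_live))
  # dead residual adds n_dead * residual
  sm2 <- signal_model(live_intensity_sigma = 0, background_mu = 0,
                      background_sd = 0, dead_residual_intensity = 0.1)
  s2 <- compute_signals(d, sm2, seed = 3)
  expect_equal(s2$signal, s2$n_live + 0.1 * s2$n_dead)
})

test_that("mean signal matches the law of total expectation", {
  n <- 2e5
  d <- simulate_droplets(loading_model(0.5, 0.5), n, seed = 11)
  s <- compute_signals(d, signal_model(live_intensity_mu = 0,
                                       live_intensity_sigma = 0,
                                       background_mu = 0, background_sd = 0),
                       seed = 11)
  # E[signal] = lambda * v * 1 = 0.25; Poisson mean has sd sqrt(0.25/n)
  expect_lt(abs(mean(s$signal) - 0.25), 3 * sqrt(0.25 / n))
})

test_that("ideal threshold sorting is a pure function of occupancy", {
  m <- loading_model(0.1, 0.5)
  ideal <- signal_model(live_intensity_mu = 0, live_intensity_sigma = 0,
                        background_mu = 0, background_sd = 0)
  d <- simulate_droplets(m, 5e4, seed = 5) |>
    compute_signals(ideal, seed = 5)
  lo <- apply_sort(d, sort_config(0.5), seed = 5)
  expect_equal(sum(lo$sorted) + sum(!lo$sorted), nrow(lo))
  expect_equal(sum(lo$n_live == 0 & lo$sorted), 0L)
  expect_true(all(lo$n_live[lo$sorted] >= 1))
  # multiplet gate excludes multi-live droplets
  gated <- apply_sort(d, sort_config(0.5, upper_threshold = 1.5), seed = 5)
  expect_equal(sum(gated$n_live >= 2 & gated$sorted), 0L)
  expect_true(all(gated$n_live[gated$sorted] == 1))
})

test_that("raising the lower threshold never sorts more droplets", {
  d <- simulate_droplets(loading_model(0.5, 0.5), 2e4, seed = 9) |>
    compute_signals(signal_model(), seed = 9)
  counts <- vapply(c(0.1, 0.5, 1, 2, 4), function(thr) {
    sum(apply_sort(d, sort_config(thr), seed = 9)$sorted)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("trigger errors flip outcomes at the configured rates", {
  d <- simulate_droplets(loading_model(0.2, 1), 5e4, seed = 13) |>
    compute_signals(signal_model(live_intensity_sigma = 0, background_mu = 0,
                                 background_sd = 0), seed = 13)
  all_miss <- apply_sort(d, sort_config(0.5, trigger_miss_rate = 1), seed = 13)
  expect_equal(sum(all_miss$sorted), 0L)
  expect_true(all(all_miss$trigger_error[all_miss$n_live > 0] == "miss"))
  all_false <- apply_sort(d, sort_config(0.5, false_trigger_rate = 1), seed = 13)
  expect_true(all(all_false$sorted))
  part <- apply_sort(d, sort_config(0.5, trigger_miss_rate = 0.1), seed = 13)
  qualifying <- part$n_live > 0
  miss_rate <- mean(!part$sorted[qualifying])
  expect_lt(abs(miss_rate - 0.1), 3 * sqrt(0.1 * 0.9 / sum(qualifying)))
})

test_that("sorted purity matches the conditional closed form", {
  # oracle: P(1,0 | >=1 live) at lambda = 0.1, v = 0.5
  oracle <- (dpois(1, 0.05) * dpois(0, 0.05)) / (1 - exp(-0.05))
  n <- 3e5
  d <- simulate_droplets(loading_model(0.1, 0.5), n, seed = 17) |>
    compute_signals(signal_model(live_intensity_mu = 0, live_intensity_sigma = 0,
                                 background_mu = 0, background_sd = 0),
                    seed = 17) |>
    apply_sort(sort_config(0.5), seed = 17)
  srt <- empirical_composition(d, "sorted")
  frac <- srt$fraction[srt$category == "single_live"]
  n_sorted <- sum(d$sorted)
  expect_lt(abs(frac - oracle), 3 * sqrt(oracle * (1 - oracle) / n_sorted))
})

test_that("empirical composition tables are populations that sum to one", {
  d <- simulate_droplets(loading_model(0.5, 0.5), 2e4, seed = 19) |>
    compute_signals(signal_model(), seed = 19) |>
    apply_sort(sort_config(0.5), seed = 19)
  for (pop in c("all", "sorted", "unsorted")) {
    tbl <- empirical_composition(d, pop)
    expect_equal(sum(tbl$fraction), 1)
    expect_equal(sum(tbl$count), if (pop == "all") nrow(d)
                 else if (pop == "sorted") sum(d$sorted) else sum(!d$sorted))
  }
  # a single empty droplet is 100% empty
  one <- simulate_droplets(loading_model(0, 0.5), 1, seed = 1)
  tbl <- empirical_composition(one, "all")
  expect_equal(tbl$fraction[tbl$category == "empty"], 1)
  # asking for a sorted population before sorting, or an empty one, errors
  expect_error(empirical_composition(one, "sorted"), "apply_sort")
  d0 <- simulate_droplets(loading_model(0, 1), 10, seed = 1) |>
    compute_signals(signal_model(background_mu = 0, background_sd = 0), seed = 1) |>
    apply_sort(sort_config(0.5), seed = 1)
  expect_error(empirical_composition(d0, "sorted"), "sorted")
})

test_that("sort configuration is validated", {
  expect_error(sort_config(1, upper_threshold = 0.5), "exceed")
  expect_error(sort_config(-1), "non-negative")
  expect_error(sort_config(0.5, trigger_miss_rate = 2), "\\[0, 1\\]")
})
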