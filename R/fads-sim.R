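#' Per-droplet fluorescence signal model
#'
#' Fluorescence read out by the detection fibre / photomultiplier as a droplet
#' passes the laser. A droplet's signal is additive: a Gaussian background
#' plus one lognormal draw per detectably stained live cell plus a fixed mean
#' residual per dead cell. With a live-cell esterase stain (Calcein-AM logic)
#' dead cells emit nothing, so `dead_residual_intensity` defaults to 0 and is
#' exposed for sensitivity analysis only. Units are abstract volt-like
#' numbers; the default scenario puts the live-singlet mode at 1.0 so a
#' multiplet-exclusion gate sits naturally between 1 and 2.
#'
#' @param live_intensity_mu,live_intensity_sigma Log-scale mean and sd of the
#'   per-live-cell lognormal intensity. Defaults `log(1)` and `0.25` (modest
#'   right-skewed spread around 1 volt-like unit).
#' @param dead_residual_intensity Mean signal contributed per dead cell, >= 0.
#' @param background_mu,background_sd Additive Gaussian droplet background.
#' @param stain_efficiency Probability a live cell is detectably stained.
#' @return An object of class `signal_model`.
#' @export
signal_model <- function(live_intensity_mu = 0,
                         live_intensity_sigma = 0.25,
                         dead_residual_intensity = 0,
                         background_mu = 0.05,
                         background_sd = 0.01,
                         stain_efficiency = 1) {
  if (live_intensity_sigma < 0 || background_sd < 0 ||
      dead_residual_intensity < 0) {
    stop("Spreads and residual intensity must be non-negative.", call. = FALSE)
  }
  if (stain_efficiency < 0 || stain_efficiency > 1) {
    stop("`stain_efficiency` must be in [0, 1].", call. = FALSE)
  }
  structure(
    list(
      live_intensity_mu = live_intensity_mu,
      live_intensity_sigma = live_intensity_sigma,
      dead_residual_intensity = dead_residual_intensity,
      background_mu = background_mu,
      background_sd = background_sd,
      stain_efficiency = stain_efficiency
    ),
    class = "signal_model"
  )
}

#' Threshold configuration for fluorescence-activated droplet sorting
#'
#' A droplet qualifies for sorting when its signal exceeds `lower_threshold`
#' and, if an upper gate is set, does not exceed `upper_threshold`. The upper
#' gate models the multiplet-exclusion voltage cap used to reject droplets
#' bright enough to hold several cells. Trigger errors flip the outcome:
#' a qualifying droplet is missed with `trigger_miss_rate`, a non-qualifying
#' one is sorted with `false_trigger_rate`.
#'
#' @param lower_threshold Signal units, >= 0.
#' @param upper_threshold Signal units (> `lower_threshold`) or `Inf` for no
#'   multiplet gate.
#' @param trigger_miss_rate,false_trigger_rate Error probabilities in \[0, 1\].
#' @return An object of class `sort_config`.
#' @export
sort_config <- function(lower_threshold,
                        upper_threshold = Inf,
                        trigger_miss_rate = 0,
                        false_trigger_rate = 0) {
  if (lower_threshold < 0 || upper_threshold < 0) {
    stop("Thresholds must be non-negative.", call. = FALSE)
  }
  if (upper_threshold <= lower_threshold) {
    stop("`upper_threshold` must exceed `lower_threshold`.", call. = FALSE)
  }
  if (trigger_miss_rate < 0 || trigger_miss_rate > 1 ||
      false_trigger_rate < 0 || false_trigger_rate > 1) {
    stop("Trigger error rates must be in [0, 1].", call. = FALSE)
  }
  structure(
    list(
      lower_threshold = lower_threshold,
      upper_threshold = upper_threshold,
      trigger_miss_rate = trigger_miss_rate,
      false_trigger_rate = false_trigger_rate
    ),
    class = "sort_config"
  )
}

# one global seed drives three named substreams so each stage is
# independently reproducible regardless of how many draws the others consume
substream_seed <- function(seed, stream = c("occupancy", "signal", "trigger")) {
  stream <- match.arg(stream)
  offset <- c(occupancy = 0L, signal = 1L, trigger = 2L)[[stream]]
  (as.integer(seed) + offset * 1000003L) %% .Machine$integer.max
}

with_stream_seed <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, stream))
  code
}

#' Simulate droplet occupancies
#'
#' Monte-Carlo twin of the closed-form loading model: draws independent
#' live and dead Poisson counts and Bernoulli bead occupancy per droplet.
#'
#' @param model A [loading_model()].
#' @param n_droplets Number of droplets to generate.
#' @param seed Integer seed; the occupancy, signal and trigger stages each
#'   use a named substream derived from it.
#' @return A tibble of class `droplet_set` with columns `droplet`, `n_live`,
#'   `n_dead`, `has_bead`; the generating model and seed are kept as
#'   attributes. [compute_signals()] and [apply_sort()] add `signal`,
#'   `sorted` and `trigger_error` columns.
#' @examples
#' simulate_droplets(loading_model(0.1, 0.5), 1000, seed = 1)
#' @export
simulate_droplets <- function(model, n_droplets, seed) {
  assert_loading_model(model)
  if (length(n_droplets) != 1L || is.na(n_droplets) || n_droplets < 0 ||
      n_droplets != floor(n_droplets)) {
    stop("`n_droplets` must be a single non-negative integer.", call. = FALSE)
  }
  n <- as.integer(n_droplets)
  out <- with_stream_seed(seed, "occupancy", {
    tibble::tibble(
      droplet = seq_len(n),
      n_live = stats::rpois(n, lambda_live(model)),
      n_dead = stats::rpois(n, lambda_dead(model)),
      has_bead = stats::runif(n) < model$bead_occupancy
    )
  })
  structure(out,
            class = c("droplet_set", class(tibble::tibble())),
            loading_model = model,
            seed = seed)
}

assert_droplet_set <- function(droplets) {
  if (!inherits(droplets, "droplet_set")) {
    stop("`droplets` must be a `droplet_set` from `simulate_droplets()`.",
         call. = FALSE)
  }
  invisible(droplets)
}

#' Compute per-droplet fluorescence signals
#'
#' Adds a `signal` column: background draw + sum of lognormal draws over the
#' droplet's detectably stained live cells + `n_dead * dead_residual`.
#'
#' @param droplets A `droplet_set` from [simulate_droplets()].
#' @param signal A [signal_model()].
#' @param seed Integer seed (the signal substream is derived from it; pass
#'   the same seed as the simulation for a single reproducible pipeline).
#' @return The `droplet_set` with a `signal` column.
#' @export
compute_signals <- function(droplets, signal = signal_model(), seed) {
  assert_droplet_set(droplets)
  if (!inherits(signal, "signal_model")) {
    stop("`signal` must be a `signal_model` object.", call. = FALSE)
  }
  n <- nrow(droplets)
  sig <- with_stream_seed(seed, "signal", {
    background <- stats::rnorm(n, signal$background_mu, signal$background_sd)
    n_stained <- if (signal$stain_efficiency >= 1) {
      droplets$n_live
    } else {
      stats::rbinom(n, droplets$n_live, signal$stain_efficiency)
    }
    live_sig <- numeric(n)
    total_draws <- sum(n_stained)
    if (total_draws > 0) {
      draws <- stats::rlnorm(total_draws,
                             signal$live_intensity_mu,
                             signal$live_intensity_sigma)
      idx <- rep.int(seq_len(n), n_stained)
      sums <- rowsum(draws, idx)
      live_sig[as.integer(rownames(sums))] <- sums[, 1L]
    }
    background + live_sig + droplets$n_dead * signal$dead_residual_intensity
  })
  droplets$signal <- sig
  attr(droplets, "signal_model") <- signal
  droplets
}

#' Apply threshold sorting to a droplet set
#'
#' Sets the `sorted` flag when the signal lies in
#' `(lower_threshold, upper_threshold]`, then flips outcomes with the
#' configured trigger error rates; each flip is recorded in `trigger_error`
#' (`"miss"`, `"false"`, or `NA` for a clean decision). Sorted and unsorted
#' droplets always partition the set.
#'
#' @param droplets A `droplet_set` with signals ([compute_signals()]).
#' @param config A [sort_config()].
#' @param seed Integer seed (trigger-error substream).
#' @return The `droplet_set` with `sorted` and `trigger_error` columns.
#' @export
apply_sort <- function(droplets, config, seed) {
  assert_droplet_set(droplets)
  if (!inherits(config, "sort_config")) {
    stop("`config` must be a `sort_config` object.", call. = FALSE)
  }
  if (!("signal" %in% names(droplets))) {
    stop("Signals have not been computed; call `compute_signals()` first.",
         call. = FALSE)
  }
  qualifies <- droplets$signal > config$lower_threshold &
    droplets$signal <= config$upper_threshold
  n <- nrow(droplets)
  res <- with_stream_seed(seed, "trigger", {
    u <- stats::runif(n)
    miss <- qualifies & u < config$trigger_miss_rate
    false_trig <- !qualifies & u < config$false_trigger_rate
    list(miss = miss, false_trig = false_trig)
  })
  droplets$sorted <- (qualifies & !res$miss) | res$false_trig
  droplets$trigger_error <- dplyr::case_when(
    res$miss ~ "miss",
    res$false_trig ~ "false",
    TRUE ~ NA_character_
  )
  attr(droplets, "sort_config") <- config
  droplets
}

categorize_occupancy <- function(n_live, n_dead) {
  dplyr::case_when(
    n_live == 0 & n_dead == 0 ~ "empty",
    n_live == 1 & n_dead == 0 ~ "single_live",
    n_live == 0 & n_dead == 1 ~ "single_dead",
    n_live == 1 & n_dead == 1 ~ "live_dead_pair",
    n_live >= 2 & n_dead == 0 ~ "multi_live",
    n_live == 0 & n_dead >= 2 ~ "multi_dead",
    TRUE ~ "mixed_multiplet"
  )
}

#' Empirical composition of a simulated droplet population
#'
#' Category fractions over all droplets, the sorted subset, or the unsorted
#' subset, in the same seven-category scheme as [predicted_composition()],
#' so Monte-Carlo and closed-form tables compare row by row.
#'
#' @param droplets A `droplet_set`.
#' @param population `"all"`, `"sorted"` or `"unsorted"` (the latter two
#'   require [apply_sort()] to have run).
#' @return A `composition_table` tibble with columns `category`, `n_live`,
#'   `n_dead`, `fraction` and a `count` column of raw droplet tallies.
#' @export
empirical_composition <- function(droplets,
                                  population = c("all", "sorted", "unsorted")) {
  assert_droplet_set(droplets)
  population <- match.arg(population)
  sub <- switch(
    population,
    all = droplets,
    sorted = {
      if (!("sorted" %in% names(droplets))) {
        stop("No sort outcome present; call `apply_sort()` first.", call. = FALSE)
      }
      droplets[droplets$sorted, ]
    },
    unsorted = {
      if (!("sorted" %in% names(droplets))) {
        stop("No sort outcome present; call `apply_sort()` first.", call. = FALSE)
      }
      droplets[!droplets$sorted, ]
    }
  )
  if (nrow(sub) == 0L) {
    stop("The `", population, "` population is empty.", call. = FALSE)
  }
  counts <- table(factor(categorize_occupancy(sub$n_live, sub$n_dead),
                         levels = composition_categories))
  out <- tibble::tibble(
    category = composition_categories,
    n_live = c(0L, 1L, 0L, 1L, NA_integer_, 0L, NA_integer_),
    n_dead = c(0L, 0L, 1L, 1L, 0L, NA_integer_, NA_integer_),
    fraction = as.numeric(counts) / nrow(sub),
    count = as.integer(counts)
  )
  new_composition_table(out, conditioning = population, source = "empirical")
}
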