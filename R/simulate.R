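#' Simulate a longitudinal string-pulling cohort
#'
#' Generates a complete synthetic dataset with the statistical structure the
#' downstream analysis assumes: per-session behavioral metrics for WT and
#' SOD1 groups over the study weeks, weekly body weights, and cross-sectional
#' motor-neuron histology coupled to the programmed behavioral decline.
#' Identical `(config, seed)` yields an identical dataset.
#'
#' @param config An [sim_config()] object.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return An object of class `sp_cohort`: a list with tibbles `sessions`
#'   (`animal_id, genotype, sex, week, session_index, time_pulling_s,
#'   time_hindlimbs_s, length_pulled_cm`), `weights` (`animal_id, genotype,
#'   sex, week, weight_g`), `histology` (see [simulate_histology()]) and the
#'   provenance `config` (with the seed actually used).
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(seed = 7))
#' dplyr::count(cohort$sessions, genotype)
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sp_config"))
  validate_sim_config(config)
  seed <- as.integer(seed)
  set.seed(seed)

  animals <- cohort_animals(config)
  m <- sp_metrics()
  rho <- config$metric_cor

  # between-animal intercepts with a shared latent factor across metrics
  n_a <- nrow(animals)
  b <- correlated_noise(n_a, config$animal_sd[m], rho)
  colnames(b) <- m
  animals <- dplyr::bind_cols(animals, as_tibble(b))

  grid <- tidyr::expand_grid(
    animal_id = animals$animal_id,
    week = config$weeks,
    session_index = seq_len(config$sessions_per_week)
  ) %>%
    left_join(animals, by = "animal_id")

  e <- correlated_noise(nrow(grid), config$noise_sd[m], rho)
  colnames(e) <- m

  mu <- vapply(m, function(mm) {
    ifelse(grid$genotype == "SOD1",
           programmed_mean(config, mm, grid$week, "SOD1"),
           programmed_mean(config, mm, grid$week, "WT"))
  }, numeric(nrow(grid)))

  raw <- mu + as.matrix(grid[, m]) + e
  pull <- pmin(pmax(raw[, "time_pulling_s"], 0), 60)
  hind <- pmin(pmax(raw[, "time_hindlimbs_s"], 0), pull)
  len <- pmax(raw[, "length_pulled_cm"], 0)

  sessions <- grid %>%
    select("animal_id", "genotype", "sex", "week", "session_index") %>%
    mutate(time_pulling_s = pull, time_hindlimbs_s = hind,
           length_pulled_cm = len)

  weights <- simulate_weights(config, animals)
  histology <- simulate_histology(config, seed = seed + 10000000L)

  config$seed <- seed
  structure(list(sessions = sessions, weights = weights,
                 histology = histology, config = config),
            class = "sp_cohort")
}

cohort_animals <- function(config) {
  make_group <- function(n, genotype) {
    n_f <- round(n * config$sex_ratio)
    tibble(
      animal_id = sprintf("%s-%02d", genotype, seq_len(n)),
      genotype = genotype,
      sex = rep(c("F", "M"), times = c(n_f, n - n_f))
    )
  }
  bind_rows(make_group(config$n_wt, "WT"), make_group(config$n_sod1, "SOD1"))
}

# n draws of k metrics with equicorrelation rho via a single shared factor;
# exact zeros when sds are zero
correlated_noise <- function(n, sds, rho) {
  k <- length(sds)
  shared <- rnorm(n)
  own <- matrix(rnorm(n * k), n, k)
  z <- sqrt(rho) * shared + sqrt(1 - rho) * own
  sweep(z, 2, sds, `*`)
}

simulate_weights <- function(config, animals) {
  w0 <- config$weight_start_g + rnorm(nrow(animals), 0, config$weight_animal_sd)
  animals$w0 <- w0
  grid <- tidyr::expand_grid(animal_id = animals$animal_id, week = config$weeks) %>%
    left_join(animals[, c("animal_id", "genotype", "sex", "w0")], by = "animal_id")
  trend <- config$wt_weight_slope * (grid$week - min(config$weeks))
  shortfall <- ifelse(
    grid$genotype == "SOD1",
    config$sod1_weight_deficit_slope *
      pmax(0, grid$week - config$sod1_weight_deficit_onset_week),
    0
  )
  eps <- rnorm(nrow(grid), 0, config$weight_noise_sd)
  grid %>%
    mutate(weight_g = pmax(0, .data$w0 + trend - shortfall + eps)) %>%
    select("animal_id", "genotype", "sex", "week", "weight_g")
}

#' Simulate cross-sectional motor-neuron histology
#'
#' Generates per-slice motor-neuron counts for both regions (M1 motor cortex,
#' CTIP2+; L5 ventral horn, large NeuN+) at the configured histology weeks,
#' for `n_histology_per_group` animals per genotype per week. The SOD1
#' programmed mean count declines linearly with the programmed group
#' behavioral decline at the matched behavioral week; WT means are constant.
#' Counts are continuous expected counts truncated at zero (see the methods
#' vignette).
#'
#' @inheritParams simulate_cohort
#' @return Tibble with columns `animal_id, genotype, week, region, slice_id,
#'   mn_count, field_area_px`.
#' @export
simulate_histology <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sp_config"))
  validate_sim_config(config)
  set.seed(as.integer(seed))

  grid_animal <- tidyr::expand_grid(
    week = config$histology_weeks,
    genotype = c("WT", "SOD1"),
    animal_index = seq_len(config$n_histology_per_group),
    region = c("M1", "L5VH")
  ) %>%
    mutate(animal_id = sprintf("H-%s-w%02d-%02d", .data$genotype, .data$week,
                               .data$animal_index))

  coupling <- config$histology_coupling
  mean_count <- mapply(function(region, genotype, week) {
    cp <- coupling[[region]]
    if (genotype == "WT") return(cp$healthy_count)
    bw <- matched_behavior_week(week, config$weeks)
    decline <- config$metric_baselines[[cp$metric]] -
      programmed_mean(config, cp$metric, bw, "SOD1")
    cp$healthy_count - cp$gain * decline
  }, grid_animal$region, grid_animal$genotype, grid_animal$week)

  a_sd <- vapply(grid_animal$region, function(r) coupling[[r]]$animal_sd, numeric(1))
  grid_animal$mu <- mean_count + rnorm(nrow(grid_animal), 0, a_sd)

  slices <- tidyr::expand_grid(
    grid_animal,
    slice_index = seq_len(config$slices_per_animal)
  )
  s_sd <- vapply(slices$region, function(r) coupling[[r]]$slice_sd, numeric(1))
  slices %>%
    mutate(
      mn_count = pmax(0, .data$mu + rnorm(dplyr::n(), 0, s_sd)),
      slice_id = sprintf("%s-%s-s%d", .data$animal_id, .data$region, .data$slice_index),
      field_area_px = 1024L * 1024L
    ) %>%
    select("animal_id", "genotype", "week", "region", "slice_id",
           "mn_count", "field_area_px")
}

#' Match a histology week to a behavioral testing week
#'
#' Behavioral testing runs over `weeks` (default 9--18) while histology is
#' sampled at weeks 7/11/15/19, so out-of-range histology weeks are clamped
#' to the nearest tested week (7 pairs with 9; 19 pairs with 18).
#'
#' @param histology_week Integer vector of histology weeks.
#' @param weeks Behavioral study weeks (default `9:18`).
#' @return Integer vector of matched behavioral weeks.
#' @export
matched_behavior_week <- function(histology_week, weeks = 9:18) {
  pmin(pmax(as.integer(histology_week), min(weeks)), max(weeks))
}

#' @export
print.sp_cohort <- function(x, ...) {
  cat("<sp_cohort> simulated string-pulling cohort\n")
  cat(sprintf("  %d sessions (%d animals), %d weight records, %d histology slices\n",
              nrow(x$sessions), dplyr::n_distinct(x$sessions$animal_id),
              nrow(x$weights), nrow(x$histology)))
  cat(sprintf("  seed: %d\n", x$config$seed))
  invisible(x)
}
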