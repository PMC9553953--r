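# shared fixtures: configs are built in code, never stored

suppressMessages({
  library(dplyr)
  library(tidyr)
  library(tibble)
})

# noise-free config with an explicit deficit SD scale (2 s / 2 s / 10 cm)
noiseless_config <- function(...) {
  sim_config(
    noise_sd = c(time_pulling_s = 0, time_hindlimbs_s = 0, length_pulled_cm = 0),
    animal_sd = c(time_pulling_s = 0, time_hindlimbs_s = 0, length_pulled_cm = 0),
    deficit_sd_scale = c(time_pulling_s = 2, time_hindlimbs_s = 2,
                         length_pulled_cm = 10),
    weight_animal_sd = 0, weight_noise_sd = 0,
    ...
  )
}

# also silence the histology noise
noiseless_histology_config <- function(...) {
  cfg <- noiseless_config(...)
  for (r in c("M1", "L5VH")) {
    cfg$histology_coupling[[r]]$animal_sd <- 0
    cfg$histology_coupling[[r]]$slice_sd <- 0
  }
  cfg
}

# small cohort for fast structural tests
small_config <- function(...) {
  sim_config(n_wt = 4, n_sod1 = 6, n_histology_per_group = 3,
             slices_per_animal = 2, ...)
}

# random 1-ms-aligned pull events for oracle comparisons
random_events <- function(n_max = 8) {
  n <- sample(n_max, 1)
  start_ms <- sample(0:58999, n, replace = TRUE)
  dur_ms <- pmin(sample(1:8000, n, replace = TRUE), 60000 - start_ms)
  tibble::tibble(
    start_s = start_ms / 1000,
    end_s = (start_ms + dur_ms) / 1000,
    posture = sample(c("standing", "seated"), n, replace = TRUE),
    displacement_cm = round(stats::runif(n, 0, 20), 2)
  )
}

# independent oracle: score a session by 1-ms discretization of [0, 60]
oracle_score_session <- function(events, dt = 0.001) {
  mids <- seq(dt / 2, 60 - dt / 2, by = dt)
  covered <- rep(FALSE, length(mids))
  standing <- rep(FALSE, length(mids))
  for (i in seq_len(nrow(events))) {
    inside <- mids > events$start_s[i] & mids < events$end_s[i]
    covered <- covered | inside
    if (events$posture[i] == "standing") standing <- standing | inside
  }
  tibble::tibble(time_pulling_s = sum(covered) * dt,
                 time_hindlimbs_s = sum(standing) * dt,
                 length_pulled_cm = sum(events$displacement_cm))
}
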