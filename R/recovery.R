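#' Onset-recovery study over replicate simulated cohorts
#'
#' Simulates one cohort per seed, runs the group-level z-threshold onset
#' detector on the three behavioral metrics and the extrapolated-baseline
#' deviation detector on weight, and collects the detected onset weeks.
#' Used to check that the analysis recovers the generator's programmed
#' crossing week.
#'
#' @param seeds Integer vector of cohort seeds.
#' @param config An [sim_config()] template (its own seed is ignored).
#' @param threshold Group z threshold (default -0.5).
#' @return Tibble `(seed, metric, onset_week)` with one row per seed and
#'   metric (including `"weight"`).
#' @export
#' @examples
#' study <- onset_recovery_study(1:5)
#' modal_week(study$onset_week[study$metric == "time_hindlimbs_s"])
onset_recovery_study <- function(seeds, config = sim_config(),
                                 threshold = -0.5) {
  purrr::map(seeds, function(s) {
    cohort <- simulate_cohort(config, seed = s)
    weekly <- weekly_metrics(cohort$sessions)
    behav <- purrr::map(sp_metrics(), function(m) {
      group_onset_analysis(weekly, m, threshold = threshold)$onset
    })
    wt <- weight_onset_analysis(cohort$weights, threshold = threshold)$onset
    bind_rows(behav, list(wt)) %>%
      select("metric", "onset_week") %>%
      mutate(seed = s, .before = 1)
  }) %>% bind_rows()
}

#' Correlation-recovery study over replicate simulated cohorts
#'
#' Simulates one cohort per seed and computes the 4-point group-mean
#' density-behavior correlations (M1 vs time pulling, L5VH vs time on
#' hindlimbs) at the matched histology timepoints.
#'
#' @inheritParams onset_recovery_study
#' @return Tibble `(seed, region, metric, r_squared)`.
#' @export
correlation_recovery_study <- function(seeds, config = sim_config()) {
  pairs <- list(c("M1", "time_pulling_s"), c("L5VH", "time_hindlimbs_s"))
  purrr::map(seeds, function(s) {
    cohort <- simulate_cohort(config, seed = s)
    weekly <- weekly_metrics(cohort$sessions)
    dens <- animal_densities(cohort$histology)
    purrr::map(pairs, function(p) {
      tibble(seed = s, region = p[1], metric = p[2],
             r_squared = density_behavior_correlation(
               dens, weekly, p[1], p[2],
               weeks = config$weeks)$r_squared)
    }) %>% bind_rows()
  }) %>% bind_rows()
}

#' Modal detected week
#'
#' Most frequent value of a vector of detected onset weeks; `NA`s (no onset)
#' are dropped. Ties resolve to the earliest week.
#'
#' @param weeks Integer vector of detected weeks (may contain `NA`).
#' @return The modal week as an integer, or `NA` if no onsets were detected.
#' @export
modal_week <- function(weeks) {
  weeks <- weeks[!is.na(weeks)]
  if (length(weeks) == 0) return(NA_integer_)
  tab <- table(weeks)
  as.integer(names(tab)[which.max(tab)])
}
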