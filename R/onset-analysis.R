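#' Group-level onset analysis for one behavioral metric
#'
#' The full group-level onset statistic for a decline metric: pool the SOD1
#' per-animal weekly values over the baseline window for the baseline mean
#' and SD, z-score the SOD1 weekly group-mean series against that baseline,
#' and call the first week the z series crosses the threshold.
#'
#' @param weekly Long weekly table from [weekly_metrics()].
#' @param metric Metric to analyse.
#' @param baseline_window Baseline weeks (default `9:11`).
#' @param threshold z threshold (default -0.5).
#' @param genotype Group whose baseline and trajectory define the statistic
#'   (default `"SOD1"`, the experimental group's own baseline).
#' @param sustain Consecutive weeks required at threshold (default 1).
#' @param baseline_sd Optional explicit baseline SD overriding the estimated
#'   pooled SD (needed e.g. for noise-free data where the estimated SD is 0).
#' @return List with `baseline` (`sp_baseline`), `z` (tibble
#'   `week, value, z` of group means), and `onset` (one-row tibble from
#'   [detect_group_onset()]).
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(seed = 3))
#' wk <- weekly_metrics(cohort$sessions)
#' group_onset_analysis(wk, "time_hindlimbs_s")$onset
group_onset_analysis <- function(weekly, metric, baseline_window = 9:11,
                                 threshold = -0.5, genotype = "SOD1",
                                 sustain = 1, baseline_sd = NULL) {
  weekly <- as_tibble(weekly) %>%
    filter(.data$metric == !!metric, .data$genotype == !!genotype)
  if (nrow(weekly) == 0) {
    sp_validation_error(sprintf("no weekly values for metric `%s`, genotype `%s`",
                                metric, genotype))
  }
  baseline <- compute_baseline(weekly, window = baseline_window, scope = "group")
  if (!is.null(baseline_sd)) baseline$sd <- baseline_sd
  group_means <- weekly %>%
    group_by(week = .data$week) %>%
    summarise(value = mean(.data$value), .groups = "drop")
  z <- zscore_series(group_means, baseline)
  onset <- detect_group_onset(z, threshold = threshold,
                              after_week = max(baseline_window),
                              sustain = sustain, metric = metric)
  list(baseline = baseline, z = z, onset = onset)
}

#' Per-animal onset calls by the 20% own-baseline rule
#'
#' Applies [detect_animal_onset()] to every animal of a genotype for one
#' metric, using each animal's own baseline-window mean.
#'
#' @inheritParams group_onset_analysis
#' @param rel_threshold Fractional deviation defining onset (default 0.20).
#' @return Tibble of one-row onset calls, one per animal.
#' @export
animal_onsets <- function(weekly, metric, baseline_window = 9:11,
                          rel_threshold = 0.20, genotype = "SOD1", sustain = 1) {
  weekly <- as_tibble(weekly) %>%
    filter(.data$metric == !!metric, .data$genotype == !!genotype)
  if (nrow(weekly) == 0) {
    sp_validation_error(sprintf("no weekly values for metric `%s`, genotype `%s`",
                                metric, genotype))
  }
  weekly %>%
    group_by(.data$animal_id) %>%
    dplyr::group_modify(function(df, key) {
      bl <- compute_baseline(df, window = baseline_window, scope = "animal")
      detect_animal_onset(df, bl, rel_threshold = rel_threshold,
                          after_week = max(baseline_window), sustain = sustain,
                          metric = metric) %>%
        select(-"animal_id") # animal_id comes from the grouping key
    }) %>%
    ungroup()
}

#' Weight onset against the extrapolated counterfactual baseline
#'
#' Implements the weight arm of the onset analysis: relative weight change to
#' the reference week per animal, an OLS growth trend fitted to the WT weekly
#' means and re-anchored at the SOD1 baseline mean
#' ([extrapolate_weight_baseline()]), per-animal deviations of SOD1 relative
#' weight from that projection, and a z-threshold onset call on the weekly
#' group-mean deviation series (baseline: pooled SOD1 deviations over the
#' baseline window).
#'
#' @param weights Weight table `(animal_id, genotype, sex, week, weight_g)`.
#' @param baseline_window Baseline weeks (default `9:11`).
#' @param reference_week Reference week for relative weight (default 9).
#' @param threshold z threshold (default -0.5).
#' @param end_week Last week of the projection (default: last observed week).
#' @param sustain Consecutive weeks required at threshold (default 1).
#' @param baseline_sd Optional explicit SD of the baseline deviation pool.
#' @return List with `projection` (tibble `week, projected`), `deviation`
#'   (per-animal tibble `animal_id, week, rel_weight, deviation`), `baseline`
#'   (`sp_baseline` of the deviation pool), `z` (tibble `week, value, z` of
#'   group-mean deviations) and `onset` (one-row tibble, metric
#'   `"weight"`).
#' @export
weight_onset_analysis <- function(weights, baseline_window = 9:11,
                                  reference_week = 9, threshold = -0.5,
                                  end_week = NULL, sustain = 1,
                                  baseline_sd = NULL) {
  rel <- relative_weight(weights, reference_week = reference_week)
  end_week <- end_week %||% max(rel$week)

  wt_means <- rel %>%
    filter(.data$genotype == "WT") %>%
    group_by(week = .data$week) %>%
    summarise(value = mean(.data$rel_weight), .groups = "drop")
  sod1 <- rel %>% filter(.data$genotype == "SOD1")
  if (nrow(sod1) == 0) sp_validation_error("no SOD1 weight records")
  sod1_baseline <- compute_baseline(
    sod1 %>% rename(value = "rel_weight"),
    window = baseline_window, scope = "group")

  projection <- extrapolate_weight_baseline(
    wt_means, sod1_baseline, end_week = end_week,
    anchor_week = mean(range(baseline_window)))

  deviation <- sod1 %>%
    left_join(projection, by = "week") %>%
    mutate(deviation = .data$rel_weight - .data$projected) %>%
    select("animal_id", "week", "rel_weight", "deviation")

  dev_baseline <- compute_baseline(
    deviation %>% rename(value = "deviation"),
    window = baseline_window, scope = "group")
  if (!is.null(baseline_sd)) dev_baseline$sd <- baseline_sd

  dev_means <- deviation %>%
    group_by(week = .data$week) %>%
    summarise(value = mean(.data$deviation), .groups = "drop")
  z <- zscore_series(dev_means, dev_baseline)
  onset <- detect_group_onset(z, threshold = threshold,
                              after_week = max(baseline_window),
                              sustain = sustain, metric = "weight")
  list(projection = projection, deviation = deviation,
       baseline = dev_baseline, z = z, onset = onset)
}
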