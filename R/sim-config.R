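#' Configuration for the synthetic SOD1 cohort generator
#'
#' Builds the full parameter set describing a simulated longitudinal
#' string-pulling study: a wild-type (WT) and a SOD1*G93A group tested twice
#' weekly over weeks 9--18, with weekly weights, a programmed progressive
#' behavioral deficit in the SOD1 group, and cross-sectional motor-neuron (MN)
#' histology at weeks 7, 11, 15 and 19 coupled to the behavioral decline.
#'
#' @details
#' The behavioral model for animal \eqn{a}, metric \eqn{m}, week \eqn{w},
#' session \eqn{s} is
#' \deqn{y = \mu_m - \delta_m(w) + b_{am} + e_{amws}}
#' with between-animal intercepts \eqn{b_{am} \sim N(0, \sigma^2_{A,m})} and
#' session noise \eqn{e \sim N(0, \sigma^2_{E,m})}, both sharing a common
#' latent factor across metrics with correlation `metric_cor` (an animal that
#' pulls less also tends to stand less). The programmed SOD1 deficit is
#' piecewise linear,
#' \deqn{\delta_m(w) = \beta \cdot s_m \cdot \max(0, w - w_0)}
#' where \eqn{\beta} is `deficit_slope_sd_per_week`, \eqn{w_0} is
#' `deficit_onset_week`, and the scale \eqn{s_m} is `deficit_sd_scale`
#' (defaulting to the session-level SD
#' \eqn{\sqrt{\sigma^2_{A,m} + \sigma^2_{E,m}}}). WT animals have
#' \eqn{\delta_m \equiv 0}. Generated sessions are clamped to the physical
#' constraints \eqn{0 \le} hindlimb time \eqn{\le} pulling time \eqn{\le 60} s
#' and all values \eqn{\ge 0}.
#'
#' Weights follow a linear growth trend `wt_weight_slope` (g/week) shared by
#' both genotypes; from `sod1_weight_deficit_onset_week` the SOD1 group falls
#' behind that trend by `sod1_weight_deficit_slope` g/week.
#'
#' Histology counts are generated per slice around a programmed mean:
#' the WT mean is the region's `healthy_count`; the SOD1 mean declines
#' linearly with the programmed group behavioral decline at the matched
#' behavioral week (histology weeks 7/11/15/19 pair with behavioral weeks
#' 9/11/15/18) via the region's `gain` (cells lost per unit of metric
#' decline). Between-animal (`animal_sd`) and between-slice (`slice_sd`)
#' Gaussian noise is added and counts are truncated at zero.
#'
#' @param n_wt,n_sod1 Number of WT and SOD1 animals (defaults 16 and 24).
#' @param sex_ratio Fraction of females in each group (default 0.5).
#' @param weeks Integer vector of study weeks (default `9:18`).
#' @param sessions_per_week Recording sessions per week (default 2).
#' @param metric_baselines Named numeric: healthy mean for each metric
#'   (`time_pulling_s`, `time_hindlimbs_s`, `length_pulled_cm`).
#' @param noise_sd Named numeric: within-animal between-session SD per metric.
#' @param animal_sd Named numeric: between-animal SD per metric.
#' @param metric_cor Shared-factor correlation of the three metrics' noise
#'   components, in `[0, 1)` (default 0.6).
#' @param deficit_onset_week First week at which the SOD1 behavioral deficit
#'   accrues (default 12).
#' @param deficit_slope_sd_per_week Decline rate in units of `deficit_sd_scale`
#'   per week (default 0.5).
#' @param deficit_sd_scale Named numeric or `NULL`: the SD unit of the
#'   programmed decline. `NULL` (default) uses the session-level SD
#'   `sqrt(animal_sd^2 + noise_sd^2)` per metric.
#' @param weight_start_g Mean body weight at week 9 (default 22 g).
#' @param weight_animal_sd Between-animal SD of starting weight (default 1.5 g).
#' @param weight_noise_sd Week-to-week measurement/physiological noise SD
#'   (default 0.4 g).
#' @param wt_weight_slope WT growth trend in g/week (default 0.25).
#' @param sod1_weight_deficit_onset_week Week SOD1 weight starts to fall
#'   behind the WT trend (default 12).
#' @param sod1_weight_deficit_slope Shortfall of SOD1 weight relative to the
#'   WT trend, g/week (default 0.3, calibrated by simulation so the group
#'   deviation z-statistic first crosses -0.5 at week 13).
#' @param histology_weeks Cross-sectional histology timepoints
#'   (default `c(7, 11, 15, 19)`).
#' @param n_histology_per_group Animals per genotype per timepoint (default 6).
#' @param slices_per_animal Slices counted per animal and region (default 3).
#' @param histology_coupling Named list with elements `M1` and `L5VH`, each a
#'   list `(healthy_count, gain, metric, animal_sd, slice_sd)`. Defaults are
#'   calibrated so that, under the default cohort, the mean 4-point
#'   density-vs-behavior R-squared over many seeds matches the reported values
#'   (cortical vs time pulling about 0.91; spinal vs time on hindlimbs about
#'   0.83).
#' @param seed Integer seed stored with the config; used by
#'   [simulate_cohort()] unless overridden.
#'
#' @return An object of class `sp_config` (a named list).
#' @seealso [simulate_cohort()], [simulate_histology()]
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$n_sod1
sim_config <- function(n_wt = 16,
                       n_sod1 = 24,
                       sex_ratio = 0.5,
                       weeks = 9:18,
                       sessions_per_week = 2,
                       metric_baselines = c(time_pulling_s = 32,
                                            time_hindlimbs_s = 22,
                                            length_pulled_cm = 110),
                       noise_sd = c(time_pulling_s = 4,
                                    time_hindlimbs_s = 3.5,
                                    length_pulled_cm = 18),
                       animal_sd = c(time_pulling_s = 3,
                                     time_hindlimbs_s = 2.5,
                                     length_pulled_cm = 12),
                       metric_cor = 0.6,
                       deficit_onset_week = 12,
                       deficit_slope_sd_per_week = 0.5,
                       deficit_sd_scale = NULL,
                       weight_start_g = 22,
                       weight_animal_sd = 1.5,
                       weight_noise_sd = 0.4,
                       wt_weight_slope = 0.25,
                       sod1_weight_deficit_onset_week = 12,
                       sod1_weight_deficit_slope = 0.3,
                       histology_weeks = c(7, 11, 15, 19),
                       n_histology_per_group = 6,
                       slices_per_animal = 3,
                       histology_coupling = default_histology_coupling(),
                       seed = 1L) {
  cfg <- list(
    n_wt = n_wt, n_sod1 = n_sod1, sex_ratio = sex_ratio,
    weeks = as.integer(weeks), sessions_per_week = as.integer(sessions_per_week),
    metric_baselines = metric_baselines, noise_sd = noise_sd,
    animal_sd = animal_sd, metric_cor = metric_cor,
    deficit_onset_week = deficit_onset_week,
    deficit_slope_sd_per_week = deficit_slope_sd_per_week,
    deficit_sd_scale = deficit_sd_scale,
    weight_start_g = weight_start_g, weight_animal_sd = weight_animal_sd,
    weight_noise_sd = weight_noise_sd, wt_weight_slope = wt_weight_slope,
    sod1_weight_deficit_onset_week = sod1_weight_deficit_onset_week,
    sod1_weight_deficit_slope = sod1_weight_deficit_slope,
    histology_weeks = as.integer(histology_weeks),
    n_histology_per_group = n_histology_per_group,
    slices_per_animal = slices_per_animal,
    histology_coupling = histology_coupling,
    seed = as.integer(seed)
  )
  class(cfg) <- "sp_config"
  validate_sim_config(cfg)
}

#' Default histology coupling parameters
#'
#' Cortical (M1, CTIP2+) counts are coupled to time spent pulling; spinal
#' (L5 ventral horn, large NeuN+) counts to time on hindlimbs. `gain` is cells
#' lost per field per unit (s) of programmed behavioral decline at the matched
#' week; `animal_sd` / `slice_sd` are Gaussian noise SDs in cells per field.
#' Noise SDs were calibrated by simulation sweep against the target mean
#' R-squared values (see the methods vignette).
#'
#' @return Named list with components `M1` and `L5VH`.
#' @export
default_histology_coupling <- function() {
  list(
    M1 = list(healthy_count = 32, gain = 0.93, metric = "time_pulling_s",
              animal_sd = 5.85, slice_sd = 1.5),
    L5VH = list(healthy_count = 13, gain = 0.605, metric = "time_hindlimbs_s",
                animal_sd = 4.6, slice_sd = 1)
  )
}

validate_sim_config <- function(cfg) {
  m <- sp_metrics()
  check_num <- function(x, field, min = NULL, len = 1, names_req = NULL) {
    if (!is.numeric(x) || length(x) != len || anyNA(x)) {
      sp_config_error(sprintf("invalid config field `%s`", field),
                      field = field)
    }
    if (!is.null(min) && any(x < min)) {
      sp_config_error(sprintf("config field `%s` must be >= %s", field, min),
                      field = field)
    }
    if (!is.null(names_req) && !all(names_req %in% names(x))) {
      sp_config_error(sprintf("config field `%s` must be named for all of: %s",
                              field, paste(names_req, collapse = ", ")),
                      field = field)
    }
    invisible(x)
  }
  check_num(cfg$n_wt, "n_wt", min = 1)
  check_num(cfg$n_sod1, "n_sod1", min = 1)
  check_num(cfg$sex_ratio, "sex_ratio", min = 0)
  if (cfg$sex_ratio > 1) sp_config_error("config field `sex_ratio` must be <= 1",
                                         field = "sex_ratio")
  if (length(cfg$weeks) < 1 || anyNA(cfg$weeks)) {
    sp_config_error("config field `weeks` must be a non-empty integer range",
                    field = "weeks")
  }
  check_num(cfg$sessions_per_week, "sessions_per_week", min = 1)
  check_num(cfg$metric_baselines, "metric_baselines", min = 0, len = 3, names_req = m)
  check_num(cfg$noise_sd, "noise_sd", min = 0, len = 3, names_req = m)
  check_num(cfg$animal_sd, "animal_sd", min = 0, len = 3, names_req = m)
  check_num(cfg$metric_cor, "metric_cor", min = 0)
  if (cfg$metric_cor >= 1) sp_config_error("config field `metric_cor` must be < 1",
                                           field = "metric_cor")
  check_num(cfg$deficit_onset_week, "deficit_onset_week")
  check_num(cfg$deficit_slope_sd_per_week, "deficit_slope_sd_per_week", min = 0)
  if (!is.null(cfg$deficit_sd_scale)) {
    check_num(cfg$deficit_sd_scale, "deficit_sd_scale", min = 0, len = 3, names_req = m)
  }
  check_num(cfg$weight_start_g, "weight_start_g", min = 0)
  check_num(cfg$weight_animal_sd, "weight_animal_sd", min = 0)
  check_num(cfg$weight_noise_sd, "weight_noise_sd", min = 0)
  check_num(cfg$wt_weight_slope, "wt_weight_slope")
  check_num(cfg$sod1_weight_deficit_onset_week, "sod1_weight_deficit_onset_week")
  check_num(cfg$sod1_weight_deficit_slope, "sod1_weight_deficit_slope", min = 0)
  if (length(cfg$histology_weeks) < 1 || anyNA(cfg$histology_weeks)) {
    sp_config_error("config field `histology_weeks` must be non-empty",
                    field = "histology_weeks")
  }
  check_num(cfg$n_histology_per_group, "n_histology_per_group", min = 1)
  check_num(cfg$slices_per_animal, "slices_per_animal", min = 1)
  for (region in c("M1", "L5VH")) {
    cp <- cfg$histology_coupling[[region]]
    if (is.null(cp)) {
      sp_config_error(sprintf("config field `histology_coupling` missing region %s", region),
                      field = "histology_coupling")
    }
    for (f in c("healthy_count", "gain", "animal_sd", "slice_sd")) {
      if (!is.numeric(cp[[f]]) || length(cp[[f]]) != 1 || is.na(cp[[f]]) || cp[[f]] < 0) {
        sp_config_error(sprintf("invalid config field `histology_coupling$%s$%s`", region, f),
                        field = "histology_coupling")
      }
    }
    if (!cp$metric %in% sp_metrics()) {
      sp_config_error(sprintf("invalid config field `histology_coupling$%s$metric`", region),
                      field = "histology_coupling")
    }
  }
  check_num(as.numeric(cfg$seed), "seed")
  cfg
}

# SD unit of the programmed deficit; session-level SD unless fixed explicitly
deficit_scale <- function(cfg) {
  if (!is.null(cfg$deficit_sd_scale)) {
    return(cfg$deficit_sd_scale[sp_metrics()])
  }
  sqrt(cfg$animal_sd[sp_metrics()]^2 + cfg$noise_sd[sp_metrics()]^2)
}

#' Programmed SOD1 group mean for a behavioral metric
#'
#' The noise-free expected value of a metric at a given week under a config:
#' baseline for WT, piecewise-linear decline for SOD1 starting at
#' `deficit_onset_week`.
#'
#' @param config An [sim_config()] object.
#' @param metric One of `"time_pulling_s"`, `"time_hindlimbs_s"`,
#'   `"length_pulled_cm"`.
#' @param week Integer vector of weeks.
#' @param genotype `"WT"` or `"SOD1"`.
#' @return Numeric vector of expected metric values.
#' @export
programmed_mean <- function(config, metric, week, genotype = "SOD1") {
  stopifnot(inherits(config, "sp_config"))
  if (!metric %in% sp_metrics()) {
    sp_config_error(sprintf("unknown metric `%s`", metric), field = "metric")
  }
  base <- unname(config$metric_baselines[[metric]])
  if (identical(genotype, "WT")) return(rep(base, length(week)))
  scale <- unname(deficit_scale(config)[[metric]])
  base - config$deficit_slope_sd_per_week * scale *
    pmax(0, week - config$deficit_onset_week)
}

#' @export
print.sp_config <- function(x, ...) {
  cat("<sp_config> synthetic SOD1 string-pulling cohort\n")
  cat(sprintf("  groups: %d WT, %d SOD1 (%.0f%% female); weeks %d-%d, %d sessions/week\n",
              x$n_wt, x$n_sod1, 100 * x$sex_ratio, min(x$weeks), max(x$weeks),
              x$sessions_per_week))
  cat(sprintf("  deficit: onset week %s, %.2f SD/week\n",
              x$deficit_onset_week, x$deficit_slope_sd_per_week))
  cat(sprintf("  histology: weeks %s, n = %d/group, %d slices/animal\n",
              paste(x$histology_weeks, collapse = "/"),
              x$n_histology_per_group, x$slices_per_animal))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
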