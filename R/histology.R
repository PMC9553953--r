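#' Classify motor neurons among labelled soma objects
#'
#' Applies the region-specific motor-neuron definition to a table of labelled
#' cell bodies: in the L5 ventral horn (`"L5VH"`), NeuN-positive somata with
#' cross-sectional area strictly greater than the size cutoff count as motor
#' neurons; in layer-5 motor cortex (`"M1"`), CTIP2 expression alone defines
#' a motor neuron, with no size filter.
#'
#' @param objects Data frame of soma objects with columns `region`
#'   (`"M1"`/`"L5VH"`), `marker` (`"NeuN"`/`"CTIP2"`) and `size_um2`
#'   (cross-sectional area; interpreted as area in square micrometres, see
#'   the methods vignette).
#' @param region Region whose rule to apply; all rows must belong to it.
#' @param size_cutoff_um2 Strict lower size cutoff for L5VH NeuN+ somata
#'   (default 250).
#' @return Integer motor-neuron count.
#' @export
#' @examples
#' obj <- tibble::tibble(region = "L5VH", marker = "NeuN",
#'                       size_um2 = c(300, 251, 250, 100))
#' classify_motoneurons(obj, "L5VH")
classify_motoneurons <- function(objects, region = c("L5VH", "M1"),
                                 size_cutoff_um2 = 250) {
  region <- match.arg(region)
  objects <- as_tibble(objects)
  if (nrow(objects) == 0) return(0L)
  if ("region" %in% names(objects) && !all(objects$region == region)) {
    sp_validation_error("soma objects from mixed regions; classify one region at a time")
  }
  if (region == "L5VH") {
    if (!"size_um2" %in% names(objects)) {
      sp_validation_error("L5VH classification needs a `size_um2` column")
    }
    sum(objects$marker == "NeuN" & objects$size_um2 > size_cutoff_um2)
  } else {
    sum(objects$marker == "CTIP2")
  }
}

#' Field-normalized motor-neuron density
#'
#' Converts a per-field count to the reported density unit: the count divided
#' by the field pixel area (1024 x 1024 by default) and multiplied by one
#' million, i.e. cells per 10^6 pixels.
#'
#' @param mn_count Motor-neuron count(s) per field (>= 0).
#' @param field_area_px Field area in pixels (default `1024 * 1024`).
#' @return Density in cells per 10^6 pixels.
#' @export
#' @examples
#' normalize_density(10) # about 9.5367
normalize_density <- function(mn_count, field_area_px = 1024 * 1024) {
  if (any(!is.finite(field_area_px)) || any(field_area_px <= 0)) {
    sp_validation_error("field_area_px must be positive")
  }
  if (any(mn_count < 0)) sp_validation_error("mn_count must be >= 0")
  mn_count / field_area_px * 1e6
}

#' Per-animal motor-neuron density
#'
#' Averages the per-slice normalized densities of one animal at one week and
#' region into a single per-animal value — each animal contributes one
#' n-value per timepoint and region.
#'
#' @param slices Slice table rows for a single animal/week/region with
#'   columns `mn_count` and `field_area_px` (plus identifying columns).
#' @return One-row tibble `(animal_id, genotype, week, region, density,
#'   n_slices)`.
#' @export
aggregate_animal <- function(slices) {
  slices <- as_tibble(slices)
  if (nrow(slices) == 0) sp_validation_error("no slices to aggregate")
  key <- c("animal_id", "week", "region")
  for (k in intersect(key, names(slices))) {
    if (dplyr::n_distinct(slices[[k]]) > 1) {
      sp_validation_error(sprintf(
        "aggregate_animal() expects slices from a single %s (got: %s)",
        k, paste(unique(slices[[k]]), collapse = ", ")))
    }
  }
  tibble(
    animal_id = slices$animal_id[1], genotype = slices$genotype[1],
    week = slices$week[1], region = slices$region[1],
    density = mean(normalize_density(slices$mn_count, slices$field_area_px)),
    n_slices = nrow(slices))
}

#' Per-animal densities for a whole histology table
#'
#' Tidy wrapper over [aggregate_animal()]: one density row per
#' animal-week-region.
#'
#' @param histology Slice table `(animal_id, genotype, week, region,
#'   slice_id, mn_count, field_area_px)`.
#' @return Tibble `(animal_id, genotype, week, region, density, n_slices)`.
#' @export
animal_densities <- function(histology) {
  as_tibble(histology) %>%
    group_by(.data$animal_id, .data$genotype, .data$week, .data$region) %>%
    summarise(density = mean(normalize_density(.data$mn_count, .data$field_area_px)),
              n_slices = dplyr::n(), .groups = "drop")
}

#' Unpaired t test between WT and SOD1 densities at one timepoint
#'
#' Classical two-sided unpaired t test (pooled variance by default, Welch
#' behind a flag) on per-animal densities.
#'
#' @param wt,sod1 Numeric vectors of per-animal densities (>= 2 each).
#' @param welch Use Welch's unequal-variance test (default `FALSE`).
#' @return One-row tibble `(n_wt, n_sod1, mean_wt, mean_sod1, t, df, p)`.
#' @export
timepoint_test <- function(wt, sod1, welch = FALSE) {
  if (length(wt) < 2 || length(sod1) < 2) {
    sp_validation_error("need at least 2 densities per group")
  }
  if (sd(wt) == 0 && sd(sod1) == 0) {
    same <- mean(wt) == mean(sod1)
    return(tibble(n_wt = length(wt), n_sod1 = length(sod1),
                  mean_wt = mean(wt), mean_sod1 = mean(sod1),
                  t = ifelse(same, 0, sign(mean(wt) - mean(sod1)) * Inf),
                  df = length(wt) + length(sod1) - 2,
                  p = ifelse(same, 1, 0)))
  }
  tt <- t.test(wt, sod1, var.equal = !welch)
  tibble(n_wt = length(wt), n_sod1 = length(sod1),
         mean_wt = mean(wt), mean_sod1 = mean(sod1),
         t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Per-timepoint WT vs SOD1 density tests for all regions
#'
#' @param densities Per-animal density table from [animal_densities()].
#' @param welch Use Welch's test (default `FALSE`, pooled variance).
#' @return Tibble with one row per region-week.
#' @export
density_timepoint_tests <- function(densities, welch = FALSE) {
  as_tibble(densities) %>%
    group_by(.data$region, .data$week) %>%
    dplyr::group_modify(function(df, key) {
      timepoint_test(df$density[df$genotype == "WT"],
                     df$density[df$genotype == "SOD1"], welch = welch)
    }) %>%
    ungroup()
}

#' Correlate motor-neuron density with behavioral decline
#'
#' Pearson correlation and OLS fit of behavior on density across matched
#' points — by default the group means at the four histology timepoints
#' (paired with behavioral weeks 9/11/15/18).
#'
#' @param data Data frame with numeric columns `density` and `behavior`
#'   (>= 3 matched points, both non-constant). Extra columns are ignored.
#' @param density_label,behavior_label Optional names recorded in the result.
#' @return An `sp_correlation` object: list with `n`, `r`, `r_squared`,
#'   `slope`, `intercept` (behavior regressed on density) and the labels.
#'   Has [tidy()] and [glance()] methods.
#' @export
#' @examples
#' d <- tibble::tibble(density = c(1, 2, 3), behavior = c(2, 4, 5))
#' glance(correlate_decline(d))
correlate_decline <- function(data, density_label = "density",
                              behavior_label = "behavior") {
  data <- as_tibble(data)
  if (!all(c("density", "behavior") %in% names(data))) {
    sp_validation_error("need columns `density` and `behavior`")
  }
  data <- data %>% filter(is.finite(.data$density), is.finite(.data$behavior))
  if (nrow(data) < 3) {
    sp_validation_error("need at least 3 matched points for a correlation")
  }
  if (sd(data$density) == 0 || sd(data$behavior) == 0) {
    sp_abort("correlation undefined: one of the series is constant",
             class = "sp_error_degenerate")
  }
  r <- cor(data$density, data$behavior)
  fit <- lm(behavior ~ density, data = data)
  structure(
    list(x = density_label, y = behavior_label, n = nrow(data), r = r,
         r_squared = r^2, slope = unname(coef(fit)[["density"]]),
         intercept = unname(coef(fit)[["(Intercept)"]]),
         points = data[, c("density", "behavior")]),
    class = "sp_correlation")
}

#' @export
print.sp_correlation <- function(x, ...) {
  cat(sprintf("<sp_correlation> %s ~ %s: r = %.4f, R^2 = %.4f (n = %d)\n",
              x$y, x$x, x$r, x$r_squared, x$n))
  invisible(x)
}

#' @rdname correlate_decline
#' @param x An `sp_correlation` object.
#' @param ... Unused.
#' @export
tidy.sp_correlation <- function(x, ...) {
  tibble(density = x$x, behavior = x$y, n = x$n, r = x$r,
         r_squared = x$r_squared, slope = x$slope, intercept = x$intercept)
}

#' @rdname correlate_decline
#' @export
glance.sp_correlation <- function(x, ...) tidy(x)

#' Density-behavior correlations at matched timepoints
#'
#' Builds the matched group-mean scatter for one region and one behavioral
#' metric — region density group means at the histology weeks against the
#' behavioral group means at the matched behavioral weeks — and runs
#' [correlate_decline()] on it. `per_animal = TRUE` instead pairs each
#' histology animal's density with the behavioral group mean of its matched
#' week (more points, same x-axis resolution: the histology animals are
#' cross-sectional and have no own behavioral series).
#'
#' @param densities Per-animal density table ([animal_densities()]).
#' @param weekly Long behavioral weekly table ([weekly_metrics()]).
#' @param region `"M1"` or `"L5VH"`.
#' @param metric Behavioral metric to pair with.
#' @param genotype Group correlated (default `"SOD1"`).
#' @param weeks Behavioral study weeks used for matching (default `9:18`).
#' @param per_animal Use per-animal density points (default `FALSE`: group
#'   means, one point per timepoint).
#' @return An `sp_correlation` object.
#' @export
density_behavior_correlation <- function(densities, weekly, region, metric,
                                         genotype = "SOD1", weeks = 9:18,
                                         per_animal = FALSE) {
  dens <- as_tibble(densities) %>%
    filter(.data$region == !!region, .data$genotype == !!genotype) %>%
    mutate(behavior_week = matched_behavior_week(.data$week, weeks))
  behav <- as_tibble(weekly) %>%
    filter(.data$metric == !!metric, .data$genotype == !!genotype) %>%
    group_by(behavior_week = .data$week) %>%
    summarise(behavior = mean(.data$value), .groups = "drop")
  if (!per_animal) {
    dens <- dens %>%
      group_by(week = .data$week, behavior_week = .data$behavior_week) %>%
      summarise(density = mean(.data$density), .groups = "drop")
  }
  pts <- dens %>% left_join(behav, by = "behavior_week")
  correlate_decline(pts, density_label = region, behavior_label = metric)
}
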