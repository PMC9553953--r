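#' @export
print.sp_analysis <- function(x, ...) {
  cat("== String-pulling cohort analysis ==\n\n")
  cat("Group-level onsets (baseline z rule):\n")
  oc <- x$onset_calls
  for (i in seq_len(nrow(oc))) {
    cat(sprintf("  %-18s onset week: %s (z <= %.2f)\n", oc$metric[i],
                ifelse(is.na(oc$onset_week[i]), "none detected", oc$onset_week[i]),
                oc$threshold[i]))
  }
  ac <- x$animal_onset_calls
  if (!is.null(ac) && nrow(ac) > 0) {
    cat("\nPer-animal onsets (20% own-baseline rule), detected/total by metric:\n")
    for (m in unique(ac$metric)) {
      w <- ac$onset_week[ac$metric == m]
      if (all(is.na(w))) {
        cat(sprintf("  %-18s no onsets detected\n", m))
      } else {
        cat(sprintf("  %-18s %d/%d animals, median week %.1f\n", m,
                    sum(!is.na(w)), length(w), stats::median(w, na.rm = TRUE)))
      }
    }
  }
  if (!is.null(x$comparisons) && nrow(x$comparisons) > 0) {
    cat(sprintf("\nWeekly WT vs SOD1 comparisons: %d of %d metric-weeks significant after Sidak (alpha = %g)\n",
                sum(x$comparisons$significant), nrow(x$comparisons),
                attr(x$comparisons, "alpha") %||% 0.05))
  }
  if (!is.null(x$densities)) {
    cat("\nMotor-neuron densities (cells per 10^6 px), mean +/- SEM:\n")
    dsum <- x$densities %>%
      group_by(.data$region, .data$genotype, .data$week) %>%
      summarise(mean = mean(.data$density),
                sem = sd(.data$density) / sqrt(dplyr::n()), .groups = "drop")
    for (i in seq_len(nrow(dsum))) {
      cat(sprintf("  %-5s %-5s week %2d: %6.2f +/- %.2f\n", dsum$region[i],
                  dsum$genotype[i], dsum$week[i], dsum$mean[i], dsum$sem[i]))
    }
    cat("\nDensity-behavior correlations (group means at matched weeks):\n")
    cr <- x$correlations
    for (i in seq_len(nrow(cr))) {
      cat(sprintf("  %-5s ~ %-18s R^2 = %.3f (n = %d%s)\n", cr$density[i],
                  cr$behavior[i], cr$r_squared[i], cr$n[i],
                  ifelse(isTRUE(cr$per_animal[i]), ", per animal", "")))
    }
  }
  if (length(x$log) > 0) {
    cat("\nLog:\n")
    cat(paste0("  ", x$log, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Tidy the onset calls of an analysis
#'
#' @param x An `sp_analysis` object.
#' @param ... Unused.
#' @return Tibble of group- and animal-level onset calls.
#' @export
tidy.sp_analysis <- function(x, ...) {
  bind_rows(x$onset_calls, x$animal_onset_calls)
}

#' One-row summary of an analysis
#'
#' @param x An `sp_analysis` object.
#' @param ... Unused.
#' @return One-row tibble: onset week per metric, number of significant
#'   comparison weeks, and the three headline R^2 values (NA when histology
#'   is absent).
#' @export
glance.sp_analysis <- function(x, ...) {
  oc <- x$onset_calls
  grab_r2 <- function(region, metric) {
    if (is.null(x$correlations)) return(NA_real_)
    hit <- x$correlations %>%
      filter(.data$density == region, .data$behavior == metric,
             !.data$per_animal)
    if (nrow(hit) == 0) NA_real_ else hit$r_squared[1]
  }
  tibble(
    onset_week_hindlimbs = oc$onset_week[oc$metric == "time_hindlimbs_s"],
    onset_week_pulling = oc$onset_week[oc$metric == "time_pulling_s"],
    onset_week_length = oc$onset_week[oc$metric == "length_pulled_cm"],
    onset_week_weight = oc$onset_week[oc$metric == "weight"],
    n_significant_weeks = if (is.null(x$comparisons)) NA_integer_
      else sum(x$comparisons$significant),
    r2_m1_pulling = grab_r2("M1", "time_pulling_s"),
    r2_m1_hindlimbs = grab_r2("M1", "time_hindlimbs_s"),
    r2_l5vh_hindlimbs = grab_r2("L5VH", "time_hindlimbs_s"))
}

#' Plot weekly group z trajectories
#'
#' Weekly z scores of the SOD1 group means (behavioral metrics) and of the
#' weight deviation from the extrapolated baseline, with the onset threshold
#' as a dashed line.
#'
#' @param report An `sp_analysis` object.
#' @param threshold Threshold line to draw (default taken from the report).
#' @return A ggplot object.
#' @export
plot_weekly_z <- function(report, threshold = NULL) {
  stopifnot(inherits(report, "sp_analysis"))
  threshold <- threshold %||% report$onset_calls$threshold[1]
  ggplot2::ggplot(report$z_series,
                  ggplot2::aes(x = .data$week, y = .data$z,
                               colour = .data$metric)) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Week of age", y = "z score vs weeks 9-11 baseline",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot motor-neuron densities by timepoint
#'
#' Per-animal densities with group mean and SEM, faceted by region.
#'
#' @param densities Per-animal density table ([animal_densities()]) or an
#'   `sp_analysis` object.
#' @return A ggplot object.
#' @export
plot_densities <- function(densities) {
  if (inherits(densities, "sp_analysis")) densities <- densities$densities
  if (is.null(densities)) sp_validation_error("no densities to plot")
  summ <- densities %>%
    group_by(.data$region, .data$genotype, .data$week) %>%
    summarise(mean = mean(.data$density),
              sem = sd(.data$density) / sqrt(dplyr::n()), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$week, y = .data$mean,
                                     colour = .data$genotype)) +
    ggplot2::geom_point(data = densities,
                        ggplot2::aes(y = .data$density), alpha = 0.4,
                        position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.4,
                           position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::geom_point(size = 2,
                        position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::facet_wrap(~region, scales = "free_y") +
    ggplot2::labs(x = "Week of age", y = "MN density (cells per 10^6 px)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_weekly_z autoplot method for `sp_analysis` (z
#'   trajectories).
#' @param object An `sp_analysis` object.
#' @param ... Unused.
#' @export
autoplot.sp_analysis <- function(object, ...) plot_weekly_z(object)

#' Scatter plot of a density-behavior correlation
#'
#' @param object An `sp_correlation` object.
#' @param ... Unused.
#' @return A ggplot object with the fitted OLS line and the R^2 in the
#'   subtitle.
#' @export
autoplot.sp_correlation <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$density, y = .data$behavior)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = paste(object$x, "density (cells per 10^6 px)"),
                  y = object$y,
                  subtitle = sprintf("R^2 = %.3f (n = %d)",
                                     object$r_squared, object$n)) +
    ggplot2::theme_minimal()
}
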