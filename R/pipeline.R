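#' Write a cohort dataset to tidy CSV files
#'
#' Writes `sessions.csv`, `weights.csv`, `histology.csv` and a `config.json`
#' provenance echo into a directory.
#'
#' @param cohort An `sp_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort_tables <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sp_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$sessions, file.path(dir, "sessions.csv"))
  readr::write_csv(cohort$weights, file.path(dir, "weights.csv"))
  readr::write_csv(cohort$histology, file.path(dir, "histology.csv"))
  jsonlite::write_json(unclass(cohort$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load and validate cohort tables
#'
#' Reads `sessions.csv`, `weights.csv` and (if present) `histology.csv` from
#' a directory, checks schemas and row-level invariants, and returns a
#' validated `sp_cohort`. All offending rows are reported together, with row
#' numbers.
#'
#' @param dir Directory containing the CSV files, or a named list/character
#'   vector with paths `sessions`, `weights`, `histology`.
#' @return An `sp_cohort` (with `config = NULL` for loaded data).
#' @export
load_cohort_tables <- function(dir) {
  paths <- if (is.character(dir) && length(dir) == 1 && dir.exists(dir)) {
    list(sessions = file.path(dir, "sessions.csv"),
         weights = file.path(dir, "weights.csv"),
         histology = file.path(dir, "histology.csv"))
  } else {
    as.list(dir)
  }
  for (f in c("sessions", "weights")) {
    if (is.null(paths[[f]]) || !file.exists(paths[[f]])) {
      sp_validation_error(sprintf("input file for `%s` not found: %s",
                                  f, paths[[f]] %||% "<missing>"))
    }
  }
  sessions <- read_checked_csv(paths$sessions, "sessions.csv",
    required = c("animal_id", "genotype", "sex", "week", "session_index",
                 "time_pulling_s", "time_hindlimbs_s", "length_pulled_cm"))
  validate_sessions(sessions)
  weights <- read_checked_csv(paths$weights, "weights.csv",
    required = c("animal_id", "genotype", "sex", "week", "weight_g"))
  validate_weights(weights)
  histology <- NULL
  if (!is.null(paths$histology) && file.exists(paths$histology)) {
    histology <- read_checked_csv(paths$histology, "histology.csv",
      required = c("animal_id", "genotype", "week", "region", "slice_id",
                   "mn_count", "field_area_px"))
    validate_histology(histology)
  }
  structure(list(sessions = sessions, weights = weights,
                 histology = histology, config = NULL),
            class = "sp_cohort")
}

read_checked_csv <- function(path, label, required) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    sp_validation_error(sprintf("%s is missing column(s): %s", label,
                                paste(missing_cols, collapse = ", ")),
                        columns = missing_cols)
  }
  df
}

collect_row_errors <- function(label, checks) {
  msgs <- character(0)
  for (what in names(checks)) {
    rows <- which(checks[[what]])
    if (length(rows) > 0) {
      shown <- utils::head(rows, 10)
      msgs <- c(msgs, sprintf("%s (row%s %s%s)", what,
                              ifelse(length(rows) > 1, "s", ""),
                              paste(shown, collapse = ", "),
                              ifelse(length(rows) > 10, ", ...", "")))
    }
  }
  if (length(msgs) > 0) {
    sp_validation_error(paste0(label, ": ", paste(msgs, collapse = "; ")))
  }
  invisible(NULL)
}

validate_sessions <- function(df) {
  dup <- duplicated(df[, c("animal_id", "week", "session_index")])
  collect_row_errors("sessions.csv", list(
    "genotype not WT/SOD1" = !df$genotype %in% c("WT", "SOD1"),
    "sex not M/F" = !df$sex %in% c("M", "F"),
    "non-integer or missing week" = !is.finite(df$week) | df$week %% 1 != 0,
    "negative metric value" = df$time_pulling_s < 0 | df$time_hindlimbs_s < 0 |
      df$length_pulled_cm < 0,
    "time_hindlimbs_s exceeds time_pulling_s" =
      df$time_hindlimbs_s > df$time_pulling_s + 1e-9,
    "time_pulling_s exceeds 60 s" = df$time_pulling_s > 60 + 1e-9,
    "duplicate (animal_id, week, session_index)" = dup
  ))
}

validate_weights <- function(df) {
  dup <- duplicated(df[, c("animal_id", "week")])
  collect_row_errors("weights.csv", list(
    "genotype not WT/SOD1" = !df$genotype %in% c("WT", "SOD1"),
    "sex not M/F" = !df$sex %in% c("M", "F"),
    "non-integer or missing week" = !is.finite(df$week) | df$week %% 1 != 0,
    "nonpositive weight" = !is.finite(df$weight_g) | df$weight_g <= 0,
    "duplicate (animal_id, week)" = dup
  ))
}

validate_histology <- function(df) {
  collect_row_errors("histology.csv", list(
    "genotype not WT/SOD1" = !df$genotype %in% c("WT", "SOD1"),
    "region not M1/L5VH" = !df$region %in% c("M1", "L5VH"),
    "negative mn_count" = !is.finite(df$mn_count) | df$mn_count < 0,
    "nonpositive field_area_px" = !is.finite(df$field_area_px) | df$field_area_px <= 0,
    "duplicate slice_id within region" = duplicated(df[, c("slice_id", "region")])
  ))
}

#' Run the full string-pulling analysis
#'
#' Composes every stage on a cohort: weekly behavioral averages, group-level
#' z-threshold onset per metric, per-animal 20% onsets, weight onset against
#' the extrapolated counterfactual baseline, Sidak-adjusted weekly WT-SOD1
#' comparisons, per-animal motor-neuron densities with per-timepoint t tests,
#' and density-behavior correlations (M1 vs time pulling and time on
#' hindlimbs; L5VH vs time on hindlimbs). Deterministic: the same cohort
#' yields the same report.
#'
#' @param cohort An `sp_cohort` (simulated or loaded), or a directory path
#'   accepted by [load_cohort_tables()].
#' @param baseline_window Baseline weeks (default `9:11`).
#' @param z_threshold Group-level z threshold (default -0.5).
#' @param rel_threshold Animal-level fractional deviation (default 0.20).
#' @param alpha Significance level for adjusted p-values (default 0.05).
#' @param welch Welch tests for weekly behavioral comparisons (default
#'   `TRUE`) ; histology t tests use pooled variance unless
#'   `welch_histology = TRUE`.
#' @param welch_histology Welch for histology timepoint tests (default
#'   `FALSE`).
#' @param sustain Consecutive weeks required at threshold (default 1).
#' @param per_animal_correlation Also compute per-animal-point correlations
#'   (default `FALSE`).
#' @param baseline_sd Optional named numeric of explicit baseline SDs per
#'   metric (names among the three metrics and `"weight"`), e.g. for
#'   noise-free data.
#' @param exclude_animals Character vector of animal IDs to drop before
#'   analysis (the user-supplied exclusion list); exclusions are recorded in
#'   the report log.
#' @return An `sp_analysis` object: list of tibbles `weekly`, `onset_calls`,
#'   `animal_onset_calls`, `comparisons`, `weight` (projection/z),
#'   `densities`, `timepoint_tests`, `correlations`, plus `log` and
#'   `provenance`.
#' @export
#' @examples
#' report <- run_cohort_analysis(simulate_cohort(sim_config(seed = 11)))
#' report$onset_calls
run_cohort_analysis <- function(cohort,
                                baseline_window = 9:11,
                                z_threshold = -0.5,
                                rel_threshold = 0.20,
                                alpha = 0.05,
                                welch = TRUE,
                                welch_histology = FALSE,
                                sustain = 1,
                                per_animal_correlation = FALSE,
                                baseline_sd = NULL,
                                exclude_animals = character(0)) {
  if (is.character(cohort)) cohort <- load_cohort_tables(cohort)
  stopifnot(inherits(cohort, "sp_cohort"))
  log_lines <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      sp_abort(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
               class = "sp_error_stage", parent = e)
    })
  }

  sessions <- cohort$sessions
  weights <- cohort$weights
  if (length(exclude_animals) > 0) {
    sessions <- sessions %>% filter(!.data$animal_id %in% exclude_animals)
    weights <- weights %>% filter(!.data$animal_id %in% exclude_animals)
    log_lines <- c(log_lines, sprintf("excluded animal %s (user-supplied exclusion list)",
                                      exclude_animals))
  }

  weekly <- stage("weekly_metrics", weekly_metrics(sessions))

  bl_sd <- function(metric) {
    if (!is.null(baseline_sd) && metric %in% names(baseline_sd))
      unname(baseline_sd[[metric]]) else NULL
  }

  group_results <- stage("group_onset", purrr::map(
    setNames(sp_metrics(), sp_metrics()),
    ~ group_onset_analysis(weekly, .x, baseline_window = baseline_window,
                           threshold = z_threshold, sustain = sustain,
                           baseline_sd = bl_sd(.x))))

  weight_result <- stage("weight_onset", weight_onset_analysis(
    weights, baseline_window = baseline_window,
    reference_week = min(baseline_window), threshold = z_threshold,
    sustain = sustain, baseline_sd = bl_sd("weight")))

  onset_calls <- bind_rows(
    purrr::map(group_results, "onset") %>% bind_rows(),
    weight_result$onset)

  animal_calls <- stage("animal_onset", purrr::map(
    sp_metrics(),
    ~ animal_onsets(weekly, .x, baseline_window = baseline_window,
                    rel_threshold = rel_threshold, sustain = sustain)) %>%
      bind_rows())

  comparisons <- stage("weekly_comparison", weekly_group_comparison(
    weekly, alpha = alpha, welch = welch,
    after_week = max(baseline_window)))
  skipped <- attr(comparisons, "skipped")
  if (!is.null(skipped) && nrow(skipped) > 0) {
    log_lines <- c(log_lines, sprintf(
      "skipped comparison for %s week %s: fewer than 2 animals per group",
      skipped$metric, skipped$week))
  }

  densities <- timepoint_tests <- correlations <- NULL
  if (!is.null(cohort$histology) && nrow(cohort$histology) > 0) {
    densities <- stage("densities", animal_densities(cohort$histology))
    timepoint_tests <- stage("timepoint_tests",
                             density_timepoint_tests(densities,
                                                     welch = welch_histology))
    pairs <- list(
      list(region = "M1", metric = "time_pulling_s"),
      list(region = "M1", metric = "time_hindlimbs_s"),
      list(region = "L5VH", metric = "time_hindlimbs_s"))
    run_cor <- function(per_animal) {
      purrr::map(pairs, function(p) {
        tidy(density_behavior_correlation(
          densities, weekly, region = p$region, metric = p$metric,
          weeks = sort(unique(weekly$week)), per_animal = per_animal)) %>%
          mutate(per_animal = per_animal)
      }) %>% bind_rows()
    }
    correlations <- stage("correlations", run_cor(FALSE))
    if (per_animal_correlation) {
      correlations <- bind_rows(correlations, stage("correlations", run_cor(TRUE)))
    }
  }

  z_series <- bind_rows(
    purrr::imap(group_results,
                ~ mutate(.x$z, metric = .y, .before = 1)) %>% bind_rows(),
    mutate(weight_result$z, metric = "weight", .before = 1))

  params <- list(baseline_window = as.integer(baseline_window),
                 z_threshold = z_threshold, rel_threshold = rel_threshold,
                 alpha = alpha, welch = welch, welch_histology = welch_histology,
                 sustain = sustain)
  provenance <- list(
    seed = if (!is.null(cohort$config)) cohort$config$seed else NA_integer_,
    config_hash = rlang::hash(cohort$config %||% "external"),
    params = params,
    package_version = as.character(utils::packageVersion("stringpull")))

  structure(
    list(weekly = weekly, z_series = z_series, onset_calls = onset_calls,
         animal_onset_calls = animal_calls, comparisons = comparisons,
         weight = weight_result, densities = densities,
         timepoint_tests = timepoint_tests, correlations = correlations,
         log = log_lines, provenance = provenance),
    class = "sp_analysis")
}

#' Write an analysis report as a CSV bundle plus JSON summary
#'
#' Emits `weekly_metrics.csv`, `onset_calls.csv` (group and animal level),
#' `comparisons.csv`, `densities.csv`, `timepoint_tests.csv`,
#' `correlations.csv` and a single `summary.json` carrying the headline
#' numbers and provenance. Byte-identical for identical reports.
#'
#' @param report An `sp_analysis` from [run_cohort_analysis()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(report, dir) {
  stopifnot(inherits(report, "sp_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$weekly, file.path(dir, "weekly_metrics.csv"))
  readr::write_csv(bind_rows(report$onset_calls, report$animal_onset_calls),
                   file.path(dir, "onset_calls.csv"))
  readr::write_csv(report$comparisons, file.path(dir, "comparisons.csv"))
  if (!is.null(report$densities)) {
    readr::write_csv(report$densities, file.path(dir, "densities.csv"))
    readr::write_csv(report$timepoint_tests, file.path(dir, "timepoint_tests.csv"))
    readr::write_csv(report$correlations, file.path(dir, "correlations.csv"))
  }
  summary <- list(
    onset = purrr::pmap(report$onset_calls, function(metric, onset_week, ...) {
      list(metric = metric, onset_week = onset_week)
    }),
    animal_onset_weeks = split(report$animal_onset_calls$onset_week,
                               report$animal_onset_calls$metric),
    n_significant_weeks = if (!is.null(report$comparisons))
      sum(report$comparisons$significant) else NULL,
    correlations = if (!is.null(report$correlations))
      purrr::pmap(report$correlations[, c("density", "behavior", "r_squared")],
                  function(density, behavior, r_squared) {
                    list(region = density, metric = behavior, r_squared = r_squared)
                  }) else NULL,
    provenance = report$provenance)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(dir)
}
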