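#' Score one recording session from annotated pull events
#'
#' Computes the three session metrics from a table of manually annotated pull
#' events within a 60 s recording: time spent pulling (union of all event
#' intervals), time on hindlimbs (union of standing-posture intervals), and
#' total length of string pulled (sum of event displacements). Overlapping
#' events are merged by interval union for the time metrics — time is
#' occupancy — while displacements are cumulative and therefore summed.
#'
#' @param events Data frame with columns `start_s`, `end_s` (seconds within
#'   `[0, 60]`, `start_s < end_s`), `posture` (`"standing"` or `"seated"`)
#'   and `displacement_cm` (>= 0). May have zero rows.
#' @param session_length_s Length of the recording (default 60 s).
#' @return One-row tibble with `time_pulling_s`, `time_hindlimbs_s`,
#'   `length_pulled_cm`. Always satisfies
#'   `0 <= time_hindlimbs_s <= time_pulling_s <= session_length_s`.
#' @export
#' @examples
#' ev <- tibble::tibble(start_s = c(0, 20), end_s = c(10, 25),
#'                      posture = c("standing", "seated"),
#'                      displacement_cm = c(15, 5))
#' score_session(ev)
score_session <- function(events, session_length_s = 60) {
  events <- as_tibble(events)
  req <- c("start_s", "end_s", "posture", "displacement_cm")
  missing_cols <- setdiff(req, names(events))
  if (length(missing_cols) > 0) {
    sp_validation_error(sprintf("events table missing column(s): %s",
                                paste(missing_cols, collapse = ", ")))
  }
  if (nrow(events) == 0) {
    return(tibble(time_pulling_s = 0, time_hindlimbs_s = 0, length_pulled_cm = 0))
  }
  bad <- which(events$start_s < 0 | events$end_s > session_length_s |
                 events$start_s >= events$end_s | events$displacement_cm < 0 |
                 !events$posture %in% c("standing", "seated"))
  if (length(bad) > 0) {
    sp_validation_error(sprintf(
      "invalid pull event(s) at row(s) %s: need 0 <= start_s < end_s <= %s, displacement_cm >= 0, posture in {standing, seated}",
      paste(bad, collapse = ", "), session_length_s), rows = bad)
  }
  standing <- events$posture == "standing"
  tibble(
    time_pulling_s = interval_union_length(events$start_s, events$end_s),
    time_hindlimbs_s = interval_union_length(events$start_s[standing],
                                             events$end_s[standing]),
    length_pulled_cm = sum(events$displacement_cm)
  )
}

# total length covered by the union of real-valued intervals [start, end]:
# sweep in start order, each interval contributes what lies beyond the
# covered front (running max of previous ends)
interval_union_length <- function(start, end) {
  if (length(start) == 0) return(0)
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  front <- c(start[1], cummax(end)[-length(end)])
  sum(pmax(0, end - pmax(start, front)))
}

#' Score every session in an annotated event table
#'
#' Applies [score_session()] per `(animal_id, week, session_index)` group and
#' returns a session-level metrics table in the same shape the simulator
#' emits.
#'
#' @param events Data frame of pull events with identifying columns
#'   `animal_id, genotype, sex, week, session_index` plus the event columns
#'   of [score_session()].
#' @param session_length_s Length of each recording (default 60 s).
#' @return Tibble with one row per session: `animal_id, genotype, sex, week,
#'   session_index, time_pulling_s, time_hindlimbs_s, length_pulled_cm`.
#' @export
score_sessions <- function(events, session_length_s = 60) {
  events <- as_tibble(events)
  key <- c("animal_id", "genotype", "sex", "week", "session_index")
  missing_cols <- setdiff(key, names(events))
  if (length(missing_cols) > 0) {
    sp_validation_error(sprintf("events table missing column(s): %s",
                                paste(missing_cols, collapse = ", ")))
  }
  events %>%
    group_by(across(all_of(key))) %>%
    dplyr::group_modify(~ score_session(.x, session_length_s)) %>%
    ungroup()
}

#' Weekly average of a session metric for one animal
#'
#' Averages the available sessions of each week (two per week by design, but
#' a week with a single session uses that session alone). Weeks with no
#' sessions are absent from the result rather than imputed.
#'
#' @param sessions Session-metric rows for a single animal.
#' @param metric Metric column name.
#' @return Tibble `(week, value)` sorted by week.
#' @export
weekly_average <- function(sessions, metric) {
  sessions <- as_tibble(sessions)
  if (dplyr::n_distinct(sessions$animal_id) > 1) {
    sp_validation_error("weekly_average() expects sessions from a single animal")
  }
  if (!metric %in% names(sessions)) {
    sp_validation_error(sprintf("metric column `%s` not found", metric))
  }
  sessions %>%
    group_by(week = .data$week) %>%
    summarise(value = mean(.data[[metric]]), .groups = "drop") %>%
    arrange(.data$week)
}

#' Weekly metric averages for a whole cohort
#'
#' Long-format weekly averages for all animals and all three metrics; the
#' tidy equivalent of applying [weekly_average()] per animal and metric.
#'
#' @param sessions Session-metric table (as produced by [simulate_cohort()]
#'   or [score_sessions()]).
#' @return Tibble `(animal_id, genotype, sex, metric, week, value)`.
#' @export
weekly_metrics <- function(sessions) {
  sessions <- as_tibble(sessions)
  sessions %>%
    tidyr::pivot_longer(all_of(sp_metrics()), names_to = "metric",
                        values_to = "value") %>%
    group_by(.data$animal_id, .data$genotype, .data$sex, .data$metric,
             .data$week) %>%
    summarise(value = mean(.data$value), .groups = "drop") %>%
    arrange(.data$animal_id, .data$metric, .data$week)
}

#' Relative weight change to a reference week
#'
#' Weekly weights expressed as the signed fractional change relative to each
#' animal's own weight at the reference week:
#' `(weight_w - weight_ref) / weight_ref`. Reported as a fraction, not a
#' percentage.
#'
#' @param weights Weight table `(animal_id, genotype, sex, week, weight_g)`
#'   for one or more animals.
#' @param reference_week Week used as each animal's own reference (default 9).
#' @return Tibble `(animal_id, genotype, sex, week, rel_weight)`.
#' @export
#' @examples
#' w <- tibble::tibble(animal_id = "a", genotype = "WT", sex = "F",
#'                     week = 9:10, weight_g = c(20, 22))
#' relative_weight(w)
relative_weight <- function(weights, reference_week = 9) {
  weights <- as_tibble(weights)
  ref <- weights %>%
    filter(.data$week == reference_week) %>%
    select("animal_id", ref_weight = "weight_g")
  missing_ref <- setdiff(unique(weights$animal_id), ref$animal_id)
  if (length(missing_ref) > 0) {
    sp_validation_error(sprintf(
      "reference week %s missing for animal(s): %s", reference_week,
      paste(missing_ref, collapse = ", ")))
  }
  if (any(ref$ref_weight <= 0)) {
    sp_validation_error(sprintf(
      "nonpositive reference weight for animal(s): %s",
      paste(ref$animal_id[ref$ref_weight <= 0], collapse = ", ")))
  }
  weights %>%
    left_join(ref, by = "animal_id") %>%
    mutate(rel_weight = (.data$weight_g - .data$ref_weight) / .data$ref_weight) %>%
    select("animal_id", "genotype", "sex", "week", "rel_weight")
}
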