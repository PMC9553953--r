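#' Baseline of a weekly series over a reference window
#'
#' Pools all per-animal weekly values falling inside the baseline window
#' (weeks 9--11 by default) and returns their arithmetic mean and sample SD
#' (n - 1 denominator). The pool may come from one animal (animal-scope
#' baseline for the 20% rule) or from all animals of a group (group-scope
#' baseline for the z rule).
#'
#' @param series Data frame with columns `week` and `value` (one row per
#'   animal-week for group scope).
#' @param window Integer vector of baseline weeks (default `9:11`).
#' @param scope `"group"` or `"animal"`; recorded in the result.
#' @return An `sp_baseline` list with `window`, `mean`, `sd` (`NA` when the
#'   pool has a single value), `n` and `scope`.
#' @export
#' @examples
#' compute_baseline(tibble::tibble(week = c(9, 10, 11), value = c(8, 10, 12)))
compute_baseline <- function(series, window = 9:11, scope = c("group", "animal")) {
  scope <- match.arg(scope)
  series <- as_tibble(series)
  pool <- series$value[series$week %in% window]
  pool <- pool[!is.na(pool)]
  if (length(pool) == 0) {
    sp_validation_error(sprintf(
      "no values inside the baseline window (weeks %s-%s)",
      min(window), max(window)))
  }
  structure(
    list(window = as.integer(window), mean = mean(pool),
         sd = if (length(pool) >= 2) sd(pool) else NA_real_,
         n = length(pool), scope = scope),
    class = "sp_baseline")
}

#' @export
print.sp_baseline <- function(x, ...) {
  cat(sprintf("<sp_baseline> %s scope, weeks %d-%d: mean %.4g, sd %s (n = %d)\n",
              x$scope, min(x$window), max(x$window), x$mean,
              ifelse(is.na(x$sd), "undefined", sprintf("%.4g", x$sd)), x$n))
  invisible(x)
}

#' Deviation (z score) of a weekly series from its baseline
#'
#' Standardizes each weekly value against the baseline window mean and SD:
#' `z(w) = (x(w) - mean) / sd`. Defined only for a non-degenerate baseline
#' (`sd > 0`).
#'
#' @param series Data frame with columns `week` and `value` (typically the
#'   weekly group means after the baseline window).
#' @param baseline An [compute_baseline()] result, or a list with `mean` and
#'   `sd`.
#' @return Tibble `(week, value, z)` sorted by week.
#' @export
zscore_series <- function(series, baseline) {
  if (is.na(baseline$sd) || baseline$sd <= 0) {
    sp_abort("degenerate baseline: sd is zero or undefined, z scores are not defined",
             class = "sp_error_degenerate")
  }
  as_tibble(series) %>%
    mutate(z = (.data$value - baseline$mean) / baseline$sd) %>%
    arrange(.data$week)
}

#' Group-level onset by baseline z-score threshold
#'
#' Earliest week at which the group-mean z score crosses the threshold
#' (`z <= threshold` for decline metrics; the crossing is inclusive and a
#' single crossing suffices unless `sustain > 1`). Weeks at or before the end
#' of the baseline window are never called as onsets.
#'
#' @param z Tibble with columns `week` and `z` (from [zscore_series()]).
#' @param threshold z threshold, default -0.5 (equivalent to a 20% deviation
#'   when the baseline SD is 40% of the baseline mean).
#' @param direction `"decline"` (threshold applied from below) or
#'   `"increase"`.
#' @param after_week Onsets must fall strictly after this week (default 11,
#'   the end of the baseline window).
#' @param sustain Number of consecutive observed weeks that must sit at or
#'   beyond the threshold (default 1; the first week of the run is the onset).
#' @param metric Optional metric label carried into the result.
#' @return One-row tibble `(level, metric, rule, onset_week, threshold,
#'   sustain)`; `onset_week` is `NA` when the threshold is never crossed.
#' @export
#' @examples
#' z <- tibble::tibble(week = 12:14, z = c(-0.2, -0.6, -1.1))
#' detect_group_onset(z)
detect_group_onset <- function(z, threshold = -0.5, direction = c("decline", "increase"),
                               after_week = 11, sustain = 1, metric = NA_character_) {
  direction <- match.arg(direction)
  z <- as_tibble(z)
  if (nrow(z) == 0) {
    sp_validation_error("empty z series: nothing to detect an onset in")
  }
  z <- z %>% filter(.data$week > after_week) %>% arrange(.data$week)
  crossed <- if (direction == "decline") z$z <= threshold else z$z >= threshold
  onset <- first_sustained(z$week, crossed, sustain)
  tibble(level = "group", metric = metric, rule = "z_threshold",
         onset_week = onset, threshold = threshold, sustain = as.integer(sustain))
}

#' Animal-level onset by 20% deviation from own baseline
#'
#' Earliest week at which an animal's weekly value deviates by at least
#' `rel_threshold` (default 20%) below its own baseline-window mean:
#' `(x(w) - mean) / mean <= -rel_threshold`, inclusive at the boundary.
#'
#' @param series Tibble `(week, value)` of one animal's weekly averages.
#' @param animal_baseline The animal's own [compute_baseline()] result
#'   (`mean` must be positive).
#' @param rel_threshold Fractional deviation defining onset (default 0.20).
#' @inheritParams detect_group_onset
#' @param animal_id Optional animal label carried into the result.
#' @return One-row tibble `(level, animal_id, metric, rule, onset_week,
#'   threshold, sustain)`.
#' @export
detect_animal_onset <- function(series, animal_baseline, rel_threshold = 0.20,
                                after_week = 11, sustain = 1,
                                metric = NA_character_, animal_id = NA_character_) {
  if (!is.finite(animal_baseline$mean) || animal_baseline$mean <= 0) {
    sp_validation_error("animal baseline mean must be positive for the relative-deviation rule")
  }
  series <- as_tibble(series) %>% filter(.data$week > after_week) %>% arrange(.data$week)
  rel_dev <- (series$value - animal_baseline$mean) / animal_baseline$mean
  onset <- first_sustained(series$week, rel_dev <= -rel_threshold, sustain)
  tibble(level = "animal", animal_id = animal_id, metric = metric,
         rule = "relative_20pct", onset_week = onset,
         threshold = rel_threshold, sustain = as.integer(sustain))
}

# week of the first run of >= sustain consecutive TRUE observations
first_sustained <- function(weeks, crossed, sustain = 1) {
  if (length(weeks) == 0 || !any(crossed)) return(NA_integer_)
  if (sustain <= 1) return(as.integer(weeks[which(crossed)[1]]))
  r <- rle(crossed)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= sustain)
  if (length(hit) == 0) return(NA_integer_)
  as.integer(weeks[ends[hit[1]] - r$lengths[hit[1]] + 1])
}

#' Extrapolated counterfactual weight baseline
#'
#' Projects the weight trajectory the SOD1 group would have followed had it
#' grown like its non-transgenic littermates: an ordinary least-squares line
#' is fitted to the WT weekly mean series, then re-anchored so it passes
#' through the SOD1 baseline mean at the midpoint of the baseline window
#' (week 10 for the 9--11 window).
#'
#' @param wt_weekly_means Tibble `(week, value)` of WT weekly group means
#'   (relative weights or absolute weights).
#' @param sod1_baseline [compute_baseline()] result for the SOD1 group over
#'   the baseline window (its `mean` anchors the projection).
#' @param end_week Last projected week (default 18).
#' @param anchor_week Week at which the projection equals the SOD1 baseline
#'   mean (default 10, the midpoint of the 9--11 window).
#' @return Tibble `(week, projected)` over the WT weeks extended to
#'   `end_week`, with attributes `slope` and `anchor`.
#' @export
extrapolate_weight_baseline <- function(wt_weekly_means, sod1_baseline,
                                        end_week = 18, anchor_week = 10) {
  wt <- as_tibble(wt_weekly_means) %>% arrange(.data$week)
  if (nrow(wt) < 2) {
    sp_validation_error("need WT means for at least 2 weeks to fit a growth trend")
  }
  slope <- unname(coef(lm(value ~ week, data = wt))[["week"]])
  weeks <- seq(min(wt$week), max(max(wt$week), end_week))
  out <- tibble(week = as.integer(weeks),
                projected = sod1_baseline$mean + slope * (weeks - anchor_week))
  attr(out, "slope") <- slope
  attr(out, "anchor") <- c(week = anchor_week, value = sod1_baseline$mean)
  out
}

#' Sidak familywise adjustment
#'
#' Adjusts a raw p-value for a family of `m` comparisons:
#' `p_adj = 1 - (1 - p)^m`, capped at 1. Always at least the raw p-value and
#' monotone in both `p` and `m`.
#'
#' @param p Raw p-value(s) in `[0, 1]`.
#' @param m Family size (>= 1).
#' @return Adjusted p-value(s).
#' @export
#' @examples
#' sidak_adjust(0.01, 10)
sidak_adjust <- function(p, m) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    sp_validation_error("p must lie in [0, 1]")
  }
  if (!is.numeric(m) || length(m) != 1 || !is.finite(m) || m < 1) {
    sp_validation_error("family size m must be a single number >= 1")
  }
  # clamp into [p, 1]: mathematically 1 - (1-p)^m always lies there, but the
  # expm1/log1p round-trip can land one ulp below p when m = 1
  pmin(1, pmax(p, -expm1(m * log1p(-p))))
}

#' Weekly WT vs SOD1 comparisons with Sidak correction
#'
#' Two-sided two-sample comparison of the per-animal weekly values at each
#' post-baseline week, for each metric present, with a Sidak familywise
#' adjustment over the weeks tested for that metric. Welch's unequal-variance
#' t test is the default; set `welch = FALSE` for the pooled-variance test.
#' Weeks with fewer than 2 animals in either group are skipped and listed in
#' the `skipped` attribute.
#'
#' @param weekly Long weekly table `(animal_id, genotype, metric, week,
#'   value)` as from [weekly_metrics()].
#' @param alpha Significance level applied to adjusted p-values (default 0.05).
#' @param welch Use Welch's t test (default `TRUE`).
#' @param after_week Test only weeks strictly after this week (default 11);
#'   `-Inf` tests every week.
#' @return Tibble `(metric, week, n_wt, n_sod1, mean_wt, mean_sod1, t, df,
#'   raw_p, adj_p, significant)`, one row per metric-week tested.
#' @export
weekly_group_comparison <- function(weekly, alpha = 0.05, welch = TRUE,
                                    after_week = 11) {
  weekly <- as_tibble(weekly) %>% filter(.data$week > after_week)
  one_week <- function(df) {
    wt <- df$value[df$genotype == "WT"]
    tg <- df$value[df$genotype == "SOD1"]
    if (length(wt) < 2 || length(tg) < 2) {
      return(tibble(n_wt = length(wt), n_sod1 = length(tg),
                    mean_wt = mean(wt), mean_sod1 = mean(tg),
                    t = NA_real_, df = NA_real_, raw_p = NA_real_))
    }
    if (sd(wt) == 0 && sd(tg) == 0) {
      # degenerate zero-variance groups: identical means give the null
      # identity (t = 0, p = 1); distinct means an infinite separation
      same <- mean(wt) == mean(tg)
      return(tibble(n_wt = length(wt), n_sod1 = length(tg),
                    mean_wt = mean(wt), mean_sod1 = mean(tg),
                    t = ifelse(same, 0, sign(mean(wt) - mean(tg)) * Inf),
                    df = length(wt) + length(tg) - 2,
                    raw_p = ifelse(same, 1, 0)))
    }
    tt <- t.test(wt, tg, var.equal = !welch)
    tibble(n_wt = length(wt), n_sod1 = length(tg),
           mean_wt = mean(wt), mean_sod1 = mean(tg),
           t = unname(tt$statistic), df = unname(tt$parameter),
           raw_p = tt$p.value)
  }
  res <- weekly %>%
    group_by(.data$metric, .data$week) %>%
    dplyr::group_modify(~ one_week(.x)) %>%
    ungroup()
  skipped <- res %>% filter(is.na(.data$raw_p))
  res <- res %>%
    filter(!is.na(.data$raw_p)) %>%
    group_by(.data$metric) %>%
    mutate(adj_p = sidak_adjust(.data$raw_p, m = dplyr::n()),
           significant = .data$adj_p < alpha) %>%
    ungroup()
  attr(res, "skipped") <- skipped
  attr(res, "alpha") <- alpha
  res
}
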