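test_that("compute_baseline pools window values for mean and sample SD", {
  b <- compute_baseline(tibble(week = c(9, 10, 11), value = c(8, 10, 12)))
  expect_equal(b$mean, 10)
  expect_equal(b$sd, 2) # textbook n-1 sample SD
  b0 <- compute_baseline(tibble(week = c(9, 10, 11), value = c(10, 10, 10)))
  expect_equal(b0$mean, 10)
  expect_equal(b0$sd, 0)
  expect_error(compute_baseline(tibble(week = 12, value = 5)),
               class = "sp_error_validation")
  single <- compute_baseline(tibble(week = 9, value = 7))
  expect_equal(single$mean, 7)
  expect_true(is.na(single$sd)) # sd undefined, flagged as NA
})

test_that("z scores standardize against the baseline and reject sd = 0", {
  b <- list(mean = 10, sd = 2)
  z <- zscore_series(tibble(week = 12:13, value = c(10, 9)), b)
  expect_equal(z$z, c(0, -0.5))
  expect_error(zscore_series(tibble(week = 12, value = 9), list(mean = 10, sd = 0)),
               class = "sp_error_degenerate")
})

test_that("group onset is the first inclusive crossing after the baseline window", {
  z <- tibble(week = 12:14, z = c(-0.2, -0.6, -1.1))
  expect_equal(detect_group_onset(z)$onset_week, 13L)
  expect_true(is.na(detect_group_onset(tibble(week = 12:14, z = c(-0.1, -0.4, -0.45)))$onset_week))
  # boundary is inclusive
  expect_equal(detect_group_onset(tibble(week = 13, z = -0.5))$onset_week, 13L)
  # weeks inside the baseline window are never onsets
  expect_equal(detect_group_onset(tibble(week = 10:13, z = c(-2, -2, -0.1, -0.7)))$onset_week, 13L)
  expect_error(detect_group_onset(tibble(week = integer(0), z = numeric(0))),
               class = "sp_error_validation")
})

test_that("group onset is monotone: pointwise-lower z never yields a later onset", {
  set.seed(31)
  for (i in 1:25) {
    z1 <- tibble(week = 12:18, z = rnorm(7, -0.3, 0.5))
    z2 <- mutate(z1, z = z - runif(7, 0, 1))
    o1 <- detect_group_onset(z1)$onset_week
    o2 <- detect_group_onset(z2)$onset_week
    if (!is.na(o1)) expect_lte(o2, o1)
  }
})

test_that("sustain requires consecutive threshold weeks", {
  z <- tibble(week = 12:16, z = c(-0.6, -0.3, -0.7, -0.8, -0.9))
  expect_equal(detect_group_onset(z, sustain = 1)$onset_week, 12L)
  expect_equal(detect_group_onset(z, sustain = 2)$onset_week, 14L)
  expect_true(is.na(detect_group_onset(z, sustain = 4)$onset_week))
})

test_that("animal onset applies the inclusive 20% own-baseline rule", {
  bl <- list(mean = 100)
  s <- tibble(week = 12:14, value = c(85, 79, 70))
  expect_equal(detect_animal_onset(s, bl)$onset_week, 13L) # first value <= 80
  expect_true(is.na(detect_animal_onset(tibble(week = 12:14, value = c(85, 81, 82)), bl)$onset_week))
  expect_equal(detect_animal_onset(tibble(week = 13, value = 80), bl)$onset_week, 13L)
  expect_error(detect_animal_onset(s, list(mean = 0)), class = "sp_error_validation")
})

test_that("the z rule and the 20% rule coincide when sd = 0.4 * mean", {
  # algebraic identity: (x - m)/(0.4 m) <= -0.5  <=>  (x - m)/m <= -0.2
  set.seed(12)
  for (i in 1:20) {
    m <- runif(1, 10, 50)
    series <- tibble(week = 12:18, value = m * runif(7, 0.6, 1.1))
    z <- zscore_series(series, list(mean = m, sd = 0.4 * m))
    o_z <- detect_group_onset(z)$onset_week
    o_rel <- detect_animal_onset(series, list(mean = m))$onset_week
    expect_identical(o_z, o_rel)
  }
})

test_that("weight extrapolation anchors the WT OLS trend at the SOD1 baseline", {
  # exactly linear WT means, slope 0.02/week; anchored at week 10 -> 1.01 + 0.02*8
  wt <- tibble(week = 9:18, value = 0.99 + 0.02 * (9:18 - 9))
  proj <- extrapolate_weight_baseline(wt, list(mean = 1.01), end_week = 18,
                                      anchor_week = 10)
  expect_equal(attr(proj, "slope"), 0.02)
  expect_equal(proj$projected[proj$week == 18], 1.01 + 0.02 * 8)
  # flat WT trend projects the constant baseline mean
  flat <- extrapolate_weight_baseline(tibble(week = 9:18, value = 1),
                                      list(mean = 1.05))
  expect_equal(flat$projected, rep(1.05, nrow(flat)))
  expect_error(extrapolate_weight_baseline(tibble(week = 9, value = 1),
                                           list(mean = 1)),
               class = "sp_error_validation")
})

test_that("the fitted WT slope equals the closed-form normal-equation solution", {
  set.seed(4)
  wk <- 9:18
  y <- 1 + 0.015 * wk + rnorm(10, 0, 0.01)
  slope_oracle <- sum((wk - mean(wk)) * (y - mean(y))) / sum((wk - mean(wk))^2)
  proj <- extrapolate_weight_baseline(tibble(week = wk, value = y),
                                      list(mean = 1.1))
  expect_equal(attr(proj, "slope"), slope_oracle, tolerance = 1e-12)
})

test_that("Sidak adjustment matches its closed form and properties", {
  expect_equal(sidak_adjust(0.05, 1), 0.05)
  expect_equal(sidak_adjust(0, 10), 0)
  expect_equal(sidak_adjust(0.01, 10), 1 - 0.99^10, tolerance = 1e-12)
  expect_equal(sidak_adjust(1, 3), 1)
  expect_error(sidak_adjust(1.2, 3), class = "sp_error_validation")
  expect_error(sidak_adjust(0.5, 0), class = "sp_error_validation")
  # p_adj >= p, monotone in p and in m
  set.seed(2)
  p <- runif(50)
  expect_true(all(sidak_adjust(p, 5) >= p))
  expect_true(all(diff(sidak_adjust(sort(p), 5)) >= 0))
  for (pp in c(0.001, 0.05, 0.4)) {
    adj <- vapply(1:10, function(m) sidak_adjust(pp, m), numeric(1))
    expect_true(all(diff(adj) >= 0))
  }
})

test_that("weekly group comparison reproduces the hand-evaluated Welch/Sidak numbers", {
  mk <- function(vals, genotype) {
    tibble(animal_id = paste0(genotype, seq_along(vals)), genotype = genotype,
           sex = "F", metric = "time_pulling_s", week = 12, value = vals)
  }
  weekly <- bind_rows(mk(c(4, 5, 6), "WT"), mk(c(1, 2, 3), "SOD1"))
  res <- weekly_group_comparison(weekly)
  # equal group variances: Welch t equals the pooled two-sample t here
  expect_equal(res$t, 3.674, tolerance = 1e-3)
  expect_equal(res$df, 4, tolerance = 1e-6)
  expect_equal(res$raw_p, 0.0213, tolerance = 1e-2)
  expect_equal(sidak_adjust(res$raw_p, 7), 1 - (1 - res$raw_p)^7)
  expect_equal(sidak_adjust(0.0213, 7), 0.1399, tolerance = 1e-3)
})

test_that("identical groups give t = 0, p = 1, and small groups are skipped", {
  mk <- function(vals, genotype, week) {
    tibble(animal_id = paste0(genotype, week, seq_along(vals)),
           genotype = genotype, sex = "F", metric = "m", week = week,
           value = vals)
  }
  weekly <- bind_rows(mk(c(5, 5, 5), "WT", 12), mk(c(5, 5, 5), "SOD1", 12),
                      mk(7, "WT", 13), mk(c(5, 6), "SOD1", 13))
  res <- weekly_group_comparison(weekly)
  expect_equal(res$t, 0)
  expect_equal(res$raw_p, 1)
  expect_equal(res$adj_p, 1)
  skipped <- attr(res, "skipped")
  expect_equal(skipped$week, 13)
})

test_that("sidak family size is the number of post-baseline weeks tested", {
  set.seed(9)
  weekly <- weekly_metrics(simulate_cohort(small_config(seed = 9))$sessions)
  res <- weekly_group_comparison(weekly)
  per_metric <- count(res, metric)
  expect_true(all(per_metric$n == 7)) # weeks 12..18
  expect_equal(res$adj_p, sidak_adjust(res$raw_p, 7), tolerance = 1e-12)
})
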