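test_that("motor-neuron classification applies the region-specific rules", {
  l5 <- tibble(region = "L5VH", marker = "NeuN", size_um2 = c(300, 251, 250, 100))
  expect_equal(classify_motoneurons(l5, "L5VH"), 2) # strict > 250
  m1 <- tibble(region = "M1", marker = c("CTIP2", "CTIP2", "CTIP2", "NeuN", "NeuN"),
               size_um2 = c(100, 400, 50, 500, 600))
  expect_equal(classify_motoneurons(m1, "M1"), 3) # marker gate, no size filter
  expect_equal(classify_motoneurons(l5[0, ], "L5VH"), 0L)
  mixed <- bind_rows(l5, m1)
  expect_error(classify_motoneurons(mixed, "L5VH"), class = "sp_error_validation")
})

test_that("classification is permutation-invariant and monotone", {
  set.seed(14)
  obj <- tibble(region = "L5VH",
                marker = sample(c("NeuN", "CTIP2"), 30, replace = TRUE),
                size_um2 = runif(30, 100, 500))
  n0 <- classify_motoneurons(obj, "L5VH")
  expect_equal(classify_motoneurons(obj[sample(30), ], "L5VH"), n0)
  plus <- bind_rows(obj, tibble(region = "L5VH", marker = "NeuN", size_um2 = 300))
  expect_equal(classify_motoneurons(plus, "L5VH"), n0 + 1)
})

test_that("density normalization follows the printed field formula", {
  expect_equal(normalize_density(0), 0)
  expect_equal(normalize_density(10), 9.5367, tolerance = 1e-4)
  expect_equal(normalize_density(1048576), 1e6) # scale identity
  # linear in count, inverse-linear in area
  expect_equal(normalize_density(20), 2 * normalize_density(10))
  expect_equal(normalize_density(10, 2 * 1048576), normalize_density(10) / 2)
  expect_error(normalize_density(10, 0), class = "sp_error_validation")
  expect_error(normalize_density(-1), class = "sp_error_validation")
})

test_that("per-animal aggregation averages slice densities", {
  sl <- tibble(animal_id = "a1", genotype = "SOD1", week = 15, region = "M1",
               slice_id = c("s1", "s2", "s3"),
               mn_count = c(8, 10, 12) / 1e6 * 1048576, field_area_px = 1048576)
  agg <- aggregate_animal(sl)
  expect_equal(agg$density, 10)
  expect_equal(agg$n_slices, 3)
  expect_equal(aggregate_animal(sl[1, ])$density, 8)
  mixed <- mutate(sl, animal_id = c("a1", "a1", "a2"))
  expect_error(aggregate_animal(mixed), class = "sp_error_validation")
  expect_error(aggregate_animal(sl[0, ]), class = "sp_error_validation")
  # tidy wrapper agrees with the single-animal op
  expect_equal(animal_densities(sl)$density, 10)
})

test_that("timepoint test reproduces the hand-evaluated pooled t", {
  res <- timepoint_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(res$t, 3.674, tolerance = 1e-3)
  expect_equal(res$df, 4)
  expect_equal(res$p, 0.0213, tolerance = 1e-2)
  same <- timepoint_test(c(5, 5), c(5, 5))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(timepoint_test(4, c(1, 2)), class = "sp_error_validation")
})

test_that("correlate_decline reproduces the hand-evaluated Pearson numbers", {
  d <- tibble(density = c(1, 2, 3), behavior = c(2, 4, 5))
  res <- correlate_decline(d)
  expect_equal(res$r, 0.9820, tolerance = 1e-4)
  expect_equal(res$r_squared, 0.9643, tolerance = 1e-4)
  expect_equal(res$r_squared, res$r^2)
  expect_equal(res$slope, 1.5) # OLS of behavior on density
  perfect <- correlate_decline(tibble(density = 1:4, behavior = 2 * (1:4) + 1))
  expect_equal(perfect$r_squared, 1)
  expect_error(correlate_decline(tibble(density = c(1, 1, 1), behavior = 1:3)),
               class = "sp_error_degenerate")
  expect_error(correlate_decline(d[1:2, ]), class = "sp_error_validation")
})

test_that("r-squared is invariant to affine rescaling of either axis", {
  set.seed(21)
  d <- tibble(density = rnorm(6, 10), behavior = rnorm(6, 20))
  base <- correlate_decline(d)$r_squared
  expect_equal(correlate_decline(mutate(d, density = 3 * density - 7))$r_squared, base)
  expect_equal(correlate_decline(mutate(d, behavior = -0.5 * behavior + 2))$r_squared, base)
})

test_that("noiseless coupling gives exactly r^2 = 1 at the matched timepoints", {
  cfg <- noiseless_histology_config(seed = 6)
  co <- simulate_cohort(cfg)
  wk <- weekly_metrics(co$sessions)
  dens <- animal_densities(co$histology)
  for (p in list(c("M1", "time_pulling_s"), c("L5VH", "time_hindlimbs_s"))) {
    res <- density_behavior_correlation(dens, wk, p[1], p[2])
    expect_equal(res$r_squared, 1)
    expect_equal(res$n, 4)
  }
})

test_that("tidy and glance expose the correlation fields", {
  res <- correlate_decline(tibble(density = c(1, 2, 3), behavior = c(2, 4, 5)),
                           density_label = "M1", behavior_label = "time_pulling_s")
  td <- generics::tidy(res)
  expect_equal(td$density, "M1")
  expect_equal(td$r_squared, res$r_squared)
  expect_identical(generics::glance(res), td)
})
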