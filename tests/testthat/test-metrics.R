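test_that("score_session computes the three metrics from annotated events", {
  ev <- tibble::tibble(start_s = c(0, 20), end_s = c(10, 25),
                       posture = c("standing", "seated"),
                       displacement_cm = c(15, 5))
  s <- score_session(ev)
  expect_equal(s$time_pulling_s, 15)
  expect_equal(s$time_hindlimbs_s, 10)
  expect_equal(s$length_pulled_cm, 20)

  empty <- score_session(ev[0, ])
  expect_equal(unlist(empty), c(time_pulling_s = 0, time_hindlimbs_s = 0,
                                length_pulled_cm = 0))
})

test_that("overlapping events are merged by interval union, displacements summed", {
  ev <- tibble::tibble(start_s = c(0, 5), end_s = c(10, 15),
                       posture = c("standing", "seated"),
                       displacement_cm = c(10, 10))
  s <- score_session(ev)
  expect_equal(s$time_pulling_s, 15) # union of [0,10] and [5,15]
  expect_equal(s$time_hindlimbs_s, 10)
  expect_equal(s$length_pulled_cm, 20)
  # nested and duplicated intervals collapse too
  ev2 <- tibble::tibble(start_s = c(0, 2, 0), end_s = c(10, 5, 10),
                        posture = "standing", displacement_cm = 1)
  expect_equal(score_session(ev2)$time_pulling_s, 10)
})

test_that("score_session matches the 1-ms discretization oracle on random events", {
  set.seed(101)
  for (i in 1:50) {
    ev <- random_events()
    got <- score_session(ev)
    want <- oracle_score_session(ev)
    expect_equal(got$time_pulling_s, want$time_pulling_s, tolerance = 1e-9)
    expect_equal(got$time_hindlimbs_s, want$time_hindlimbs_s, tolerance = 1e-9)
    expect_equal(got$length_pulled_cm, want$length_pulled_cm)
  }
})

test_that("score_session is invariant to event order and to splitting events", {
  set.seed(7)
  ev <- random_events()
  shuffled <- ev[sample(nrow(ev)), ]
  expect_equal(score_session(ev), score_session(shuffled))
  # split a single event into contiguous pieces (displacement split as well)
  one <- tibble::tibble(start_s = 10, end_s = 20, posture = "standing",
                        displacement_cm = 8)
  parts <- tibble::tibble(start_s = c(10, 14), end_s = c(14, 20),
                          posture = "standing", displacement_cm = c(3, 5))
  expect_equal(score_session(one), score_session(parts))
})

test_that("invalid events are rejected with the offending rows identified", {
  bad <- tibble::tibble(start_s = c(0, 30), end_s = c(10, 25),
                        posture = "standing", displacement_cm = 1)
  err <- tryCatch(score_session(bad), error = identity)
  expect_s3_class(err, "sp_error_validation")
  expect_match(conditionMessage(err), "2")
  expect_error(score_session(tibble::tibble(start_s = -1, end_s = 5,
                                            posture = "seated",
                                            displacement_cm = 1)),
               class = "sp_error_validation")
  expect_error(score_session(tibble::tibble(start_s = 0, end_s = 61,
                                            posture = "seated",
                                            displacement_cm = 1)),
               class = "sp_error_validation")
  expect_error(score_session(dplyr::select(bad, -posture)),
               class = "sp_error_validation")
})

test_that("weekly_average averages available sessions and drops empty weeks", {
  s <- tibble::tibble(animal_id = "a", week = c(9, 9, 10), value = c(10, 12, 7))
  names(s)[3] <- "time_pulling_s"
  wa <- weekly_average(s, "time_pulling_s")
  expect_equal(wa$value[wa$week == 9], 11)
  expect_equal(wa$value[wa$week == 10], 7) # single-session week is used as-is
  expect_false(11 %in% wa$week) # absent week stays absent
  # idempotent on already-averaged single values
  expect_equal(weekly_average(s[3, ], "time_pulling_s")$value, 7)
})

test_that("relative weight is the signed fraction against the reference week", {
  w <- tibble::tibble(animal_id = "a", genotype = "SOD1", sex = "M",
                      week = c(9, 10, 11), weight_g = c(20, 22, 16))
  rw <- relative_weight(w)
  expect_equal(rw$rel_weight, c(0, 0.10, -0.20))
  expect_error(relative_weight(dplyr::filter(w, week > 9)),
               class = "sp_error_validation")
  w$weight_g[1] <- 0
  err <- tryCatch(relative_weight(w), error = identity)
  expect_s3_class(err, "sp_error_validation")
  expect_match(conditionMessage(err), "a")
})

test_that("score_sessions and weekly_metrics agree with per-animal computation", {
  ev <- tidyr::expand_grid(animal_id = c("x", "y"), week = 9:10,
                           session_index = 1:2) %>%
    dplyr::mutate(genotype = "WT", sex = "F")
  ev <- tidyr::expand_grid(ev, tibble::tibble(start_s = c(0, 30), end_s = c(10, 40),
                                              posture = c("standing", "seated"),
                                              displacement_cm = c(5, 5)))
  scored <- score_sessions(ev)
  expect_equal(nrow(scored), 8)
  expect_true(all(scored$time_pulling_s == 20))
  wk <- weekly_metrics(scored)
  expect_equal(nrow(wk), 2 * 2 * 3)
  expect_true(all(wk$value[wk$metric == "time_hindlimbs_s"] == 10))
})
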