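test_that("flag_series flags exactly the qualifying adjacent pairs", {
  s <- scr_series("A", c(0, 3, 10), c(100, 150, 150))
  fl <- flag_series(s)
  expect_equal(nrow(fl), 1L)
  expect_equal(fl$flag_time, 3)
  expect_identical(fl$stage, 1L)
  expect_equal(fl$rc, 0.5)
  # exhaustive-pair enumeration oracle on random series
  set.seed(99)
  for (i in 1:50) {
    n <- sample(2:20, 1)
    ser <- scr_series("R", sort(runif(n, 0, 400)), runif(n, 50, 500))
    fl <- flag_series(ser)
    want <- 0L
    for (j in 2:n) {
      if (oracle_classify(ser$scr[j - 1], ser$scr[j]) > 0) want <- want + 1L
    }
    expect_equal(nrow(fl), want)
    if (nrow(fl)) {
      expect_identical(fl$stage,
                       vapply(seq_len(nrow(fl)), function(k) {
                         oracle_classify(ser$scr[fl$s_index[k]],
                                         ser$scr[fl$t_index[k]])
                       }, integer(1)))
    }
  }
})

test_that("monotone-decreasing and single-measurement series never flag", {
  expect_equal(nrow(flag_series(scr_series("A", 0:5, seq(300, 200, length.out = 6)))), 0L)
  expect_equal(nrow(flag_series(scr_series("A", 0, 100))), 0L)
})

test_that("flag_series refuses series with dialysis values still present", {
  s <- scr_series("A", 0:2, c(100, 160, 100), on_dialysis = c(FALSE, TRUE, FALSE))
  expect_error(flag_series(s), "exclude_dialysis_values")
})

test_that("dialysis exclusion preserves order and conserves counts", {
  s <- scr_series("A", 0:5, c(100, 150, 120, 180, 130, 140),
                  on_dialysis = c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE))
  out <- exclude_dialysis_values(s)
  expect_equal(length(out), 4L)
  expect_equal(out$times, c(0, 2, 4, 5))
  expect_true(all(diff(out$times) > 0))
  # all flagged -> empty; none flagged -> identity
  allfl <- scr_series("A", 0:1, c(100, 160), on_dialysis = c(TRUE, TRUE))
  expect_equal(length(exclude_dialysis_values(allfl)), 0L)
  none <- scr_series("A", 0:1, c(100, 160))
  expect_identical(exclude_dialysis_values(none), none)
})

test_that("flags merge into episodes by the 7-day chained window", {
  fl <- data.frame(s_index = c(1L, 2L, 4L), t_index = c(2L, 3L, 5L),
                   rc = c(0.6, 1.2, 0.55), abs_increase = c(60, 120, 55),
                   stage = c(1L, 2L, 1L), flag_time = c(2, 5, 20))
  ep <- merge_flags_to_episodes(fl)
  expect_equal(nrow(ep), 2L)
  expect_equal(ep$start_day, c(2, 20))
  expect_equal(ep$end_day, c(5, 20))
  expect_identical(ep$stage, c(2L, 1L))
  expect_identical(ep$ordinal, 1:2)
  expect_identical(ep$n_flags, c(2L, 1L))
  # chained gaps of exactly <= 7 days form one episode
  fl2 <- fl
  fl2$flag_time <- c(0, 6, 12)
  ep2 <- merge_flags_to_episodes(fl2)
  expect_equal(nrow(ep2), 1L)
  expect_equal(c(ep2$start_day, ep2$end_day), c(0, 12))
  # single flag: degenerate episode
  ep3 <- merge_flags_to_episodes(fl[1, ])
  expect_equal(ep3$start_day, ep3$end_day)
  expect_identical(ep3$stage, 1L)
  expect_error(merge_flags_to_episodes(fl[c(2, 1), ]), "ordered")
})

test_that("chaining agrees with the gap-cut oracle on random flag trains", {
  set.seed(7)
  for (i in 1:100) {
    times <- sort(runif(sample(1:12, 1), 0, 120))
    fl <- data.frame(s_index = seq_along(times), t_index = seq_along(times) + 1L,
                     rc = 0.6, abs_increase = 60, stage = 1L,
                     flag_time = times)
    ep <- merge_flags_to_episodes(fl)
    grp <- oracle_chain(times, 7)
    expect_equal(nrow(ep), max(grp))
    expect_equal(sum(ep$n_flags), length(times)) # every flag in one episode
    expect_lte(nrow(ep), length(times))
    if (nrow(ep) > 1) expect_true(all(diff(ep$start_day) > 7))
  }
})

test_that("episode grade follows the nadir of renal function", {
  # gradual rise: every adjacent pair is only stage 1 by absolute increase,
  # but the nadir-to-peak change is stage 2
  s <- scr_series("A", 0:5, c(100, 130, 160, 190, 220, 250))
  fl <- flag_series(s)
  expect_true(all(fl$stage == 1L))
  ep <- merge_flags_to_episodes(fl, series = s)
  expect_equal(nrow(ep), 1L)
  expect_identical(ep$stage, 2L) # 100 -> 250, RC 1.5
  # without the series, only the max flag stage is available
  ep0 <- merge_flags_to_episodes(fl)
  expect_identical(ep0$stage, 1L)
})

test_that("RRT initiation inside an episode window promotes it to stage 3", {
  fl <- data.frame(s_index = 1L, t_index = 2L, rc = 0.6, abs_increase = 60,
                   stage = 1L, flag_time = 10)
  expect_identical(merge_flags_to_episodes(fl, rrt_day = 12)$stage, 3L)
  expect_identical(merge_flags_to_episodes(fl, rrt_day = 17)$stage, 3L)
  expect_identical(merge_flags_to_episodes(fl, rrt_day = 40)$stage, 1L)
  expect_identical(merge_flags_to_episodes(fl, rrt_day = 2)$stage, 1L)
})

test_that("peri-AKI mask covers episode windows and nothing else", {
  eps <- data.frame(patient_id = "A", ordinal = 1L, start_day = 10,
                    end_day = 12, stage = 1L, n_flags = 1L)
  times <- c(-25, -20, 0, 11, 42, 43, 50)
  m <- peri_aki_egfr_mask(times, eps, pre_days = 30, post_days = 30)
  expect_identical(m, c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_identical(peri_aki_egfr_mask(times, eps[0, ]), rep(FALSE, 7))
  # an episode spanning the whole series masks everything
  wide <- data.frame(patient_id = "A", ordinal = 1L, start_day = -30,
                     end_day = 60, stage = 1L, n_flags = 1L)
  expect_true(all(peri_aki_egfr_mask(times, wide)))
  # conservative: never adds measurements
  expect_equal(length(m), length(times))
})

test_that("detection performance has the right degenerate values", {
  truth <- data.frame(patient_id = c("A", "A", "B"),
                      start_day = c(10, 40, 5), stage = c(1L, 2L, 3L))
  perf <- detection_performance(truth, truth)
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$stage_accuracy, 1)
  expect_equal(sum(diag(perf$confusion)), 3L)
  expect_equal(sum(perf$confusion), 3L)
  perf0 <- detection_performance(truth[0, ], truth)
  expect_equal(perf0$sensitivity, 0)
  expect_equal(perf0$n_matched, 0L)
})

test_that("episode matching is optimal against exhaustive enumeration", {
  set.seed(2024)
  for (i in 1:60) {
    nd <- sample(0:6, 1)
    ng <- sample(1:6, 1)
    d <- sort(runif(nd, 0, 50))
    g <- sort(runif(ng, 0, 50))
    det <- data.frame(patient_id = rep("A", nd), start_day = d,
                      stage = sample(1:3, nd, replace = TRUE))
    tru <- data.frame(patient_id = rep("A", ng), start_day = g,
                      stage = sample(1:3, ng, replace = TRUE))
    perf <- detection_performance(det, tru, match_tolerance_days = 5)
    best <- oracle_match(d, g, 5)
    expect_equal(perf$n_matched, best$n)
  }
})

test_that("cohort-level detection combines exclusion, flagging and merging", {
  labs <- data.frame(
    patient_id = rep(c("A", "B"), c(4, 2)),
    time_days = c(0, 10, 12, 40, 0, 30),
    scr_umol_l = c(100, 170, 260, 110, 200, 205),
    on_dialysis = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    inpatient = FALSE
  )
  out <- data.frame(patient_id = c("A", "B"), rrt_day = c(NA, NA),
                    death_day = c(NA, NA), censor_day = c(100, 100))
  ep <- detect_episodes(labs, out)
  expect_equal(unique(ep$patient_id), "A")
  expect_equal(nrow(ep), 1L)
  # nadir 100 -> peak 260: RC 1.6, stage 2
  expect_identical(ep$stage, 2L)
})
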