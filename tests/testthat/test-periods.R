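episodes_df <- function(pid, starts, ends = starts, stages) {
  if (!length(starts)) {
    return(data.frame(patient_id = character(), ordinal = integer(),
                      start_day = numeric(), end_day = numeric(),
                      stage = integer(), n_flags = integer()))
  }
  data.frame(patient_id = pid, ordinal = seq_along(starts),
             start_day = starts, end_day = ends, stage = stages,
             n_flags = 1L)
}

outcomes_df <- function(pid, rrt = NA, death = NA, censor = NA) {
  data.frame(patient_id = pid, rrt_day = rrt, death_day = death,
             censor_day = censor)
}

test_that("the four-period gap-time partition follows the episode cascade", {
  eps <- episodes_df("A", c(100, 200), stages = c(1L, 2L))
  out <- outcomes_df("A", death = 400)
  rec <- build_period_records(eps, out)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$period, 1:3)
  expect_equal(rec$entry_day, c(0, 0, 0))
  expect_equal(rec$exit_day, c(100, 100, 200))
  expect_equal(rec$event, c("AKI1", "AKI23", "DEATH"))
  expect_equal(rec$prev_aki_severe, c(NA, FALSE, TRUE))
})

test_that("patients without episodes contribute a single period-1 record", {
  rec <- build_period_records(episodes_df("A", numeric(0), stages = integer(0)),
                              outcomes_df("A", censor = 300))
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$exit_day, 300)
  expect_equal(rec$event, "CENSORED")
  expect_true(is.na(rec$prev_aki_severe))
})

test_that("period 4 is terminated only by RRT, death or censoring", {
  eps <- episodes_df("A", c(50, 120, 200, 260), stages = c(1L, 1L, 2L, 3L))
  out <- outcomes_df("A", rrt = 400)
  rec <- build_period_records(eps, out)
  expect_equal(nrow(rec), 4L)
  # the fourth episode is not typed as an event; period 4 runs to RRT
  expect_equal(rec$event[4], "RRT")
  expect_equal(rec$exit_day[4], 400 - 200)
  expect_equal(rec$prev_aki_severe[4], TRUE)
})

test_that("episodes after the terminal event are ignored", {
  eps <- episodes_df("A", c(100, 500), stages = c(2L, 1L))
  out <- outcomes_df("A", death = 300)
  rec <- build_period_records(eps, out)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$event, c("AKI23", "DEATH"))
})

test_that("outcomes preceding recruitment are rejected", {
  expect_error(
    build_period_records(episodes_df("A", numeric(0), stages = integer(0)),
                         outcomes_df("A", censor = -5)),
    "precedes recruitment")
})

test_that("the calendar clock reproduces gap times after shifting", {
  eps <- episodes_df("A", c(100, 200), stages = c(1L, 2L))
  out <- outcomes_df("A", death = 400)
  cal <- build_period_records(eps, out, clock = "calendar")
  expect_equal(cal$entry_day, c(0, 100, 200))
  expect_equal(cal$exit_day, c(100, 200, 400))
})

test_that("the partitioner agrees with an independent walk on random cases", {
  set.seed(4242)
  for (i in 1:2000) {
    n_ep <- sample(0:5, 1)
    starts <- sort(round(runif(n_ep, 1, 900)))
    dur <- runif(n_ep, 0, 10)
    keep <- !duplicated(starts)
    starts <- starts[keep]; dur <- dur[keep]
    ends <- starts + dur
    stages <- sample(1:3, length(starts), replace = TRUE)
    terminal_day <- round(runif(1, 1, 1000))
    terminal_type <- sample(c("RRT", "DEATH", "CENSORED"), 1)
    ok <- !length(starts) || all(ends < terminal_day | starts >= terminal_day)
    if (!ok) next # overlapping terminal handled separately
    eps <- episodes_df("A", starts, ends, stages)
    out <- outcomes_df(
      "A",
      rrt = if (terminal_type == "RRT") terminal_day else NA,
      death = if (terminal_type == "DEATH") terminal_day else NA,
      censor = if (terminal_type == "CENSORED") terminal_day else NA
    )
    got <- build_period_records(eps, out)
    want <- oracle_partition(starts, ends, stages, terminal_day,
                             terminal_type)
    expect_equal(got$period, want$period, info = paste("case", i))
    expect_equal(got$exit_day, want$exit_day, info = paste("case", i))
    expect_equal(got$event, want$event, info = paste("case", i))
    expect_equal(got$prev_aki_severe, want$prev_aki_severe,
                 info = paste("case", i))
  }
})

test_that("partition conservation holds on a generated cohort", {
  co <- generate_cohort(cohort_config(n_patients = 150, seed = 31))
  ep <- detect_episodes(co$labs, co$outcomes)
  rec <- build_period_records(ep, co$outcomes)
  # every patient appears in period 1 exactly once
  p1 <- rec[rec$period == 1, ]
  expect_equal(sort(p1$patient_id), sort(co$outcomes$patient_id))
  # period-(k+1) entrants equal AKI events in period k
  for (k in 1:3) {
    aki_k <- sum(rec$period == k & rec$event %in% c("AKI1", "AKI23"))
    expect_equal(sum(rec$period == k + 1), aki_k)
  }
  # exactly one terminal event or censoring per record
  expect_true(all(rec$event %in% c("AKI1", "AKI23", "RRT", "DEATH",
                                   "CENSORED")))
  expect_true(all(rec$exit_day > rec$entry_day))
})

test_that("consort accounting sums level by level", {
  co <- generate_cohort(cohort_config(n_patients = 100, seed = 13))
  ep <- detect_episodes(co$labs, co$outcomes)
  rec <- build_period_records(ep, co$outcomes)
  cs <- consort_summary(ep, rec)
  expect_equal(cs$n_patients, 100L)
  expect_equal(cs$patients_with_aki, length(unique(ep$patient_id)))
  expect_equal(cs$total_episodes, nrow(ep))
  for (nm in names(cs$periods)) {
    per <- cs$periods[[nm]]
    expect_equal(Reduce(`+`, per$events), per$n_at_risk)
  }
  # period 2 entrants equal period-1 AKI exits
  if (!is.null(cs$periods$period_2)) {
    expect_equal(cs$periods$period_2$n_at_risk,
                 cs$periods$period_1$events$AKI1 +
                   cs$periods$period_1$events$AKI23)
  }
})

test_that("consort handles the no-episode and one-episode-each cases", {
  out <- outcomes_df(c("A", "B"), censor = c(100, 200))
  eps0 <- episodes_df("A", numeric(0), stages = integer(0))
  rec0 <- build_period_records(eps0, out)
  cs0 <- consort_summary(eps0, rec0)
  expect_equal(cs0$total_episodes, 0L)
  expect_equal(cs0$periods$period_1$n_at_risk, 2L)
  expect_equal(cs0$periods$period_1$events$CENSORED, 2L)
  # every patient exactly one stage-1 episode, then censored
  eps1 <- rbind(episodes_df("A", 50, stages = 1L),
                episodes_df("B", 80, stages = 1L))
  rec1 <- build_period_records(eps1, out)
  cs1 <- consort_summary(eps1, rec1)
  expect_equal(cs1$periods$period_2$n_at_risk, 2L)
  expect_equal(cs1$periods$period_2$events$AKI1 +
                 cs1$periods$period_2$events$AKI23, 0L)
  expect_equal(cs1$periods$period_1$aki_stage_split$stage1, 2L)
})
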