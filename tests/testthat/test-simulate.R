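test_that("cohort generation is deterministic and extends stably", {
  cfg <- cohort_config(n_patients = 20, seed = 5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$labs, b$labs)
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(a$ground_truth, b$ground_truth)
  # per-patient substreams: enlarging the cohort leaves patients unchanged
  big <- generate_cohort(cohort_config(n_patients = 30, seed = 5))
  expect_identical(big$covariates[1:20, ], a$covariates)
  expect_identical(big$labs[big$labs$patient_id %in% a$covariates$patient_id, ],
                   a$labs)
})

test_that("an empty cohort is empty, not an error", {
  co <- generate_cohort(cohort_config(n_patients = 0, seed = 1))
  expect_equal(nrow(co$covariates), 0L)
  expect_equal(nrow(co$labs), 0L)
  expect_equal(nrow(co$outcomes), 0L)
  expect_equal(nrow(co$ground_truth), 0L)
})

test_that("covariate marginals converge to their configuration", {
  cfg <- cohort_config(n_patients = 5000, seed = 17,
                       followup_horizon_years = 1,
                       measurement_rate_per_year = 1,
                       aki_injection = aki_injection_params(
                         episode_rate_per_year = 0))
  co <- generate_cohort(cfg)
  p_male <- mean(co$covariates$sex == "male")
  se <- sqrt(0.618 * 0.382 / 5000)
  expect_lt(abs(p_male - 0.618), 3 * se)
  p_dm <- mean(co$covariates$diabetes)
  expect_lt(abs(p_dm - 0.316), 3 * sqrt(0.316 * 0.684 / 5000))
  p_sm <- mean(co$covariates$smoker)
  expect_lt(abs(p_sm - 0.673), 3 * sqrt(0.673 * 0.327 / 5000))
  expect_true(all(co$covariates$age >= 20 & co$covariates$age <= 94.3))
})

test_that("every patient has a recruitment measurement and ordered times", {
  co <- generate_cohort(cohort_config(n_patients = 40, seed = 3))
  expect_equal(sort(unique(co$labs$patient_id)), sort(co$covariates$patient_id))
  for (pid in co$covariates$patient_id) {
    t <- co$labs$time_days[co$labs$patient_id == pid]
    expect_gte(length(t), 1L)
    expect_equal(min(t), 0)
    if (length(t) > 1) expect_true(all(diff(t) > 0))
  }
  # exactly one outcome day observed per patient
  n_obs <- rowSums(!is.na(co$outcomes[c("rrt_day", "death_day", "censor_day")]))
  expect_true(all(n_obs == 1))
})

test_that("a degenerate trajectory equals the fixed-effect mean", {
  p <- lmm_params(beta = c(intercept = 40, years = -3),
                  sigma2_intercept = 0, sigma2_process = 0,
                  phi_days = 10, sigma2_noise = 0)
  t <- c(0, 100, 400)
  expect_equal(simulate_egfr_trajectory(p, t), 40 - 3 * t / 365.25)
  expect_error(simulate_egfr_trajectory(p, c(5, 1)), "sorted")
})

test_that("trajectory covariance matches the closed form", {
  p <- lmm_params(beta = c(intercept = 30), sigma2_intercept = 4,
                  sigma2_process = 9, phi_days = 50, sigma2_noise = 1)
  set.seed(11)
  reps <- t(replicate(4000, simulate_egfr_trajectory(p, c(0, 50))))
  expect_equal(cov(reps[, 1], reps[, 2]), 4 + 9 * exp(-1), tolerance = 0.12)
  expect_equal(var(reps[, 1]), 4 + 9 + 1, tolerance = 0.05)
  # single time point: variance is the sum of all three components
  set.seed(12)
  one <- replicate(4000, simulate_egfr_trajectory(p, 30))
  expect_equal(var(one), 14, tolerance = 0.05)
})

test_that("excursion injection shapes the series as configured", {
  prm <- aki_injection_params(
    excursion_peak_multiplier_by_stage = c(1.6, 2.5, 3.5),
    excursion_duration_days = 14, recovery_fraction = 1)
  s <- flat_series(0:40)
  out <- inject_aki_excursion(s, 8, 1, prm)
  expect_equal(out$scr[s$times < 8 | s$times > 22], rep(100, sum(s$times < 8 | s$times > 22)))
  expect_equal(max(out$scr), 100 * (1 + 0.6 * (4 / 4.2)), tolerance = 1e-6)
  expect_error(inject_aki_excursion(s, 8, 5, prm), "stage")
  expect_error(inject_aki_excursion(s, 99, 1, prm), "span")
  # identity multiplier leaves the series unchanged
  prm1 <- aki_injection_params(excursion_peak_multiplier_by_stage = c(1, 1, 1))
  expect_equal(inject_aki_excursion(s, 8, 1, prm1)$scr, s$scr)
})

test_that("injected excursions are staged correctly by the detector", {
  prm <- aki_injection_params(
    excursion_peak_multiplier_by_stage = c(1.6, 2.5, 3.5),
    excursion_duration_days = 14, recovery_fraction = 1)
  s <- flat_series(0:60)
  detect_stage <- function(stage) {
    inj <- inject_aki_excursion(s, 20, stage, prm)
    fl <- flag_series(inj, baseline = "rolling")
    ep <- merge_flags_to_episodes(fl, series = inj)
    expect_equal(nrow(ep), 1L)
    ep$stage
  }
  expect_identical(detect_stage(1), 1L)  # RC 0.6 in [0.5, 1)
  expect_identical(detect_stage(3), 3L)  # RC 2.5 > 2
})

test_that("competing event types follow the analytic probabilities", {
  set.seed(21)
  types <- replicate(10000, simulate_competing_event_times(
    c(x = 0), list(a = list(rate = 0.3), b = list(rate = 0.1)), Inf)$type)
  frac_a <- mean(types == "a")
  expect_lt(abs(frac_a - 0.75), 3 * sqrt(0.75 * 0.25 / 10000))
  set.seed(22)
  tm <- replicate(10000, simulate_competing_event_times(
    c(x = 0), list(a = list(rate = 0.5)), Inf)$time_years)
  expect_lt(abs(mean(tm) - 2), 3 * 2 / sqrt(10000))
})

test_that("null covariate effects leave the random path unchanged", {
  hz0 <- list(a = list(rate = 0.2), b = list(rate = 0.1))
  hz1 <- list(a = list(rate = 0.2, loghr = c(x = 0)),
              b = list(rate = 0.1, loghr = c(x = 0)))
  set.seed(33); r0 <- simulate_competing_event_times(c(x = 1.7), hz0, 10)
  set.seed(33); r1 <- simulate_competing_event_times(c(x = 1.7), hz1, 10)
  expect_identical(r0, r1)
  # all-zero rates: censored at the horizon, not an error
  res <- simulate_competing_event_times(c(x = 0),
                                        list(a = list(rate = 0)), 7)
  expect_equal(res, list(time_years = 7, type = "CENSORED"))
})

test_that("configuration errors name the offending field", {
  expect_error(cohort_config(-1), "n_patients")
  expect_error(cohort_config(10, covariate_marginals = modifyList(
    default_covariate_marginals(), list(male = 1.2))), "male")
  bad_prd <- default_covariate_marginals()
  bad_prd$primary_renal_disease <- c(a = 0.5, b = 0.4)
  expect_error(cohort_config(10, covariate_marginals = bad_prd),
               "primary_renal_disease")
  expect_error(aki_injection_params(stage_probabilities = c(0.5, 0.5, 0.5)),
               "stage_probabilities")
  expect_error(aki_injection_params(
    excursion_peak_multiplier_by_stage = c(2, 1.5, 3)),
    "excursion_peak_multiplier_by_stage")
  expect_error(lmm_params(sigma2_noise = -1), "sigma2_noise")
  expect_error(lmm_params(phi_days = 0), "phi_days")
  expect_error(cohort_config(10, measurement_rate_per_year = 0),
               "measurement_rate_per_year")
})

test_that("cohort round-trips through its delimited files", {
  co <- generate_cohort(cohort_config(n_patients = 8, seed = 2))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "covariates.csv", "labs.csv", "outcomes.csv",
    "ground_truth_episodes.csv")))))
  back <- read_cohort(dir)
  expect_equal(back$labs$scr_umol_l, co$labs$scr_umol_l, tolerance = 1e-12)
  expect_equal(nrow(back$outcomes), 8L)
})
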