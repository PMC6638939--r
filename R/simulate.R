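#' Linear mixed model parameters for the eGFR trajectory
#'
#' Parameters of the trajectory model
#' \deqn{Y_{ij} = x_{ij}'\beta + b_i + W_i(t_{ij}) + \epsilon_{ij}}
#' with patient random intercept \eqn{b_i \sim N(0, \sigma^2_b)}, a
#' zero-mean Gaussian serial process \eqn{W_i} with exponential correlation
#' \eqn{\exp(-|u|/\phi)} and variance \eqn{\sigma^2_w}, and measurement
#' noise \eqn{\epsilon_{ij} \sim N(0, \sigma^2_e)}.
#'
#' Default fixed effects place the population intercept at a mean baseline
#' eGFR of 30.5 ml/min/1.73m^2 with a decline of 2 ml/min per year, and
#' covariate shifts of the order reported for advanced-CKD cohorts
#' (e.g. lower baseline function with diabetic or polycystic primary renal
#' disease, slightly higher with any alcohol intake).
#'
#' @param beta named numeric vector of fixed effects in eGFR units;
#'   recognised names are `intercept`, `years` (slope per year) and any
#'   column of [build_covariate_design()]
#' @param sigma2_intercept variance of the patient random intercept
#' @param sigma2_process variance of the serial process
#' @param phi_days correlation range of the exponential correlation, days
#' @param sigma2_noise measurement-error variance
#' @return an object of class `lmm_params`
#' @export
lmm_params <- function(beta = c(intercept = 30.5, years = -2,
                                age_c = -0.1, alcohol = 1.5,
                                prd_diabetes = -5.9, prd_polycystic = -6.1,
                                prd_pyelonephritis = -3.7,
                                prd_immune_vasculitis = 4.43),
                       sigma2_intercept = 100,
                       sigma2_process = 4,
                       phi_days = 60,
                       sigma2_noise = 1) {
  if (is.null(names(beta)) || anyNA(names(beta)) || any(names(beta) == "")) {
    stop("configuration error in field 'beta': must be a named vector",
         call. = FALSE)
  }
  for (f in c("sigma2_intercept", "sigma2_process", "sigma2_noise")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("configuration error in field '", f,
           "': variance must be a nonnegative number", call. = FALSE)
    }
  }
  if (!is.numeric(phi_days) || length(phi_days) != 1L ||
      !is.finite(phi_days) || phi_days <= 0) {
    stop("configuration error in field 'phi_days': must be positive",
         call. = FALSE)
  }
  structure(list(beta = beta, sigma2_intercept = sigma2_intercept,
                 sigma2_process = sigma2_process, phi_days = phi_days,
                 sigma2_noise = sigma2_noise),
            class = "lmm_params")
}

#' AKI excursion injection parameters
#'
#' Controls the forward model for injected creatinine excursions: episodes
#' arrive as a Poisson process (thinned so excursions never overlap), each
#' drawing a target stage; creatinine within the excursion window is
#' multiplied by a profile that rises linearly to the stage's peak
#' multiplier over `rise_fraction` of the window and then decays linearly
#' until `recovery_fraction` of the excursion has resolved at the window's
#' end. Peak multipliers must be stage-monotone.
#'
#' @param episode_rate_per_year Poisson intensity of candidate episodes
#' @param stage_probabilities probabilities of stages 1-3; must sum to 1
#' @param excursion_peak_multiplier_by_stage peak creatinine multiplier for
#'   stages 1-3; each >= 1 (1 = identity) and nondecreasing in stage
#' @param excursion_duration_days excursion window length, days
#' @param recovery_fraction fraction of the excursion resolved at window
#'   end, in `[0, 1]`
#' @param rise_fraction fraction of the window spent rising to peak
#' @param burst_rate_per_day extra laboratory draws per day during an
#'   excursion (0 = none); emulates clustered inpatient sampling
#' @param burst_lead_days how many days before excursion onset the burst
#'   sampling window opens, so a pre-injury baseline draw exists (default
#'   2)
#' @return an object of class `aki_injection_params`
#' @export
aki_injection_params <- function(episode_rate_per_year = 0.17,
                                 stage_probabilities = c(0.523, 0.320, 0.157),
                                 excursion_peak_multiplier_by_stage =
                                   c(1.7, 2.5, 3.6),
                                 excursion_duration_days = 14,
                                 recovery_fraction = 0.9,
                                 rise_fraction = 0.3,
                                 burst_rate_per_day = 0,
                                 burst_lead_days = 2) {
  if (!is.numeric(episode_rate_per_year) || episode_rate_per_year < 0) {
    stop("configuration error in field 'episode_rate_per_year': ",
         "must be nonnegative", call. = FALSE)
  }
  if (length(stage_probabilities) != 3L || any(stage_probabilities < 0) ||
      abs(sum(stage_probabilities) - 1) > 1e-9) {
    stop("configuration error in field 'stage_probabilities': ",
         "three nonnegative values summing to 1", call. = FALSE)
  }
  pk <- excursion_peak_multiplier_by_stage
  if (length(pk) != 3L || any(pk < 1) || is.unsorted(pk)) {
    stop("configuration error in field ",
         "'excursion_peak_multiplier_by_stage': must be >= 1 and ",
         "nondecreasing in stage", call. = FALSE)
  }
  if (excursion_duration_days <= 0) {
    stop("configuration error in field 'excursion_duration_days': ",
         "must be positive", call. = FALSE)
  }
  if (recovery_fraction < 0 || recovery_fraction > 1) {
    stop("configuration error in field 'recovery_fraction': must lie in ",
         "[0, 1]", call. = FALSE)
  }
  if (rise_fraction <= 0 || rise_fraction >= 1) {
    stop("configuration error in field 'rise_fraction': must lie in (0, 1)",
         call. = FALSE)
  }
  if (burst_rate_per_day < 0) {
    stop("configuration error in field 'burst_rate_per_day': ",
         "must be nonnegative", call. = FALSE)
  }
  if (burst_lead_days < 0) {
    stop("configuration error in field 'burst_lead_days': ",
         "must be nonnegative", call. = FALSE)
  }
  structure(list(episode_rate_per_year = episode_rate_per_year,
                 stage_probabilities = stage_probabilities,
                 excursion_peak_multiplier_by_stage = pk,
                 excursion_duration_days = excursion_duration_days,
                 recovery_fraction = recovery_fraction,
                 rise_fraction = rise_fraction,
                 burst_rate_per_day = burst_rate_per_day,
                 burst_lead_days = burst_lead_days),
            class = "aki_injection_params")
}

#' Default baseline covariate marginals
#'
#' Category probabilities matching the demographics of a large all-cause
#' CKD cohort: 61.8% male, 67.3% ex/current smokers, 47.9% any alcohol,
#' 31.6% diabetic, 19.9% prior cardiovascular event, 29.8% recruited at the
#' base hospital, and a seven-category primary renal disease mix dominated
#' by vascular disease. Black ethnicity defaults to probability 0 (the
#' emulated cohort is 96.2% Caucasian and ethnicity enters only through the
#' MDRD multiplier).
#'
#' @return named list of marginal probabilities
#' @export
default_covariate_marginals <- function() {
  list(
    male = 0.618,
    ethnicity_black = 0,
    smoker = 0.673,
    alcohol = 0.479,
    diabetes = 0.316,
    prior_cv = 0.199,
    base_hospital = 0.298,
    primary_renal_disease = c(
      diabetes = 375, glomerulonephritis = 383, immune_vasculitis = 64,
      polycystic = 131, pyelonephritis = 137, vascular = 635, other = 562
    ) / 2287,
    age_range = c(20, 94.3)
  )
}

#' Default cause-specific event hazards
#'
#' Baseline yearly rates and log-hazard-ratios for the two terminal
#' competing events, renal replacement therapy (RRT) and death. Covariate
#' effects follow the direction and magnitude of hazard ratios reported for
#' advanced CKD: mortality increasing with age, male sex, smoking,
#' diabetes and prior cardiovascular disease and decreasing with alcohol
#' intake; RRT slightly less likely with advancing age and at the base
#' hospital.
#'
#' @return named list; one element per cause with `rate` (events per
#'   person-year at covariate reference) and `loghr` (named log-hazard
#'   ratios over [build_covariate_design()] columns)
#' @export
default_cause_hazards <- function() {
  list(
    rrt = list(rate = 0.05,
               loghr = c(age_c = log(0.97), base_hospital = log(0.45))),
    death = list(rate = 0.08,
                 loghr = c(age_c = log(1.08), male = log(1.27),
                           smoker = log(1.39), alcohol = log(0.77),
                           diabetes = log(1.58), prior_cv = log(1.36),
                           base_hospital = log(0.60)))
  )
}

#' Synthetic cohort configuration
#'
#' Bundles everything [generate_cohort()] needs: cohort size, seed,
#' follow-up horizon, laboratory sampling intensity, covariate marginals,
#' eGFR trajectory parameters, AKI injection parameters and competing
#' event hazards. All randomness derives from `seed` through per-patient
#' substreams, so enlarging the cohort leaves existing patients unchanged.
#'
#' @param n_patients number of patients (0 allowed: empty cohort)
#' @param seed integer seed
#' @param followup_horizon_years administrative follow-up horizon
#' @param measurement_rate_per_year Poisson intensity of laboratory draws;
#'   one draw at recruitment (day 0) is always present
#' @param covariate_marginals see [default_covariate_marginals()]
#' @param lmm_params an [lmm_params()] object (default: `lmm_params()`)
#' @param aki_injection an [aki_injection_params()] object
#' @param cause_hazards see [default_cause_hazards()]
#' @param admin_censor_range_years administrative censoring is drawn
#'   uniformly on this range (staggered recruitment against a common
#'   database lock)
#' @param dialysis_prob per-measurement probability of a dialysis-flagged
#'   draw
#' @param inpatient_prob per-measurement probability of an inpatient draw
#' @return an object of class `cohort_config`
#' @export
cohort_config <- function(n_patients,
                          seed = 1L,
                          followup_horizon_years = 10.9,
                          measurement_rate_per_year = 5,
                          covariate_marginals = default_covariate_marginals(),
                          lmm_params = NULL,
                          aki_injection = aki_injection_params(),
                          cause_hazards = default_cause_hazards(),
                          admin_censor_range_years = c(0.25,
                                                       followup_horizon_years),
                          dialysis_prob = 0,
                          inpatient_prob = 0.113) {
  if (is.null(lmm_params)) {
    # the argument shadows the constructor of the same name
    lmm_params <- get("lmm_params", envir = parent.env(environment()),
                      mode = "function")()
  }
  if (!is.numeric(n_patients) || length(n_patients) != 1L ||
      n_patients < 0 || n_patients != round(n_patients)) {
    stop("configuration error in field 'n_patients': ",
         "must be a nonnegative integer", call. = FALSE)
  }
  if (followup_horizon_years <= 0) {
    stop("configuration error in field 'followup_horizon_years': ",
         "must be positive", call. = FALSE)
  }
  if (measurement_rate_per_year <= 0) {
    stop("configuration error in field 'measurement_rate_per_year': ",
         "must be positive", call. = FALSE)
  }
  cm <- covariate_marginals
  for (f in c("male", "ethnicity_black", "smoker", "alcohol", "diabetes",
              "prior_cv", "base_hospital")) {
    p <- cm[[f]]
    if (is.null(p) || !is.numeric(p) || p < 0 || p > 1) {
      stop("configuration error in field 'covariate_marginals$", f,
           "': probability in [0, 1] required", call. = FALSE)
    }
  }
  prd <- cm$primary_renal_disease
  if (is.null(prd) || any(prd < 0) || abs(sum(prd) - 1) > 1e-9 ||
      is.null(names(prd))) {
    stop("configuration error in field ",
         "'covariate_marginals$primary_renal_disease': named ",
         "probabilities summing to 1 required", call. = FALSE)
  }
  if (length(cm$age_range) != 2L || cm$age_range[1] <= 0 ||
      diff(cm$age_range) <= 0) {
    stop("configuration error in field 'covariate_marginals$age_range'",
         call. = FALSE)
  }
  stopifnot(inherits(lmm_params, "lmm_params"),
            inherits(aki_injection, "aki_injection_params"))
  for (cz in names(cause_hazards)) {
    if (is.null(cause_hazards[[cz]]$rate) || cause_hazards[[cz]]$rate < 0) {
      stop("configuration error in field 'cause_hazards$", cz,
           "$rate': nonnegative rate required", call. = FALSE)
    }
  }
  if (dialysis_prob < 0 || dialysis_prob > 1) {
    stop("configuration error in field 'dialysis_prob'", call. = FALSE)
  }
  if (inpatient_prob < 0 || inpatient_prob > 1) {
    stop("configuration error in field 'inpatient_prob'", call. = FALSE)
  }
  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    followup_horizon_years = followup_horizon_years,
    measurement_rate_per_year = measurement_rate_per_year,
    covariate_marginals = cm, lmm_params = lmm_params,
    aki_injection = aki_injection, cause_hazards = cause_hazards,
    admin_censor_range_years = admin_censor_range_years,
    dialysis_prob = dialysis_prob, inpatient_prob = inpatient_prob
  ), class = "cohort_config")
}

# Per-patient substream seed: a fixed mix of the master seed and the
# patient index, independent of cohort size.
substream_seed <- function(seed, i) {
  as.integer((as.double(seed %% 2147483647L) * 69069 + i * 104729) %%
               2147483629)
}

#' Covariate design matrix shared by simulator and fitters
#'
#' Expands the baseline covariate table into the numeric design used for
#' event hazards, the eGFR fixed effects and the Cox models: centred age
#' (`age_c`, years minus 66.8), binary indicators (`male`, `smoker`,
#' `alcohol`, `diabetes`, `prior_cv`, `base_hospital`) and primary renal
#' disease dummies (`prd_*`, reference category "other").
#'
#' @param covariates baseline covariate data frame from
#'   [generate_cohort()]
#' @param age_center centring constant for age, years
#' @return numeric matrix, one row per patient, named columns
#' @export
build_covariate_design <- function(covariates, age_center = 66.8) {
  prd_levels <- c("diabetes", "glomerulonephritis", "immune_vasculitis",
                  "polycystic", "pyelonephritis", "vascular")
  x <- cbind(
    age_c = covariates$age - age_center,
    male = as.numeric(covariates$sex == "male"),
    smoker = as.numeric(covariates$smoker),
    alcohol = as.numeric(covariates$alcohol),
    diabetes = as.numeric(covariates$diabetes),
    prior_cv = as.numeric(covariates$prior_cv),
    base_hospital = as.numeric(covariates$base_hospital)
  )
  for (lv in prd_levels) {
    x <- cbind(x, as.numeric(covariates$primary_renal_disease == lv))
    colnames(x)[ncol(x)] <- paste0("prd_", lv)
  }
  rownames(x) <- covariates$patient_id
  x
}

#' Simulate an eGFR trajectory from the mixed model
#'
#' Draws one realisation of the trajectory model at the given times: the
#' fixed-effect mean plus a patient random intercept, an exponentially
#' correlated serial Gaussian process and independent measurement noise.
#' Uses R's global random number generator; seed with [set.seed()].
#'
#' @param params an [lmm_params()] object
#' @param times day offsets, sorted ascending
#' @param x optional named covariate vector matched against `names(params$beta)`
#' @return numeric vector of eGFR values (ml/min/1.73m^2 scale, unclamped)
#' @export
simulate_egfr_trajectory <- function(params, times, x = NULL) {
  stopifnot(inherits(params, "lmm_params"))
  if (length(times) && is.unsorted(times, strictly = FALSE)) {
    stop("'times' must be sorted ascending", call. = FALSE)
  }
  n <- length(times)
  if (!n) return(numeric(0))
  b <- params$beta
  mu <- rep(0, n)
  if ("intercept" %in% names(b)) mu <- mu + b[["intercept"]]
  if ("years" %in% names(b)) mu <- mu + b[["years"]] * times / 365.25
  if (!is.null(x)) {
    shared <- intersect(names(b), names(x))
    if (length(shared)) mu <- mu + sum(b[shared] * x[shared])
  }
  y <- mu
  if (params$sigma2_intercept > 0) {
    y <- y + rnorm(1, 0, sqrt(params$sigma2_intercept))
  }
  if (params$sigma2_process > 0) {
    r <- exp_correlation(outer(times, times, "-"), 0, params$phi_days)
    w <- drop(crossprod(chol(r + diag(1e-10, n)), rnorm(n))) *
      sqrt(params$sigma2_process)
    y <- y + w
  }
  if (params$sigma2_noise > 0) {
    y <- y + rnorm(n, 0, sqrt(params$sigma2_noise))
  }
  y
}

# Multiplicative excursion profile at measurement times: linear rise from 1
# to `peak` over the first rise_fraction of the window, then linear decay
# toward 1 + (peak - 1) * (1 - recovery_fraction) at the window end.
excursion_multiplier <- function(times, start_day, peak, duration_days,
                                 recovery_fraction, rise_fraction) {
  u <- (times - start_day) / duration_days
  m <- rep(1, length(times))
  inw <- u >= 0 & u <= 1
  endval <- 1 + (peak - 1) * (1 - recovery_fraction)
  rising <- inw & u < rise_fraction
  falling <- inw & u >= rise_fraction
  m[rising] <- 1 + (peak - 1) * u[rising] / rise_fraction
  m[falling] <- peak + (endval - peak) *
    (u[falling] - rise_fraction) / (1 - rise_fraction)
  m
}

#' Inject an AKI excursion into a creatinine series
#'
#' Multiplies creatinine values inside the excursion window
#' `[start_day, start_day + duration]` by the stage's rise-and-decay
#' profile; measurements outside the window are unchanged. A peak
#' multiplier of exactly 1 leaves the series unchanged.
#'
#' @param series an [scr_series()]
#' @param start_day excursion onset, within the series time span
#' @param stage target stage, 1, 2 or 3
#' @param params an [aki_injection_params()] object
#' @return the modified `scr_series`
#' @export
inject_aki_excursion <- function(series, start_day, stage, params) {
  stopifnot(inherits(series, "scr_series"),
            inherits(params, "aki_injection_params"))
  if (!stage %in% 1:3) {
    stop("'stage' must be 1, 2 or 3", call. = FALSE)
  }
  if (start_day < min(series$times) || start_day > max(series$times)) {
    stop("'start_day' lies outside the series time span", call. = FALSE)
  }
  peak <- params$excursion_peak_multiplier_by_stage[stage]
  m <- excursion_multiplier(series$times, start_day, peak,
                            params$excursion_duration_days,
                            params$recovery_fraction, params$rise_fraction)
  scr_series(series$patient_id, series$times, series$scr * m,
             series$on_dialysis, series$inpatient)
}

#' Simulate competing event times
#'
#' Latent exponential times for each cause under log-linear covariate
#' effects; the earliest cause wins, and times beyond the horizon are
#' administratively censored. A unit exponential is drawn per cause and
#' scaled by the cause's hazard, so the random-number path is identical
#' across covariate-effect settings.
#'
#' @param x named covariate vector (design scale, see
#'   [build_covariate_design()])
#' @param cause_hazards as in [default_cause_hazards()]
#' @param horizon_years administrative horizon (may be `Inf`)
#' @return list with `time_years` and `type` (cause name or `"CENSORED"`)
#' @export
simulate_competing_event_times <- function(x, cause_hazards, horizon_years) {
  times <- vapply(names(cause_hazards), function(cz) {
    h <- cause_hazards[[cz]]
    lp <- 0
    if (!is.null(h$loghr) && length(h$loghr)) {
      shared <- intersect(names(h$loghr), names(x))
      if (length(shared)) lp <- sum(h$loghr[shared] * x[shared])
    }
    lambda <- h$rate * exp(lp)
    e <- rexp(1)
    if (lambda > 0) e / lambda else Inf
  }, numeric(1))
  if (!length(times) || min(times) > horizon_years) {
    return(list(time_years = horizon_years, type = "CENSORED"))
  }
  k <- which.min(times)
  list(time_years = times[[k]], type = names(times)[k])
}

#' Generate a synthetic CKD cohort
#'
#' Generates baseline covariates, competing RRT/death/censoring outcomes,
#' irregular creatinine series driven by the eGFR mixed model, and injected
#' AKI excursions with ground-truth labels. Fully reproducible: identical
#' `config` (including its `seed`) gives byte-identical output, and each
#' patient is generated from their own seed substream so a larger cohort
#' extends a smaller one.
#'
#' Ground-truth episodes carry two stage labels: `stage_sampled`, the
#' stage category drawn when the excursion was injected, and `stage_rule`,
#' the stage the creatinine staging rules assign to the excursion's actual
#' baseline-to-peak rise (the two differ when, e.g., an excursion peaks
#' above the absolute stage-3 level from a high chronic baseline).
#' Detector validation compares against `stage_rule`.
#'
#' @param config a [cohort_config()]
#' @return object of class `aki_cohort`: list of data frames `covariates`,
#'   `labs`, `outcomes`, `ground_truth`
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cm <- config$covariate_marginals
  inj <- config$aki_injection
  horizon_days <- config$followup_horizon_years * 365.25
  cov_rows <- vector("list", config$n_patients)
  lab_rows <- vector("list", config$n_patients)
  out_rows <- vector("list", config$n_patients)
  gt_rows <- vector("list", config$n_patients)

  for (i in seq_len(config$n_patients)) {
    set.seed(substream_seed(config$seed, i))
    pid <- sprintf("P%05d", i)
    covi <- data.frame(
      patient_id = pid,
      age = runif(1, cm$age_range[1], cm$age_range[2]),
      sex = if (rbinom(1, 1, cm$male) == 1) "male" else "female",
      ethnicity_black = rbinom(1, 1, cm$ethnicity_black) == 1,
      smoker = rbinom(1, 1, cm$smoker) == 1,
      alcohol = rbinom(1, 1, cm$alcohol) == 1,
      diabetes = rbinom(1, 1, cm$diabetes) == 1,
      prior_cv = rbinom(1, 1, cm$prior_cv) == 1,
      base_hospital = rbinom(1, 1, cm$base_hospital) == 1,
      primary_renal_disease = sample(names(cm$primary_renal_disease), 1,
                                     prob = cm$primary_renal_disease),
      stringsAsFactors = FALSE
    )
    x <- drop(build_covariate_design(covi))

    censor_years <- runif(1, config$admin_censor_range_years[1],
                          min(config$admin_censor_range_years[2],
                              config$followup_horizon_years))
    ev <- simulate_competing_event_times(x, config$cause_hazards,
                                         config$followup_horizon_years)
    if (ev$type == "CENSORED" || ev$time_years >= censor_years) {
      terminal_years <- censor_years
      terminal_type <- "CENSORED"
    } else {
      terminal_years <- ev$time_years
      terminal_type <- ev$type
    }
    terminal_day <- terminal_years * 365.25

    # candidate episode onsets: Poisson process thinned so that excursions
    # are separated by at least the excursion window plus the 7-day merge
    # window
    ep_start <- numeric(0)
    ep_stage <- integer(0)
    if (inj$episode_rate_per_year > 0) {
      t_cur <- 0
      min_gap <- inj$excursion_duration_days + 7
      repeat {
        gap_days <- rexp(1, inj$episode_rate_per_year) * 365.25
        t_cur <- t_cur + gap_days
        if (t_cur >= terminal_day) break
        if (!length(ep_start) || t_cur >= ep_start[length(ep_start)] +
            min_gap) {
          ep_start <- c(ep_start, t_cur)
          ep_stage <- c(ep_stage,
                        sample(1:3, 1, prob = inj$stage_probabilities))
        }
      }
    }

    n_base <- rpois(1, config$measurement_rate_per_year * terminal_years)
    t_meas <- c(0, runif(n_base, 0, terminal_day))
    if (inj$burst_rate_per_day > 0 && length(ep_start)) {
      for (s in ep_start) {
        lo <- max(0, s - inj$burst_lead_days)
        hi <- min(s + inj$excursion_duration_days, terminal_day)
        nb <- rpois(1, inj$burst_rate_per_day * (hi - lo))
        t_meas <- c(t_meas, runif(nb, lo, hi))
      }
    }
    t_meas <- sort(unique(t_meas))

    egfr <- simulate_egfr_trajectory(config$lmm_params, t_meas, x)
    egfr <- pmax(egfr, 5)
    scr_u <- scr_from_egfr(egfr, covi$age, covi$sex == "female",
                           covi$ethnicity_black)

    scr <- scr_u
    if (length(ep_start)) {
      for (k in seq_along(ep_start)) {
        peak <- inj$excursion_peak_multiplier_by_stage[ep_stage[k]]
        scr <- scr * excursion_multiplier(t_meas, ep_start[k], peak,
                                          inj$excursion_duration_days,
                                          inj$recovery_fraction,
                                          inj$rise_fraction)
      }
      near_start <- vapply(ep_start, function(s) {
        which.min(abs(t_meas - s))
      }, integer(1))
      u0 <- scr_u[near_start]
      peak_mult <- inj$excursion_peak_multiplier_by_stage[ep_stage]
      gt_rows[[i]] <- data.frame(
        patient_id = pid,
        ordinal = seq_along(ep_start),
        start_day = ep_start,
        end_day = ep_start + inj$excursion_duration_days,
        stage_sampled = ep_stage,
        stage_rule = classify_pair(u0, u0 * peak_mult),
        peak_multiplier = peak_mult
      )
    }

    on_dial <- if (config$dialysis_prob > 0) {
      rbinom(length(t_meas), 1, config$dialysis_prob) == 1
    } else rep(FALSE, length(t_meas))
    inpat <- rbinom(length(t_meas), 1, config$inpatient_prob) == 1

    lab_rows[[i]] <- data.frame(
      patient_id = pid, time_days = t_meas, scr_umol_l = scr,
      on_dialysis = on_dial, inpatient = inpat
    )
    out_rows[[i]] <- data.frame(
      patient_id = pid,
      rrt_day = if (terminal_type == "rrt") terminal_day else NA_real_,
      death_day = if (terminal_type == "death") terminal_day else NA_real_,
      censor_day = if (terminal_type == "CENSORED") terminal_day else NA_real_
    )
    cov_rows[[i]] <- covi
  }

  empty_gt <- data.frame(patient_id = character(), ordinal = integer(),
                         start_day = numeric(), end_day = numeric(),
                         stage_sampled = integer(), stage_rule = integer(),
                         peak_multiplier = numeric())
  gt <- gt_rows[!vapply(gt_rows, is.null, logical(1))]
  structure(list(
    covariates = if (config$n_patients) do.call(rbind, cov_rows) else
      data.frame(patient_id = character(), age = numeric(),
                 sex = character(), ethnicity_black = logical(),
                 smoker = logical(), alcohol = logical(),
                 diabetes = logical(), prior_cv = logical(),
                 base_hospital = logical(),
                 primary_renal_disease = character()),
    labs = if (config$n_patients) do.call(rbind, lab_rows) else
      data.frame(patient_id = character(), time_days = numeric(),
                 scr_umol_l = numeric(), on_dialysis = logical(),
                 inpatient = logical()),
    outcomes = if (config$n_patients) do.call(rbind, out_rows) else
      data.frame(patient_id = character(), rrt_day = numeric(),
                 death_day = numeric(), censor_day = numeric()),
    ground_truth = if (length(gt)) do.call(rbind, gt) else empty_gt
  ), class = "aki_cohort", config = config)
}

#' @export
print.aki_cohort <- function(x, ...) {
  cat("<aki_cohort>", nrow(x$covariates), "patients,",
      nrow(x$labs), "creatinine measurements,",
      nrow(x$ground_truth), "injected AKI episodes\n")
  invisible(x)
}

#' Write a cohort to delimited files
#'
#' Writes `covariates.csv`, `labs.csv`, `outcomes.csv` and
#' `ground_truth_episodes.csv` (comma separated, header row; unobserved
#' outcome days are empty fields).
#'
#' @param cohort an `aki_cohort` from [generate_cohort()]
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "aki_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("covariates.csv", "labs.csv", "outcomes.csv",
                            "ground_truth_episodes.csv"))
  write.csv(cohort$covariates, paths[1], row.names = FALSE, na = "")
  write.csv(cohort$labs, paths[2], row.names = FALSE, na = "")
  write.csv(cohort$outcomes, paths[3], row.names = FALSE, na = "")
  write.csv(cohort$ground_truth, paths[4], row.names = FALSE, na = "")
  invisible(paths)
}

#' Read a cohort from delimited files
#'
#' Inverse of [write_cohort()]; the ground-truth file is optional (absent
#' for real data).
#'
#' @param dir directory containing `covariates.csv`, `labs.csv`,
#'   `outcomes.csv`
#' @return an `aki_cohort` list
#' @export
read_cohort <- function(dir) {
  covariates <- read.csv(file.path(dir, "covariates.csv"))
  labs <- read.csv(file.path(dir, "labs.csv"))
  outcomes <- read.csv(file.path(dir, "outcomes.csv"))
  gt_path <- file.path(dir, "ground_truth_episodes.csv")
  gt <- if (file.exists(gt_path)) read.csv(gt_path) else NULL
  structure(list(covariates = covariates, labs = labs, outcomes = outcomes,
                 ground_truth = gt), class = "aki_cohort")
}
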