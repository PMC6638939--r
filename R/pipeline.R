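#' Validate pipeline input tables
#'
#' Report-only schema and plausibility checks on the three input tables:
#' required columns, strictly increasing measurement times per patient,
#' positive creatinine with a plausibility band of 10-3000 micromol/L
#' (values outside it are flagged as warnings, not errors), orphan patient
#' ids across tables, patients with a single measurement (retained for
#' survival analysis but unable to raise flags), and outcome rows with no
#' observed day or negative days.
#'
#' @param labs,covariates,outcomes input tables (see [generate_cohort()]
#'   for the schema)
#' @return data frame with columns `severity` (`"error"`/`"warning"`),
#'   `table`, `patient_id`, `message`; zero rows when clean
#' @export
validate_inputs <- function(labs, covariates, outcomes) {
  v <- list()
  add <- function(severity, table, patient_id, message) {
    v[[length(v) + 1L]] <<- data.frame(
      severity = severity, table = table,
      patient_id = as.character(patient_id), message = message
    )
  }
  need <- list(
    labs = c("patient_id", "time_days", "scr_umol_l", "on_dialysis",
             "inpatient"),
    covariates = c("patient_id", "age", "sex", "ethnicity_black", "smoker",
                   "alcohol", "diabetes", "prior_cv", "base_hospital",
                   "primary_renal_disease"),
    outcomes = c("patient_id", "rrt_day", "death_day", "censor_day")
  )
  tabs <- list(labs = labs, covariates = covariates, outcomes = outcomes)
  for (tn in names(need)) {
    miss <- setdiff(need[[tn]], names(tabs[[tn]]))
    if (length(miss)) {
      add("error", tn, NA, paste("missing columns:",
                                 paste(miss, collapse = ", ")))
    }
  }
  if (nrow(do.call(rbind, v) %||% data.frame())) {
    out <- do.call(rbind, v)
    rownames(out) <- NULL
    return(out)
  }
  for (pid in unique(labs$patient_id)) {
    t <- labs$time_days[labs$patient_id == pid]
    if (length(t) > 1L && any(diff(t[order(t)]) <= 0)) {
      add("error", "labs", pid, "measurement times not strictly increasing")
    }
    if (length(t) == 1L) {
      add("warning", "labs", pid,
          "single creatinine measurement; no flags possible")
    }
  }
  bad_scr <- !is.finite(labs$scr_umol_l) | labs$scr_umol_l <= 0
  for (pid in unique(labs$patient_id[bad_scr])) {
    add("error", "labs", pid, "nonpositive or missing creatinine value")
  }
  implaus <- !bad_scr & (labs$scr_umol_l < 10 | labs$scr_umol_l > 3000)
  for (pid in unique(labs$patient_id[implaus])) {
    add("warning", "labs", pid,
        "creatinine outside the 10-3000 micromol/L plausibility band")
  }
  for (pid in setdiff(labs$patient_id, covariates$patient_id)) {
    add("error", "labs", pid, "patient id absent from covariate table")
  }
  for (pid in setdiff(outcomes$patient_id, covariates$patient_id)) {
    add("error", "outcomes", pid, "patient id absent from covariate table")
  }
  for (pid in setdiff(covariates$patient_id, outcomes$patient_id)) {
    add("error", "covariates", pid, "patient has no outcome row")
  }
  for (r in seq_len(nrow(outcomes))) {
    days <- c(outcomes$rrt_day[r], outcomes$death_day[r],
              outcomes$censor_day[r])
    if (all(is.na(days))) {
      add("error", "outcomes", outcomes$patient_id[r],
          "no outcome or censoring day observed")
    } else if (min(days, na.rm = TRUE) < 0) {
      add("error", "outcomes", outcomes$patient_id[r],
          "outcome day precedes recruitment")
    }
  }
  out <- do.call(rbind, v) %||%
    data.frame(severity = character(), table = character(),
               patient_id = character(), message = character())
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> validate -> detect -> eGFR/LMM ->
#' competing risks as one reproducible run, writing all tabular outputs as
#' CSV, all fits as JSON, and a manifest with configuration echo and MD5
#' checksums of every output. A rerun with the same configuration and seed
#' reproduces identical episode tables and fit point estimates.
#'
#' `config` is a named list (or a path to a YAML/JSON file holding one)
#' with exactly one of:
#'
#' * `simulate`: arguments for [cohort_config()] (e.g. `n_patients`), or
#' * `inputs`: list of paths `labs`, `covariates`, `outcomes` (CSV).
#'
#' Optional elements tune the stages: `detect` (`window_days`, `baseline`,
#' `lookback_days`, `anchor`), `egfr` (`pre_days`, `post_days`,
#' `covariate_cols`, `n_starts`), `survival` (`clock`, `ties`,
#' `max_periods`, `min_events`, `covariate_cols`), and `stages` (character
#' subset of `c("detect", "egfr", "survival")` to run after data
#' acquisition).
#'
#' @param config run configuration (list or file path)
#' @param outdir output directory, created if needed
#' @param seed integer seed overriding `config$simulate$seed`
#' @return invisibly, the manifest list (also written to `manifest.json`)
#' @export
run_pipeline <- function(config, outdir, seed = NULL) {
  t0 <- Sys.time()
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) {
    stop("configuration error: 'config' must be a list or a YAML/JSON path",
         call. = FALSE)
  }
  has_sim <- !is.null(config$simulate)
  has_inp <- !is.null(config$inputs)
  if (has_sim == has_inp) {
    stop("configuration error: exactly one of 'simulate' or 'inputs' ",
         "must be provided", call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% c("detect", "egfr", "survival")
  warnings_log <- character(0)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cohort <- run_stage("acquire", {
    if (has_sim) {
      sim_args <- config$simulate
      if (!inherits(sim_args, "cohort_config")) {
        if (!is.null(seed)) sim_args$seed <- seed
        sim_args <- do.call(cohort_config, sim_args)
      }
      co <- generate_cohort(sim_args)
      write_cohort(co, outdir)
      co
    } else {
      structure(list(
        labs = read.csv(config$inputs$labs),
        covariates = read.csv(config$inputs$covariates),
        outcomes = read.csv(config$inputs$outcomes),
        ground_truth = NULL
      ), class = "aki_cohort")
    }
  })

  run_stage("validate", {
    rep <- validate_inputs(cohort$labs, cohort$covariates, cohort$outcomes)
    errs <- rep[rep$severity == "error", , drop = FALSE]
    if (nrow(errs)) {
      stop(paste0(errs$table, "/", errs$patient_id, ": ", errs$message,
                  collapse = "; "))
    }
    warnings_log <<- c(warnings_log,
                       paste0(rep$table, "/", rep$patient_id, ": ",
                              rep$message))
    NULL
  })

  episodes <- NULL
  if ("detect" %in% stages) {
    episodes <- run_stage("detect", {
      dopt <- config$detect %||% list()
      ep <- detect_episodes(
        cohort$labs, cohort$outcomes,
        window_days = dopt$window_days %||% 7,
        baseline = dopt$baseline %||% "adjacent",
        lookback_days = dopt$lookback_days %||% 7,
        anchor = dopt$anchor %||% "latest"
      )
      write.csv(ep, file.path(outdir, "episodes.csv"), row.names = FALSE)
      ep
    })
  }

  if ("egfr" %in% stages) {
    run_stage("egfr", {
      eopt <- config$egfr %||% list()
      egfr_tab <- compute_egfr_table(
        cohort$labs, cohort$covariates, episodes,
        pre_days = eopt$pre_days %||% 30,
        post_days = eopt$post_days %||% 30
      )
      write.csv(egfr_tab, file.path(outdir, "egfr.csv"), row.names = FALSE)
      ld <- lmm_data(egfr_tab, cohort$covariates,
                     covariate_cols = eopt$covariate_cols)
      fit <- fit_lmm(ld, n_starts = eopt$n_starts %||% 3)
      if (!fit$converged) {
        warnings_log <<- c(warnings_log, "egfr: LMM optimiser did not converge")
      }
      jsonlite::write_json(
        list(beta_hat = as.list(fit$beta_hat),
             beta_se = as.list(fit$beta_se),
             sigma2_intercept_hat = fit$sigma2_intercept_hat,
             sigma2_process_hat = fit$sigma2_process_hat,
             phi_hat = fit$phi_hat,
             sigma2_noise_hat = fit$sigma2_noise_hat,
             loglik = fit$loglik, converged = fit$converged,
             n_obs = fit$n_obs, n_patients = fit$n_patients),
        file.path(outdir, "lmm_fit.json"),
        auto_unbox = TRUE, digits = NA
      )
      NULL
    })
  }

  if ("survival" %in% stages) {
    run_stage("survival", {
      sopt <- config$survival %||% list()
      records <- build_period_records(
        episodes %||% detect_episodes(cohort$labs, cohort$outcomes),
        cohort$outcomes,
        clock = sopt$clock %||% "gap",
        max_periods = sopt$max_periods %||% 4
      )
      fits <- fit_period_models(records, cohort$covariates,
                                covariate_cols = sopt$covariate_cols,
                                min_events = sopt$min_events %||% 5,
                                ties = sopt$ties %||% "efron")
      jsonlite::write_json(
        lapply(fits, function(pk) lapply(pk, serialize_cox_fit)),
        file.path(outdir, "fits.json"), auto_unbox = TRUE, digits = NA
      )
      cif_rows <- list()
      for (k in sort(unique(records$period))) {
        rk <- records[records$period == k, , drop = FALSE]
        ck <- aalen_johansen_cif(rk)
        if (nrow(ck)) {
          cif_rows[[length(cif_rows) + 1L]] <- cbind(period = k, ck)
        }
      }
      cif_tab <- if (length(cif_rows)) do.call(rbind, cif_rows) else
        data.frame(period = integer(), cause = character(),
                   time = numeric(), cif = numeric())
      write.csv(cif_tab, file.path(outdir, "cif.csv"), row.names = FALSE)
      jsonlite::write_json(consort_summary(episodes, records),
                           file.path(outdir, "consort.json"),
                           auto_unbox = TRUE, digits = NA)
      NULL
    })
  }

  files <- list.files(outdir, pattern = "\\.(csv|json)$")
  files <- setdiff(files, "manifest.json")
  manifest <- list(
    package_version = as.character(packageVersion("akicourse")),
    started = format(t0, "%Y-%m-%d %H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    stages = stages,
    config = config_echo(config),
    outputs = as.list(md5sum(file.path(outdir, files))),
    warnings = warnings_log
  )
  names(manifest$outputs) <- files
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# Echo a configuration as plain lists for the manifest.
config_echo <- function(config) {
  rapply(config, function(x) {
    if (is.function(x)) "<function>" else x
  }, how = "replace")
}

serialize_cox_fit <- function(f) {
  if (inherits(f, "cs_cox_skip")) {
    return(list(skipped = TRUE, note = f$note))
  }
  list(
    cause = f$cause, period = f$period,
    hr = as.list(f$hr), ci_lower = as.list(f$ci_lower),
    ci_upper = as.list(f$ci_upper), p = as.list(f$p),
    identifiable = as.list(f$identifiable),
    n = f$n, n_events = f$n_events, loglik = f$loglik,
    converged = f$converged
  )
}
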