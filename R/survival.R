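#' Partition follow-up into inter-episode periods
#'
#' Builds the recurrent-event competing-risks dataset: up to four periods
#' per patient (recruitment to first AKI; first to second; second to
#' third; after the third), each terminated by the first of the next AKI
#' episode (typed stage 1 vs stage 2/3), renal replacement therapy, death,
#' or censoring. In period 4 no further AKI events are typed; only
#' RRT/death/censoring terminate it. By default the clock is gap time —
#' it resets at each episode's end, the injury considered resolved when
#' its last flag closes — with a calendar-time option, and the next period
#' may alternatively be anchored at the episode's start.
#'
#' @param episodes episode table ([detect_episodes()] output)
#' @param outcomes outcome table: `patient_id`, `rrt_day`, `death_day`,
#'   `censor_day` (exactly the observed one non-missing)
#' @param clock `"gap"` (default; `entry_day = 0`, `exit_day` = time since
#'   period start) or `"calendar"` (entry/exit on the recruitment clock)
#' @param period_entry anchor of period k+1: episode k's `"end"` (default)
#'   or `"start"`
#' @param max_periods number of periods retained (default 4)
#' @param min_gap_days positive lower bound imposed on a period's duration
#'   when an outcome coincides with the period's start (default 0.5)
#' @return data frame of period records: `patient_id`, `period`,
#'   `entry_day`, `exit_day`, `event` (`AKI1`, `AKI23`, `RRT`, `DEATH`,
#'   `CENSORED`), `prev_aki_severe` (`NA` in period 1)
#' @export
build_period_records <- function(episodes, outcomes,
                                 clock = c("gap", "calendar"),
                                 period_entry = c("end", "start"),
                                 max_periods = 4, min_gap_days = 0.5) {
  clock <- match.arg(clock)
  period_entry <- match.arg(period_entry)
  anchor_col <- if (period_entry == "end") "end_day" else "start_day"
  rows <- vector("list", nrow(outcomes))
  for (r in seq_len(nrow(outcomes))) {
    pid <- outcomes$patient_id[r]
    days <- c(RRT = outcomes$rrt_day[r], DEATH = outcomes$death_day[r],
              CENSORED = outcomes$censor_day[r])
    if (all(is.na(days))) {
      stop("patient ", pid, " has no outcome or censoring day",
           call. = FALSE)
    }
    terminal_day <- min(days, na.rm = TRUE)
    terminal_type <- names(days)[which(days == terminal_day)][1L]
    if (terminal_day < 0) {
      stop("outcome precedes recruitment for patient ", pid, call. = FALSE)
    }
    eps <- episodes[episodes$patient_id == pid, , drop = FALSE]
    eps <- eps[order(eps$ordinal), , drop = FALSE]
    eps <- eps[eps$start_day < terminal_day, , drop = FALSE]
    nep <- nrow(eps)
    n_periods <- min(max_periods, nep + 1L)
    prec <- vector("list", n_periods)
    for (k in seq_len(n_periods)) {
      a <- if (k == 1L) 0 else eps[[anchor_col]][k - 1L]
      if (k <= nep && k < max_periods) {
        ev_day <- eps$start_day[k]
        ev <- if (eps$stage[k] >= 2L) "AKI23" else "AKI1"
      } else {
        ev_day <- terminal_day
        ev <- terminal_type
      }
      gap <- max(ev_day - a, min_gap_days)
      prec[[k]] <- data.frame(
        patient_id = pid, period = k,
        entry_day = if (clock == "gap") 0 else a,
        exit_day = if (clock == "gap") gap else a + gap,
        event = ev,
        prev_aki_severe = if (k == 1L) NA else eps$stage[k - 1L] >= 2L
      )
    }
    rows[[r]] <- do.call(rbind, prec)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cox partial log-likelihood with Efron tie correction
#'
#' Evaluates the cause-specific Cox partial log-likelihood at a given
#' coefficient vector over risk sets defined by `(entry, exit]`; subjects
#' experiencing other event types contribute as censored. With `d` tied
#' events at a time, the Efron correction averages the tied subjects out
#' of the risk set; `ties = "breslow"` keeps the full risk set for every
#' tied event.
#'
#' @param beta coefficient vector
#' @param exit event/censoring times
#' @param status 1 = event of the cause under study, 0 = otherwise
#' @param X design matrix (rows = subjects)
#' @param entry optional left-truncation entry times (default 0)
#' @param ties `"efron"` (default) or `"breslow"`
#' @return the partial log-likelihood (scalar; 0 when no events)
#' @export
cox_partial_loglik <- function(beta, exit, status, X,
                               entry = NULL, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  if (is.null(entry)) entry <- rep(0, length(exit))
  stopifnot(length(exit) == nrow(X), length(status) == nrow(X),
            length(beta) == ncol(X))
  eta <- drop(X %*% beta)
  w <- exp(eta)
  ll <- 0
  for (t in sort(unique(exit[status == 1]))) {
    D <- which(status == 1 & exit == t)
    R <- which(entry < t & exit >= t)
    d <- length(D)
    sR <- sum(w[R])
    sD <- sum(w[D])
    ll <- ll + sum(eta[D])
    if (ties == "efron") {
      ll <- ll - sum(log(sR - (seq_len(d) - 1) / d * sD))
    } else {
      ll <- ll - d * log(sR)
    }
  }
  ll
}

#' Fit a cause-specific Cox model for one period
#'
#' Treats the chosen cause as the event and all competing events as
#' censoring at their exit time, and maximises the Efron partial
#' likelihood by Newton-Raphson (via [survival::coxph()]). Covariates are
#' the baseline design (see [build_covariate_design()]); for periods
#' beyond the first, an indicator that the previous AKI episode was stage
#' 2/3 is added, so the severity of the last injury is a risk factor for
#' what happens next. Hazard ratios carry Wald 95% intervals and p-values.
#'
#' Coefficients that cannot be estimated — constant or collinear
#' covariates, or monotone likelihood (perfect separation) driving a
#' coefficient to infinity — are flagged `identifiable = FALSE` rather
#' than reported as real effects.
#'
#' @param records period records for a single period
#'   ([build_period_records()])
#' @param cause one of `"AKI1"`, `"AKI23"`, `"RRT"`, `"DEATH"`
#' @param covariates baseline covariate table
#' @param covariate_cols design columns to adjust for; `NULL` = all
#' @param ties tie handling, `"efron"` (default) or `"breslow"`
#' @return object of class `cs_cox_fit`: `cause`, `period`, `coef`, `se`,
#'   `hr`, `ci_lower`, `ci_upper`, `p`, `identifiable`, `n`, `n_events`,
#'   `loglik`, `converged`
#' @export
fit_cause_specific_cox <- function(records, cause, covariates,
                                   covariate_cols = NULL,
                                   ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (length(unique(records$period)) != 1L) {
    stop("records must all belong to one period", call. = FALSE)
  }
  period <- records$period[1L]
  status <- as.integer(records$event == cause)
  if (sum(status) < 1L) {
    stop("no events of cause '", cause, "' in these records", call. = FALSE)
  }
  xmat <- build_covariate_design(covariates)
  if (!is.null(covariate_cols)) xmat <- xmat[, covariate_cols, drop = FALSE]
  X <- xmat[match(records$patient_id, rownames(xmat)), , drop = FALSE]
  if (period >= 2L) {
    X <- cbind(X, prev_aki_severe = as.numeric(records$prev_aki_severe))
  }
  use_entry <- any(records$entry_day > 0)
  df <- data.frame(
    entry = records$entry_day, exit = records$exit_day, status = status
  )
  df <- cbind(df, as.data.frame(X))
  fml <- if (use_entry) {
    stats::as.formula(paste("survival::Surv(entry, exit, status) ~",
                            paste(colnames(X), collapse = " + ")))
  } else {
    stats::as.formula(paste("survival::Surv(exit, status) ~",
                            paste(colnames(X), collapse = " + ")))
  }
  warn <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = ties),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))[names(co)]
  se[is.na(co)] <- NA_real_
  identifiable <- !is.na(co) & is.finite(se) & abs(co) < 15 & se < 100
  z <- co / se
  structure(list(
    cause = cause, period = period,
    coef = co, se = se,
    hr = exp(co),
    ci_lower = exp(co - qnorm(0.975) * se),
    ci_upper = exp(co + qnorm(0.975) * se),
    p = 2 * pnorm(-abs(z)),
    identifiable = identifiable,
    n = nrow(records), n_events = sum(status),
    loglik = fit$loglik[length(fit$loglik)],
    converged = length(warn) == 0L,
    warnings = warn
  ), class = "cs_cox_fit")
}

#' @export
print.cs_cox_fit <- function(x, ...) {
  cat(sprintf("Cause-specific Cox fit: %s, period %d (%d events / %d at risk)\n",
              x$cause, x$period, x$n_events, x$n))
  tab <- data.frame(HR = round(x$hr, 3),
                    `2.5%` = round(x$ci_lower, 3),
                    `97.5%` = round(x$ci_upper, 3),
                    p = signif(x$p, 3),
                    check.names = FALSE)
  tab$flag <- ifelse(x$identifiable, "", "non-identifiable")
  print(tab)
  invisible(x)
}

#' Fit all cause-specific models across periods
#'
#' Convenience loop over periods and causes. Period 4 admits only RRT and
#' death as events. Cause/period combinations with fewer events than
#' `min_events` are skipped (recorded as `NULL` with a note attribute).
#'
#' @param records full period-record table
#' @param covariates baseline covariate table
#' @param covariate_cols design columns to adjust for
#' @param min_events minimum events required to attempt a fit
#' @param ties tie handling
#' @return nested list `fits[[period]][[cause]]` of [fit_cause_specific_cox()]
#'   results
#' @export
fit_period_models <- function(records, covariates, covariate_cols = NULL,
                              min_events = 5, ties = "efron") {
  out <- list()
  for (k in sort(unique(records$period))) {
    rk <- records[records$period == k, , drop = FALSE]
    causes <- if (k >= 4) c("RRT", "DEATH") else
      c("AKI1", "AKI23", "RRT", "DEATH")
    pk <- list()
    for (cz in causes) {
      n_ev <- sum(rk$event == cz)
      pk[[cz]] <- if (n_ev >= min_events) {
        tryCatch(
          fit_cause_specific_cox(rk, cz, covariates,
                                 covariate_cols = covariate_cols,
                                 ties = ties),
          error = function(e) structure(list(note = conditionMessage(e)),
                                        class = "cs_cox_skip")
        )
      } else {
        structure(list(note = sprintf("only %d events", n_ev)),
                  class = "cs_cox_skip")
      }
    }
    out[[paste0("period_", k)]] <- pk
  }
  out
}

#' Aalen-Johansen cumulative incidence functions
#'
#' Nonparametric cause-specific cumulative incidence in the presence of
#' competing risks:
#' \deqn{CIF_k(t) = \sum_{t_i \le t} S(t_i-)\, d_{k,i}/n_i}
#' where \eqn{S} is the all-cause Kaplan-Meier survivor function,
#' \eqn{d_{k,i}} the cause-k events at \eqn{t_i} and \eqn{n_i} the number
#' at risk. With a single cause this reduces to one minus the Kaplan-Meier
#' curve; with no censoring the terminal values are the empirical cause
#' proportions.
#'
#' @param records period records for one period (gap-time clock,
#'   `entry_day = 0`)
#' @param causes causes to report (default: every non-censoring event
#'   present)
#' @return data frame: `cause`, `time`, `cif` (step-function values at the
#'   event times); the all-cause Kaplan-Meier curve is attached as
#'   attribute `"km"` (data frame `time`, `surv`)
#' @export
aalen_johansen_cif <- function(records, causes = NULL) {
  if (any(records$entry_day != 0)) {
    stop("aalen_johansen_cif expects gap-time records (entry_day = 0)",
         call. = FALSE)
  }
  if (is.null(causes)) {
    causes <- setdiff(sort(unique(records$event)), "CENSORED")
  }
  ev_times <- sort(unique(records$exit_day[records$event != "CENSORED"]))
  if (!length(ev_times)) {
    out <- data.frame(cause = character(), time = numeric(),
                      cif = numeric())
    attr(out, "km") <- data.frame(time = numeric(), surv = numeric())
    return(out)
  }
  s_prev <- 1
  surv <- numeric(length(ev_times))
  cif <- matrix(0, length(ev_times), length(causes),
                dimnames = list(NULL, causes))
  cif_cum <- setNames(numeric(length(causes)), causes)
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    n_risk <- sum(records$exit_day >= t)
    d_all <- sum(records$exit_day == t & records$event != "CENSORED")
    for (cz in causes) {
      d_k <- sum(records$exit_day == t & records$event == cz)
      cif_cum[cz] <- cif_cum[cz] + s_prev * d_k / n_risk
    }
    s_prev <- s_prev * (1 - d_all / n_risk)
    surv[i] <- s_prev
    cif[i, ] <- cif_cum
  }
  out <- do.call(rbind, lapply(causes, function(cz) {
    data.frame(cause = cz, time = ev_times, cif = cif[, cz])
  }))
  rownames(out) <- NULL
  attr(out, "km") <- data.frame(time = ev_times, surv = surv)
  out
}

#' Consort-style accounting of the episode cascade
#'
#' Tabulates, for each period, the number of patients entering and the
#' breakdown of how the period ended (stage 1 AKI, stage 2/3 AKI, RRT,
#' death, censoring), together with the detected stage split of the
#' period's AKI events. Counts at each level sum to the level above:
#' every period entrant exits by exactly one event, and period k+1
#' entrants equal the AKI events of period k.
#'
#' @param episodes episode table
#' @param records period-record table ([build_period_records()])
#' @return nested list with `n_patients`, `patients_with_aki`,
#'   `total_episodes`, and per-period counts
#' @export
consort_summary <- function(episodes, records) {
  per_period <- list()
  for (k in sort(unique(records$period))) {
    rk <- records[records$period == k, , drop = FALSE]
    ev <- c(AKI1 = sum(rk$event == "AKI1"),
            AKI23 = sum(rk$event == "AKI23"),
            RRT = sum(rk$event == "RRT"),
            DEATH = sum(rk$event == "DEATH"),
            CENSORED = sum(rk$event == "CENSORED"))
    ep_k <- episodes[episodes$ordinal == k, , drop = FALSE]
    per_period[[paste0("period_", k)]] <- list(
      n_at_risk = nrow(rk),
      events = as.list(ev),
      aki_stage_split = as.list(c(
        stage1 = sum(ep_k$stage == 1),
        stage2 = sum(ep_k$stage == 2),
        stage3 = sum(ep_k$stage == 3)
      ))
    )
  }
  list(
    n_patients = length(unique(records$patient_id)),
    patients_with_aki = length(unique(episodes$patient_id)),
    total_episodes = nrow(episodes),
    periods = per_period
  )
}
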