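# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately written in a different style from the package
# code (scalar if-chains, explicit loops, or calls into survival/nlme) so
# that agreement is evidence, not tautology.

flat_series <- function(times, scr = 100, pid = "PX") {
  scr_series(pid, times, rep(scr, length(times)))
}

# single-patient covariate row with neutral defaults
one_patient_covariates <- function(pid = "PX", age = 66.8, sex = "male",
                                   smoker = FALSE, alcohol = FALSE,
                                   diabetes = FALSE, prior_cv = FALSE,
                                   base_hospital = FALSE,
                                   prd = "other") {
  data.frame(patient_id = pid, age = age, sex = sex,
             ethnicity_black = FALSE, smoker = smoker, alcohol = alcohol,
             diabetes = diabetes, prior_cv = prior_cv,
             base_hospital = base_hospital, primary_renal_disease = prd,
             stringsAsFactors = FALSE)
}

many_patient_covariates <- function(pids, ...) {
  do.call(rbind, lapply(pids, function(p) one_patient_covariates(p, ...)))
}

period_records_df <- function(pids, exit, event, period = 1,
                              prev_severe = NA) {
  data.frame(patient_id = pids, period = period, entry_day = 0,
             exit_day = exit, event = event,
             prev_aki_severe = prev_severe)
}

# --- independent scalar re-implementation of the printed staging rules ---
oracle_classify <- function(s, t) {
  rc <- (t - s) / s
  is_aki <- FALSE
  if (rc >= 0.5) is_aki <- TRUE
  if (t - s >= 26.5) is_aki <- TRUE
  if (!is_aki) return(0L)
  if (rc > 2) return(3L)
  if (t >= 353.6) return(3L)
  if (rc >= 1) return(2L)
  1L
}

# --- brute-force chaining of flag times into 7-day-linked groups ---
# With a window anchored at the latest flag, chaining is equivalent to
# cutting wherever the gap between consecutive flags exceeds the window.
oracle_chain <- function(times, window = 7) {
  if (!length(times)) return(integer(0))
  cumsum(c(1L, as.integer(diff(times) > window)))
}

# --- exhaustive 1-to-1 episode matching (maximise matches, then minimise
# total distance) over all injective assignments; feasible for <= 6 ---
oracle_match <- function(d, g, tol) {
  nd <- length(d); ng <- length(g)
  best <- list(n = -1L, cost = Inf)
  assign_next <- function(i, used, n, cost) {
    if (i > nd) {
      if (n > best$n || (n == best$n && cost < best$cost)) {
        best <<- list(n = n, cost = cost)
      }
      return(invisible())
    }
    assign_next(i + 1L, used, n, cost) # leave d[i] unmatched
    for (j in seq_len(ng)) {
      if (!used[j] && abs(d[i] - g[j]) <= tol) {
        used[j] <- TRUE
        assign_next(i + 1L, used, n + 1L, cost + abs(d[i] - g[j]))
        used[j] <- FALSE
      }
    }
  }
  assign_next(1L, rep(FALSE, ng), 0L, 0)
  best
}

# --- independent follow-up partitioner (imperative, calendar walk) ---
oracle_partition <- function(starts, ends, stages, terminal_day,
                             terminal_type, max_periods = 4) {
  keep <- starts < terminal_day
  starts <- starts[keep]; ends <- ends[keep]; stages <- stages[keep]
  out <- list()
  k <- 1L
  clock_zero <- 0
  repeat {
    if (k > max_periods) break
    has_next_aki <- k <= length(starts) && k < max_periods
    if (has_next_aki) {
      ev_day <- starts[k]
      ev <- if (stages[k] >= 2) "AKI23" else "AKI1"
    } else {
      ev_day <- terminal_day
      ev <- terminal_type
    }
    out[[k]] <- data.frame(
      period = k,
      exit_day = max(ev_day - clock_zero, 0.5),
      event = ev,
      prev_aki_severe = if (k == 1L) NA else stages[k - 1L] >= 2
    )
    if (!has_next_aki) break
    clock_zero <- ends[k]
    k <- k + 1L
  }
  do.call(rbind, out)
}

# --- dense multivariate-normal log-density on the stacked block-diagonal
# covariance, via determinant() and solve() ---
oracle_lmm_loglik <- function(params, data) {
  total <- 0
  for (pd in data) {
    n <- length(pd$y)
    V <- matrix(params$sigma2_intercept, n, n) +
      params$sigma2_process *
        exp(-abs(outer(pd$t, pd$t, "-")) / params$phi_days) +
      diag(params$sigma2_noise, n)
    r <- pd$y - drop(pd$X %*% params$beta)
    total <- total - 0.5 * (n * log(2 * pi) +
                              as.numeric(determinant(V)$modulus) +
                              drop(t(r) %*% solve(V) %*% r))
  }
  total
}

# random small survival instance with day-granular ties
random_cox_instance <- function(n_max = 6) {
  n <- sample(3:n_max, 1)
  list(
    time = sample(1:4, n, replace = TRUE),
    status = rbinom(n, 1, 0.7),
    X = cbind(x1 = round(rnorm(n), 2), x2 = rbinom(n, 1, 0.5)),
    beta = round(rnorm(2, sd = 0.8), 2)
  )
}
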