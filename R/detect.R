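#' Relative change in serum creatinine between two measurements
#'
#' The e-alert statistic: \eqn{RC = (SCr_t - SCr_s)/SCr_s} where `s` is the
#' earlier and `t` the later measurement. Negative values indicate
#' recovery and never raise a flag.
#'
#' @param scr_s,scr_t serum creatinine at the earlier (`s`) and later (`t`)
#'   measurement, micromol/L; vectorised
#' @return dimensionless relative change
#' @examples
#' relative_change(100, 150) # 0.5
#' @export
relative_change <- function(scr_s, scr_t) {
  if (any(!is.finite(scr_s)) || any(scr_s <= 0)) {
    stop("baseline creatinine 'scr_s' must be positive", call. = FALSE)
  }
  (scr_t - scr_s) / scr_s
}

#' Classify a creatinine pair into an AKI stage
#'
#' Applies the creatinine-only staging rules to a successive pair of
#' measurements. A pair qualifies as AKI when the relative change reaches
#' 0.5 or the absolute increase reaches 26.5 micromol/L. Among qualifying
#' pairs the stage is:
#'
#' * stage 1: \eqn{0.5 \le RC < 1}, or absolute increase \eqn{\ge} 26.5
#'   micromol/L;
#' * stage 2: \eqn{1 \le RC \le 2};
#' * stage 3: \eqn{RC > 2}, or final creatinine \eqn{\ge} 353.6 micromol/L.
#'
#' The absolute-level 353.6 micromol/L criterion promotes a pair to stage 3
#' only when the pair already qualifies by an increase criterion: in an
#' advanced-CKD population many patients chronically exceed that level, and
#' a standing creatinine above 353.6 with no acute rise is chronic disease,
#' not an injury event. Stage 3 through initiation of renal replacement
#' therapy is handled at episode level (see [merge_flags_to_episodes()]),
#' not here.
#'
#' @inheritParams relative_change
#' @return integer stage per pair: 0 (no AKI), 1, 2 or 3
#' @examples
#' classify_pair(100, 150)   # RC = 0.5 -> stage 1
#' classify_pair(200, 230)   # increase 30 >= 26.5 -> stage 1
#' classify_pair(100, 350)   # RC = 2.5 -> stage 3
#' @export
classify_pair <- function(scr_s, scr_t) {
  if (any(!is.finite(scr_s)) || any(scr_s <= 0) ||
      any(!is.finite(scr_t)) || any(scr_t <= 0)) {
    stop("creatinine values must be positive", call. = FALSE)
  }
  rc <- (scr_t - scr_s) / scr_s
  inc <- scr_t - scr_s
  qualifies <- rc >= 0.5 | inc >= 26.5
  stage <- integer(length(rc))
  stage[qualifies] <- 1L
  stage[qualifies & rc >= 1] <- 2L
  stage[qualifies & (rc > 2 | scr_t >= 353.6)] <- 3L
  stage
}

#' Flag AKI alerts in a creatinine series
#'
#' Scans a (dialysis-free) creatinine series and emits one flag for every
#' comparison whose [classify_pair()] stage is nonzero. By default the
#' comparison is between adjacent measurements (`t = s + 1`), the minimal
#' reading of "two successive measurements". With `baseline = "rolling"`
#' each measurement is instead compared against the minimum creatinine in
#' the preceding `lookback_days`; this recovers slow rises that dense
#' sampling splits into many small increments, at the price of a baseline
#' definition the adjacent-pair rule does not use.
#'
#' @param series an [scr_series()]; must not contain dialysis-flagged
#'   values (apply [exclude_dialysis_values()] first)
#' @param baseline `"adjacent"` (default) or `"rolling"`
#' @param lookback_days rolling-baseline window, days (used only when
#'   `baseline = "rolling"`)
#' @return data frame of flags: `s_index`, `t_index`, `rc`, `abs_increase`,
#'   `stage`, `flag_time` — ordered by time; zero rows when nothing flags
#' @export
flag_series <- function(series, baseline = c("adjacent", "rolling"),
                        lookback_days = 7) {
  stopifnot(inherits(series, "scr_series"))
  baseline <- match.arg(baseline)
  if (any(series$on_dialysis)) {
    stop("series still contains dialysis-flagged values; ",
         "apply exclude_dialysis_values() first", call. = FALSE)
  }
  empty <- data.frame(s_index = integer(), t_index = integer(),
                      rc = numeric(), abs_increase = numeric(),
                      stage = integer(), flag_time = numeric())
  n <- length(series$times)
  if (n < 2L) return(empty)
  if (baseline == "adjacent") {
    s_idx <- seq_len(n - 1L)
    t_idx <- s_idx + 1L
  } else {
    t_idx <- 2:n
    s_idx <- vapply(t_idx, function(t) {
      win <- which(series$times >= series$times[t] - lookback_days &
                     series$times < series$times[t])
      if (!length(win)) return(NA_integer_)
      win[which.min(series$scr[win])]
    }, integer(1))
    keep <- !is.na(s_idx)
    s_idx <- s_idx[keep]
    t_idx <- t_idx[keep]
  }
  if (!length(t_idx)) return(empty)
  stage <- classify_pair(series$scr[s_idx], series$scr[t_idx])
  hit <- stage > 0L
  data.frame(
    s_index = s_idx[hit],
    t_index = t_idx[hit],
    rc = relative_change(series$scr[s_idx[hit]], series$scr[t_idx[hit]]),
    abs_increase = series$scr[t_idx[hit]] - series$scr[s_idx[hit]],
    stage = stage[hit],
    flag_time = series$times[t_idx[hit]]
  )
}

#' Merge AKI flags into staged episodes
#'
#' Flags raised within 7 days of each other belong to the same injury
#' event. Flags are chained: a flag joins the open episode when its time is
#' at most `window_days` after the episode's latest flag (with
#' `anchor = "first"` the window is measured from the episode's first flag
#' instead). The episode grade follows the nadir-of-function rule — the
#' greatest creatinine increase observed during the episode: when the
#' originating `series` is supplied, the stage is the maximum of the
#' contributing flag stages and of [classify_pair()] applied to the lowest
#' creatinine preceding the episode peak versus the peak itself. Initiation
#' of renal replacement therapy during an episode (within `window_days` of
#' its last flag) makes that episode stage 3.
#'
#' @param flags flag data frame from [flag_series()], time-ordered
#' @param rrt_day optional day of renal replacement therapy initiation
#' @param window_days merge window, days (default 7)
#' @param series optional [scr_series()] the flags came from; enables the
#'   nadir-of-function grade
#' @param anchor `"latest"` (default; chained window) or `"first"`
#' @return data frame of episodes: `ordinal`, `start_day`, `end_day`,
#'   `stage`, `n_flags`
#' @export
merge_flags_to_episodes <- function(flags, rrt_day = NULL, window_days = 7,
                                    series = NULL,
                                    anchor = c("latest", "first")) {
  anchor <- match.arg(anchor)
  empty <- data.frame(ordinal = integer(), start_day = numeric(),
                      end_day = numeric(), stage = integer(),
                      n_flags = integer())
  if (is.null(flags) || !nrow(flags)) return(empty)
  if (is.unsorted(flags$flag_time)) {
    stop("flags must be ordered by flag_time", call. = FALSE)
  }
  grp <- integer(nrow(flags))
  grp[1L] <- 1L
  anchor_time <- flags$flag_time[1L]
  for (i in seq_len(nrow(flags))[-1L]) {
    if (flags$flag_time[i] <= anchor_time + window_days) {
      grp[i] <- grp[i - 1L]
      if (anchor == "latest") anchor_time <- flags$flag_time[i]
    } else {
      grp[i] <- grp[i - 1L] + 1L
      anchor_time <- flags$flag_time[i]
    }
  }
  eps <- lapply(split(seq_len(nrow(flags)), grp), function(ii) {
    fl <- flags[ii, , drop = FALSE]
    stage <- max(fl$stage)
    if (!is.null(series)) {
      i0 <- min(fl$s_index)
      i1 <- max(fl$t_index)
      v <- series$scr[i0:i1]
      peak <- which.max(v)
      nadir <- min(v[seq_len(peak)])
      if (nadir < v[peak]) {
        stage <- max(stage, classify_pair(nadir, v[peak]))
      }
    }
    data.frame(start_day = min(fl$flag_time), end_day = max(fl$flag_time),
               stage = as.integer(stage), n_flags = nrow(fl))
  })
  out <- do.call(rbind, eps)
  out <- out[order(out$start_day), , drop = FALSE]
  if (!is.null(rrt_day) && length(rrt_day) == 1L && is.finite(rrt_day)) {
    inside <- rrt_day >= out$start_day & rrt_day <= out$end_day + window_days
    out$stage[inside] <- 3L
  }
  out <- cbind(ordinal = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Peri-AKI exclusion mask for eGFR measurements
#'
#' Marks measurements falling in the immediate peri-AKI period — from
#' `pre_days` before an episode's start to `post_days` after its end — for
#' exclusion from eGFR trajectory modelling, where acute excursions would
#' otherwise be mistaken for chronic decline.
#'
#' @param times measurement times (days) or an [scr_series()]
#' @param episodes episode data frame with `start_day`, `end_day`
#' @param pre_days,post_days window extension, days (default 30 each)
#' @return logical vector, `TRUE` = excluded (peri-AKI)
#' @export
peri_aki_egfr_mask <- function(times, episodes, pre_days = 30, post_days = 30) {
  if (inherits(times, "scr_series")) times <- times$times
  mask <- rep(FALSE, length(times))
  if (is.null(episodes) || !nrow(episodes)) return(mask)
  for (k in seq_len(nrow(episodes))) {
    mask <- mask | (times >= episodes$start_day[k] - pre_days &
                      times <= episodes$end_day[k] + post_days)
  }
  mask
}

#' Detect AKI episodes for a whole cohort
#'
#' Convenience wrapper running [exclude_dialysis_values()],
#' [flag_series()] and [merge_flags_to_episodes()] for each patient in a
#' laboratory table, attaching renal-replacement-therapy days from the
#' outcome table for the stage-3 RRT rule.
#'
#' @param labs laboratory table (see [split_series()])
#' @param outcomes optional outcome table with `patient_id`, `rrt_day`
#' @param window_days episode merge window, days
#' @param baseline,lookback_days passed to [flag_series()]
#' @param anchor passed to [merge_flags_to_episodes()]
#' @return episode data frame: `patient_id`, `ordinal`, `start_day`,
#'   `end_day`, `stage`, `n_flags`
#' @export
detect_episodes <- function(labs, outcomes = NULL, window_days = 7,
                            baseline = c("adjacent", "rolling"),
                            lookback_days = 7,
                            anchor = c("latest", "first")) {
  baseline <- match.arg(baseline)
  anchor <- match.arg(anchor)
  series <- split_series(labs)
  res <- lapply(series, function(s) {
    s <- exclude_dialysis_values(s)
    fl <- flag_series(s, baseline = baseline, lookback_days = lookback_days)
    rrt <- NULL
    if (!is.null(outcomes)) {
      r <- outcomes$rrt_day[outcomes$patient_id == s$patient_id]
      if (length(r) == 1L && !is.na(r)) rrt <- r
    }
    ep <- merge_flags_to_episodes(fl, rrt_day = rrt,
                                  window_days = window_days,
                                  series = s, anchor = anchor)
    if (nrow(ep)) cbind(patient_id = s$patient_id, ep) else NULL
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    return(data.frame(patient_id = character(), ordinal = integer(),
                      start_day = numeric(), end_day = numeric(),
                      stage = integer(), n_flags = integer()))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Compare detected episodes against ground truth
#'
#' Matches detected episodes to ground-truth episodes one-to-one within
#' each patient by start-time proximity: both lists are time-ordered, and
#' an optimal non-crossing alignment maximises the number of matches
#' within `match_tolerance_days` (ties broken by minimal total time
#' discrepancy). Reports sensitivity (fraction of truth episodes matched),
#' the fraction matched with the correct stage, and the 3x3 stage confusion
#' matrix over matched pairs.
#'
#' @param detected episode table (`patient_id`, `start_day`, `stage`)
#' @param truth ground-truth episode table (same columns; the generator's
#'   `stage_rule` column is used as the truth stage when present)
#' @param match_tolerance_days maximum start-time discrepancy for a match
#' @return list: `sensitivity`, `stage_accuracy` (correct-stage fraction
#'   among truth), `confusion` (truth stage x detected stage), `n_truth`,
#'   `n_detected`, `n_matched`, `false_positives`
#' @export
detection_performance <- function(detected, truth, match_tolerance_days = 7) {
  truth_stage_col <- if ("stage_rule" %in% names(truth)) "stage_rule" else "stage"
  confusion <- matrix(0L, 3, 3,
                      dimnames = list(truth = 1:3, detected = 1:3))
  n_truth <- nrow(truth)
  n_detected <- nrow(detected)
  n_matched <- 0L
  n_correct <- 0L
  for (pid in unique(c(detected$patient_id, truth$patient_id))) {
    d <- detected[detected$patient_id == pid, , drop = FALSE]
    g <- truth[truth$patient_id == pid, , drop = FALSE]
    d <- d[order(d$start_day), , drop = FALSE]
    g <- g[order(g$start_day), , drop = FALSE]
    m <- match_episode_times(d$start_day, g$start_day, match_tolerance_days)
    for (k in seq_len(nrow(m))) {
      ds <- d$stage[m$i[k]]
      gs <- g[[truth_stage_col]][m$j[k]]
      n_matched <- n_matched + 1L
      if (ds >= 1 && ds <= 3 && gs >= 1 && gs <= 3) {
        confusion[gs, ds] <- confusion[gs, ds] + 1L
      }
      if (identical(as.integer(ds), as.integer(gs))) n_correct <- n_correct + 1L
    }
  }
  list(
    sensitivity = if (n_truth) n_matched / n_truth else NA_real_,
    stage_accuracy = if (n_truth) n_correct / n_truth else NA_real_,
    confusion = confusion,
    n_truth = n_truth,
    n_detected = n_detected,
    n_matched = n_matched,
    false_positives = n_detected - n_matched
  )
}

# Optimal non-crossing 1-to-1 alignment of two sorted time vectors:
# maximise matches with |d - g| <= tol, tie-break on minimal total |d - g|.
# Returns data.frame(i, j) of matched index pairs.
match_episode_times <- function(d, g, tol) {
  nd <- length(d)
  ng <- length(g)
  if (!nd || !ng) return(data.frame(i = integer(), j = integer()))
  # DP over prefixes; score = (n_matches, -total_distance)
  best_n <- matrix(0L, nd + 1L, ng + 1L)
  best_c <- matrix(0, nd + 1L, ng + 1L)
  move <- matrix(0L, nd + 1L, ng + 1L) # 1 = match, 2 = skip d, 3 = skip g
  for (i in seq_len(nd)) {
    for (j in seq_len(ng)) {
      n1 <- best_n[i, j + 1L]; c1 <- best_c[i, j + 1L]      # skip d[i]
      n2 <- best_n[i + 1L, j]; c2 <- best_c[i + 1L, j]      # skip g[j]
      nb <- n1; cb <- c1; mv <- 2L
      if (n2 > nb || (n2 == nb && c2 < cb)) { nb <- n2; cb <- c2; mv <- 3L }
      dist <- abs(d[i] - g[j])
      if (dist <= tol) {
        n3 <- best_n[i, j] + 1L
        c3 <- best_c[i, j] + dist
        if (n3 > nb || (n3 == nb && c3 < cb)) { nb <- n3; cb <- c3; mv <- 1L }
      }
      best_n[i + 1L, j + 1L] <- nb
      best_c[i + 1L, j + 1L] <- cb
      move[i + 1L, j + 1L] <- mv
    }
  }
  i <- nd; j <- ng
  mi <- integer(0); mj <- integer(0)
  while (i > 0L && j > 0L) {
    mv <- move[i + 1L, j + 1L]
    if (mv == 1L) {
      mi <- c(i, mi); mj <- c(j, mj); i <- i - 1L; j <- j - 1L
    } else if (mv == 2L) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  data.frame(i = mi, j = mj)
}
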