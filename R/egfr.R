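#' Four-variable MDRD estimated glomerular filtration rate
#'
#' Computes eGFR (ml/min/1.73m^2) from serum creatinine in micromol/L using
#' the 4-variable MDRD study equation with the standard 88.4 micromol/L per
#' mg/dL conversion:
#' \deqn{175 \cdot (SCr/88.4)^{-1.154} \cdot age^{-0.203} \cdot 0.742^{[female]} \cdot 1.212^{[black]}}
#'
#' @param scr serum creatinine, micromol/L (vectorised, must be > 0)
#' @param age_years age in years (> 0)
#' @param female logical, female sex
#' @param black logical, black ethnicity
#' @return eGFR in ml/min/1.73m^2
#' @examples
#' mdrd_egfr(88.4, 50, female = FALSE, black = FALSE)
#' @export
mdrd_egfr <- function(scr, age_years, female = FALSE, black = FALSE) {
  if (any(!is.finite(scr)) || any(scr <= 0)) {
    stop("'scr' must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(age_years)) || any(age_years <= 0)) {
    stop("'age_years' must be positive and finite", call. = FALSE)
  }
  175 * (scr / 88.4)^(-1.154) * age_years^(-0.203) *
    ifelse(female, 0.742, 1) * ifelse(black, 1.212, 1)
}

#' Serum creatinine implied by an MDRD eGFR
#'
#' Inverts [mdrd_egfr()]: given an eGFR value and demographics, returns the
#' creatinine (micromol/L) that the 4-variable MDRD equation maps to it.
#' Used by the cohort generator to turn simulated eGFR trajectories into
#' laboratory creatinine values.
#'
#' @inheritParams mdrd_egfr
#' @param egfr eGFR, ml/min/1.73m^2 (> 0)
#' @return serum creatinine, micromol/L
#' @export
scr_from_egfr <- function(egfr, age_years, female = FALSE, black = FALSE) {
  if (any(!is.finite(egfr)) || any(egfr <= 0)) {
    stop("'egfr' must be positive and finite", call. = FALSE)
  }
  demog <- 175 * age_years^(-0.203) * ifelse(female, 0.742, 1) *
    ifelse(black, 1.212, 1)
  88.4 * (egfr / demog)^(-1 / 1.154)
}

#' Exponential serial correlation
#'
#' Correlation between two measurement times under the exponential
#' correlation model of the serial Gaussian process,
#' \eqn{\rho(u) = \exp(-|u|/\phi)}.
#'
#' @param t1,t2 times (days); vectorised
#' @param phi correlation range parameter, days (> 0)
#' @return correlation in (0, 1]
#' @export
exp_correlation <- function(t1, t2, phi) {
  if (!is.numeric(phi) || length(phi) != 1L || !is.finite(phi) || phi <= 0) {
    stop("'phi' must be a single positive number", call. = FALSE)
  }
  exp(-abs(t1 - t2) / phi)
}

#' eGFR table for a cohort
#'
#' Joins the laboratory table to the baseline covariates and computes MDRD
#' eGFR for every measurement. When episodes are supplied, a logical
#' `included` column marks measurements outside the peri-AKI exclusion
#' window (see [peri_aki_egfr_mask()]); peri-AKI values are flagged rather
#' than dropped.
#'
#' @param labs data frame with `patient_id`, `time_days`, `scr_umol_l`,
#'   `on_dialysis`
#' @param covariates data frame with `patient_id`, `age`, `sex`
#'   ("male"/"female"), `ethnicity_black` (logical or 0/1)
#' @param episodes optional episode table as returned by
#'   [detect_episodes()]
#' @param pre_days,post_days peri-AKI exclusion window around each episode
#' @return data frame: `patient_id`, `time_days`, `egfr`, `included`
#' @export
compute_egfr_table <- function(labs, covariates, episodes = NULL,
                               pre_days = 30, post_days = 30) {
  idx <- match(labs$patient_id, covariates$patient_id)
  if (anyNA(idx)) {
    stop("labs contain patient ids absent from the covariate table",
         call. = FALSE)
  }
  keep <- !as.logical(labs$on_dialysis)
  out <- data.frame(
    patient_id = labs$patient_id,
    time_days = labs$time_days,
    egfr = mdrd_egfr(labs$scr_umol_l,
                     covariates$age[idx],
                     covariates$sex[idx] == "female",
                     as.logical(covariates$ethnicity_black[idx])),
    included = keep
  )
  if (!is.null(episodes) && nrow(episodes)) {
    for (pid in unique(out$patient_id)) {
      sel <- out$patient_id == pid
      eps <- episodes[episodes$patient_id == pid, , drop = FALSE]
      if (!nrow(eps)) next
      excl <- peri_aki_egfr_mask(out$time_days[sel], eps,
                                 pre_days = pre_days, post_days = post_days)
      out$included[sel] <- out$included[sel] & !excl
    }
  }
  out
}
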