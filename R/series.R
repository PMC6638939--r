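#' One patient's creatinine series
#'
#' Validating constructor for a single patient's longitudinal serum
#' creatinine record: measurement times (days from recruitment, strictly
#' increasing), creatinine values (micromol/L, positive) and per-measurement
#' dialysis / inpatient flags.
#'
#' @param patient_id scalar identifier
#' @param times numeric, day offsets from recruitment, strictly increasing
#' @param scr numeric, serum creatinine micromol/L, positive
#' @param on_dialysis logical, value drawn while on dialysis (default all
#'   `FALSE`)
#' @param inpatient logical, inpatient sample (default all `FALSE`)
#' @return an object of class `scr_series`
#' @export
scr_series <- function(patient_id, times, scr,
                       on_dialysis = rep(FALSE, length(times)),
                       inpatient = rep(FALSE, length(times))) {
  times <- as.numeric(times)
  scr <- as.numeric(scr)
  n <- length(times)
  if (length(scr) != n || length(on_dialysis) != n || length(inpatient) != n) {
    stop("'times', 'scr', 'on_dialysis' and 'inpatient' must have equal length",
         call. = FALSE)
  }
  if (n > 1L && any(diff(times) <= 0)) {
    stop("measurement times must be strictly increasing (patient ",
         patient_id, ")", call. = FALSE)
  }
  if (any(!is.finite(scr)) || any(scr <= 0)) {
    stop("serum creatinine must be positive (patient ", patient_id, ")",
         call. = FALSE)
  }
  structure(
    list(patient_id = patient_id, times = times, scr = scr,
         on_dialysis = as.logical(on_dialysis),
         inpatient = as.logical(inpatient)),
    class = "scr_series"
  )
}

#' @export
print.scr_series <- function(x, ...) {
  cat("<scr_series> patient", x$patient_id, "-", length(x$times),
      "measurements over", if (length(x$times)) diff(range(x$times)) else 0,
      "days\n")
  invisible(x)
}

#' @export
length.scr_series <- function(x) length(x$times)

#' Remove measurements taken during dialysis
#'
#' Creatinine drawn while a patient is being dialysed does not reflect
#' intrinsic kidney function; such values are removed before any AKI
#' flagging. Ordering of the remaining measurements is preserved.
#'
#' @param series an [scr_series()]
#' @return an `scr_series` with dialysis-flagged measurements removed
#' @export
exclude_dialysis_values <- function(series) {
  stopifnot(inherits(series, "scr_series"))
  keep <- !series$on_dialysis
  scr_series(series$patient_id, series$times[keep], series$scr[keep],
             series$on_dialysis[keep], series$inpatient[keep])
}

#' Split a laboratory table into per-patient series
#'
#' @param labs data frame with columns `patient_id`, `time_days`,
#'   `scr_umol_l`, `on_dialysis`, `inpatient`
#' @return named list of [scr_series()], one per patient
#' @export
split_series <- function(labs) {
  need <- c("patient_id", "time_days", "scr_umol_l", "on_dialysis", "inpatient")
  miss <- setdiff(need, names(labs))
  if (length(miss)) {
    stop("labs table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  labs <- labs[order(labs$patient_id, labs$time_days), , drop = FALSE]
  out <- lapply(split(labs, labs$patient_id), function(d) {
    scr_series(d$patient_id[1L], d$time_days, d$scr_umol_l,
               as.logical(d$on_dialysis), as.logical(d$inpatient))
  })
  out[order(names(out))]
}
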