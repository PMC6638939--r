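#' Assemble per-patient data for the eGFR mixed model
#'
#' Builds the fitting data from an eGFR table (see [compute_egfr_table()])
#' and baseline covariates: one entry per patient holding measurement
#' times (days), the response, and the fixed-effect design row-expanded
#' over measurements (intercept, years in study, baseline covariates).
#' Masked (peri-AKI or dialysis) measurements are dropped here.
#'
#' @param egfr_table data frame from [compute_egfr_table()]
#' @param covariates baseline covariate table
#' @param covariate_cols columns of [build_covariate_design()] to include
#'   as fixed effects; `NULL` for all
#' @return list of class `lmm_data`: per patient `t` (days), `y`, `X`
#' @export
lmm_data <- function(egfr_table, covariates, covariate_cols = NULL) {
  keep <- egfr_table$included & is.finite(egfr_table$egfr)
  d <- egfr_table[keep, , drop = FALSE]
  xmat <- build_covariate_design(covariates)
  if (!is.null(covariate_cols)) {
    xmat <- xmat[, covariate_cols, drop = FALSE]
  }
  idx <- match(d$patient_id, covariates$patient_id)
  if (anyNA(idx)) {
    stop("eGFR table contains patient ids absent from the covariate table",
         call. = FALSE)
  }
  out <- lapply(split(seq_len(nrow(d)), d$patient_id), function(ii) {
    ii <- ii[order(d$time_days[ii])]
    t <- d$time_days[ii]
    X <- cbind(intercept = 1, years = t / 365.25,
               xmat[idx[ii], , drop = FALSE])
    list(t = t, y = d$egfr[ii], X = X)
  })
  structure(out, class = "lmm_data")
}

#' Log-likelihood of the eGFR mixed model
#'
#' Evaluates the exact marginal log-likelihood: independently across
#' patients, observations are multivariate normal with mean \eqn{X\beta}
#' and covariance
#' \deqn{\sigma^2_b J + \sigma^2_w \exp(-|t_j - t_k|/\phi) + \sigma^2_e I}
#' (random intercept, exponentially correlated serial process, measurement
#' noise). Computed per patient via a Cholesky factorisation.
#'
#' @param params an [lmm_params()] object; `params$beta` must be a full
#'   coefficient vector ordered as the design columns of `data`
#' @param data an [lmm_data()] object
#' @return the log-likelihood (scalar)
#' @export
lmm_loglik <- function(params, data) {
  stopifnot(inherits(params, "lmm_params"))
  theta <- c(params$sigma2_intercept, params$sigma2_process,
             params$phi_days, params$sigma2_noise)
  ll <- 0
  for (pd in data) {
    V <- lmm_cov(pd$t, theta)
    L <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(L)) {
      stop("covariance matrix numerically non-positive-definite at ",
           "sigma2_intercept=", theta[1], ", sigma2_process=", theta[2],
           ", phi_days=", theta[3], ", sigma2_noise=", theta[4],
           call. = FALSE)
    }
    r <- pd$y - drop(pd$X %*% params$beta)
    z <- backsolve(L, r, transpose = TRUE)
    ll <- ll - 0.5 * (length(r) * log(2 * pi) + 2 * sum(log(diag(L))) +
                        sum(z^2))
  }
  ll
}

# Marginal covariance for one patient; theta = (s2_int, s2_proc, phi, s2_noise)
lmm_cov <- function(t, theta) {
  n <- length(t)
  V <- matrix(theta[1], n, n)
  if (theta[2] > 0) {
    V <- V + theta[2] * exp(-abs(outer(t, t, "-")) / theta[3])
  }
  V + diag(rep(theta[4], n), n)
}

# Profile negative log-likelihood over beta: given covariance parameters,
# beta is the GLS solution. Returns list(nll, beta, XtViX).
lmm_profile <- function(ltheta, data) {
  theta <- exp(ltheta)
  p <- ncol(data[[1]]$X)
  A <- matrix(0, p, p)
  b <- numeric(p)
  parts <- vector("list", length(data))
  logdet <- 0
  n_tot <- 0L
  for (k in seq_along(data)) {
    pd <- data[[k]]
    L <- tryCatch(chol(lmm_cov(pd$t, theta)), error = function(e) NULL)
    if (is.null(L)) return(list(nll = Inf))
    Xw <- backsolve(L, pd$X, transpose = TRUE)
    yw <- backsolve(L, pd$y, transpose = TRUE)
    A <- A + crossprod(Xw)
    b <- b + crossprod(Xw, yw)
    parts[[k]] <- list(Xw = Xw, yw = yw)
    logdet <- logdet + 2 * sum(log(diag(L)))
    n_tot <- n_tot + length(pd$y)
  }
  beta <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(beta)) return(list(nll = Inf))
  rss <- 0
  for (pt in parts) rss <- rss + sum((pt$yw - pt$Xw %*% beta)^2)
  nll <- 0.5 * (n_tot * log(2 * pi) + logdet + rss)
  list(nll = nll, beta = drop(beta), XtViX = A)
}

#' Fit the eGFR mixed model by maximum likelihood
#'
#' Maximises the marginal likelihood of the random-intercept plus
#' exponentially-correlated-process model. The fixed effects are profiled
#' out by generalised least squares; the four covariance parameters are
#' optimised on the log scale by quasi-Newton (BFGS) from three starting
#' points (a moment-based start and scaled perturbations of it) to guard
#' against local maxima. Standard errors of the fixed effects come from
#' the inverse GLS information at the optimum; covariance-parameter
#' standard errors come from the numerical Hessian of the profile
#' likelihood (delta method from the log scale).
#'
#' The fit is deterministic given the data: the multi-start perturbations
#' are fixed factors, and no random numbers are consumed.
#'
#' @param data an [lmm_data()] object (at least 2 patients with at least
#'   2 observations each)
#' @param start optional [lmm_params()] giving starting covariance
#'   parameters
#' @param n_starts number of starting points (default 3)
#' @param reltol convergence tolerance on the log-likelihood
#' @param maxit maximum BFGS iterations per start
#' @return object of class `lmm_fit`: `beta_hat` (with `beta_se`; aliased
#'   columns dropped from the design are reported as `NA` and listed in
#'   `dropped`), `sigma2_intercept_hat`, `sigma2_process_hat`, `phi_hat`,
#'   `sigma2_noise_hat` (with `theta_se`), `loglik`, `converged`,
#'   `n_obs`, `n_patients`
#' @export
fit_lmm <- function(data, start = NULL, n_starts = 3, reltol = 1e-8,
                    maxit = 200) {
  n_obs_pp <- vapply(data, function(pd) length(pd$y), integer(1))
  if (length(data) < 2L || sum(n_obs_pp >= 2L) < 2L) {
    stop("need at least 2 patients with at least 2 observations each",
         call. = FALSE)
  }
  # drop aliased fixed-effect columns (constant or collinear in this
  # dataset, e.g. an unobserved rare category); they are reported as NA
  all_cols <- colnames(data[[1]]$X)
  qx <- qr(do.call(rbind, lapply(data, `[[`, "X")))
  dropped <- character(0)
  if (qx$rank < length(all_cols)) {
    keep <- sort(qx$pivot[seq_len(qx$rank)])
    dropped <- all_cols[-keep]
    data <- structure(lapply(data, function(pd) {
      pd$X <- pd$X[, keep, drop = FALSE]
      pd
    }), class = "lmm_data")
  }
  if (is.null(start)) {
    y_all <- unlist(lapply(data, `[[`, "y"))
    v <- var(y_all)
    gaps <- unlist(lapply(data, function(pd) diff(pd$t)))
    phi0 <- max(median(gaps), 1)
    start_theta <- c(0.5 * v, 0.25 * v, phi0, 0.25 * v)
  } else {
    stopifnot(inherits(start, "lmm_params"))
    start_theta <- pmax(c(start$sigma2_intercept, start$sigma2_process,
                          start$phi_days, start$sigma2_noise), 1e-4)
  }
  scales <- list(c(1, 1, 1, 1), c(0.3, 3, 0.25, 0.5), c(3, 0.3, 4, 2))
  best <- NULL
  conv <- FALSE
  for (s in seq_len(min(n_starts, length(scales)))) {
    lt0 <- log(start_theta * scales[[s]])
    opt <- tryCatch(
      optim(lt0, function(lt) lmm_profile(lt, data)$nll, method = "BFGS",
            control = list(reltol = reltol, maxit = maxit)),
      error = function(e) NULL
    )
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value - 1e-10) {
      best <- opt
      conv <- opt$convergence == 0L
    }
  }
  if (is.null(best)) {
    stop("mixed-model optimisation failed from all starting points",
         call. = FALSE)
  }
  prof <- lmm_profile(best$par, data)
  theta_hat <- exp(best$par)
  beta_se <- sqrt(diag(solve(prof$XtViX)))
  # delta method: Var(theta) = theta^2 * Var(log theta)
  H <- tryCatch(
    stats::optimHess(best$par, function(lt) lmm_profile(lt, data)$nll),
    error = function(e) NULL
  )
  theta_se <- rep(NA_real_, 4)
  if (!is.null(H)) {
    hi <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(hi) && all(diag(hi) > 0)) {
      theta_se <- theta_hat * sqrt(diag(hi))
    }
  }
  cn <- colnames(data[[1]]$X)
  beta_hat <- setNames(prof$beta, cn)
  beta_se <- setNames(beta_se, cn)
  if (length(dropped)) {
    fill <- setNames(rep(NA_real_, length(dropped)), dropped)
    beta_hat <- c(beta_hat, fill)[all_cols]
    beta_se <- c(beta_se, fill)[all_cols]
  }
  structure(list(
    beta_hat = beta_hat,
    beta_se = beta_se,
    dropped = dropped,
    sigma2_intercept_hat = theta_hat[1],
    sigma2_process_hat = theta_hat[2],
    phi_hat = theta_hat[3],
    sigma2_noise_hat = theta_hat[4],
    theta_se = setNames(theta_se, c("sigma2_intercept", "sigma2_process",
                                    "phi_days", "sigma2_noise")),
    loglik = -best$value,
    converged = conv,
    n_obs = sum(n_obs_pp),
    n_patients = length(data)
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("eGFR linear mixed model (ML", if (!x$converged) ", NOT converged",
      ")\n", sep = "")
  cat(sprintf("  %d patients, %d observations, loglik %.3f\n",
              x$n_patients, x$n_obs, x$loglik))
  est <- cbind(estimate = x$beta_hat, se = x$beta_se)
  print(round(est, 4))
  cat(sprintf(paste0("  sigma2_intercept %.3f  sigma2_process %.3f  ",
                     "phi %.1f days  sigma2_noise %.3f\n"),
              x$sigma2_intercept_hat, x$sigma2_process_hat, x$phi_hat,
              x$sigma2_noise_hat))
  invisible(x)
}
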