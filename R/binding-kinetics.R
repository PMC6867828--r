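## Stopped-flow pseudo-first-order analysis: single-exponential trace
## fitting, association-rate extraction by linear regression of k_obs vs.
## titrant concentration, and dissociation-rate computation with first-order
## error propagation (k_off = K_D * k_on).

#' Stopped-flow fluorescence trace
#'
#' @param time time points (s), strictly increasing, starting at >= 0.
#' @param intensity fluorescence intensity (arbitrary units).
#' @param profilin_total total titrant (profilin) concentration (molar).
#' @return an object of class `stopped_flow_trace`.
#' @export
stopped_flow_trace <- function(time, intensity, profilin_total) {
  .check_nonneg(time, "time")
  .check_finite(intensity, "intensity")
  .check_nonneg(profilin_total, "profilin_total")
  if (length(time) != length(intensity) || length(time) < 10) {
    stop("time and intensity must have equal length >= 10", call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("time must be strictly increasing", call. = FALSE)
  }
  structure(list(time = time, intensity = intensity,
                 profilin_total = profilin_total),
            class = "stopped_flow_trace")
}

#' Fit a single-exponential relaxation to a stopped-flow trace
#'
#' Fits `I(t) = (I_f - I_b) * exp(-k_obs * t) + I_b` by least squares
#' (Levenberg-Marquardt), with starting guesses taken from the trace
#' endpoints and a log-linearized slope. A warning is issued when the trace
#' spans fewer than three e-folding times of the fitted decay. The fitted
#' rate is invariant to uniform intensity rescaling and, with
#' `offset = TRUE`, to time translation.
#'
#' @param trace a [stopped_flow_trace()].
#' @param offset treat the first sample as time zero? An explicit dead-time
#'   offset is not separately identifiable from the amplitude (it only
#'   rescales `I_f - I_b`), so translation invariance is obtained by
#'   shifting the time origin; amplitudes then refer to the observation
#'   window. Default `FALSE`.
#' @param drift include a linear baseline-drift term? Default `FALSE`.
#' @return a list of class `pseudo_first_order_result` with `k_obs`,
#'   `k_obs_err`, `i_free`, `i_bound`, `profilin_total` and the `nls` fit.
#' @export
fit_single_exponential <- function(trace, offset = FALSE, drift = FALSE) {
  stopifnot(inherits(trace, "stopped_flow_trace"))
  t <- trace$time
  if (offset) t <- t - t[1]
  y <- trace$intensity
  if (diff(range(y)) <= .Machine$double.eps * max(abs(y), 1)) {
    stop("flat trace: no relaxation to fit", call. = FALSE)
  }

  # starting values: baseline from the trace tail, amplitude from the head,
  # rate from a log-linear fit of the (signed) residual amplitude
  n <- length(y)
  ib0 <- mean(y[max(1, floor(0.9 * n)):n])
  if0 <- mean(y[1:max(1, ceiling(0.05 * n))])
  amp <- if0 - ib0
  z <- (y - ib0) / amp
  ok <- z > 1e-3
  k0 <- if (sum(ok) >= 3) {
    max(-stats::coef(stats::lm(log(z[ok]) ~ t[ok]))[[2]], 1e-6)
  } else {
    1 / max(diff(range(t)), .Machine$double.eps)
  }

  form <- if (drift) {
    y ~ (i_f - i_b) * exp(-k * t) + i_b + d * t
  } else {
    y ~ (i_f - i_b) * exp(-k * t) + i_b
  }
  start <- list(k = k0, i_f = if0, i_b = ib0)
  if (drift) start$d <- 0

  fit <- tryCatch(
    minpack.lm::nlsLM(form, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("exponential fit failed to converge: ",
                             conditionMessage(e), call. = FALSE)
  )
  est <- .lm_coefs(fit)
  k <- est["k", 1]
  if (k <= 0) {
    stop(sprintf("fitted k_obs is non-positive (%.3g s^-1); trace rejected", k),
         call. = FALSE)
  }
  if (k * diff(range(t)) < 3) {
    warning(sprintf("trace spans only %.2f e-folding times of the decay; ",
                    k * diff(range(t))),
            "k_obs may be poorly constrained", call. = FALSE)
  }
  structure(
    list(k_obs = k, k_obs_err = est["k", 2],
         i_free = est["i_f", 1], i_bound = est["i_b", 1],
         profilin_total = trace$profilin_total, fit = fit),
    class = "pseudo_first_order_result"
  )
}

#' Association rate constant from a k_obs vs. concentration ladder
#'
#' Under the pseudo-first-order relaxation model
#' `k_obs = k_on * [P] + k_off`, the association rate constant is the slope
#' of a linear regression of `k_obs` on the total titrant concentration.
#' The intercept is estimated (not fixed at zero) and provides an
#' independent estimate of the dissociation rate.
#'
#' @param results a list of `pseudo_first_order_result` objects (each
#'   carrying its `profilin_total`), or a data.frame with columns `k_obs`
#'   and `profilin_total` (optionally `k_obs_err`).
#' @return a list with `k_on`, `k_on_err` (M^-1 s^-1), `intercept`,
#'   `intercept_err` (s^-1) and the `lm` fit.
#' @export
fit_association_rate <- function(results) {
  if (is.data.frame(results)) {
    df <- results
  } else {
    stopifnot(all(vapply(results, inherits, logical(1),
                         "pseudo_first_order_result")))
    df <- data.frame(
      k_obs = vapply(results, `[[`, numeric(1), "k_obs"),
      k_obs_err = vapply(results, `[[`, numeric(1), "k_obs_err"),
      profilin_total = vapply(results, `[[`, numeric(1), "profilin_total")
    )
  }
  if (length(unique(df$profilin_total)) < 3) {
    stop("need k_obs at >= 3 distinct concentrations", call. = FALSE)
  }
  fit <- stats::lm(k_obs ~ profilin_total, data = df)
  est <- .lm_coefs(fit)
  slope <- est["profilin_total", 1]
  if (slope <= 0) {
    stop("non-physical negative association rate (k_obs decreases with ",
         "concentration)", call. = FALSE)
  }
  list(k_on = slope, k_on_err = est["profilin_total", 2],
       intercept = est["(Intercept)", 1],
       intercept_err = est["(Intercept)", 2],
       fit = fit)
}

#' Dissociation rate from equilibrium and association constants
#'
#' Computes `k_off = K_D * k_on` with first-order Gaussian error
#' propagation: `sigma_koff = sqrt((k_on sigma_KD)^2 + (K_D sigma_kon)^2)`.
#'
#' @param kd an [affinity_constant()] (or a number, molar).
#' @param k_on association rate constant (M^-1 s^-1).
#' @param k_on_err standard error of `k_on` (optional).
#' @return a list with `k_off` (s^-1) and `k_off_err` (NA when neither
#'   input error is available).
#' @export
dissociation_rate <- function(kd, k_on, k_on_err = NA_real_) {
  if (!inherits(kd, "affinity_constant")) kd <- affinity_constant(kd)
  .check_pos(k_on, "k_on")
  k_off <- kd$kd * k_on
  k_off_err <- .prod_err(kd$kd, kd$kd_err, k_on, k_on_err)
  list(k_off = k_off, k_off_err = k_off_err)
}
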