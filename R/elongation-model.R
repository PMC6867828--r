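## Three-reaction elongation-cycle model of actin filament barbed-end growth
## from profilin-actin:
##
##   E --(k_bind * c)--> C1 --(k_trans)--> C2 --(k_release)--> E, length +1
##
## where E is a free end, C1 a profilin-capped end before the
## monomer-to-filament transition and C2 a profilin-capped end after it.
## The cycle is sequential and irreversible; its steady-state velocity is
## the harmonic sum v(c) = 1 / (1/(k_bind c) + 1/k_trans + 1/k_release),
## an exact hyperbola in c with v_max = (1/k_trans + 1/k_release)^-1 and
## half-saturation K_0.5 = v_max / k_bind. Formins accelerate reactions 1
## (binding) and 3 (profilin release) multiplicatively.

# subunit rise along the filament axis: one incorporated actin monomer
# contributes 2.7 nm of filament length
.RISE_NM <- 2.7

#' Rise per incorporated subunit
#'
#' @param unit `"nm"`, `"um"` or `"m"`.
#' @return length contributed per subunit in the requested unit.
#' @export
subunit_rise <- function(unit = c("nm", "um", "m")) {
  unit <- match.arg(unit)
  switch(unit, nm = .RISE_NM, um = .RISE_NM * 1e-3, m = .RISE_NM * 1e-9)
}

#' Convert an elongation velocity between subunits/s and um/s
#'
#' @param v velocity value(s).
#' @param from,to `"subunits_per_s"` or `"um_per_s"`.
#' @return converted velocity.
#' @export
convert_velocity <- function(v, from = "subunits_per_s", to = "um_per_s") {
  units <- c("subunits_per_s", "um_per_s")
  stopifnot(from %in% units, to %in% units)
  if (from == to) return(v)
  if (from == "subunits_per_s") v * subunit_rise("um") else v / subunit_rise("um")
}

# ---- domain types ----------------------------------------------------------

#' Microscopic rate constants of the elongation cycle
#'
#' @param k_bind second-order binding rate constant of profilin-actin to a
#'   free barbed end (M^-1 s^-1), reaction 1.
#' @param k_trans first-order monomer-to-filament transition rate (s^-1),
#'   reaction 2.
#' @param k_release first-order profilin release rate from the terminal
#'   protomer (s^-1), reaction 3 (rate-limiting at saturation).
#' @return an object of class `cycle_rates`.
#' @export
cycle_rates <- function(k_bind, k_trans, k_release) {
  .check_pos(k_bind, "k_bind")
  .check_pos(k_trans, "k_trans")
  .check_pos(k_release, "k_release")
  structure(list(k_bind = k_bind, k_trans = k_trans, k_release = k_release),
            class = "cycle_rates")
}

#' @export
print.cycle_rates <- function(x, ...) {
  cat(sprintf(
    "elongation cycle: k_bind = %.3g M^-1 s^-1, k_trans = %.3g s^-1, k_release = %.3g s^-1\n",
    x$k_bind, x$k_trans, x$k_release))
  invisible(x)
}

#' Formin acceleration factors
#'
#' Formins accelerate the binding of profilin-actin to the barbed end
#' (reaction 1, via FH1) and profilin release from the terminal protomer
#' (reaction 3, via FH2); the monomer-to-filament transition is unmodified.
#'
#' @param f_bind multiplicative acceleration of reaction 1 (>= 1).
#' @param f_release multiplicative acceleration of reaction 3 (>= 1).
#' @param label formin identity tag (e.g. `"mDia1"`).
#' @return an object of class `formin_factors`.
#' @export
formin_factors <- function(f_bind, f_release, label = "formin") {
  .check_finite(f_bind, "f_bind")
  .check_finite(f_release, "f_release")
  if (f_bind < 1 || f_release < 1) {
    stop("formin factors must be >= 1 (formins accelerate, not inhibit)",
         call. = FALSE)
  }
  structure(list(f_bind = f_bind, f_release = f_release, label = label),
            class = "formin_factors")
}

#' Bare-actin (profilin-free) end kinetics
#'
#' @param k_plus monomer association rate constant (M^-1 s^-1).
#' @param k_minus monomer dissociation rate (s^-1).
#' @return an object of class `bare_actin_rates`.
#' @export
bare_actin_rates <- function(k_plus, k_minus) {
  .check_pos(k_plus, "k_plus")
  .check_nonneg(k_minus, "k_minus")
  structure(list(k_plus = k_plus, k_minus = k_minus),
            class = "bare_actin_rates")
}

#' Concentration-velocity data from single-filament assays
#'
#' @param conc total profilin-actin concentrations (molar).
#' @param v_mean mean per-filament velocities (subunits/s).
#' @param v_sd standard deviations of per-filament velocities.
#' @param n filament counts per condition.
#' @return an object of class `velocity_curve`.
#' @export
velocity_curve <- function(conc, v_mean, v_sd = rep(0, length(conc)),
                           n = rep(1L, length(conc))) {
  .check_nonneg(conc, "conc")
  .check_finite(v_mean, "v_mean")
  .check_nonneg(v_sd, "v_sd")
  if (any(n < 1)) stop("filament counts must be >= 1", call. = FALSE)
  len <- length(conc)
  if (length(v_mean) != len || length(v_sd) != len || length(n) != len) {
    stop("conc, v_mean, v_sd and n must have equal lengths", call. = FALSE)
  }
  structure(list(conc = conc, v_mean = v_mean, v_sd = v_sd, n = n),
            class = "velocity_curve")
}

#' Hyperbolic saturation fit parameters
#'
#' @param v_max maximal elongation velocity (subunits/s).
#' @param k_half half-saturation profilin-actin concentration (molar).
#' @param v_max_err,k_half_err standard errors (optional).
#' @return an object of class `hyperbolic_fit`.
#' @export
hyperbolic_fit <- function(v_max, k_half, v_max_err = NA_real_,
                           k_half_err = NA_real_) {
  .check_pos(v_max, "v_max")
  .check_pos(k_half, "k_half")
  structure(list(v_max = v_max, k_half = k_half,
                 v_max_err = v_max_err, k_half_err = k_half_err),
            class = "hyperbolic_fit")
}

#' @export
print.hyperbolic_fit <- function(x, ...) {
  cat(sprintf("hyperbolic saturation fit: v_max = %.4g subunits/s", x$v_max))
  if (!is.na(x$v_max_err)) cat(sprintf(" (SE %.3g)", x$v_max_err))
  cat(sprintf(", K_0.5 = %.4g M", x$k_half))
  if (!is.na(x$k_half_err)) cat(sprintf(" (SE %.3g)", x$k_half_err))
  cat("\n")
  invisible(x)
}

#' Evaluate a hyperbolic fit
#'
#' @param object a [hyperbolic_fit()].
#' @param conc concentrations (molar).
#' @param ... unused.
#' @return predicted velocities (subunits/s).
#' @export
predict.hyperbolic_fit <- function(object, conc, ...) {
  object$v_max * conc / (object$k_half + conc)
}

# ---- analytic model --------------------------------------------------------

#' Steady-state elongation velocity of the cycle model
#'
#' The mean cycle time at profilin-actin concentration `c` is the sum of the
#' three exponential waiting times, so the steady-state velocity is
#' `v(c) = 1 / (1/(k_bind c) + 1/k_trans + 1/k_release)` - exactly a
#' hyperbola in `c`, saturating at `(1/k_trans + 1/k_release)^-1`.
#'
#' @param rates a [cycle_rates()].
#' @param conc total profilin-actin concentration(s) (molar), >= 0.
#' @return velocity (subunits/s), vectorized over `conc`.
#' @export
cycle_velocity <- function(rates, conc) {
  stopifnot(inherits(rates, "cycle_rates"))
  .check_nonneg(conc, "conc")
  v <- 1 / (1 / (rates$k_bind * conc) + 1 / rates$k_trans + 1 / rates$k_release)
  v[conc == 0] <- 0
  v
}

#' Exact hyperbolic parameters of the cycle model
#'
#' Closed-form reduction of the cycle model to its saturation law:
#' `v_max = (1/k_trans + 1/k_release)^-1` and `K_0.5 = v_max / k_bind`, so
#' that `cycle_velocity(rates, k_half) == v_max / 2` exactly.
#'
#' @param rates a [cycle_rates()].
#' @return a [hyperbolic_fit()] with no errors (exact reduction).
#' @export
hyperbolic_params_from_cycle <- function(rates) {
  stopifnot(inherits(rates, "cycle_rates"))
  v_max <- 1 / (1 / rates$k_trans + 1 / rates$k_release)
  hyperbolic_fit(v_max = v_max, k_half = v_max / rates$k_bind)
}

#' Apply formin acceleration to cycle rates
#'
#' @param rates a [cycle_rates()].
#' @param factors a [formin_factors()].
#' @return a [cycle_rates()] with `k_bind * f_bind` and
#'   `k_release * f_release`; `k_trans` unchanged.
#' @export
apply_formin <- function(rates, factors) {
  stopifnot(inherits(rates, "cycle_rates"), inherits(factors, "formin_factors"))
  cycle_rates(k_bind = rates$k_bind * factors$f_bind,
              k_trans = rates$k_trans,
              k_release = rates$k_release * factors$f_release)
}

#' Relative formin rate enhancement vs. concentration
#'
#' Ratio of formin-assisted to free-end cycle velocity at a given
#' concentration. The ratio interpolates monotonically between `f_bind` (the
#' binding-limited regime, `c -> 0`) and the v_max ratio (the
#' release-limited regime, `c -> Inf`), so with matched factors the
#' enhancement varies only weakly with substrate concentration.
#'
#' @param rates a [cycle_rates()] for the free end.
#' @param factors a [formin_factors()].
#' @param conc concentration(s) (molar). At `conc = 0` the limiting value
#'   `f_bind` is returned with attribute `limit = TRUE`.
#' @return enhancement ratio(s), vectorized over `conc`.
#' @export
relative_enhancement <- function(rates, factors, conc) {
  stopifnot(inherits(rates, "cycle_rates"), inherits(factors, "formin_factors"))
  .check_nonneg(conc, "conc")
  frates <- apply_formin(rates, factors)
  ratio <- ifelse(conc == 0,
                  factors$f_bind,
                  cycle_velocity(frates, conc) / cycle_velocity(rates, conc))
  if (any(conc == 0)) attr(ratio, "limit") <- TRUE
  ratio
}

# ---- stochastic simulation -------------------------------------------------

.new_trajectory <- function(times, lengths, end_state, seed, params) {
  structure(list(times = times, lengths = lengths, end_state = end_state,
                 seed = seed, params = params),
            class = "filament_trajectory")
}

#' @export
print.filament_trajectory <- function(x, ...) {
  cat(sprintf("filament trajectory: %d events, final length %d subunits, seed %d\n",
              length(x$times), if (length(x$lengths)) x$lengths[length(x$lengths)] else 0L,
              x$seed))
  invisible(x)
}

#' Exact stochastic simulation of one filament under the elongation cycle
#'
#' Exact-event realization of the sequential cycle
#' E -> C1 (rate `k_bind * conc`) -> C2 (rate `k_trans`) -> E + 1 subunit
#' (rate `k_release`). Length is incremented at the binding event (subunit
#' incorporation); end occupancy is tracked separately. Waiting times are
#' drawn per reaction from their exponential distributions, so trajectories
#' are exact and bit-reproducible per seed.
#'
#' @param rates a [cycle_rates()].
#' @param conc total profilin-actin concentration (molar).
#' @param duration simulated time (s), > 0.
#' @param seed integer RNG seed (recorded in the trajectory).
#' @param event_cap maximum number of events before the simulation aborts
#'   with a truncation error carrying the partial trajectory.
#' @return a `filament_trajectory` with event `times` (s), `lengths`
#'   (subunits, starting at 0) and `end_state`
#'   (`"free"`, `"capped_pre"`, `"capped_post"`).
#' @export
simulate_filament <- function(rates, conc, duration, seed, event_cap = 1e7) {
  stopifnot(inherits(rates, "cycle_rates"))
  .check_nonneg(conc, "conc")
  .check_pos(duration, "duration")
  params <- list(rates = rates, conc = conc, duration = duration)
  if (conc == 0) {
    return(.new_trajectory(numeric(0), integer(0), character(0), seed, params))
  }
  withr::local_seed(seed)

  kb <- rates$k_bind * conc; kt <- rates$k_trans; kr <- rates$k_release
  v <- cycle_velocity(rates, conc)

  times <- numeric(0)
  kind <- integer(0)   # 1 = bind, 2 = trans, 3 = release
  t_end <- 0
  repeat {
    # chunk of whole cycles: expected remaining cycles plus slack
    n <- max(32L, ceiling((duration - t_end) * v * 1.2 + 6 * sqrt((duration - t_end) * v + 1)))
    if ((length(times) + 3 * n) > event_cap) {
      cond <- structure(
        class = c("actinpacer_truncation", "error", "condition"),
        list(message = sprintf("event cap (%g) exceeded in simulate_filament", event_cap),
             call = NULL,
             trajectory = .finish_cycle_trajectory(times, kind, duration, seed, params)))
      stop(cond)
    }
    tb <- stats::rexp(n, kb); tt <- stats::rexp(n, kt); tr <- stats::rexp(n, kr)
    base <- t_end + c(0, cumsum(tb + tt + tr))[seq_len(n)]
    bind_t <- base + tb
    trans_t <- bind_t + tt
    rel_t <- trans_t + tr
    times <- c(times, as.vector(rbind(bind_t, trans_t, rel_t)))
    kind <- c(kind, rep(c(1L, 2L, 3L), n))
    t_end <- rel_t[n]
    if (t_end >= duration) break
  }
  .finish_cycle_trajectory(times, kind, duration, seed, params)
}

.finish_cycle_trajectory <- function(times, kind, duration, seed, params) {
  keep <- times <= duration
  times <- times[keep]; kind <- kind[keep]
  lengths <- cumsum(kind == 1L)
  end_state <- c("capped_pre", "capped_post", "free")[kind]
  .new_trajectory(times, as.integer(lengths), end_state, seed, params)
}

#' Stochastic simulation of a bare (profilin-free) filament end
#'
#' Birth-death process with gain rate `k_plus * conc` and loss rate
#' `k_minus`; the length is floored at 0 (at length 0 only a gain event can
#' occur). The mean long-run velocity is `k_plus * conc - k_minus` away from
#' the boundary; at the critical concentration `k_minus / k_plus` the mean
#' velocity is zero.
#'
#' @param rates a [bare_actin_rates()].
#' @param conc free monomer concentration (molar).
#' @param duration simulated time (s), > 0.
#' @param seed integer RNG seed.
#' @param length0 initial length (subunits), default 0.
#' @param event_cap maximum number of events.
#' @return a `filament_trajectory`; `end_state` is `"free"` throughout.
#' @export
simulate_bare_filament <- function(rates, conc, duration, seed, length0 = 0L,
                                   event_cap = 1e7) {
  stopifnot(inherits(rates, "bare_actin_rates"))
  .check_nonneg(conc, "conc")
  .check_pos(duration, "duration")
  .check_nonneg(length0, "length0")
  params <- list(rates = rates, conc = conc, duration = duration,
                 length0 = length0)
  kp <- rates$k_plus * conc; km <- rates$k_minus
  if (kp == 0 && km == 0) {
    return(.new_trajectory(numeric(0), integer(0), character(0), seed, params))
  }
  withr::local_seed(seed)

  times <- numeric(0)
  lens <- integer(0)
  t <- 0; len <- as.integer(length0)
  total <- kp + km
  p_up <- kp / total
  chunk <- 8192L
  while (t < duration) {
    if (length(times) > event_cap) {
      cond <- structure(
        class = c("actinpacer_truncation", "error", "condition"),
        list(message = sprintf("event cap (%g) exceeded in simulate_bare_filament",
                               event_cap),
             call = NULL,
             trajectory = .new_trajectory(times, lens, rep("free", length(times)),
                                          seed, params)))
      stop(cond)
    }
    if (len == 0L) {
      if (kp == 0) break  # absorbed: no gain possible
      # at the boundary only a gain event can fire
      t <- t + stats::rexp(1, kp)
      if (t > duration) break
      len <- 1L
      times <- c(times, t); lens <- c(lens, len)
      next
    }
    wt <- stats::rexp(chunk, total)
    steps <- ifelse(stats::runif(chunk) < p_up, 1L, -1L)
    ct <- t + cumsum(wt)
    cl <- len + cumsum(steps)
    # truncate the chunk at the first visit to length 0 (dynamics change)
    hit0 <- match(0L, cl)
    if (!is.na(hit0)) {
      ct <- ct[seq_len(hit0)]; cl <- cl[seq_len(hit0)]
    }
    in_time <- ct <= duration
    times <- c(times, ct[in_time]); lens <- c(lens, cl[in_time])
    if (!all(in_time)) break
    t <- ct[length(ct)]; len <- cl[length(cl)]
  }
  .new_trajectory(times, as.integer(lens), rep("free", length(times)),
                  seed, params)
}

#' Estimate the growth velocity of a filament trajectory
#'
#' Least-squares slope of length vs. time over all trajectory points
#' (mirroring kymograph slope fitting), with standard error from the
#' regression.
#'
#' @param traj a `filament_trajectory` with >= 2 events.
#' @return a list with `velocity` (subunits/s), `velocity_err` and
#'   `velocity_um_per_s`.
#' @export
estimate_trajectory_velocity <- function(traj) {
  stopifnot(inherits(traj, "filament_trajectory"))
  if (length(traj$times) < 2) {
    stop("trajectory must contain >= 2 events to estimate a slope",
         call. = FALSE)
  }
  fit <- stats::lm(lengths ~ times,
                   data = data.frame(times = traj$times, lengths = traj$lengths))
  est <- .lm_coefs(fit)
  v <- est["times", 1]
  list(velocity = v, velocity_err = est["times", 2],
       velocity_um_per_s = convert_velocity(v))
}

# ---- velocity-curve fitting ------------------------------------------------

#' Fit the hyperbolic saturation law to a velocity curve
#'
#' Least-squares fit of `v = v_max * c / (K_0.5 + c)`.
#'
#' @param curve a [velocity_curve()] with >= 4 concentrations; a warning is
#'   issued when the data do not span both sides of the fitted
#'   half-saturation point or show no curvature.
#' @return a [hyperbolic_fit()] with standard errors, carrying the `nls`
#'   object as attribute `"fit"`.
#' @export
fit_hyperbolic <- function(curve) {
  stopifnot(inherits(curve, "velocity_curve"))
  conc <- curve$conc; v <- curve$v_mean
  if (length(conc) < 4) {
    warning("fewer than 4 concentrations; hyperbolic fit may be unreliable",
            call. = FALSE)
  }
  vmax0 <- max(v)
  khalf0 <- conc[which.min(abs(v - vmax0 / 2))]
  if (khalf0 <= 0) khalf0 <- stats::median(conc[conc > 0])
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ vmax * conc / (khalf + conc),
                      start = list(vmax = vmax0, khalf = khalf0),
                      lower = c(vmax = 0, khalf = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("hyperbolic fit failed to converge: ",
                             conditionMessage(e), call. = FALSE)
  )
  est <- .lm_coefs(fit)
  kh <- est["khalf", 1]
  if (kh > max(conc)) {
    warning("fitted K_0.5 lies above the sampled concentration range; ",
            "curve shows little curvature and v_max/K_0.5 are only jointly ",
            "identifiable", call. = FALSE)
  } else if (kh < min(conc[conc > 0])) {
    warning("all data lie above the fitted half-saturation point; K_0.5 is ",
            "poorly constrained", call. = FALSE)
  }
  out <- hyperbolic_fit(est["vmax", 1], kh,
                        v_max_err = est["vmax", 2], k_half_err = est["khalf", 2])
  attr(out, "fit") <- fit
  out
}

#' Linear fit of the low-concentration regime
#'
#' Fits a weighted straight line to the points at or below `conc_cutoff`;
#' the slope is interpretable as the apparent association rate constant of
#' profilin-actin for the barbed end (the initial slope `v_max / K_0.5` of
#' the saturation law). Weights are inverse squared standard errors of the
#' mean (`n / v_sd^2`) when SDs are available, otherwise uniform.
#'
#' @param curve a [velocity_curve()].
#' @param conc_cutoff concentration cutoff (molar); >= 3 points required
#'   at or below it.
#' @return a list with `slope` (M^-1 s^-1), `slope_err`, `intercept`,
#'   `intercept_err` and the `lm` fit.
#' @export
fit_linear_regime <- function(curve, conc_cutoff) {
  stopifnot(inherits(curve, "velocity_curve"))
  .check_pos(conc_cutoff, "conc_cutoff")
  keep <- curve$conc <= conc_cutoff
  if (sum(keep) < 3) {
    stop("need >= 3 points at or below conc_cutoff for a linear fit",
         call. = FALSE)
  }
  df <- data.frame(conc = curve$conc[keep], v = curve$v_mean[keep])
  w <- if (all(curve$v_sd[keep] > 0)) {
    curve$n[keep] / curve$v_sd[keep]^2
  } else {
    rep(1, sum(keep))
  }
  fit <- stats::lm(v ~ conc, data = df, weights = w)
  est <- .lm_coefs(fit)
  list(slope = est["conc", 1], slope_err = est["conc", 2],
       intercept = est["(Intercept)", 1],
       intercept_err = est["(Intercept)", 2],
       fit = fit)
}

#' Velocity buffering ratio under the saturation law
#'
#' Ratio `v(fold * c_base) / v(c_base)` under a hyperbolic fit; quantifies
#' how insensitive the elongation speed is to changes in the soluble subunit
#' concentration. Near saturation (`c_base >> K_0.5`) the ratio approaches
#' 1; in the linear regime it approaches `fold`. The closed form is
#' `fold * (K_0.5 + c_base) / (K_0.5 + fold * c_base)`.
#'
#' @param fit a [hyperbolic_fit()].
#' @param c_base base concentration (molar), > 0.
#' @param fold fold-change in concentration, > 0.
#' @return the velocity ratio (dimensionless).
#' @export
buffering_ratio <- function(fit, c_base, fold) {
  stopifnot(inherits(fit, "hyperbolic_fit"))
  .check_pos(c_base, "c_base")
  .check_pos(fold, "fold")
  fold * (fit$k_half + c_base) / (fit$k_half + fold * c_base)
}
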