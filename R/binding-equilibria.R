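## Exact equilibrium solvers and fitters for monomer-binding assays:
## two-ligand competition (profilin + fluorescent probe competing for actin
## monomers), single-site ligand-depletion binding (quadratic isotherm), and
## free-species tables for assay-mix design.
##
## All concentrations are stored internally in molar.

# ---- domain types ----------------------------------------------------------

#' Equilibrium dissociation constant
#'
#' @param kd dissociation constant (molar), must be positive.
#' @param kd_err standard error (molar), optional.
#' @return an object of class `affinity_constant`.
#' @export
affinity_constant <- function(kd, kd_err = NA_real_) {
  .check_pos(kd, "kd")
  if (!is.na(kd_err)) .check_nonneg(kd_err, "kd_err")
  structure(list(kd = kd, kd_err = kd_err), class = "affinity_constant")
}

.as_kd <- function(x) if (inherits(x, "affinity_constant")) x$kd else .check_pos(x, "kd")

#' @export
print.affinity_constant <- function(x, ...) {
  cat(sprintf("K_D = %.4g M", x$kd))
  if (!is.na(x$kd_err)) cat(sprintf(" (SE %.3g M)", x$kd_err))
  cat("\n")
  invisible(x)
}

#' Two-ligand, one-receptor competition mixture
#'
#' Describes a mixture in which two ligands (a competitor such as profilin,
#' and a probe such as a labeled WCA domain or thymosin-beta4) compete for
#' a single binding site on a receptor (the actin monomer).
#'
#' @param a_total total receptor (actin) concentration (molar).
#' @param p_total total competitor (profilin) concentration (molar).
#' @param w_total total probe concentration (molar).
#' @param kp competitor affinity, an [affinity_constant()] or a number (molar).
#' @param kw probe affinity, as `kp`.
#' @return an object of class `competition_mixture`.
#' @export
competition_mixture <- function(a_total, p_total, w_total, kp, kw) {
  .check_nonneg(a_total, "a_total")
  .check_nonneg(p_total, "p_total")
  .check_nonneg(w_total, "w_total")
  structure(
    list(a_total = a_total, p_total = p_total, w_total = w_total,
         kp = .as_kd(kp), kw = .as_kd(kw)),
    class = "competition_mixture"
  )
}

#' Equilibrium species concentrations of a competition mixture
#'
#' @param a_free,p_free,w_free free receptor/competitor/probe (molar).
#' @param pa,wa bound complex concentrations (molar).
#' @return an object of class `species_state`.
#' @export
species_state <- function(a_free, p_free, w_free, pa, wa) {
  for (nm in c("a_free", "p_free", "w_free", "pa", "wa")) {
    .check_nonneg(get(nm), nm)
  }
  structure(list(a_free = a_free, p_free = p_free, w_free = w_free,
                 pa = pa, wa = wa),
            class = "species_state")
}

#' Anisotropy endpoints of a fluorescent probe
#'
#' @param r_free anisotropy of the unbound probe.
#' @param r_bound anisotropy of the fully bound probe.
#' @return an object of class `anisotropy_endpoints`.
#' @export
anisotropy_endpoints <- function(r_free, r_bound) {
  .check_finite(r_free, "r_free")
  .check_finite(r_bound, "r_bound")
  if (r_bound == r_free) stop("r_bound must differ from r_free", call. = FALSE)
  structure(list(r_free = r_free, r_bound = r_bound),
            class = "anisotropy_endpoints")
}

#' Fluorescence-quench endpoints
#'
#' @param i_free,i_bound fluorescence intensity of free and bound probe
#'   (arbitrary units).
#' @return an object of class `quench_endpoints`.
#' @export
quench_endpoints <- function(i_free, i_bound) {
  .check_finite(i_free, "i_free")
  .check_finite(i_bound, "i_bound")
  if (i_bound == i_free) stop("i_bound must differ from i_free", call. = FALSE)
  structure(list(i_free = i_free, i_bound = i_bound),
            class = "quench_endpoints")
}

#' Titration series
#'
#' A set of measured signals (anisotropy or intensity) at increasing titrant
#' concentrations. The series is sorted by titrant concentration; duplicate
#' concentrations are allowed and treated as replicates.
#'
#' @param titrant_total titrant concentrations (molar), non-negative.
#' @param signal measured signal values.
#' @param signal_err optional per-point standard errors; when present, fits
#'   use inverse-variance weighting.
#' @return an object of class `titration_series`.
#' @export
titration_series <- function(titrant_total, signal, signal_err = NULL) {
  .check_nonneg(titrant_total, "titrant_total")
  .check_finite(signal, "signal")
  if (length(titrant_total) != length(signal) || length(signal) < 4) {
    stop("titrant_total and signal must have equal length >= 4", call. = FALSE)
  }
  if (!is.null(signal_err)) {
    .check_nonneg(signal_err, "signal_err")
    if (length(signal_err) != length(signal)) {
      stop("signal_err must match signal length", call. = FALSE)
    }
  }
  ord <- order(titrant_total)
  structure(list(titrant_total = titrant_total[ord], signal = signal[ord],
                 signal_err = if (is.null(signal_err)) NULL else signal_err[ord]),
            class = "titration_series")
}

# ---- solver ----------------------------------------------------------------

# conservation function for free receptor A: monotone increasing in A,
# f(A) = A (1 + P0/(KP+A) + W0/(KW+A)) - A0, root on [0, A0]
.competition_f <- function(A, a0, p0, w0, kp, kw) {
  A * (1 + p0 / (kp + A) + w0 / (kw + A)) - a0
}

.competition_fprime <- function(A, p0, w0, kp, kw) {
  1 + p0 * kp / (kp + A)^2 + w0 * kw / (kw + A)^2
}

# closed-form free receptor concentration from the trigonometric solution of
# the competition cubic; returns NA when numerically degenerate
.competition_closed_form <- function(a0, p0, w0, kp, kw, clamp = 1e-9) {
  a <- kp + kw + p0 + w0 - a0
  b <- kp * (w0 - a0) + kw * (p0 - a0) + kp * kw
  cc <- -kp * kw * a0
  q <- a * a - 3 * b
  if (!is.finite(q) || q <= 0) return(NA_real_)
  arg <- (-2 * a^3 + 9 * a * b - 27 * cc) / (2 * sqrt(q^3))
  if (!is.finite(arg)) return(NA_real_)
  if (abs(arg) > 1) {
    if (abs(arg) - 1 <= clamp) arg <- sign(arg) else return(NA_real_)
  }
  theta <- acos(arg)
  (2 * sqrt(q) * cos(theta / 3) - a) / 3
}

# Newton refinement of the free-receptor root (monotone concave f)
.competition_newton <- function(A, a0, p0, w0, kp, kw, maxit = 50L) {
  for (i in seq_len(maxit)) {
    fx <- .competition_f(A, a0, p0, w0, kp, kw)
    step <- fx / .competition_fprime(A, p0, w0, kp, kw)
    Anew <- A - step
    if (Anew < 0) Anew <- A / 2
    if (Anew > a0) Anew <- a0
    if (abs(Anew - A) <= .Machine$double.eps * max(Anew, .Machine$double.xmin)) {
      return(Anew)
    }
    A <- Anew
  }
  A
}

# cancellation-free species from the free receptor concentration
.species_from_afree <- function(A, a0, p0, w0, kp, kw) {
  species_state(
    a_free = A,
    p_free = p0 * kp / (kp + A),
    w_free = w0 * kw / (kw + A),
    pa     = p0 * A / (kp + A),
    wa     = w0 * A / (kw + A)
  )
}

#' Solve a two-ligand competition equilibrium exactly
#'
#' Computes the unique physical equilibrium of two ligands competing for a
#' single receptor site by the closed-form trigonometric solution of the
#' governing cubic, with a fallback to iterative root-finding (Brent bracket
#' plus Newton polish on the monotone conservation function) when the closed
#' form is numerically degenerate. Species are reconstructed from the free
#' receptor concentration through the mass-action relations, so mass action
#' holds at machine precision by construction.
#'
#' @param mix a [competition_mixture()].
#' @param method `"auto"` (closed form with fallback, the default),
#'   `"closed_form"` (no fallback) or `"root"` (iterative only).
#' @param tol acceptance tolerance on the estimated relative error of the
#'   free receptor concentration before the fallback is invoked.
#' @return a [species_state()].
#' @export
solve_two_ligand_competition <- function(mix,
                                         method = c("auto", "closed_form", "root"),
                                         tol = 1e-10) {
  stopifnot(inherits(mix, "competition_mixture"))
  method <- match.arg(method)
  a0 <- mix$a_total; p0 <- mix$p_total; w0 <- mix$w_total
  kp <- mix$kp; kw <- mix$kw

  # trivial limits
  if (a0 == 0) {
    return(species_state(0, p0, w0, 0, 0))
  }
  if (p0 == 0 && w0 == 0) {
    return(species_state(a0, 0, 0, 0, 0))
  }

  A <- NA_real_
  if (method != "root") {
    A <- .competition_closed_form(a0, p0, w0, kp, kw)
    if (!is.na(A) && (A < 0 || A > a0)) A <- NA_real_
    if (!is.na(A) && method == "auto") {
      # estimated absolute error of the root from the residual; accept the
      # closed form only when its implied relative error is below tol
      err <- abs(.competition_f(A, a0, p0, w0, kp, kw)) /
        .competition_fprime(A, p0, w0, kp, kw)
      if (err > tol * max(A, .Machine$double.xmin)) A <- NA_real_
    }
    if (is.na(A) && method == "closed_form") {
      stop("closed-form competition solution is numerically degenerate; ",
           "use method = 'auto' or 'root'", call. = FALSE)
    }
  }

  if (is.na(A)) {
    root <- stats::uniroot(.competition_f, c(0, a0), a0 = a0, p0 = p0, w0 = w0,
                           kp = kp, kw = kw, tol = 1e-300, maxiter = 2000L)$root
    A <- .competition_newton(root, a0, p0, w0, kp, kw)
  } else if (method == "auto") {
    A <- .competition_newton(A, a0, p0, w0, kp, kw, maxit = 3L)
  }

  st <- .species_from_afree(A, a0, p0, w0, kp, kw)
  # conservation check (mass action is exact by construction)
  resid <- abs(st$a_free + st$pa + st$wa - a0) / a0
  if (resid > 1e-8) {
    stop("competition solver failed to satisfy receptor conservation ",
         sprintf("(relative residual %.3g)", resid), call. = FALSE)
  }
  st
}

#' Predict fluorescence anisotropy of a competition mixture
#'
#' The default (`form = "fraction"`) is linear in the bound fraction of the
#' fluorescent probe, `r = r_free + (r_bound - r_free) * wa / w_total`, which
#' is the dimensionally consistent reading. `form = "printed"` reproduces the
#' literal published formula, linear in the molar concentration of the
#' profilin-actin complex, for audit purposes.
#'
#' @param state a [species_state()].
#' @param ends an [anisotropy_endpoints()].
#' @param w_total total probe concentration (molar), must be positive.
#' @param form `"fraction"` (default) or `"printed"`.
#' @return predicted anisotropy (dimensionless).
#' @export
predict_anisotropy <- function(state, ends, w_total,
                               form = c("fraction", "printed")) {
  stopifnot(inherits(state, "species_state"),
            inherits(ends, "anisotropy_endpoints"))
  form <- match.arg(form)
  if (!is.numeric(w_total) || !is.finite(w_total) || w_total <= 0) {
    stop("w_total must be positive", call. = FALSE)
  }
  x <- switch(form,
              fraction = state$wa / w_total,
              printed  = state$pa)
  ends$r_free + (ends$r_bound - ends$r_free) * x
}

# forward model of a competition titration: anisotropy at each titrant total
.competition_signal <- function(p_totals, a_total, w_total, kp, kw, ends) {
  vapply(p_totals, function(p0) {
    st <- solve_two_ligand_competition(
      competition_mixture(a_total, p0, w_total, kp, kw))
    predict_anisotropy(st, ends, w_total)
  }, numeric(1))
}

#' Fit a competitor affinity from an anisotropy competition titration
#'
#' Least-squares fit of the competitor dissociation constant (and the probe
#' anisotropy endpoints) to a titration series, with the exact competition
#' solver nested inside the model function. The probe affinity `kw` is held
#' fixed at the value in `mix_template`.
#'
#' @param series a [titration_series()] of anisotropy vs. competitor total.
#' @param mix_template a [competition_mixture()] giving `a_total`, `w_total`
#'   and the fixed probe affinity `kw`; its `p_total` and `kp` are ignored.
#' @param ends_guess an [anisotropy_endpoints()] used as starting values.
#' @return a list with `kp` (an [affinity_constant()] with standard error),
#'   `ends` (fitted endpoints), `ends_err`, `fit` (the `nls` object) and
#'   `residual_sd`.
#' @export
fit_competition_affinity <- function(series, mix_template, ends_guess) {
  stopifnot(inherits(series, "titration_series"),
            inherits(mix_template, "competition_mixture"),
            inherits(ends_guess, "anisotropy_endpoints"))
  p0 <- series$titrant_total
  y <- series$signal
  if (diff(range(y)) < 3 * stats::sd(diff(y)) / sqrt(2)) {
    warning("titration signal change is small relative to point-to-point ",
            "scatter; kp may be unidentifiable", call. = FALSE)
  }
  # starting kp: titrant concentration at the half-signal crossing
  half <- (max(y) + min(y)) / 2
  cross <- p0[which.min(abs(y - half))]
  kp0 <- max(cross, 1e-10)

  weights <- if (!is.null(series$signal_err) && all(series$signal_err > 0)) {
    1 / series$signal_err^2
  } else {
    rep(1, length(y))
  }

  a_total <- mix_template$a_total
  w_total <- mix_template$w_total
  kw <- mix_template$kw

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ .competition_signal(p0, a_total, w_total, kp, kw,
                              anisotropy_endpoints(rf, rb)),
      start = list(kp = kp0, rf = ends_guess$r_free, rb = ends_guess$r_bound),
      lower = c(kp = 1e-15, rf = -Inf, rb = -Inf),
      weights = weights,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) stop("competition fit failed to converge: ",
                             conditionMessage(e), call. = FALSE)
  )
  est <- summary(fit)$coefficients
  list(
    kp = affinity_constant(est["kp", 1], est["kp", 2]),
    ends = anisotropy_endpoints(est["rf", 1], est["rb", 1]),
    ends_err = c(r_free = est["rf", 2], r_bound = est["rb", 2]),
    fit = fit,
    residual_sd = summary(fit)$sigma
  )
}

#' Predict fluorescence intensity under the ligand-depletion binding isotherm
#'
#' Evaluates the quadratic ("ligand depletion") binding model. The bound
#' complex concentration is the physical root
#' `((K+A+T) - sqrt((K+A+T)^2 - 4 A T)) / 2`. With
#' `normalize = "titrant"` (the literal published form) the root is divided
#' by the total titrant `[T]`; with `normalize = "receptor"` it is divided by
#' the total labeled receptor `[A]`, i.e. the signal tracks the bound
#' fraction of the fluorescent species.
#'
#' @param a_total total labeled receptor (actin) concentration (molar).
#' @param t_total total titrant (e.g. thymosin-beta4) concentration (molar).
#' @param kd dissociation constant, [affinity_constant()] or number (molar).
#' @param ends a [quench_endpoints()].
#' @param normalize `"titrant"` (printed form, default) or `"receptor"`.
#' @return predicted intensity (arbitrary units).
#' @export
predict_quench <- function(a_total, t_total, kd, ends,
                           normalize = c("titrant", "receptor")) {
  stopifnot(inherits(ends, "quench_endpoints"))
  normalize <- match.arg(normalize)
  .check_nonneg(a_total, "a_total")
  .check_nonneg(t_total, "t_total")
  kd <- if (inherits(kd, "affinity_constant")) kd$kd else kd
  .check_nonneg(kd, "kd")
  if (normalize == "titrant" && any(t_total == 0)) {
    stop("t_total must be positive under titrant normalization", call. = FALSE)
  }
  s <- kd + a_total + t_total
  disc <- s^2 - 4 * a_total * t_total
  if (any(disc < 0)) {
    stop("negative discriminant in quadratic binding model", call. = FALSE)
  }
  at <- (s - sqrt(disc)) / 2
  frac <- switch(normalize,
                 titrant = at / t_total,
                 receptor = at / a_total)
  ends$i_free + (ends$i_bound - ends$i_free) * frac
}

#' Fit a dissociation constant from a fluorescence-quench titration
#'
#' Least-squares fit of the quadratic binding model to intensity vs. titrant
#' total. Defaults to `normalize = "receptor"` (signal tracks the bound
#' fraction of the labeled receptor), which is the identifiable form when
#' the titrant is in large excess over the labeled species; the literal
#' titrant-normalized form is selectable.
#'
#' @param series a [titration_series()] of intensity vs. titrant total.
#' @param a_total total labeled receptor concentration (molar).
#' @param normalize `"receptor"` (default) or `"titrant"`.
#' @return a list with `kd` (an [affinity_constant()]), `ends`
#'   (fitted [quench_endpoints()]), `ends_err`, `fit` and `residual_sd`.
#' @export
fit_quench_affinity <- function(series, a_total,
                                normalize = c("receptor", "titrant")) {
  stopifnot(inherits(series, "titration_series"))
  normalize <- match.arg(normalize)
  tt <- series$titrant_total
  y <- series$signal
  if (normalize == "titrant" && any(tt == 0)) {
    keep <- tt > 0
    tt <- tt[keep]; y <- y[keep]
  }
  half <- (max(y) + min(y)) / 2
  kd0 <- max(tt[which.min(abs(y - half))], 1e-9)
  weights <- if (!is.null(series$signal_err) && all(series$signal_err > 0)) {
    1 / series$signal_err^2
  } else {
    rep(1, length(y))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ predict_quench(a_total, tt, kd, quench_endpoints(i_f, i_b),
                         normalize = normalize),
      start = list(kd = kd0, i_f = y[1], i_b = y[length(y)]),
      lower = c(kd = 1e-15, i_f = -Inf, i_b = -Inf),
      weights = weights,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) stop("quench fit failed to converge: ",
                             conditionMessage(e), call. = FALSE)
  )
  est <- summary(fit)$coefficients
  list(
    kd = affinity_constant(est["kd", 1], est["kd", 2]),
    ends = quench_endpoints(est["i_f", 1], est["i_b", 1]),
    ends_err = c(i_free = est["i_f", 2], i_bound = est["i_b", 2]),
    fit = fit,
    residual_sd = summary(fit)$sigma
  )
}

#' Tabulate equilibrium species over a list of mixtures
#'
#' Solves each condition and returns one row per mixture; used to verify
#' assay designs (e.g. that added free profilin or thymosin-beta4 leaves the
#' profilin-actin complex as the dominant actin-bound pool).
#'
#' @param conditions a list of [competition_mixture()] objects.
#' @return a data.frame with totals, affinities and all equilibrium species.
#' @export
free_species_table <- function(conditions) {
  stopifnot(is.list(conditions))
  cols <- c("a_total", "p_total", "w_total", "kp", "kw",
            "a_free", "p_free", "w_free", "pa", "wa")
  if (length(conditions) == 0) {
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
    return(out)
  }
  rows <- lapply(conditions, function(mix) {
    st <- solve_two_ligand_competition(mix)
    data.frame(a_total = mix$a_total, p_total = mix$p_total,
               w_total = mix$w_total, kp = mix$kp, kw = mix$kw,
               a_free = st$a_free, p_free = st$p_free, w_free = st$w_free,
               pa = st$pa, wa = st$wa)
  })
  do.call(rbind, rows)
}
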