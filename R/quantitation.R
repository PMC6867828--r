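## Cellular quantitation arithmetic: western-blot standard curves and
## per-cell protein concentrations, lognormal cell-volume fitting,
## soluble/pellet fractionation, and Gaussian fitting of single-molecule
## formin velocity distributions.
##
## Per-cell concentration (molar):
##   concentration = (intensity / slope / n_cells) /
##                   (molecular_weight * accessible_fraction * cell_volume)
## with band intensity converted to protein mass through the slope of the
## reference standard curve, and only the endomembrane-free half of the
## cell volume assumed accessible by default.

# 1 um^3 = 1e-15 L
.UM3_TO_L <- 1e-15

#' Western-blot standard curve
#'
#' Ordinary least-squares line of band intensity vs. loaded protein mass.
#' The intercept is estimated and reported for QC, but mass inversion uses
#' the slope only.
#'
#' @param masses loaded reference masses (ng), strictly increasing, >= 3.
#' @param intensities background-subtracted band intensities.
#' @return an object of class `standard_curve` with `slope` (intensity/ng),
#'   `slope_err`, `intercept`, `intercept_err` and the `lm` fit.
#' @export
fit_standard_curve <- function(masses, intensities) {
  .check_nonneg(masses, "masses")
  .check_finite(intensities, "intensities")
  if (length(masses) < 3 || length(masses) != length(intensities)) {
    stop("need >= 3 (mass, intensity) pairs", call. = FALSE)
  }
  if (any(diff(sort(masses)) <= 0)) {
    stop("reference masses must be distinct", call. = FALSE)
  }
  fit <- stats::lm(intensities ~ masses)
  est <- .lm_coefs(fit)
  slope <- est["masses", 1]
  if (slope <= 0) {
    stop("non-positive standard-curve slope; check intensities", call. = FALSE)
  }
  structure(list(masses = masses, intensities = intensities,
                 slope = slope, slope_err = est["masses", 2],
                 intercept = est["(Intercept)", 1],
                 intercept_err = est["(Intercept)", 2],
                 fit = fit),
            class = "standard_curve")
}

#' Single western-blot band measurement
#'
#' @param intensity background-subtracted band intensity (>= 0).
#' @param n_cells number of cells loaded in the lane (>= 1).
#' @param protein label (`"actin"`, `"profilin1"`, `"profilin2"`, ...).
#' @param mw molecular weight (g/mol); defaults 42000 for actin, 15000 for
#'   profilins.
#' @return an object of class `blot_measurement`.
#' @export
blot_measurement <- function(intensity, n_cells, protein = "actin",
                             mw = NULL) {
  .check_nonneg(intensity, "intensity")
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  if (is.null(mw)) {
    mw <- if (grepl("^profilin", protein)) 15000 else 42000
  }
  .check_pos(mw, "mw")
  structure(list(intensity = intensity, n_cells = n_cells,
                 protein = protein, mw = mw),
            class = "blot_measurement")
}

#' Lognormal cell-volume model
#'
#' Maximum-likelihood lognormal fit on the raw volume samples (closed-form
#' MLE: mean and SD of log-volumes). The reported mean and SD are those of
#' the fitted lognormal distribution, `exp(mu + sigma^2/2)` and
#' `mean * sqrt(exp(sigma^2) - 1)`. A histogram least-squares mode is
#' available for comparison with histogram-based workflows.
#'
#' @param samples cell volumes (um^3), all positive; >= 30 required, a
#'   warning is issued below 300 samples.
#' @param method `"mle"` (default) or `"histogram"` (least squares of the
#'   lognormal density to binned counts).
#' @param bin_width histogram bin width (um^3) for the histogram mode.
#' @return an object of class `cell_volume_model` with `meanlog`, `sdlog`,
#'   `mean_volume` (um^3), `sd_volume` and `n`.
#' @export
fit_lognormal_volume <- function(samples, method = c("mle", "histogram"),
                                 bin_width = NULL) {
  method <- match.arg(method)
  .check_finite(samples, "samples")
  if (any(samples <= 0)) stop("volumes must be positive", call. = FALSE)
  n <- length(samples)
  if (n < 30) stop("need >= 30 volume samples", call. = FALSE)
  if (n < 300) {
    warning("fewer than 300 volume samples; volume model may be imprecise",
            call. = FALSE)
  }
  lx <- log(samples)
  if (method == "mle") {
    mu <- mean(lx)
    sig <- sqrt(mean((lx - mu)^2))  # MLE (n denominator)
  } else {
    if (is.null(bin_width)) bin_width <- diff(range(samples)) / 25
    breaks <- seq(min(samples) - bin_width, max(samples) + bin_width,
                  by = bin_width)
    h <- graphics::hist(samples, breaks = breaks, plot = FALSE)
    mids <- h$mids; dens <- h$density
    fit <- minpack.lm::nlsLM(
      dens ~ stats::dlnorm(mids, mu, sig),
      start = list(mu = mean(lx), sig = max(stats::sd(lx), 1e-3)),
      lower = c(mu = -Inf, sig = 1e-6))
    mu <- stats::coef(fit)[["mu"]]
    sig <- stats::coef(fit)[["sig"]]
  }
  mean_v <- exp(mu + sig^2 / 2)
  sd_v <- mean_v * sqrt(max(exp(sig^2) - 1, 0))
  structure(list(samples = samples, meanlog = mu, sdlog = sig,
                 mean_volume = mean_v, sd_volume = sd_v, n = n,
                 method = method),
            class = "cell_volume_model")
}

#' Build a volume model from summary values
#'
#' Convenience constructor when only a mean volume (and optionally its SD)
#' is available rather than raw samples.
#'
#' @param mean_volume mean cell volume (um^3).
#' @param sd_volume SD of the volume distribution (um^3), default 0.
#' @return a `cell_volume_model`.
#' @export
cell_volume_model <- function(mean_volume, sd_volume = 0) {
  .check_pos(mean_volume, "mean_volume")
  .check_nonneg(sd_volume, "sd_volume")
  structure(list(samples = NULL, meanlog = NA_real_, sdlog = NA_real_,
                 mean_volume = mean_volume, sd_volume = sd_volume,
                 n = NA_integer_, method = "summary"),
            class = "cell_volume_model")
}

#' Per-cell protein concentration from a blot measurement
#'
#' Inverts the band intensity through the standard-curve slope to a lane
#' mass, divides by the number of cells loaded, and converts to a molar
#' concentration using the molecular weight and the accessible fraction of
#' the mean cell volume. Errors are propagated to first order from the
#' slope standard error and the volume SD (treated as the uncertainty of
#' the mean volume when no sample count is available, otherwise scaled to
#' the standard error of the mean).
#'
#' @param meas a [blot_measurement()].
#' @param curve a [fit_standard_curve()] result.
#' @param vol a `cell_volume_model`.
#' @param accessible_volume_fraction fraction of the cell volume accessible
#'   to the protein (default 0.5: the endomembrane system is excluded).
#' @return an object of class `concentration_estimate` with `concentration`
#'   (molar), `concentration_err`, `mass_per_cell` (g) and the inputs.
#' @export
concentration_per_cell <- function(meas, curve, vol,
                                   accessible_volume_fraction = 0.5) {
  stopifnot(inherits(meas, "blot_measurement"),
            inherits(curve, "standard_curve"),
            inherits(vol, "cell_volume_model"))
  f <- accessible_volume_fraction
  if (f <= 0 || f > 1) {
    stop("accessible_volume_fraction must be in (0, 1]", call. = FALSE)
  }
  if (curve$slope == 0 || vol$mean_volume == 0) {
    stop("zero slope or zero volume", call. = FALSE)
  }
  mass_ng <- meas$intensity / curve$slope          # lane mass in ng
  mass_per_cell <- mass_ng * 1e-9 / meas$n_cells   # grams per cell
  vol_l <- vol$mean_volume * .UM3_TO_L
  conc <- mass_per_cell / (meas$mw * f * vol_l)

  vol_rel <- if (!is.na(vol$n) && vol$n > 1) {
    (vol$sd_volume / sqrt(vol$n)) / vol$mean_volume
  } else {
    vol$sd_volume / vol$mean_volume
  }
  conc_err <- .rel_err(conc, c(curve$slope_err / curve$slope, vol_rel))

  structure(list(concentration = conc, concentration_err = conc_err,
                 mass_per_cell = mass_per_cell,
                 accessible_volume_fraction = f,
                 protein = meas$protein),
            class = "concentration_estimate")
}

#' @export
print.concentration_estimate <- function(x, ...) {
  cat(sprintf("%s: %.3g uM", x$protein, x$concentration * 1e6))
  if (!is.na(x$concentration_err)) {
    cat(sprintf(" +/- %.2g uM", x$concentration_err * 1e6))
  }
  cat(sprintf(" (accessible volume fraction %.2g)\n",
              x$accessible_volume_fraction))
  invisible(x)
}

#' Soluble fraction and concentration from a fractionation measurement
#'
#' Computes the soluble fraction `S / (S + P)` from supernatant and pellet
#' band intensities and the absolute soluble concentration
#' `fraction * total`, with first-order error propagation from the
#' intensity errors (if given) and the total-concentration error.
#'
#' @param supernatant_intensity,pellet_intensity band intensities (>= 0,
#'   not both zero).
#' @param total_concentration total protein concentration (molar).
#' @param total_err standard error of the total concentration.
#' @param supernatant_err,pellet_err optional intensity standard errors.
#' @return a list with `fraction_soluble`, `fraction_err`,
#'   `soluble_concentration` and `soluble_err`.
#' @export
soluble_fraction <- function(supernatant_intensity, pellet_intensity,
                             total_concentration, total_err = NA_real_,
                             supernatant_err = NA_real_,
                             pellet_err = NA_real_) {
  .check_nonneg(supernatant_intensity, "supernatant_intensity")
  .check_nonneg(pellet_intensity, "pellet_intensity")
  .check_nonneg(total_concentration, "total_concentration")
  s <- supernatant_intensity; p <- pellet_intensity
  if (s + p == 0) stop("supernatant and pellet intensities are both zero",
                       call. = FALSE)
  frac <- s / (s + p)
  # d(frac)/ds = p/(s+p)^2, d(frac)/dp = -s/(s+p)^2
  frac_err <- if (is.na(supernatant_err) && is.na(pellet_err)) {
    NA_real_
  } else {
    se <- if (is.na(supernatant_err)) 0 else supernatant_err
    pe <- if (is.na(pellet_err)) 0 else pellet_err
    sqrt((p * se)^2 + (s * pe)^2) / (s + p)^2
  }
  sol <- frac * total_concentration
  sol_err <- .prod_err(frac, frac_err, total_concentration, total_err)
  list(fraction_soluble = frac, fraction_err = frac_err,
       soluble_concentration = sol, soluble_err = sol_err)
}

#' Gaussian fit of a single-molecule velocity distribution
#'
#' Maximum-likelihood Gaussian fit (sample mean and SD) of per-molecule
#' velocities, with optional per-cell grouping that averages within cells
#' before fitting (molecules are pooled by default, matching histogram
#' workflows). A histogram least-squares mode is available for comparison.
#'
#' @param velocities per-molecule velocities (subunits/s or um/s).
#' @param cell_id optional per-molecule cell identifiers.
#' @param per_cell average within cells first? Default `FALSE` (pooled).
#' @param unit unit tag carried through (`"subunits_per_s"` default).
#' @param method `"mle"` (default) or `"histogram"`.
#' @param bin_width histogram bin width for the histogram mode.
#' @return an object of class `velocity_distribution` with `mu`, `mu_err`,
#'   `sigma`, `sigma_err`, `n_molecules`, `n_cells` and `unit`.
#' @export
fit_gaussian_velocity <- function(velocities, cell_id = NULL,
                                  per_cell = FALSE,
                                  unit = "subunits_per_s",
                                  method = c("mle", "histogram"),
                                  bin_width = NULL) {
  method <- match.arg(method)
  .check_finite(velocities, "velocities")
  n_mol <- length(velocities)
  if (length(unique(velocities)) < 2) {
    stop("need at least 2 distinct velocity values", call. = FALSE)
  }
  if (n_mol < 30) {
    warning("fewer than 30 velocity values; distribution fit may be ",
            "imprecise", call. = FALSE)
  }
  n_cells <- if (is.null(cell_id)) NA_integer_ else length(unique(cell_id))
  x <- velocities
  if (per_cell) {
    if (is.null(cell_id)) stop("per_cell = TRUE requires cell_id", call. = FALSE)
    x <- as.numeric(tapply(velocities, cell_id, mean))
  }
  if (method == "mle") {
    mu <- mean(x)
    sig <- stats::sd(x)
  } else {
    if (is.null(bin_width)) bin_width <- diff(range(x)) / 20
    breaks <- seq(min(x) - bin_width, max(x) + bin_width, by = bin_width)
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    mids <- h$mids; dens <- h$density
    fit <- minpack.lm::nlsLM(dens ~ stats::dnorm(mids, mu, sig),
                             start = list(mu = mean(x), sig = stats::sd(x)),
                             lower = c(mu = -Inf, sig = 1e-12))
    mu <- stats::coef(fit)[["mu"]]
    sig <- stats::coef(fit)[["sig"]]
  }
  m <- length(x)
  structure(list(velocities = velocities, mu = mu, mu_err = sig / sqrt(m),
                 sigma = sig, sigma_err = sig / sqrt(2 * (m - 1)),
                 n_molecules = n_mol, n_cells = n_cells,
                 per_cell = per_cell, unit = unit, method = method),
            class = "velocity_distribution")
}

#' Velocity vs. relative concentration: proportional vs. saturating model
#'
#' Compares a linear-through-origin model (velocity proportional to the
#' soluble subunit concentration) against the hyperbolic saturation law for
#' a set of velocity distributions measured at different relative
#' profilin-actin levels, reporting the residual sum of squares of each so
#' that buffered elongation (near-constant velocity despite concentration
#' changes) is quantifiable.
#'
#' @param dists list of `velocity_distribution` objects.
#' @param rel_conc relative concentrations (same length as `dists`).
#' @param abs_conc optional absolute concentrations (molar); when supplied
#'   with >= 4 points, the hyperbolic model is fitted on them.
#' @return a list with `table` (means, SDs, concentrations),
#'   `proportional` (`slope`, `rss`) and `hyperbolic`
#'   (`fit`, `rss`, `identifiable`).
#' @export
velocity_vs_concentration <- function(dists, rel_conc, abs_conc = NULL) {
  stopifnot(is.list(dists))
  if (length(dists) != length(rel_conc)) {
    stop("dists and rel_conc must have matching lengths", call. = FALSE)
  }
  mus <- vapply(dists, `[[`, numeric(1), "mu")
  sds <- vapply(dists, `[[`, numeric(1), "sigma")
  ns <- vapply(dists, `[[`, numeric(1), "n_molecules")
  tab <- data.frame(rel_conc = rel_conc, v_mean = mus, v_sd = sds, n = ns)
  if (!is.null(abs_conc)) tab$abs_conc <- abs_conc

  prop_fit <- stats::lm(v_mean ~ 0 + rel_conc, data = tab)
  prop <- list(slope = stats::coef(prop_fit)[["rel_conc"]],
               rss = sum(stats::resid(prop_fit)^2))

  hyp <- list(fit = NULL, rss = NA_real_, identifiable = FALSE)
  if (!is.null(abs_conc) && length(mus) >= 4) {
    res <- tryCatch({
      curve <- velocity_curve(abs_conc, mus, sds, pmax(ns, 1))
      hfit <- suppressWarnings(fit_hyperbolic(curve))
      list(fit = hfit,
           rss = sum((mus - predict(hfit, abs_conc))^2),
           identifiable = TRUE)
    }, error = function(e) hyp)
    hyp <- res
  }
  list(table = tab, proportional = prop, hyperbolic = hyp)
}
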