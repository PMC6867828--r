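## Seeded generators emulating each assay the analysis stages consume, so
## that every fitter is testable by parameter recovery without experimental
## data. Each generator is a bit-reproducible function of
## (truth, design, noise, seed), has a zero-noise mode whose output lies
## exactly on the corresponding forward model, and returns the generating
## truth alongside the data.
##
## Default designs mirror the study conditions: anisotropy competition at
## 150 nM actin / 4 nM probe with 0-20 uM competitor; quench titration over
## 0-200 uM; stopped flow against 0.5 uM actin; velocity curves with 12
## concentrations from 1-175 uM and 40 filaments each; single-molecule
## velocity data with >= 10 cells and >= 650 molecules. Noise magnitudes
## (anisotropy SD 0.002, intensity CV 5%, per-filament velocity CV 15%)
## are synthetic conventions chosen at the visual scale of the assays'
## error bars.

# log-spaced concentration ladder including 0 is avoided: log spacing from
# lo to hi, n points
.ladder <- function(lo, hi, n) exp(seq(log(lo), log(hi), length.out = n))

#' Generate a synthetic anisotropy competition titration
#'
#' Forward model: exact two-ligand competition equilibrium followed by the
#' bound-probe-fraction anisotropy readout, plus additive Gaussian noise.
#'
#' @param kp true competitor (profilin) dissociation constant (molar).
#' @param kw probe dissociation constant (molar), held fixed in fitting.
#' @param a_total,w_total receptor and probe totals (molar).
#' @param titrant concentrations of the competitor (molar); default 12
#'   log-spaced points over 20 nM - 20 uM plus a zero point.
#' @param ends true [anisotropy_endpoints()].
#' @param noise_sd additive Gaussian SD on the anisotropy (0 = exact).
#' @param seed RNG seed (mandatory).
#' @return a list with `series` (a [titration_series()]), `mix_template`
#'   (a [competition_mixture()] with the fixed `kw`) and `truth`.
#' @export
gen_competition_titration <- function(kp = 18e-9, kw = 100e-9,
                                      a_total = 150e-9, w_total = 4e-9,
                                      titrant = c(0, .ladder(20e-9, 20e-6, 11)),
                                      ends = anisotropy_endpoints(0.05, 0.15),
                                      noise_sd = 0.002, seed) {
  .check_nonneg(noise_sd, "noise_sd")
  signal <- .competition_signal(titrant, a_total, w_total, kp, kw, ends)
  if (noise_sd > 0) {
    withr::local_seed(seed)
    signal <- signal + stats::rnorm(length(signal), 0, noise_sd)
  }
  list(series = titration_series(titrant, signal,
                                 signal_err = if (noise_sd > 0)
                                   rep(noise_sd, length(signal)) else NULL),
       mix_template = competition_mixture(a_total, 0, w_total, kp, kw),
       truth = list(kp = kp, kw = kw, a_total = a_total, w_total = w_total,
                    ends = ends, noise_sd = noise_sd, seed = seed))
}

#' Generate a synthetic fluorescence-quench titration
#'
#' Forward model: quadratic ligand-depletion isotherm (receptor-normalized
#' by default, the identifiable form when the titrant is in large excess),
#' plus multiplicative Gaussian noise.
#'
#' @param kd true dissociation constant (molar).
#' @param a_total labeled receptor total (molar).
#' @param titrant titrant concentrations (molar); default 12 log-spaced
#'   points over 50 nM - 200 uM plus a zero point.
#' @param ends true [quench_endpoints()].
#' @param noise_cv multiplicative noise CV (0 = exact).
#' @param normalize `"receptor"` (default) or `"titrant"` (printed form;
#'   zero titrant point dropped).
#' @param seed RNG seed.
#' @return a list with `series`, `a_total` and `truth`.
#' @export
gen_quench_titration <- function(kd = 1.2e-6, a_total = 150e-9,
                                 titrant = c(0, .ladder(50e-9, 200e-6, 11)),
                                 ends = quench_endpoints(1, 0.3),
                                 noise_cv = 0.05,
                                 normalize = c("receptor", "titrant"), seed) {
  normalize <- match.arg(normalize)
  .check_nonneg(noise_cv, "noise_cv")
  if (normalize == "titrant") titrant <- titrant[titrant > 0]
  signal <- predict_quench(a_total, titrant, kd, ends, normalize = normalize)
  if (noise_cv > 0) {
    withr::local_seed(seed)
    signal <- signal * (1 + stats::rnorm(length(signal), 0, noise_cv))
  }
  list(series = titration_series(titrant, signal),
       a_total = a_total,
       truth = list(kd = kd, a_total = a_total, ends = ends,
                    noise_cv = noise_cv, normalize = normalize, seed = seed))
}

#' Generate synthetic stopped-flow traces over a concentration ladder
#'
#' Each trace decays exponentially with
#' `k_obs = k_on * conc + k_off`, from `i_free` to `i_bound`, with additive
#' Gaussian noise. The titrant ladder defaults to excess profilin against
#' 0.5 uM actin. The time grid of each trace spans five e-folding times of
#' its own decay.
#'
#' @param k_on true association rate constant (M^-1 s^-1); no default - the
#'   generating value is always supplied by the caller.
#' @param k_off true dissociation rate (s^-1).
#' @param concs titrant concentrations (molar).
#' @param n_points points per trace.
#' @param i_free,i_bound true amplitudes.
#' @param noise_sd additive Gaussian SD on intensity (0 = exact).
#' @param seed RNG seed.
#' @return a list with `traces` (list of [stopped_flow_trace()]) and `truth`.
#' @export
gen_stopped_flow <- function(k_on, k_off,
                             concs = seq(1e-6, 10e-6, length.out = 6),
                             n_points = 500, i_free = 1, i_bound = 0,
                             noise_sd = 0.01, seed) {
  .check_pos(k_on, "k_on")
  .check_nonneg(k_off, "k_off")
  .check_nonneg(noise_sd, "noise_sd")
  withr::local_seed(seed)
  traces <- lapply(concs, function(cc) {
    k_obs <- k_on * cc + k_off
    tmax <- 5 / k_obs
    t <- seq(0, tmax, length.out = n_points)
    y <- (i_free - i_bound) * exp(-k_obs * t) + i_bound
    if (noise_sd > 0) y <- y + stats::rnorm(n_points, 0, noise_sd)
    stopped_flow_trace(t, y, profilin_total = cc)
  })
  list(traces = traces,
       truth = list(k_on = k_on, k_off = k_off, concs = concs,
                    i_free = i_free, i_bound = i_bound,
                    noise_sd = noise_sd, seed = seed))
}

#' Generate a synthetic concentration-velocity curve
#'
#' Per-filament velocities are drawn either by exact stochastic simulation
#' of the elongation cycle (`mode = "stochastic"`) or, in fast mode, from a
#' Gaussian centered on the analytic cycle velocity with a fixed
#' coefficient of variation (`mode = "gaussian"`, the default). With
#' `cv = 0` in fast mode the curve lies exactly on the analytic model.
#'
#' @param rates true [cycle_rates()].
#' @param concs concentrations (molar); default 12 log-spaced points over
#'   1-175 uM.
#' @param n_filaments filaments per concentration (default 40).
#' @param duration per-filament observation time (s), stochastic mode.
#' @param mode `"gaussian"` (fast) or `"stochastic"` (exact simulation).
#' @param cv per-filament velocity CV in fast mode (default 0.15).
#' @param seed RNG seed.
#' @return a list with `curve` (a [velocity_curve()]), `velocities`
#'   (per-condition list of per-filament velocities) and `truth`
#'   (including the exact `v_max`/`k_half` of the generating cycle).
#' @export
gen_velocity_curve <- function(rates, concs = .ladder(1e-6, 175e-6, 12),
                               n_filaments = 40, duration = 30,
                               mode = c("gaussian", "stochastic"),
                               cv = 0.15, seed) {
  stopifnot(inherits(rates, "cycle_rates"))
  mode <- match.arg(mode)
  .check_nonneg(cv, "cv")
  withr::local_seed(seed)
  v_true <- cycle_velocity(rates, concs)
  vels <- vector("list", length(concs))
  if (mode == "gaussian") {
    for (i in seq_along(concs)) {
      vels[[i]] <- if (cv == 0) rep(v_true[i], n_filaments)
      else stats::rnorm(n_filaments, v_true[i], cv * v_true[i])
    }
  } else {
    sub_seeds <- matrix(sample.int(.Machine$integer.max,
                                   length(concs) * n_filaments),
                        nrow = length(concs))
    for (i in seq_along(concs)) {
      vels[[i]] <- vapply(seq_len(n_filaments), function(j) {
        traj <- simulate_filament(rates, concs[i], duration,
                                  seed = sub_seeds[i, j])
        estimate_trajectory_velocity(traj)$velocity
      }, numeric(1))
    }
  }
  curve <- velocity_curve(
    conc = concs,
    v_mean = vapply(vels, mean, numeric(1)),
    v_sd = vapply(vels, stats::sd, numeric(1)),
    n = rep(n_filaments, length(concs))
  )
  hp <- hyperbolic_params_from_cycle(rates)
  list(curve = curve, velocities = vels,
       truth = list(rates = rates, v_max = hp$v_max, k_half = hp$k_half,
                    mode = mode, cv = cv, duration = duration, seed = seed))
}

#' Generate a panel of mutant velocity curves
#'
#' One curve per profilin variant, sharing `k_trans`, with per-variant
#' scale factors on the profilin release rate (and optionally on the
#' binding rate). The default panel mirrors a tight-binding variant
#' (release slowed 5-fold), wild type, and two progressively weaker
#' binders (release accelerated ~1.5- and ~4-fold), so the generated
#' maximal velocities are ordered by the release rate.
#'
#' @param rates wild-type [cycle_rates()].
#' @param release_scale named vector of `k_release` scale factors.
#' @param bind_scale optional named vector of `k_bind` scale factors
#'   (default: all 1).
#' @param seed RNG seed; per-variant curves use sub-seeds drawn from it.
#' @param ... passed to [gen_velocity_curve()] (concs, n_filaments, mode, cv).
#' @return a list with `curves` (named list of [velocity_curve()]) and
#'   `truth` (per-variant rates and exact saturation parameters).
#' @export
gen_mutant_panel <- function(rates,
                             release_scale = c(tight = 0.2, wt = 1,
                                               E82A = 1.5, R88K = 4),
                             bind_scale = NULL, seed, ...) {
  stopifnot(inherits(rates, "cycle_rates"))
  if (is.null(bind_scale)) {
    bind_scale <- stats::setNames(rep(1, length(release_scale)),
                                  names(release_scale))
  }
  stopifnot(identical(names(bind_scale), names(release_scale)))
  withr::local_seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, length(release_scale))
  curves <- list(); truth <- list()
  for (i in seq_along(release_scale)) {
    nm <- names(release_scale)[i]
    ri <- cycle_rates(rates$k_bind * bind_scale[[i]], rates$k_trans,
                      rates$k_release * release_scale[[i]])
    g <- gen_velocity_curve(ri, seed = sub_seeds[i], ...)
    curves[[nm]] <- g$curve
    truth[[nm]] <- g$truth
  }
  list(curves = curves, truth = truth)
}

#' Generate formin-accelerated velocity curves
#'
#' One curve per formin, generated from the free-end cycle with that
#' formin's acceleration factors applied; a `"free"` curve (no formin) is
#' always included. The default panel gives mDia1 a 4-fold release
#' acceleration.
#'
#' @param rates free-end [cycle_rates()].
#' @param formins named list of [formin_factors()].
#' @param seed RNG seed.
#' @param ... passed to [gen_velocity_curve()].
#' @return a list with `curves` and `truth`.
#' @export
gen_formin_curves <- function(rates,
                              formins = list(
                                mDia1 = formin_factors(6, 4, "mDia1")),
                              seed, ...) {
  stopifnot(inherits(rates, "cycle_rates"))
  withr::local_seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, length(formins) + 1L)
  g0 <- gen_velocity_curve(rates, seed = sub_seeds[1], ...)
  curves <- list(free = g0$curve)
  truth <- list(free = g0$truth)
  for (i in seq_along(formins)) {
    nm <- names(formins)[i]
    gi <- gen_velocity_curve(apply_formin(rates, formins[[i]]),
                             seed = sub_seeds[i + 1L], ...)
    curves[[nm]] <- gi$curve
    truth[[nm]] <- c(gi$truth, list(factors = formins[[i]]))
  }
  list(curves = curves, truth = truth)
}

#' Generate hierarchical single-molecule velocity data
#'
#' Per-cell mean velocities are drawn from `Normal(mu, sigma_cell)` and
#' per-molecule velocities from `Normal(cell mean, sigma_mol)`;
#' `sigma_cell = 0` gives the pooled model. Defaults give 10 cells with 65
#' molecules each (650 molecules total).
#'
#' @param mu true mean velocity (subunits/s).
#' @param sigma_mol within-cell molecular SD.
#' @param sigma_cell between-cell SD of cell means (default 0).
#' @param n_cells number of cells.
#' @param n_per_cell molecules per cell.
#' @param seed RNG seed.
#' @return a list with `data` (data.frame `cell_id`, `velocity`) and `truth`.
#' @export
gen_single_molecule_velocities <- function(mu = 1450, sigma_mol = 300,
                                           sigma_cell = 0, n_cells = 10,
                                           n_per_cell = 65, seed) {
  .check_nonneg(sigma_mol, "sigma_mol")
  .check_nonneg(sigma_cell, "sigma_cell")
  withr::local_seed(seed)
  cell_means <- if (sigma_cell == 0) rep(mu, n_cells)
  else stats::rnorm(n_cells, mu, sigma_cell)
  vel <- unlist(lapply(seq_len(n_cells), function(i) {
    if (sigma_mol == 0) rep(cell_means[i], n_per_cell)
    else stats::rnorm(n_per_cell, cell_means[i], sigma_mol)
  }))
  list(data = data.frame(cell_id = rep(seq_len(n_cells), each = n_per_cell),
                         velocity = vel),
       truth = list(mu = mu, sigma_mol = sigma_mol, sigma_cell = sigma_cell,
                    n_cells = n_cells, n_per_cell = n_per_cell, seed = seed))
}

#' Generate a synthetic quantitative western-blot dataset
#'
#' Inverts the per-cell concentration arithmetic to produce lane
#' intensities from true per-cell concentrations: per-cell protein mass is
#' `conc * mw * fraction * mean_volume`, the lane intensity is
#' `slope * lane mass`, and multiplicative noise is applied to all
#' intensities. Cell volumes are drawn from the generating lognormal; in
#' the zero-noise mode all volumes collapse to the true distribution mean,
#' making the round trip through the quantitation stage an exact inverse.
#'
#' @param true_conc named vector of true per-cell concentrations (molar).
#' @param mw named vector of molecular weights (g/mol), same names.
#' @param mean_volume true mean cell volume (um^3).
#' @param sdlog_volume lognormal shape of the volume distribution.
#' @param n_volumes number of single-cell volume samples.
#' @param n_replicates independent blot replicates per protein (the
#'   analysis averages lane intensities per protein before inversion).
#' @param n_cells_per_lane cells loaded per lane.
#' @param slope true standard-curve slope (intensity per ng).
#' @param standard_masses reference masses (ng).
#' @param accessible_volume_fraction as in [concentration_per_cell()].
#' @param noise_cv multiplicative noise CV on all intensities (0 = exact).
#' @param seed RNG seed.
#' @return a list with `standards` (data.frame `mass_ng`, `intensity`),
#'   `lanes` (data.frame `lane`, `protein`, `replicate`, `intensity`,
#'   `n_cells`, `mw`), `volumes` (data.frame `volume_um3`) and `truth`.
#' @export
gen_blot_dataset <- function(true_conc = c(actin = 100e-6, profilin1 = 50e-6),
                             mw = c(actin = 42000, profilin1 = 15000),
                             mean_volume = 2000, sdlog_volume = 0.3,
                             n_volumes = 350, n_replicates = 3,
                             n_cells_per_lane = 5e4,
                             slope = 100,
                             standard_masses = c(2.5, 5, 10, 20, 40, 80),
                             accessible_volume_fraction = 0.5,
                             noise_cv = 0.1, seed) {
  stopifnot(identical(names(true_conc), names(mw)))
  .check_nonneg(noise_cv, "noise_cv")
  withr::local_seed(seed)

  f <- accessible_volume_fraction
  vol_l <- mean_volume * .UM3_TO_L
  mass_per_cell <- true_conc * mw * f * vol_l          # grams
  lane_mass_ng <- mass_per_cell * n_cells_per_lane * 1e9

  noisy <- function(x) if (noise_cv == 0) x else
    x * (1 + stats::rnorm(length(x), 0, noise_cv))

  standards <- data.frame(mass_ng = standard_masses,
                          intensity = noisy(slope * standard_masses))
  nprot <- length(true_conc)
  lanes <- data.frame(
    lane = seq_len(nprot * n_replicates),
    protein = rep(names(true_conc), each = n_replicates),
    replicate = rep(seq_len(n_replicates), nprot),
    intensity = noisy(rep(slope * lane_mass_ng, each = n_replicates)),
    n_cells = n_cells_per_lane,
    mw = rep(unname(mw), each = n_replicates))
  volumes <- data.frame(volume_um3 = if (noise_cv == 0)
    rep(mean_volume, n_volumes)
    else stats::rlnorm(n_volumes,
                       log(mean_volume) - sdlog_volume^2 / 2, sdlog_volume))
  list(standards = standards, lanes = lanes, volumes = volumes,
       truth = list(conc = true_conc, mw = mw, mean_volume = mean_volume,
                    sdlog_volume = sdlog_volume, slope = slope,
                    n_replicates = n_replicates,
                    n_cells_per_lane = n_cells_per_lane,
                    accessible_volume_fraction = f,
                    noise_cv = noise_cv, seed = seed))
}
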