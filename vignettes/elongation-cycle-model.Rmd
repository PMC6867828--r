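---
title: "The profilin-actin elongation cycle: models, fitters and synthetic assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The profilin-actin elongation cycle: models, fitters and synthetic assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actinpacer)
```

## The problem

Cells maintain tens to hundreds of micromolar of polymerizable actin, almost
all of it as the 1:1 profilin-actin complex. The textbook picture of barbed-end
elongation is a single diffusion-limited binding step, so the growth speed
should scale linearly with the soluble subunit concentration — and should
therefore vary wildly between cell types and conditions. `actinpacer`
implements the alternative: elongation from profilin-actin is a multi-step
cycle whose last step, profilin release from the terminal protomer, is
concentration-independent and rate-limiting near physiological subunit levels.
That single feature makes growth speeds *saturate*, and makes them robust
("buffered") against changes in the soluble pool. Formin polymerases
accelerate both the binding and the release step, raising the ceiling without
destroying the buffering.

The package provides, as tested and reusable components, every quantitative
stage such a study needs: the exact competition-binding and quench equilibria
used to measure monomer affinities, stopped-flow pseudo-first-order analysis,
the elongation-cycle model itself (analytic and stochastic), velocity-curve
fitting, the cellular quantitation arithmetic for per-cell protein
concentrations, and seeded synthetic-data generators so that every fitter is
validated by parameter recovery rather than against unavailable raw data.

## The elongation-cycle model

A barbed end cycles through three states:

1. **Binding** (bimolecular): a profilin-actin complex binds a free end with
   rate `k_bind * c`, where `c` is the total profilin-actin concentration.
   The incoming subunit is incorporated at this point, so the filament length
   increments here; the end is now transiently capped by profilin.
2. **Monomer-to-filament transition** (`k_trans`, first order): the terminal
   subunit's structural transition, independent of `c` and of ATP hydrolysis.
3. **Profilin release** (`k_release`, first order): profilin dissociates from
   the terminal protomer, regenerating a free end.

Because the three steps are sequential and (on the timescale of growth)
irreversible, the mean time per added subunit is the sum of three exponential
waiting times, and the steady-state velocity is the harmonic sum

```
v(c) = [ 1/(k_bind c) + 1/k_trans + 1/k_release ]^-1 .
```

This is *exactly* the hyperbolic (Michaelis-Menten-like) saturation law
`v = v_max c / (K_0.5 + c)` with

```
v_max = (1/k_trans + 1/k_release)^-1 ,    K_0.5 = v_max / k_bind .
```

`cycle_velocity()` evaluates the harmonic sum, and
`hyperbolic_params_from_cycle()` performs the closed-form reduction; the
equivalence is checked to 1e-12 relative over random rate sets in the test
suite. Two consequences carried through the package:

* `v_max` depends only on the two first-order rates — and only through their
  harmonic sum. Velocity data alone therefore cannot separate `k_trans` from
  `k_release`; the package reports the lumped `v_max` and treats `k_trans` as
  "fast" in its default parameterizations. This degeneracy is intrinsic, not
  a fitting artifact.
* The initial slope of the curve is exactly `k_bind`, which is why
  `fit_linear_regime()` on the low-concentration points estimates the
  apparent association rate constant.

Reversibility of the binding step is omitted: a finite unbinding rate before
the transition renormalizes the effective `k_bind` without changing the
hyperbolic form, and the data this model is fitted to are two-parameter
hyperbolas. Depolymerization is likewise neglected in cycle mode (growth at
hundreds of subunits/s dwarfs barbed-end off-rates); the bare-filament
simulator (`simulate_bare_filament()`) keeps the loss pathway for
profilin-free monomer kinetics, where it matters.

### Formins

Formins act on the cycle in two places: the FH1 domains concentrate
profilin-actin at the end (multiplying `k_bind` by `f_bind`), and the FH2
ring promotes profilin release (multiplying `k_release` by `f_release`).
`apply_formin()` implements exactly this; `k_trans` is left unmodified
because velocity data cannot attribute a change to it separately (see the
degeneracy above). `relative_enhancement()` shows the signature of this
two-point action: the velocity ratio formin/free interpolates monotonically
from `f_bind` at vanishing concentration to the `v_max` ratio (≈ `f_release`
when release limits) at saturation. When the two factors are matched, the
enhancement is the same at every concentration — the "constant rate
enhancement" regime.

### Stochastic simulator

`simulate_filament()` draws the three exponential waiting times of each cycle
directly (an exact-event realization — no time discretization), increments
length at the binding event, and records per-event end occupancy. Waiting
times are generated in vectorized chunks for speed, which does not change the
distribution: each reaction's time is still an independent exponential draw.
Trajectories are bit-reproducible given the recorded seed; an event cap
(default 1e7) aborts runaway simulations with a truncation error that still
carries the partial trajectory. `estimate_trajectory_velocity()` fits a
least-squares slope through all trajectory points, mirroring how kymograph
slopes are measured, and converts via the 2.7 nm subunit rise
(`convert_velocity()`: 1450 subunits/s = 3.915 µm/s).

The bare-filament mode is a birth-death process (gain `k_plus c`, loss
`k_minus`, floored at zero length, where only gain can fire). Its analytic
mean velocity `k_plus c - k_minus` — zero at the critical concentration — is
the oracle the simulator is tested against.

## Binding equilibria

Monomer affinities come from two assay models:

**Two-ligand competition** (anisotropy assays): profilin and a fluorescent
probe compete for actin monomers. Free actin `A` satisfies the conservation
equation `A (1 + P0/(K_P+A) + W0/(K_W+A)) = A0`, a cubic in `A`.
`solve_two_ligand_competition()` uses the closed-form trigonometric solution
of that cubic. Two numerical guards matter in practice:

* the argument of `acos` can leave `[-1, 1]` by a few ulp near degenerate
  roots; it is clamped when within 1e-9, and
* when totals and affinities are strongly mismatched (free receptor many
  orders of magnitude below the totals), the closed form loses up to half its
  digits to cancellation. The solver estimates its own root error from the
  conservation residual and falls back to bracketed root-finding (Brent plus
  a Newton polish on the monotone conservation function) whenever the
  estimated relative error exceeds 1e-10.

All species are reconstructed from the free-receptor root through the
mass-action ratios (`p_free = P0 K_P/(K_P+A)` etc.), which is cancellation
free, so mass action holds at machine precision by construction and
conservation is checked explicitly. The test suite compares the solver
against an independently coded bisection oracle over 1000 random mixtures
spanning 1 nM-1 mM totals and 1 nM-100 µM affinities.

The anisotropy readout defaults to linearity in the *bound probe fraction*
(`wa / w_total`), the dimensionally consistent form; a literal published
variant that is linear in the molar complex concentration is retained behind
`form = "printed"` for auditability.

**Ligand-depletion quadratic** (quench assays): a labeled monomer at fixed
concentration titrated with a binder, no competing species. The bound complex
is the physical root of the quadratic. Two normalizations exist in the
literature: dividing the root term by the total *titrant* or by the total
labeled *receptor*. `predict_quench()` defaults to the titrant form (the
printed convention it reproduces); the fitting and generation stages default
to the receptor form, because with a titrant in 1000-fold excess the
titrant-normalized signal excursion is of order 1e-4 of full scale and no
affinity is identifiable from it — the receptor-normalized signal spans the
full free-to-bound range. Both are selectable everywhere.

## Stopped-flow kinetics

`fit_single_exponential()` fits `I(t) = (I_f - I_b) exp(-k_obs t) + I_b` with
endpoint-derived starting values and a log-linearized rate guess, warns when
the trace spans fewer than three e-folding times, and rejects non-positive
rates. A dead-time offset is *not* a separate parameter — it is structurally
confounded with the amplitude (`(I_f-I_b) e^{k t0}` is one constant), so the
`offset` option shifts the time origin instead, which is what translation
invariance of `k_obs` requires. An optional linear drift term is off by
default. `fit_association_rate()` regresses `k_obs` on titrant concentration
with a free intercept: the slope is `k_on`, and the intercept is an
independent check on `k_off`. `dissociation_rate()` applies
`k_off = K_D k_on` with first-order Gaussian error propagation
(`σ² = (k_on σ_KD)² + (K_D σ_kon)²`), validated against 1e5-draw Monte-Carlo
to better than 2%.

## Cellular quantitation

`concentration_per_cell()` chains: band intensity → lane mass via the
standard-curve *slope* (the fitted intercept is reported for QC but not used
in the inversion), ÷ cells per lane → mass per cell, ÷ (molecular weight ×
accessible volume) → molar concentration. Division by the cell count is the
only dimensionally consistent reading of the published arithmetic and is
applied explicitly. The accessible volume fraction defaults to 0.5 (the
endomembrane system excludes roughly half the cell volume); since this is an
assumption bounding at most a two-fold overestimate, it is a plain argument.
Volume and velocity distributions are fitted by closed-form maximum
likelihood on the raw samples (exact for the lognormal and Gaussian
families); a histogram least-squares mode exists for comparison with
histogram-based workflows, and the two agree asymptotically. Molecular
weights default to 42 kDa (actin) and 15 kDa (profilin). A worked dimensional
anchor: 1 pg of a 42 kDa protein per cell, in half of a 2000 µm³ volume, is
23.8 µM.

`velocity_vs_concentration()` formalizes the buffering comparison: it fits
both a proportional (through-origin) model and the saturation law to mean
velocities across conditions and reports both residual sums of squares, so
"velocity does not scale with concentration" becomes a model comparison
rather than a verbal claim. `buffering_ratio()` gives the closed form
`fold (K_0.5 + c) / (K_0.5 + fold·c)`; at `c = 5 K_0.5` a 3-fold rise in
subunits yields only a 12.5% velocity increase.

## Synthetic data and what passing tests show

Every assay consumed by the fitting stages has a seeded generator
(`gen_*`) that records its generating truth. Three contracts hold throughout
and are tested: bit-reproducibility per seed, a zero-noise mode lying exactly
on the forward model, and a closed recovery loop with its fitter.

Default designs are the study conditions: anisotropy competition at 150 nM
actin and 4 nM probe over 0-20 µM competitor; quench titrations over 0-200 µM;
stopped flow against 0.5 µM actin with the titrant in excess; velocity curves
with 12 concentrations spanning 1-175 µM and 40 filaments per condition;
single-molecule velocities from ≥10 cells and ≥650 molecules; cell-volume
samples n ≥ 300; blot intensities in replicate (N = 3, averaged per protein
before inversion). The wild-type cycle parameterization used in examples and
recovery runs is `k_bind = 1e7 M⁻¹s⁻¹`, `k_trans = 5000 s⁻¹`,
`k_release = 556 s⁻¹`, i.e. `v_max ≈ 500` subunits/s with `K_0.5 ≈ 50 µM` —
saturation above 100 µM and near-linearity below 10 µM. Mutant panels scale
`k_release` by {0.2, 1, 1.5, 4} (a tight binder that slows release five-fold,
wild type, and two progressively weaker binders), and the default formin
factors are (6, 4).

Noise magnitudes are synthetic conventions, not measured values: additive
anisotropy SD 0.002, intensity CV 5% (blots 10%), per-filament velocity CV
15% in the fast (Gaussian) curve mode. They are chosen at the visual scale of
the corresponding assays' error bars and are stated wherever they matter.
Recovery tolerances for the noisy fits were fixed once from multi-seed
oracle runs before being frozen into the tests (25% for the two titration
affinities at these designs — the information content of a 12-point titration
with these endpoints, not a solver limitation; 10%/15% for the velocity-curve
parameters).

What these generators deliberately do not emulate: image-level artifacts
(tracking errors, bleaching, background), filament nucleation and pausing,
instrument dead time, inter-blot transfer variability, or cell-to-cell
kinetic heterogeneity beyond a Gaussian between-cell term. Passing recovery
tests therefore demonstrate the correctness and statistical calibration of
the estimators under the stated noise models — not robustness to every
failure mode of the real assays.

## Numerical choices and degenerate inputs

* Titration series are sorted by titrant concentration; duplicates are
  treated as replicates. Fits are unweighted unless per-point errors are
  supplied, in which case inverse-variance weights are used.
* Nonlinear fits use Levenberg-Marquardt (`minpack.lm::nlsLM`) with
  data-derived starting values (half-saturation crossings, endpoint
  amplitudes, log-linear rate guesses). Parameter lower bounds are zero.
* Zero-ligand, zero-receptor and zero-concentration limits short-circuit to
  their exact answers before any numerics run.
* Simulation RNG is scoped (`withr`): runs are reproducible per seed without
  clobbering the caller's RNG state; multi-run generators draw sub-seeds
  from the master seed.
* Low-information inputs produce warnings, not silent numbers: flat
  titrations, traces shorter than three e-folds, curves with no curvature
  (`K_0.5` outside the sampled range), volume samples below n = 300,
  velocity samples below n = 30.

## Limitations

The cycle model is a forward, sequential, memoryless description: no
force-velocity coupling, no nucleotide-state tracking on the lattice, no
pointed-end dynamics, no nucleation, at most two competing ligands in the
equilibria. `v_max` identifies only the harmonic sum of the two first-order
rates. Whether formins also modify the monomer-to-filament transition cannot
be decided from velocity data and is fixed to "no" by construction. These
boundaries are deliberate; within them every exported quantity is backed by
an analytic oracle, an independent numerical oracle, or a pre-registered
recovery tolerance in the test suite.
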