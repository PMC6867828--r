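# actinpacer

Kinetic and equilibrium analysis of actin filament elongation from
profilin-actin.

Most cytoplasmic actin monomers in mammalian cells are held in profilin-actin
complexes at 50-200 µM. If barbed-end growth were a single diffusion-limited
binding step, filament velocities would scale linearly with that
concentration and differ several-fold between cell types. `actinpacer`
implements the multi-step alternative: elongation is a three-reaction cycle —

```
free end  --k_bind·c-->  profilin-capped end  --k_trans-->  post-transition end  --k_release-->  free end  (+1 subunit)
```

— whose concentration-independent last step, profilin release from the
terminal protomer, caps the growth rate. The steady-state velocity is the
harmonic sum

v(c) = [ 1/(k_bind·c) + 1/k_trans + 1/k_release ]⁻¹,

which is exactly the saturation law v = v_max·c/(K₀.₅ + c) with
v_max = (1/k_trans + 1/k_release)⁻¹ and K₀.₅ = v_max/k_bind. Formin
polymerases multiply k_bind (via FH1) and k_release (via FH2), raising the
ceiling while preserving the insensitivity of velocity to the soluble pool
("buffered" elongation).

The package covers the full quantitative workflow around that model:

* **binding equilibria** — exact two-ligand competition solver (closed-form
  trigonometric cubic with a root-finding fallback), anisotropy and
  fluorescence-quench forward models, affinity fitters
  (`solve_two_ligand_competition`, `fit_competition_affinity`,
  `fit_quench_affinity`, `free_species_table`);
* **binding kinetics** — stopped-flow single-exponential fits, k_obs vs.
  concentration regression for k_on, and k_off = K_D·k_on with error
  propagation (`fit_single_exponential`, `fit_association_rate`,
  `dissociation_rate`);
* **elongation model** — analytic cycle velocity, exact stochastic
  single-filament simulation, formin factors, hyperbolic/linear velocity
  fits, buffering ratios (`cycle_velocity`, `simulate_filament`,
  `apply_formin`, `fit_hyperbolic`, `fit_linear_regime`, `buffering_ratio`);
* **quantitation** — western-blot standard curves, per-cell molar
  concentrations, lognormal cell-volume and Gaussian velocity-distribution
  fits, soluble fractions (`fit_standard_curve`, `concentration_per_cell`,
  `fit_lognormal_volume`, `fit_gaussian_velocity`, `soluble_fraction`);
* **synthetic data** — seeded generators for every assay above (`gen_*`),
  each with recorded ground truth, an exact zero-noise mode and a closed
  parameter-recovery loop in the tests.

## Worked example

Simulate single filaments at the wild-type cycle parameterization
(v_max ≈ 500 subunits/s, K₀.₅ ≈ 50 µM), refit the saturation law, and ask how
buffered growth is near saturation:

```r
library(actinpacer)

rates <- cycle_rates(k_bind = 1e7, k_trans = 5000, k_release = 556)
hyperbolic_params_from_cycle(rates)
#> hyperbolic saturation fit: v_max = 500.4 subunits/s, K_0.5 = 5.004e-05 M

sim <- gen_velocity_curve(rates, mode = "stochastic",
                          n_filaments = 40, duration = 30, seed = 2026)
fit <- fit_hyperbolic(sim$curve)
fit
#> hyperbolic saturation fit: v_max = 500.3 subunits/s (SE 0.362), K_0.5 = 5.005e-05 M (SE 8.69e-08)

buffering_ratio(fit, c_base = 5 * fit$k_half, fold = 3)
#> [1] 1.125
```

480 simulated filaments (12 concentrations × 40 filaments, 30 s each) return
the generating v_max and K₀.₅ to a fraction of a percent, and tripling the
subunit concentration from 5×K₀.₅ raises the velocity by only 12.5% — the
model-level statement of buffered elongation.

The equilibrium side, on a synthetic anisotropy competition titration
(150 nM actin, 4 nM probe, truth K_D = 18 nM, anisotropy noise SD 0.002):

```r
tit <- gen_competition_titration(kp = 18e-9, noise_sd = 0.002, seed = 42)
cf <- fit_competition_affinity(tit$series, tit$mix_template,
                               anisotropy_endpoints(0.04, 0.16))
cf$kp
#> K_D = 1.509e-08 M (SE 2.72e-09 M)

dissociation_rate(cf$kp, k_on = 4.28e7, k_on_err = 2e6)$k_off
#> [1] 0.6457683
```

The fitted K_D (15.1 ± 2.7 nM against a generating 18 nM) reflects the
information content of a 12-point titration at this noise level; combining it
with an association rate constant gives the profilin-from-monomer
dissociation rate via k_off = K_D·k_on.

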