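# Elongation-cycle model: analytic velocity, hyperbolic reduction, formin
# factors, stochastic simulators, velocity estimation and curve fitting.

test_that("cycle velocity is zero at zero concentration and saturates at the release-limited rate", {
  r <- wt_rates()
  expect_equal(cycle_velocity(r, 0), 0)
  # k_trans -> infinity proxy: saturation approaches k_release
  r_fast <- cycle_rates(5e7, 1e12, 500)
  expect_equal(cycle_velocity(r_fast, 1), 500, tolerance = 1e-3)
  # direct arithmetic oracle: harmonic sum at 100 uM
  r2 <- cycle_rates(5e7, 5000, 556)
  expect_equal(cycle_velocity(r2, 100e-6),
               1 / (1 / (5e7 * 100e-6) + 1 / 5000 + 1 / 556),
               tolerance = 1e-12)
  # monotone increasing in concentration
  v <- cycle_velocity(r, seq(1e-6, 500e-6, length.out = 50))
  expect_true(all(diff(v) > 0))
})

test_that("the cycle model is exactly hyperbolic with the closed-form parameters", {
  withr::with_seed(5, {
    for (i in 1:20) {
      r <- cycle_rates(10^runif(1, 6, 8), 10^runif(1, 2, 5), 10^runif(1, 1, 4))
      hp <- hyperbolic_params_from_cycle(r)
      conc <- 10^seq(-7, -2, length.out = 200)
      dev <- max(abs(cycle_velocity(r, conc) - predict(hp, conc))) / hp$v_max
      expect_lt(dev, 1e-12)
      # half-saturation identity
      expect_equal(cycle_velocity(r, hp$k_half), hp$v_max / 2,
                   tolerance = 1e-12)
    }
  })
})

test_that("saturation parameters obey the cycle scaling laws", {
  r <- wt_rates()
  hp <- hyperbolic_params_from_cycle(r)
  # doubling k_bind halves k_half, leaves v_max unchanged
  hp2 <- hyperbolic_params_from_cycle(
    cycle_rates(2 * r$k_bind, r$k_trans, r$k_release))
  expect_equal(hp2$v_max, hp$v_max)
  expect_equal(hp2$k_half, hp$k_half / 2)
  # v_max increases with k_release and k_trans, independent of k_bind
  expect_gt(hyperbolic_params_from_cycle(
    cycle_rates(r$k_bind, r$k_trans, 2 * r$k_release))$v_max, hp$v_max)
  expect_gt(hyperbolic_params_from_cycle(
    cycle_rates(r$k_bind, 2 * r$k_trans, r$k_release))$v_max, hp$v_max)
})

test_that("formin factors act multiplicatively on reactions 1 and 3 only", {
  r <- wt_rates()
  expect_equal(apply_formin(r, formin_factors(1, 1)), r)
  fr <- apply_formin(r, formin_factors(6, 4, "mDia1"))
  expect_equal(fr$k_bind, 6 * r$k_bind)
  expect_equal(fr$k_trans, r$k_trans)
  expect_equal(fr$k_release, 4 * r$k_release)
  expect_error(formin_factors(0.5, 1), ">= 1")
})

test_that("a pure release acceleration multiplies the maximal rate when release limits", {
  # k_trans >> k_release: 4-fold release acceleration ~4x v_max
  r <- cycle_rates(1e7, 1e6, 500)
  f4 <- formin_factors(1, 4)
  ratio <- hyperbolic_params_from_cycle(apply_formin(r, f4))$v_max /
    hyperbolic_params_from_cycle(r)$v_max
  expect_equal(ratio, 4, tolerance = 0.01)
})

test_that("relative enhancement interpolates monotonically from f_bind to the v_max ratio", {
  r <- cycle_rates(1e7, 1e6, 500)
  fac <- formin_factors(6, 4)
  conc <- 10^seq(-8, -1, length.out = 100)
  enh <- relative_enhancement(r, fac, conc)
  expect_true(all(diff(enh) < 0))
  expect_equal(enh[1], 6, tolerance = 1e-3)
  vmr <- hyperbolic_params_from_cycle(apply_formin(r, fac))$v_max /
    hyperbolic_params_from_cycle(r)$v_max
  expect_equal(enh[length(enh)], vmr, tolerance = 1e-3)
  expect_true(all(enh <= 6 & enh >= vmr))
  # matched factors: enhancement is exactly constant
  fm <- formin_factors(3, 3)
  rm <- cycle_rates(1e7, 1e12, 500)
  enh_m <- relative_enhancement(rm, fm, conc)
  expect_equal(max(enh_m) / min(enh_m), 1, tolerance = 1e-6)
  # conc = 0 returns the binding-limited limit with a flag
  z <- relative_enhancement(r, fac, 0)
  expect_equal(as.numeric(z), 6)
  expect_true(attr(z, "limit"))
})

test_that("cycle simulation is deterministic per seed and inert at zero concentration", {
  r <- wt_rates()
  t1 <- simulate_filament(r, 50e-6, 2, seed = 11)
  t2 <- simulate_filament(r, 50e-6, 2, seed = 11)
  expect_identical(t1$times, t2$times)
  expect_identical(t1$lengths, t2$lengths)
  t3 <- simulate_filament(r, 50e-6, 2, seed = 12)
  expect_false(identical(t1$times, t3$times))

  t0 <- simulate_filament(r, 0, 2, seed = 11)
  expect_length(t0$times, 0)
})

test_that("cycle trajectories respect event ordering and length bookkeeping", {
  traj <- simulate_filament(wt_rates(), 50e-6, 2, seed = 21)
  expect_true(all(diff(traj$times) > 0))
  dl <- diff(traj$lengths)
  expect_true(all(dl %in% c(0L, 1L)))
  # length increments exactly at binding events
  expect_equal(which(dl == 1L) + 1L, which(traj$end_state == "capped_pre")[-1])
  # states cycle bind -> trans -> release
  expect_equal(unique(traj$end_state[seq(1, length(traj$end_state), by = 3)]),
               "capped_pre")
})

test_that("the event cap aborts with a truncation error carrying a partial trajectory", {
  err <- tryCatch(
    simulate_filament(wt_rates(), 100e-6, 30, seed = 1, event_cap = 1000),
    actinpacer_truncation = function(e) e)
  expect_s3_class(err, "actinpacer_truncation")
  expect_s3_class(err$trajectory, "filament_trajectory")
})

test_that("mean simulated cycle velocity converges to the analytic value", {
  r <- wt_rates()
  conc <- 10 * hyperbolic_params_from_cycle(r)$k_half
  vs <- vapply(1:60, function(i)
    estimate_trajectory_velocity(simulate_filament(r, conc, 10, seed = 1000 + i))$velocity,
    numeric(1))
  va <- cycle_velocity(r, conc)
  sem <- sd(vs) / sqrt(length(vs))
  expect_lt(abs(mean(vs) - va), 3 * sem)
})

test_that("bare-filament birth-death statistics match the analytic mean", {
  r <- bare_actin_rates(1.16e7, 1.4)
  # supercritical growth
  vs <- vapply(1:40, function(i)
    estimate_trajectory_velocity(
      simulate_bare_filament(r, 5e-6, 20, seed = 2000 + i))$velocity,
    numeric(1))
  expect_lt(abs(mean(vs) - (1.16e7 * 5e-6 - 1.4)),
            3 * sd(vs) / sqrt(length(vs)))
  # critical concentration: mean velocity ~0 (start away from the boundary)
  ccrit <- 1.4 / 1.16e7
  vs0 <- vapply(1:40, function(i)
    estimate_trajectory_velocity(
      simulate_bare_filament(r, ccrit, 20, seed = 3000 + i,
                             length0 = 500))$velocity,
    numeric(1))
  expect_lt(abs(mean(vs0)), 3 * sd(vs0) / sqrt(length(vs0)) + 0.05)
  # no dissociation: lengths never decrease
  nd <- simulate_bare_filament(bare_actin_rates(1.16e7, 0), 2e-6, 10, seed = 4)
  expect_true(all(diff(nd$lengths) >= 0))
})

test_that("trajectory slope estimation and subunit-length conversion are exact", {
  traj <- structure(list(times = seq(0.1, 10, by = 0.1),
                         lengths = as.integer(round(5 * seq(0.1, 10, by = 0.1))),
                         end_state = rep("free", 100), seed = 1L,
                         params = list()),
                    class = "filament_trajectory")
  est <- estimate_trajectory_velocity(traj)
  expect_equal(est$velocity, 5.0, tolerance = 1e-2)
  # 2.7 nm per subunit: 1 subunit/s = 2.7 nm/s; 1450 subunits/s = 3.915 um/s
  expect_equal(convert_velocity(1), 2.7e-3)
  expect_equal(convert_velocity(1450), 3.915)
  expect_equal(convert_velocity(3.915, "um_per_s", "subunits_per_s"), 1450)
})

test_that("hyperbolic fit recovers exact and simulated curves", {
  conc <- c(1, 2.5, 5, 10, 20, 40, 80, 160) * 1e-6
  v <- 500 * conc / (20e-6 + conc)
  fit <- fit_hyperbolic(velocity_curve(conc, v))
  expect_equal(fit$v_max, 500, tolerance = 1e-6)
  expect_equal(fit$k_half, 20e-6, tolerance = 1e-6)

  g <- gen_velocity_curve(wt_rates(), mode = "stochastic", seed = 9)
  hf <- fit_hyperbolic(g$curve)
  expect_lt(abs(hf$v_max - g$truth$v_max) / g$truth$v_max, 0.10)
  expect_lt(abs(hf$k_half - g$truth$k_half) / g$truth$k_half, 0.10)
})

test_that("mutant release-rate scaling orders the fitted maximal velocities", {
  panel <- gen_mutant_panel(wt_rates(), seed = 31)
  vmax <- vapply(panel$curves, function(cu)
    suppressWarnings(fit_hyperbolic(cu))$v_max, numeric(1))
  expect_true(all(diff(vmax[c("tight", "wt", "E82A", "R88K")]) > 0))
})

test_that("linear regime fit recovers the apparent association rate constant", {
  conc <- c(0.5, 1, 2, 5, 10, 20, 50, 100) * 1e-6
  v <- 500 * conc / (50e-6 + conc)
  # sampled far below k_half the slope approaches v_max / k_half
  lr <- fit_linear_regime(velocity_curve(conc, v), conc_cutoff = 2e-6)
  expect_equal(lr$slope, 500 / 50e-6, tolerance = 0.05)
  expect_error(fit_linear_regime(velocity_curve(conc, v), 0.4e-6), ">= 3")

  g <- gen_velocity_curve(wt_rates(), mode = "stochastic", seed = 9)
  lr2 <- fit_linear_regime(g$curve, 10e-6)
  expect_lt(abs(lr2$slope - 1e7) / 1e7, 0.15)
})

test_that("buffering ratio matches its closed form and limits", {
  fit <- hyperbolic_fit(v_max = 500, k_half = 10e-6)
  # saturation: insensitive; linear regime: proportional
  expect_equal(buffering_ratio(fit, 1e-2, 3), 1, tolerance = 1e-2)
  expect_equal(buffering_ratio(fit, 1e-12, 3), 3, tolerance = 1e-4)
  # c_base = 5 k_half, fold 3: (15/16)/(5/6) = 1.125
  expect_equal(buffering_ratio(fit, 5 * fit$k_half, 3), 1.125)
})
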