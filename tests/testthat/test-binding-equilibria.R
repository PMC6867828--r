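# Exact competition equilibrium, anisotropy/quench forward models and
# affinity fitters.

test_that("solver handles degenerate mixtures (no ligand / no receptor)", {
  st <- solve_two_ligand_competition(
    competition_mixture(150e-9, 0, 0, 18e-9, 100e-9))
  expect_equal(st$a_free, 150e-9)
  expect_equal(c(st$pa, st$wa, st$p_free, st$w_free), rep(0, 4))

  st2 <- solve_two_ligand_competition(
    competition_mixture(0, 1e-6, 4e-9, 18e-9, 100e-9))
  expect_equal(st2$p_free, 1e-6)
  expect_equal(st2$w_free, 4e-9)
  expect_equal(c(st2$pa, st2$wa, st2$a_free), rep(0, 3))
})

test_that("solver reproduces the frozen bisection-oracle equilibrium", {
  # oracle values computed once by interval bisection on the conservation
  # equation for A0=150 nM, P0=500 nM, W0=4 nM, KP=18 nM, KW=100 nM
  st <- solve_two_ligand_competition(
    competition_mixture(150e-9, 500e-9, 4e-9, 18e-9, 100e-9))
  expect_equal(st$a_free, 7.178592857215e-09, tolerance = 1e-10)
  expect_equal(st$pa, 1.425534957002e-07, tolerance = 1e-10)
  expect_equal(st$wa, 2.679114426060e-10, tolerance = 1e-10)
})

test_that("closed form and root fallback agree with the bisection oracle on a random grid", {
  grid <- random_mixtures(250, seed = 101)
  worst <- 0
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    st <- solve_two_ligand_competition(
      competition_mixture(g$a0, g$p0, g$w0, g$kp, g$kw))
    orc <- oracle_competition(g$a0, g$p0, g$w0, g$kp, g$kw)
    worst <- max(worst, max_rel_err(unlist(st), unlist(orc)))
  }
  expect_lt(worst, 1e-8)
})

test_that("conservation and mass action hold at every solver output", {
  grid <- random_mixtures(250, seed = 202)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    st <- solve_two_ligand_competition(
      competition_mixture(g$a0, g$p0, g$w0, g$kp, g$kw))
    expect_lt(abs(st$a_free + st$pa + st$wa - g$a0) / g$a0, 1e-10)
    expect_lt(abs(st$p_free + st$pa - g$p0) / max(g$p0, 1e-300), 1e-10)
    expect_lt(abs(st$w_free + st$wa - g$w0) / max(g$w0, 1e-300), 1e-10)
    # mass action: pa * kp = a_free * p_free
    expect_lt(abs(st$pa * g$kp - st$a_free * st$p_free) /
                max(st$pa * g$kp, 1e-300), 1e-8)
    expect_lt(abs(st$wa * g$kw - st$a_free * st$w_free) /
                max(st$wa * g$kw, 1e-300), 1e-8)
  }
})

test_that("with no probe the solver reduces to the single-site quadratic solution", {
  cases <- expand.grid(a0 = c(40e-9, 150e-9, 10e-6),
                       p0 = c(10e-9, 500e-9, 100e-6),
                       kp = c(1e-9, 18e-9, 1.2e-6))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    st <- solve_two_ligand_competition(
      competition_mixture(cs$a0, cs$p0, 0, cs$kp, 100e-9))
    expect_lt(abs(st$a_free - oracle_single_site_afree(cs$a0, cs$p0, cs$kp)) /
                oracle_single_site_afree(cs$a0, cs$p0, cs$kp), 1e-10)
  }
})

test_that("swapping the two ligands swaps the two complexes", {
  grid <- random_mixtures(50, seed = 303)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    st <- solve_two_ligand_competition(
      competition_mixture(g$a0, g$p0, g$w0, g$kp, g$kw))
    sw <- solve_two_ligand_competition(
      competition_mixture(g$a0, g$w0, g$p0, g$kw, g$kp))
    expect_equal(st$pa, sw$wa, tolerance = 1e-12)
    expect_equal(st$wa, sw$pa, tolerance = 1e-12)
    expect_equal(st$a_free, sw$a_free, tolerance = 1e-12)
  }
})

test_that("solver rejects non-finite input", {
  expect_error(competition_mixture(NaN, 0, 0, 18e-9, 100e-9), "finite")
  expect_error(competition_mixture(1e-9, -1e-9, 0, 18e-9, 100e-9),
               "non-negative")
})

test_that("anisotropy readout is linear in the bound probe fraction", {
  ends <- anisotropy_endpoints(0.05, 0.15)
  mk <- function(wa, w0) species_state(1e-9, 1e-9, w0 - wa, 1e-9, wa)
  expect_equal(predict_anisotropy(mk(0, 4e-9), ends, 4e-9), 0.05)
  expect_equal(predict_anisotropy(mk(4e-9, 4e-9), ends, 4e-9), 0.15)
  expect_equal(predict_anisotropy(mk(2e-9, 4e-9), ends, 4e-9), 0.10)
  expect_error(predict_anisotropy(mk(0, 4e-9), ends, 0), "positive")
})

test_that("printed anisotropy form is linear in the complex concentration", {
  ends <- anisotropy_endpoints(0, 1)
  st <- species_state(1e-9, 1e-9, 2e-9, 0.25, 1e-9)
  expect_equal(predict_anisotropy(st, ends, 4e-9, form = "printed"), 0.25)
})

test_that("quench model hits its stoichiometric and dilute limits", {
  ends <- quench_endpoints(1, 0)
  # kd -> 0 with T = A and titrant normalization: fully bound, I -> i_bound
  expect_equal(predict_quench(150e-9, 150e-9, 1e-300, ends), 0)
  # T -> 0 with receptor normalization: no titrant, I -> i_free
  expect_equal(predict_quench(150e-9, 1e-15, 1.2e-6, ends,
                              normalize = "receptor"), 1, tolerance = 1e-6)
  # frozen quadratic-root oracle: A=150 nM, KD=1.2 uM, T=1.2 uM
  expect_equal(predict_quench(150e-9, 1.2e-6, 1.2e-6, ends),
               0.939451221368, tolerance = 1e-9)
  expect_equal(predict_quench(150e-9, 1.2e-6, 1.2e-6, ends,
                              normalize = "receptor"),
               0.515609770941, tolerance = 1e-9)
})

test_that("quench bound fraction agrees with an independent mass-action solve", {
  # cross-check the quadratic root against the single-site bisection oracle
  a0 <- 150e-9; kd <- 1.2e-6; t0 <- 1.2e-6
  orc <- oracle_competition(a0, t0, 0, kd, 1)   # degenerate second ligand
  at_quad <- (1 - predict_quench(a0, t0, kd, quench_endpoints(1, 0),
                                 normalize = "receptor")) * a0
  expect_equal(at_quad, orc$pa, tolerance = 1e-8)
})

test_that("competition affinity fit is self-consistent on exact data", {
  g <- gen_competition_titration(kp = 18e-9, noise_sd = 0, seed = 1)
  f <- fit_competition_affinity(g$series, g$mix_template,
                                anisotropy_endpoints(0.04, 0.16))
  expect_equal(f$kp$kd, 18e-9, tolerance = 1e-3)
  expect_equal(f$ends$r_free, 0.05, tolerance = 1e-3)
  expect_equal(f$ends$r_bound, 0.15, tolerance = 1e-3)
})

test_that("a 4-fold weaker competitor is recovered as a ~4-fold kd ratio", {
  g_wt <- gen_competition_titration(kp = 18e-9, noise_sd = 0, seed = 1)
  g_mut <- gen_competition_titration(kp = 4 * 18e-9, noise_sd = 0, seed = 1)
  f_wt <- fit_competition_affinity(g_wt$series, g_wt$mix_template,
                                   anisotropy_endpoints(0.04, 0.16))
  f_mut <- fit_competition_affinity(g_mut$series, g_mut$mix_template,
                                    anisotropy_endpoints(0.04, 0.16))
  expect_equal(f_mut$kp$kd / f_wt$kp$kd, 4, tolerance = 0.01)
})

test_that("noisy competition titration recovers kd within the pre-registered tolerance", {
  # tolerance 25% frozen from a 40-seed recovery-oracle run
  # (median error ~12%, 90th percentile ~23%) at noise SD 0.002
  g <- gen_competition_titration(kp = 18e-9, noise_sd = 0.002, seed = 42)
  f <- fit_competition_affinity(g$series, g$mix_template,
                                anisotropy_endpoints(0.04, 0.16))
  expect_lt(abs(f$kp$kd - 18e-9) / 18e-9, 0.25)
  expect_gt(f$kp$kd_err, 0)
})

test_that("quench affinity fit is self-consistent and order-preserving", {
  g <- gen_quench_titration(kd = 1.2e-6, noise_cv = 0, seed = 1)
  f <- fit_quench_affinity(g$series, g$a_total)
  expect_equal(f$kd$kd, 1.2e-6, tolerance = 1e-3)

  # monotonicity: shifting the half-saturation right raises the fitted kd
  g_hi <- gen_quench_titration(kd = 6e-6, noise_cv = 0, seed = 1)
  f_hi <- fit_quench_affinity(g_hi$series, g_hi$a_total)
  expect_gt(f_hi$kd$kd, f$kd$kd)
})

test_that("noisy quench titration over 0-200 uM recovers kd within the pre-registered tolerance", {
  # tolerance 25% frozen from a 40-seed recovery-oracle run at 5% CV
  g <- gen_quench_titration(kd = 1.2e-6, noise_cv = 0.05, seed = 11)
  f <- fit_quench_affinity(g$series, g$a_total)
  expect_lt(abs(f$kd$kd - 1.2e-6) / 1.2e-6, 0.25)
})

test_that("free-species table is empty-safe, deterministic and monotone in competitor", {
  expect_equal(nrow(free_species_table(list())), 0)

  mix <- competition_mixture(150e-9, 500e-9, 4e-9, 18e-9, 100e-9)
  tab <- free_species_table(list(mix, mix))
  expect_equal(tab[1, ], tab[2, ], ignore_attr = TRUE)

  grid <- lapply(seq(0, 2e-6, length.out = 9), function(p0)
    competition_mixture(150e-9, p0, 4e-9, 18e-9, 100e-9))
  tab2 <- free_species_table(grid)
  expect_true(all(diff(tab2$pa) >= 0))
  expect_true(all(diff(tab2$wa) <= 0))  # probe is displaced
})
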