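# Independent numerical oracles used across the suite. These deliberately
# avoid the package's solver internals: the competition oracle is plain
# interval bisection on the receptor-conservation equation, and the
# single-site solution is the textbook quadratic formula.

# bisection mass-action oracle for the two-ligand competition equilibrium
oracle_competition <- function(a0, p0, w0, kp, kw) {
  if (a0 == 0) {
    return(list(a_free = 0, p_free = p0, w_free = w0, pa = 0, wa = 0))
  }
  f <- function(A) A * (1 + p0 / (kp + A) + w0 / (kw + A)) - a0
  lo <- 0; hi <- a0
  for (i in 1:300) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if ((hi - lo) <= .Machine$double.eps * mid) break
  }
  A <- (lo + hi) / 2
  list(a_free = A,
       p_free = p0 * kp / (kp + A), w_free = w0 * kw / (kw + A),
       pa = p0 * A / (kp + A), wa = w0 * A / (kw + A))
}

# closed-form single-site (one ligand) free-receptor concentration,
# cancellation-free branch of the quadratic formula
oracle_single_site_afree <- function(a0, p0, kp) {
  b <- kp + p0 - a0
  if (b >= 0) {
    2 * kp * a0 / (b + sqrt(b^2 + 4 * kp * a0))
  } else {
    (-b + sqrt(b^2 + 4 * kp * a0)) / 2
  }
}

max_rel_err <- function(got, want) {
  max(abs(got - want) / pmax(abs(want), .Machine$double.xmin))
}

# study-condition wild-type cycle rates: k_bind 1e7 M^-1 s^-1,
# k_trans 5000 s^-1, k_release 556 s^-1 (v_max ~500 subunits/s,
# K_0.5 ~50 uM)
wt_rates <- function() cycle_rates(1e7, 5000, 556)

# random mixture grid for property tests: totals log-uniform 1 nM - 1 mM,
# affinities log-uniform 1 nM - 100 uM
random_mixtures <- function(n, seed) {
  withr::with_seed(seed, {
    data.frame(
      a0 = 10^runif(n, -9, -3), p0 = 10^runif(n, -9, -3),
      w0 = 10^runif(n, -9, -3),
      kp = 10^runif(n, -9, -4), kw = 10^runif(n, -9, -4)
    )
  })
}
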