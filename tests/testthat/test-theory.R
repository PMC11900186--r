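# Closed-form cylinder theory: tether relations, the nondimensional shape
# equation and its stability boundary.

test_that("tether radius and force satisfy the closed forms and identities", {
  expect_equal(tether_radius(1, 1), sqrt(0.5), tolerance = 1e-12)
  expect_equal(tether_force(1, 1), 2 * pi * sqrt(2), tolerance = 1e-12)
  # gamma -> 4 gamma halves R and doubles f
  expect_equal(tether_radius(1, 4), tether_radius(1, 1) / 2)
  expect_equal(tether_force(1, 4), 2 * tether_force(1, 1))
  # algebraic identities f R = 2 pi kappa and f = 4 pi gamma R
  set.seed(7)
  for (i in 1:20) {
    kap <- exp(stats::rnorm(1)); gam <- exp(stats::rnorm(1))
    f <- tether_force(kap, gam); R <- tether_radius(kap, gam)
    expect_equal(f * R, 2 * pi * kap, tolerance = 1e-12)
    expect_equal(f, 4 * pi * gam * R, tolerance = 1e-12)
  }
  expect_error(tether_radius(1, -1))
})

test_that("stress parameter is dimensionless and scale invariant", {
  expect_identical(stress_parameter(0, 1, 1), 0)
  expect_equal(stress_parameter(0.4, 1, 1), 0.4)
  # rescaling all lengths by s (P -> P/s^3, gamma -> gamma/s^2, kappa fixed)
  # leaves p unchanged
  set.seed(11)
  for (i in 1:20) {
    P <- stats::rnorm(1); kap <- exp(stats::rnorm(1)); gam <- exp(stats::rnorm(1))
    s <- exp(stats::rnorm(1))
    expect_equal(stress_parameter(P / s^3, kap, gam / s^2),
                 stress_parameter(P, kap, gam), tolerance = 1e-12)
  }
  expect_error(stress_parameter(1, 1, 0))
})

test_that("cylinder equilibrium roots follow the nondimensional cubic", {
  # p = 0: the tether, j = sqrt(2)
  eq0 <- cylinder_equilibrium(0)
  expect_equal(eq0$j, sqrt(2), tolerance = 1e-12)
  expect_identical(eq0$branch, "stable")
  # double root at the critical point
  pc <- critical_stress_cylinder()
  eqc <- cylinder_equilibrium(pc)
  expect_equal(eqc$j, sqrt(2 / 3), tolerance = 1e-9)
  expect_identical(eqc$branch, "marginal")
  # no positive equilibrium above critical
  expect_identical(nrow(cylinder_equilibrium(0.6)), 0L)
  # roots actually solve j^3/2 - j + p = 0 and R = lambda / j
  for (p in c(0.1, 0.3, 0.5)) {
    eq <- cylinder_equilibrium(p)
    expect_identical(nrow(eq), 2L)
    expect_true(all(abs(eq$j^3 / 2 - eq$j + p) < 1e-12))
    expect_equal(eq$R_over_lambda, 1 / eq$j)
    expect_identical(eq$branch, c("unstable", "stable"))
  }
})

test_that("critical stress equals the maximum of p(j) and the root-count boundary", {
  pc <- critical_stress_cylinder()
  expect_equal(pc, (2 / 3)^1.5, tolerance = 1e-15)
  expect_equal(round(pc, 4), 0.5443)
  # brute-force grid maximum of j - j^3/2
  j <- seq(1e-6, sqrt(2), by = 1e-6)
  expect_equal(max(j - j^3 / 2), pc, tolerance = 1e-9)
  # root count changes from 2 to 0 exactly at pc (bisection)
  lo <- 0.5; hi <- 0.6
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (nrow(cylinder_equilibrium(mid)) >= 1) lo <- mid else hi <- mid
  }
  expect_equal((lo + hi) / 2, pc, tolerance = 1e-9)
  # junction criterion sits below the cylinder criterion
  expect_gt(pc, 0.4)
})
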