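# Ensemble specification and energy assembly.

test_that("ensemble_spec enforces one clamped member per conjugate pair", {
  expect_s3_class(ensemble_spec(L = 5, gamma = 1, P = 0), "ensemble_spec")
  expect_error(ensemble_spec(L = 5, f = 2, gamma = 1, P = 0), "exactly one")
  expect_error(ensemble_spec(gamma = 1, P = 0), "exactly one")
  expect_error(ensemble_spec(L = 5, A = 1, gamma = 1, P = 0), "exactly one")
})

test_that("divergent (tension, pressure)-clamped ensembles are refused", {
  expect_error(ensemble_spec(L = 4, gamma = 1, P = 0.3), "divergent")
  sp <- ensemble_spec(L = 4, gamma = 1, P = 0.3, allow_divergent = TRUE)
  expect_true(is_divergent_ensemble(sp))
  # P = 0 with clamped gamma is the benign initial-state ensemble
  expect_false(is_divergent_ensemble(ensemble_spec(L = 5, gamma = 1, P = 0)))
})

test_that("the functional includes exactly the work terms of clamped intensives", {
  m <- build_cylinder_mesh(1 / sqrt(2), 10, 0.3)
  params <- material_params()
  A <- surface_area(m); V <- enclosed_volume(m); FB <- bending_energy(m)

  # clamped gamma, P: F = F_B + gamma A - P V
  br <- total_functional(m, params,
                         ensemble_spec(L = 5, gamma = 2, P = 0.1,
                                       allow_divergent = TRUE))
  expect_equal(br$F_A, 2 * A)
  expect_equal(br$F_V, -0.1 * V)
  expect_identical(br$F_L, 0)
  expect_equal(br$F_total, FB + 2 * A - 0.1 * V, tolerance = 1e-12)

  # clamped A, V, f: junction work term is -f * (sum of arm lengths)
  br2 <- total_functional(m, params, ensemble_spec(f = 3, A = A, V = V))
  expect_equal(br2$F_L, -3 * sum(br2$L))
  expect_identical(br2$F_A, 0)
  expect_identical(br2$F_V, 0)

  # all geometry clamped: bending energy alone
  br3 <- total_functional(m, params, ensemble_spec(L = 5, A = A, V = V))
  expect_equal(br3$F_total, FB, tolerance = 1e-12)

  # F_V vanishes whenever P = 0
  br4 <- total_functional(m, params, ensemble_spec(L = 5, gamma = 1, P = 0))
  expect_identical(br4$F_V, 0)
})

test_that("clamped-gamma cylinder energy is minimized at the tether radius", {
  # per unit length: F/L = pi kappa / R + 2 pi gamma R, optimal R = sqrt(kappa/2gamma)
  gam <- 1.7
  E <- function(R) {
    m <- build_cylinder_mesh(R, 12, 0.25)
    bending_energy(m) + gam * surface_area(m)
  }
  Rs <- seq(0.35, 0.75, by = 0.02)
  Ropt <- Rs[which.min(sapply(Rs, E))]
  expect_rel(Ropt, tether_radius(1, gam), 0.06)
})

test_that("Legendre consistency links the clamped-gamma and clamped-A functionals", {
  st <- fx_tether()
  params <- st$params
  brG <- total_functional(st$mesh, params, ensemble_spec(L = 8, gamma = 1, P = 0))
  brA <- total_functional(st$mesh, params,
                          ensemble_spec(L = 8, A = st$A, V = NULL, P = 0))
  expect_equal(brG$F_total, brA$F_total + 1 * st$A, tolerance = 1e-9)
})
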