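# The independent axisymmetric profile minimizer, and its agreement with
# the closed-form tether.

test_that("axisymmetric minimizer finds the tether radius under clamped tension", {
  out <- axisym_minimize(12, ensemble_spec(L = 6, gamma = 1, P = 0),
                         n = 61, r_init = 0.6)
  expect_true(out$converged)
  expect_rel(mean(out$r), sqrt(0.5), 0.01)
  expect_lt(stats::sd(out$r), 1e-3)
})

test_that("clamping the tether's own area and volume leaves its profile fixed", {
  ref <- axisym_minimize(12, ensemble_spec(L = 6, gamma = 1, P = 0),
                         n = 61, r_init = 0.6)
  out <- axisym_minimize(12, ensemble_spec(L = 6, A = ref$A, V = ref$V),
                         n = 61, r_init = ref$r)
  expect_true(out$converged)
  expect_lt(max(abs(out$r - ref$r) / ref$r), 0.01)
})

test_that("3D cylinder solver and 1D profile minimizer agree on R(z)", {
  st <- fx_tether()
  prof3d <- mesh_radial_profile(st$mesh, nbins = 16)
  out <- axisym_minimize(16, ensemble_spec(L = 8, gamma = 1, P = 0),
                         n = 81, r_init = 0.75)
  r1d <- stats::approx(out$z, out$r, xout = prof3d$z)$y
  # interior agreement to 1%
  sel <- abs(prof3d$z) < 6
  expect_lt(max(abs(prof3d$r[sel] - r1d[sel]) / r1d[sel]), 0.01)
})
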