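# Excess quantities, master-curve assembly and parameter recovery.

# synthetic equilibrium-state stub with consistent fields
stub_state <- function(gamma, P, R, L, V, A, kappa = 1) {
  structure(list(gamma = gamma, P = P, R = R, L = L, V = V, A = A,
                 lambda = sqrt(kappa / gamma),
                 p = P * sqrt(kappa / gamma^3),
                 params = material_params(kappa, 1), converged = TRUE),
            class = "equilibrium_state")
}

test_that("excess quantities vanish for the smooth cylinder and follow closed forms", {
  # smooth cylinder: state coincides with its conformation-for-comparison
  R <- 1 / sqrt(2); L <- c(10, 10)
  st <- stub_state(gamma = 1, P = 0, R = R, L = L,
                   V = pi * R^2 * 20, A = 2 * pi * R * 20)
  ex <- excess_quantities(st)
  expect_equal(ex$Vexc, 0, tolerance = 1e-12)
  expect_equal(ex$Aexc, 0, tolerance = 1e-12)
  expect_equal(ex$R_over_lambda, R)

  # sphere of radius 3 lambda sitting on a tube of radius lambda/sqrt(2):
  # hand-computed excess volume (V - pi R^2 L) / lambda^3 = 36 pi
  lam <- 1
  Vst <- pi * R^2 * 20 + 4 / 3 * pi * (3 * lam)^3
  st2 <- stub_state(1, 0, R, c(10, 10), Vst, 2 * pi * R * 20 + 4 * pi * 9)
  ex2 <- excess_quantities(st2)
  expect_equal(ex2$Vexc, 36 * pi, tolerance = 1e-9)
  expect_equal(ex2$Aexc, 36 * pi, tolerance = 1e-9)
})

test_that("excess quantities of a real smooth tether state are near zero", {
  st <- fx_tether()
  ex <- excess_quantities(st)
  expect_lt(abs(ex$Vexc), 0.8)
  expect_lt(abs(ex$Aexc), 0.6)
})

test_that("master-curve assembly sorts, interpolates and cross-validates", {
  # synthetic states along a known curve p(Vexc) = 0.5 - 0.01 (Vexc - 5)^2
  states <- lapply(seq(1, 9, length.out = 12), function(vx) {
    gamma <- 1 + 0.1 * vx
    lam <- 1 / sqrt(gamma)
    R <- 0.7 * lam
    L <- c(5, 5, 5)
    p <- 0.5 - 0.01 * (vx - 5)^2
    P <- p * gamma^1.5
    V <- vx * lam^3 + pi * R^2 * 15
    A <- (2 + 0.05 * vx) * lam^2 + 2 * pi * R * 15
    st <- stub_state(gamma, P, R, L, V, A)
    attr(st, "ensemble") <- "synthetic"
    st
  })
  curve <- assemble_master_curves(states, geometry = "junction")
  expect_true(all(diff(curve$table$Vexc) > 0))
  expect_rel(curve$f_p(5), 0.5, 0.01)
  expect_lt(curve$cv_error, 0.01)
  expect_error(assemble_master_curves(states[1:4]), "at least 10")
})

test_that("parameter recovery round-trips a hand-constructed state", {
  # build an analytic master curve, pick a point on it, assemble the
  # matching initial conditions, and demand recovery of (gamma, P, R)
  f_p <- function(v) 0.45 - 0.004 * (v - 6)^2
  f_A <- function(v) 1.5 + 0.3 * v
  f_R <- function(v) 0.72 - 0.01 * v
  tab <- data.frame(Vexc = seq(1, 12, 0.5))
  tab$p <- f_p(tab$Vexc); tab$Aexc <- f_A(tab$Vexc)
  tab$R_over_lambda <- f_R(tab$Vexc)
  curve <- structure(list(
    table = tab,
    f_p = stats::splinefun(tab$Vexc, tab$p),
    f_A = stats::splinefun(tab$Vexc, tab$Aexc),
    f_R = stats::splinefun(tab$Vexc, tab$R_over_lambda),
    range = range(tab$Vexc), geometry = "junction", cv_error = 0),
    class = "master_curve")
  # true state at Vexc = 7 with gamma = 1.8
  vx <- 7; gamma <- 1.8; lam <- 1 / sqrt(gamma); L0 <- 5.5; n <- 3
  R <- f_R(vx) * lam
  A0 <- f_A(vx) * lam^2 + 2 * pi * n * L0 * R
  Vtot <- vx * lam^3 + pi * n * L0 * R^2
  V0 <- Vtot - 2.5                    # split total into V0 + dV
  sol <- recover_parameters(A0, V0, L0, dV = 2.5, curve, "junction")
  expect_gt(nrow(sol), 0)
  best <- sol[which.min(abs(sol$Vexc - vx)), ]
  expect_rel(best$gamma, gamma, 1e-6)
  expect_rel(best$R, R, 1e-6)
  expect_rel(best$P, f_p(vx) * gamma^1.5, 1e-5)
  # out-of-range alteration: no solution
  none <- recover_parameters(A0, V0, L0, dV = 1e4, curve, "junction")
  expect_identical(nrow(none), 0L)
})
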