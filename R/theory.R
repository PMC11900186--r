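# Closed-form results for cylindrical membrane tubules: the tether radius
# and force, the nondimensionalized shape equation and its stability
# boundary.  These are the analytic oracles against which the triangulated
# solver is checked.
#
# Nondimensionalization: with j = J * sqrt(kappa/gamma) and
# p = P * sqrt(kappa/gamma^3), the cylinder shape equation
# P - gamma J + (kappa/2) J^3 = 0 becomes p = j - j^3/2.

#' Equilibrium curvatures of a pressurized cylinder
#'
#' All real positive roots of \eqn{j^3/2 - j + p = 0}, i.e. the
#' dimensionless curvatures \eqn{j = J\lambda} at which a cylinder of
#' radius \eqn{R = \lambda/j} is in equilibrium at stress parameter `p`.
#' Solved in closed trigonometric form (exact at the double root).  An empty
#' result for `p` above the critical value signals loss of the cylindrical
#' equilibrium.
#'
#' @param p stress parameter, >= 0.
#' @return data frame with columns `j`, `R_over_lambda` and `branch`
#'   (`"stable"` for the large-j root continuously connected to the tether
#'   at p = 0, `"marginal"` at the double root, `"unstable"` otherwise);
#'   zero rows when no positive equilibrium exists.
#' @export
cylinder_equilibrium <- function(p) {
  stopifnot(length(p) == 1, is.finite(p), p >= 0)
  pc <- critical_stress_cylinder()
  # depressed cubic j^3 + qj + r with q = -2, r = 2p
  if (p > pc + 1e-14) {
    return(data.frame(j = numeric(0), R_over_lambda = numeric(0),
                      branch = character(0)))
  }
  if (p == 0) {
    j <- sqrt(2)
  } else {
    # trigonometric solution of j^3 - 2j + 2p = 0
    m <- 2 * sqrt(2 / 3)
    th <- acos(pmin(1, pmax(-1, -p / pc)))
    j_all <- m * cos(th / 3 - 2 * pi * (0:2) / 3)
    j <- sort(j_all[j_all > 1e-12])
    if (length(j) == 2 && abs(j[1] - j[2]) < 1e-7) j <- mean(j)  # double root
  }
  jc <- sqrt(2 / 3)
  branch <- ifelse(abs(j - jc) < 1e-7, "marginal",
                   ifelse(j > jc, "stable", "unstable"))
  data.frame(j = j, R_over_lambda = 1 / j, branch = branch)
}

#' Critical stress parameter of a cylindrical tubule
#'
#' The maximum of \eqn{p(j) = j - j^3/2} over \eqn{j > 0}:
#' \eqn{p^*_{cyl} = (2/3)^{3/2} \approx 0.544}.  Above it the cylinder has
#' no positive-curvature equilibrium and loses stability (pearls).
#' @return scalar.
#' @export
critical_stress_cylinder <- function() (2 / 3)^(3 / 2)

#' Tether radius
#'
#' Equilibrium radius \eqn{R = \sqrt{\kappa/2\gamma}} of a membrane tube
#' pulled from a reservoir at tension gamma and zero pressure.
#' @param kappa bending modulus, > 0.
#' @param gamma tension, > 0.
#' @return scalar radius.
#' @export
tether_radius <- function(kappa, gamma) {
  stopifnot(all(kappa > 0), all(gamma > 0))
  sqrt(kappa / (2 * gamma))
}

#' Tether pulling force
#'
#' Equilibrium pulling force \eqn{f = 2\pi\sqrt{2\kappa\gamma}} on the end
#' of a membrane tether; satisfies \eqn{f R = 2\pi\kappa} and
#' \eqn{f = 4\pi\gamma R}.
#' @param kappa bending modulus, > 0.
#' @param gamma tension, > 0.
#' @return scalar force.
#' @export
tether_force <- function(kappa, gamma) {
  stopifnot(all(kappa > 0), all(gamma > 0))
  2 * pi * sqrt(2 * kappa * gamma)
}
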