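# Independent axisymmetric oracle: a one-dimensional profile minimizer for
# surfaces of revolution r(z), implementing the same Helfrich functional and
# ensemble constraints as the triangulated solver but on a completely
# different discretization.  Used to cross-check the 3D solver on cylinder
# topology (criterion: matched ensembles agree on the radial profile).

axisym_measures <- function(r, z, kappa) {
  n <- length(r)
  dz <- diff(z)
  rmid <- (r[-1] + r[-n]) / 2
  drdz <- diff(r) / dz
  ds <- sqrt(1 + drdz^2) * dz
  A <- sum(2 * pi * rmid * ds)
  # exact frustum volume
  V <- sum(pi * dz * (r[-n]^2 + r[-n] * r[-1] + r[-1]^2) / 3)
  # nodal curvatures with mirror (tangency) ghosts at both ends
  rp <- c(r[2], r, r[n - 1])
  zp <- c(z[1] - dz[1], z, z[n] + dz[n - 1])
  i <- 2:(n + 1)
  h1 <- zp[i] - zp[i - 1]; h2 <- zp[i + 1] - zp[i]
  d1 <- (rp[i] - rp[i - 1]) / h1; d2 <- (rp[i + 1] - rp[i]) / h2
  rz <- (d1 * h2 + d2 * h1) / (h1 + h2)
  rzz <- 2 * (d2 - d1) / (h1 + h2)
  J <- 1 / (r * sqrt(1 + rz^2)) - rzz / (1 + rz^2)^1.5
  wnode <- 2 * pi * r * sqrt(1 + rz^2) *
    c(dz[1] / 2, (dz[-(n - 1)] + dz[-1]) / 2, dz[n - 1] / 2)
  FB <- sum(kappa / 2 * J^2 * wnode)
  list(A = A, V = V, FB = FB, J = J)
}

#' Axisymmetric profile minimizer
#'
#' Minimizes the Helfrich functional over an axisymmetric radial profile
#' r(z) under the same ensemble conventions as [minimize_state()]: clamped
#' area and volume are enforced by an augmented Lagrangian; the end radii
#' share a single scalar with zero slope (tangency).  Serves as an
#' independent oracle for the triangulated solver on cylinder topology.
#'
#' @param length total axial length.
#' @param spec an [ensemble_spec()] (L must be clamped; the profile grid is
#'   fixed in z).
#' @param params a [material_params()].
#' @param n number of axial nodes.
#' @param r_init initial radius (scalar or length-n profile).
#' @param perturb amplitude of a single-period cosine perturbation used to
#'   seed bulged branches.
#' @return list with `z`, `r`, `R` (end radius), `A`, `V`, `F_B`,
#'   `gamma`, `P` (multiplier estimates), `converged`.
#' @export
axisym_minimize <- function(length, spec, params = material_params(),
                            n = 81, r_init = NULL, perturb = 0) {
  stopifnot(!is.null(spec$L))
  kappa <- params$kappa
  z <- seq(-length / 2, length / 2, length.out = n)
  r0 <- if (is.null(r_init)) rep(tether_radius(kappa, params$gamma0), n)
        else if (base::length(r_init) == 1) rep(r_init, n) else r_init
  if (perturb != 0)
    r0 <- r0 * (1 + perturb * cos(pi * (z - z[1]) / (z[n] - z[1]) * 2 - pi))
  # parameters: interior radii r[2..n-1] and the shared end radius
  pack <- function(r) c(r[2:(n - 1)], r[1])
  unpack <- function(p) c(p[n - 1], p[1:(n - 2)], p[n - 1])
  has_A <- !is.null(spec$A); has_V <- !is.null(spec$V)
  muA <- muV <- 0; rho <- 1e4
  obj <- function(p) {
    r <- unpack(p)
    if (any(r <= 1e-4)) return(1e10)
    me <- axisym_measures(r, z, kappa)
    E <- me$FB
    if (!is.null(spec$gamma)) E <- E + spec$gamma * me$A
    if (!is.null(spec$P) && spec$P != 0) E <- E - spec$P * me$V
    if (has_A) { cA <- (me$A - spec$A) / spec$A; E <- E + muA * cA + rho / 2 * cA^2 }
    if (has_V) { cV <- (me$V - spec$V) / spec$V; E <- E + muV * cV + rho / 2 * cV^2 }
    E
  }
  p <- pack(r0)
  for (outer in 1:12) {
    op <- stats::optim(p, obj, method = "L-BFGS-B",
                       lower = rep(1e-3, base::length(p)),
                       control = list(maxit = 2000, factr = 1e7))
    p <- op$par
    r <- unpack(p)
    me <- axisym_measures(r, z, kappa)
    resA <- if (has_A) (me$A - spec$A) / spec$A else 0
    resV <- if (has_V) (me$V - spec$V) / spec$V else 0
    if (max(abs(resA), abs(resV)) < 1e-6 && outer > 1) break
    if (has_A) muA <- muA + rho * resA
    if (has_V) muV <- muV + rho * resV
  }
  r <- unpack(p)
  me <- axisym_measures(r, z, kappa)
  gamma <- if (!is.null(spec$gamma)) spec$gamma else muA / spec$A
  P <- if (!is.null(spec$P)) spec$P else -muV / spec$V
  list(z = z, r = r, R = r[1], A = me$A, V = me$V, F_B = me$FB,
       gamma = gamma, P = P,
       converged = max(abs(if (has_A) (me$A - spec$A) / spec$A else 0),
                       abs(if (has_V) (me$V - spec$V) / spec$V else 0)) < 1e-5)
}

#' Radial profile of a cylinder-topology mesh
#'
#' Bin-averaged radius as a function of the axial coordinate, for
#' comparison against [axisym_minimize()].
#' @param mesh a cylinder-topology [surface_mesh()] with axis z.
#' @param nbins number of axial bins.
#' @return data frame with `z` (bin centers) and `r` (mean radius).
#' @export
mesh_radial_profile <- function(mesh, nbins = 20) {
  V <- mesh$vertices
  rr <- sqrt(V[, 1]^2 + V[, 2]^2)
  br <- seq(min(V[, 3]), max(V[, 3]), length.out = nbins + 1)
  idx <- cut(V[, 3], br, include.lowest = TRUE)
  data.frame(z = (br[-1] + br[-(nbins + 1)]) / 2,
             r = as.numeric(tapply(rr, idx, mean)))
}
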