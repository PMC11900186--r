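# Universal description of altered tubular systems: the
# conformation-for-comparison, excess volume and area, master curves over
# excess volume, and the recovery of thermodynamic parameters from them.

#' Conformation-for-comparison
#'
#' The reference system of smooth cylinders sharing the state's boundary
#' radius R and arm lengths: one cylinder per arm, so for the three-way
#' junction the reference consists of three cylinders of per-arm length L.
#'
#' @param state an `equilibrium_state`.
#' @return list with `R`, `L` (per arm), `A_C`, `V_C`.
#' @export
comparison_conformation <- function(state) {
  R <- state$R
  Ls <- state$L
  Ltot <- sum(Ls)
  list(R = R, L = Ls, A_C = 2 * pi * R * Ltot, V_C = pi * R^2 * Ltot)
}

#' Excess volume and area
#'
#' \deqn{V_{exc} = (V - V_C)/\lambda^3, \quad A_{exc} = (A - A_C)/\lambda^2}
#' with the relaxation length \eqn{\lambda = \sqrt{\kappa/\gamma}} computed
#' from the state's own retrieved tension (the virtual-reservoir tension),
#' not the initial tension — this is what closes the recovery equations.
#'
#' @param state an `equilibrium_state`.
#' @return list with `Vexc`, `Aexc`, `lambda`, `R_over_lambda`.
#' @export
excess_quantities <- function(state) {
  cc <- comparison_conformation(state)
  lam <- state$lambda
  list(Vexc = (state$V - cc$V_C) / lam^3,
       Aexc = (state$A - cc$A_C) / lam^2,
       lambda = lam, R_over_lambda = state$R / lam)
}

#' Equilibrium states over a grid of alterations and ensembles
#'
#' Runs the constrained minimizer for each combination of an alteration
#' (volume, area or force change relative to the initial state) and a
#' compatible thermodynamic ensemble, warm-starting along each alteration
#' path.  Ensembles clamping both tension and pressure are excluded (no
#' bounded bulged equilibria).
#'
#' @param initial an `initial_state`.
#' @param alterations data frame with columns `kind`
#'   (`"volume"`, `"area"`, `"force"`) and `value` (relative change: e.g.
#'   `dV/V0` for volume, `dA/A0` for area, `f/f0` for force).
#' @param ensembles character vector naming ensembles by their clamped
#'   triple, from `"AVL"`, `"AVf"`, `"gVL"`, `"APL"` (tension gamma is
#'   written `g`).
#' @param schedule a [solver_schedule()].
#' @return list of `equilibrium_state` objects with attributes `kind`,
#'   `value`, `ensemble`; failed cells are reported as `NULL` with a
#'   warning, not an error.
#' @export
run_ensemble_grid <- function(initial, alterations, ensembles,
                              schedule = solver_schedule()) {
  A0 <- initial$A0; V0 <- initial$V0; L0 <- initial$L0; f0 <- initial$f0
  g0 <- initial$gamma0
  out <- list()
  for (ens in ensembles) {
    mesh <- initial$state$mesh
    warm <- initial$state$warm
    for (i in seq_len(nrow(alterations))) {
      kind <- alterations$kind[i]; val <- alterations$value[i]
      spec <- switch(paste(ens, kind),
        "AVL volume" = ensemble_spec(L = L0, A = A0, V = V0 * (1 + val)),
        "AVf volume" = ensemble_spec(f = f0, A = A0, V = V0 * (1 + val)),
        "gVL volume" = ensemble_spec(L = L0, gamma = g0, V = V0 * (1 + val)),
        "AVL area"   = ensemble_spec(L = L0, A = A0 * (1 + val), V = V0),
        "AVf area"   = ensemble_spec(f = f0, A = A0 * (1 + val), V = V0),
        "APL area"   = ensemble_spec(L = L0, A = A0 * (1 + val), P = 0),
        "AVf force"  = ensemble_spec(f = f0 * val, A = A0, V = V0),
        "APL force"  = NULL,
        stop(sprintf("unsupported ensemble/alteration cell '%s %s'", ens, kind)))
      if (is.null(spec)) next
      st <- tryCatch(minimize_state(mesh, initial$params, spec, schedule,
                                    warm = warm),
                     error = function(e) e)
      if (inherits(st, "error")) {
        warning(sprintf("cell %s/%s=%g failed: %s", ens, kind, val,
                        conditionMessage(st)))
        out[[length(out) + 1]] <- NULL
        next
      }
      mesh <- st$mesh; warm <- st$warm
      attr(st, "kind") <- kind; attr(st, "value") <- val
      attr(st, "ensemble") <- ens
      out[[length(out) + 1]] <- st
    }
  }
  out
}

#' Assemble master curves from equilibrium states
#'
#' Tabulates `(Vexc, p, Aexc, R/lambda)` for the supplied states, sorts and
#' deduplicates by excess volume, and builds spline interpolants
#' `f_p`, `f_A`, `f_R` over the sampled range (no extrapolation).  The
#' maximal cross-ensemble scatter of `p` at matched `Vexc` is reported from
#' leave-one-out cross-validation.
#'
#' @param states list of `equilibrium_state` objects (converged).
#' @param geometry tag stored on the curve (`"cylinder"` or `"junction"`).
#' @return a `master_curve`: list with the tabulation `table`, interpolants
#'   `f_p`, `f_A`, `f_R`, the `range` of Vexc, `geometry` and `cv_error`.
#' @export
assemble_master_curves <- function(states, geometry = "junction") {
  states <- Filter(function(s) !is.null(s) && isTRUE(s$converged), states)
  if (length(states) < 10)
    stop("need at least 10 converged states spanning the Vexc range")
  tab <- do.call(rbind, lapply(states, function(s) {
    ex <- excess_quantities(s)
    data.frame(Vexc = ex$Vexc, p = s$p, Aexc = ex$Aexc,
               R_over_lambda = ex$R_over_lambda,
               ensemble = attr(s, "ensemble") %||% "",
               control = attr(s, "value") %||% NA_real_)
  }))
  tab <- tab[order(tab$Vexc), ]
  # merge near-duplicate abscissae
  dup <- c(FALSE, diff(tab$Vexc) < 1e-8)
  tab <- tab[!dup, ]
  if (diff(range(tab$Vexc)) <= 0)
    stop("insufficient Vexc span for a master curve")
  f_p <- stats::splinefun(tab$Vexc, tab$p, method = "monoH.FC")
  f_A <- stats::splinefun(tab$Vexc, tab$Aexc, method = "monoH.FC")
  f_R <- stats::splinefun(tab$Vexc, tab$R_over_lambda, method = "monoH.FC")
  # leave-one-out cross-validation on p
  cv <- rep(NA_real_, nrow(tab))
  if (nrow(tab) >= 5) {
    for (i in 2:(nrow(tab) - 1)) {
      fi <- stats::splinefun(tab$Vexc[-i], tab$p[-i], method = "monoH.FC")
      cv[i] <- abs(fi(tab$Vexc[i]) - tab$p[i])
    }
  }
  structure(list(table = tab, f_p = f_p, f_A = f_A, f_R = f_R,
                 range = range(tab$Vexc), geometry = geometry,
                 cv_error = max(cv, na.rm = TRUE)),
            class = "master_curve")
}

#' Recover thermodynamic parameters from a master curve
#'
#' Solves the closed system for a volume alteration `dV` of an initial
#' state under fixed area and volume: with n reference cylinders
#' (1 for a plain tubule, 3 for a junction),
#' \deqn{V_0 + \Delta V = V_{exc}\lambda^3 + n\pi L_0 R^2,}
#' \deqn{A_0 = A_{exc}\lambda^2 + 2\pi n L_0 R,}
#' with \eqn{p = f_p(V_{exc})}, \eqn{A_{exc} = f_A(V_{exc})},
#' \eqn{R/\lambda = f_R(V_{exc})} and \eqn{\lambda = \sqrt{\kappa/\gamma}}.
#' The system is reduced to a one-dimensional root search in `Vexc`; all
#' roots in the curve's range are returned.
#'
#' @param A0,V0,L0 initial area, volume and per-arm length.
#' @param dV added volume (absolute units).
#' @param curve a `master_curve`.
#' @param geometry `"cylinder"` or `"junction"`.
#' @param kappa bending modulus.
#' @return data frame of solution branches with columns `Vexc`, `gamma`,
#'   `P`, `R`, `Aexc`, `f`, `lambda`; zero rows if no solution lies in the
#'   curve's range.
#' @export
recover_parameters <- function(A0, V0, L0, dV, curve,
                               geometry = curve$geometry, kappa = 1) {
  n <- if (geometry == "junction") 3 else 1
  Ltot <- n * L0
  lam_of <- function(vx) {
    # area equation: Aexc lam^2 + 2 pi Ltot (R/lam) lam^2 ... careful:
    # R = (R/lam) * lam, so A0 = Aexc lam^2 + 2 pi Ltot Rn lam^2 / ... no:
    # A0 = Aexc lam^2 + 2 pi Ltot * Rn * lam  -> quadratic in lam
    Aexc <- curve$f_A(vx); Rn <- curve$f_R(vx)
    a <- Aexc; b <- 2 * pi * Ltot * Rn; cc <- -A0
    if (abs(a) < 1e-12) return(-cc / b)
    disc <- b^2 - 4 * a * cc
    if (disc < 0) return(NA_real_)
    (-b + sqrt(disc)) / (2 * a)
  }
  resid <- function(vx) {
    lam <- lam_of(vx)
    if (!is.finite(lam) || lam <= 0) return(NA_real_)
    Rn <- curve$f_R(vx)
    (vx * lam^3 + pi * Ltot * (Rn * lam)^2) - (V0 + dV)
  }
  lo <- curve$range[1]; hi <- curve$range[2]
  grid <- seq(lo, hi, length.out = 400)
  rv <- vapply(grid, resid, numeric(1))
  roots <- c()
  for (i in seq_len(length(grid) - 1)) {
    if (!is.finite(rv[i]) || !is.finite(rv[i + 1])) next
    if (rv[i] == 0) roots <- c(roots, grid[i])
    if (rv[i] * rv[i + 1] < 0) {
      rt <- stats::uniroot(resid, c(grid[i], grid[i + 1]))$root
      roots <- c(roots, rt)
    }
  }
  if (length(roots) == 0)
    return(data.frame(Vexc = numeric(0), gamma = numeric(0), P = numeric(0),
                      R = numeric(0), Aexc = numeric(0), f = numeric(0),
                      lambda = numeric(0)))
  do.call(rbind, lapply(roots, function(vx) {
    lam <- lam_of(vx)
    gamma <- kappa / lam^2
    p <- curve$f_p(vx)
    P <- p * sqrt(gamma^3 / kappa)
    R <- curve$f_R(vx) * lam
    # axial force carried by a tubular arm of radius R under (gamma, P)
    f <- 2 * pi * R * gamma + pi * kappa / R - pi * R^2 * P
    data.frame(Vexc = vx, gamma = gamma, P = P, R = R,
               Aexc = curve$f_A(vx), f = f, lambda = lam)
  }))
}
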