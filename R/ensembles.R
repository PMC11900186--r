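# Thermodynamic ensembles for tubular membrane systems.
#
# The system has three conjugate pairs: (arm length L, pulling force f),
# (membrane area A, tension gamma), (luminal volume V, pressure P).  An
# ensemble clamps exactly one member of each pair.  Clamped geometric
# variables (L, A, V) enter the minimization as constraints and contribute
# no energy term; clamped intensive variables contribute work terms
# gamma*A, -P*V and -f*L to the minimized functional.

#' Ensemble specification
#'
#' Supply exactly one member of each conjugate pair.  `L` and `f` are per
#' arm (a single scalar applied identically to all arms).
#'
#' @param L fixed arm length (per arm), or `NULL` if `f` is given.
#' @param f fixed pulling force per arm end, or `NULL` if `L` is given.
#' @param A fixed membrane area, or `NULL` if `gamma` is given.
#' @param gamma fixed tension, or `NULL` if `A` is given.
#' @param V fixed luminal volume, or `NULL` if `P` is given.
#' @param P fixed pressure, or `NULL` if `V` is given.
#' @param allow_divergent permit the (gamma, P)-clamped ensembles, which
#'   have no bulged equilibria (shapes inflate without bound) and are
#'   refused by the sweep drivers.
#' @return an object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(L = NULL, f = NULL, A = NULL, gamma = NULL,
                          V = NULL, P = NULL, allow_divergent = FALSE) {
  one_of <- function(a, b, nm) {
    if (is.null(a) == is.null(b))
      stop(sprintf("exactly one of %s must be given", nm))
  }
  one_of(L, f, "(L, f)")
  one_of(A, gamma, "(A, gamma)")
  one_of(V, P, "(V, P)")
  spec <- structure(list(L = L, f = f, A = A, gamma = gamma, V = V, P = P,
                         allow_divergent = isTRUE(allow_divergent)),
                    class = "ensemble_spec")
  if (is_divergent_ensemble(spec) && !allow_divergent)
    stop("ensemble clamps both tension and pressure; no bounded bulged ",
         "equilibria exist (set allow_divergent = TRUE to override)")
  spec
}

#' @export
print.ensemble_spec <- function(x, ...) {
  nm <- function(a, b, na, nb)
    if (!is.null(x[[a]])) sprintf("%s = %g", na, x[[a]]) else sprintf("%s = %g", nb, x[[b]])
  cat("ensemble:", nm("L", "f", "L", "f"), "|", nm("A", "gamma", "A", "gamma"),
      "|", nm("V", "P", "V", "P"), "\n")
  invisible(x)
}

#' Is an ensemble of the divergent (tension, pressure)-clamped type?
#' @param spec an [ensemble_spec()].
#' @return logical.
#' @export
is_divergent_ensemble <- function(spec) {
  !is.null(spec$gamma) && !is.null(spec$P) && spec$P != 0
}

# observables needed by the functional
ensemble_observables <- function(mesh, params) {
  tr <- mesh_terms(mesh, kappa = params$kappa, grad = FALSE)
  Ls <- vapply(mesh$rings, `[[`, numeric(1), "d")
  list(A = tr$area, V = tr$volume, fb = tr$fb, L = Ls)
}

#' Ensemble energy functional
#'
#' Assembles the minimized functional for the given ensemble:
#' \deqn{\bar F = F_B + \gamma A - P V - f \sum_k L_k,}
#' where the tension, pressure and force terms are present only when the
#' corresponding intensive variable is clamped; clamped geometric members
#' (A, V, L) are enforced as constraints by the solver and contribute no
#' energy term.
#'
#' @param mesh a [surface_mesh()].
#' @param params a [material_params()].
#' @param spec an [ensemble_spec()].
#' @return an `energy_breakdown` list with fields `F_B`, `F_A`, `F_V`,
#'   `F_L`, `F_total` and the observables `A`, `V`, `L`.
#' @export
total_functional <- function(mesh, params, spec) {
  ob <- ensemble_observables(mesh, params)
  F_A <- if (!is.null(spec$gamma)) spec$gamma * ob$A else 0
  F_V <- if (!is.null(spec$P)) -spec$P * ob$V else 0
  F_L <- if (!is.null(spec$f)) -spec$f * sum(ob$L) else 0
  structure(list(F_B = ob$fb, F_A = F_A, F_V = F_V, F_L = F_L,
                 F_total = ob$fb + F_A + F_V + F_L,
                 A = ob$A, V = ob$V, L = ob$L),
            class = "energy_breakdown")
}

#' Stress parameter
#'
#' The dimensionless combination \eqn{p = P\sqrt{\kappa/\gamma^3}} that
#' governs the stability of tubular membrane shapes.
#' @param P pressure.
#' @param kappa bending modulus (> 0).
#' @param gamma tension (> 0).
#' @return dimensionless scalar.
#' @export
stress_parameter <- function(P, kappa, gamma) {
  if (any(gamma <= 0)) stop("stress parameter requires gamma > 0")
  if (any(kappa <= 0)) stop("stress parameter requires kappa > 0")
  P * sqrt(kappa / gamma^3)
}
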