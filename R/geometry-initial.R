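# Initial states: the equilibrium of the tubular system with a real
# reservoir at tension gamma0 and vanishing pressure, computed by relaxing a
# seed mesh under clamped arm length with free area, volume and boundary
# radius.  Far from the junction the arms settle onto the tether radius
# sqrt(kappa/2 gamma0); the junction core width is of the order of the
# relaxation length.

#' Compute the initial (reservoir-equilibrated) state
#'
#' Relaxes a cylinder or three-way junction under the ensemble
#' (gamma = gamma0, P = 0, L = L0), interleaving one remeshing pass so the
#' relaxed mesh is isotropic, and records the initial observables used by
#' the sweep drivers.
#'
#' @param geometry `"cylinder"` or `"junction"`.
#' @param params a [material_params()].
#' @param L0 arm length (per arm; a cylinder has two arms meeting at the
#'   origin, so its total length is `2 * L0`).
#' @param edge_target mesh edge length, in units of the relaxation length.
#' @param schedule a [solver_schedule()].
#' @return an `initial_state`: list with the converged `state`
#'   (an `equilibrium_state`), `A0`, `V0`, `L0`, `R0`, `f0`, `gamma0` and
#'   `geometry`.
#' @export
compute_initial_state <- function(geometry = c("junction", "cylinder"),
                                  params = material_params(), L0,
                                  edge_target = params$lambda0 / 3,
                                  schedule = solver_schedule()) {
  geometry <- match.arg(geometry)
  lam0 <- params$lambda0
  if (L0 < 5 * lam0)
    warning("arm length below 5 relaxation lengths: tether asymptotics ",
            "(and the universal description) are unreliable")
  R0_t <- tether_radius(params$kappa, params$gamma0)
  mesh <- if (geometry == "junction") {
    build_junction_seed_mesh(R0_t, L0, edge_target)
  } else {
    build_cylinder_mesh(R0_t, 2 * L0, edge_target)
  }
  spec <- ensemble_spec(L = L0, gamma = params$gamma0, P = 0)
  st <- minimize_state(mesh, params, spec, schedule)
  st <- groom_state(st, params, spec, schedule, edge_target, full = TRUE)
  structure(list(state = st, A0 = st$A, V0 = st$V, L0 = L0, R0 = st$R,
                 f0 = st$f, gamma0 = params$gamma0, geometry = geometry,
                 edge_target = edge_target, params = params),
            class = "initial_state")
}

#' @export
print.initial_state <- function(x, ...) {
  cat(sprintf("initial_state (%s): R0=%.4f f0=%.4f A0=%.4f V0=%.4f L0=%.3f\n",
              x$geometry, x$R0, x$f0, x$A0, x$V0, x$L0))
  invisible(x)
}

# remesh/groom a state and re-minimize under the same spec
groom_state <- function(st, params, spec, schedule, edge_target,
                        full = FALSE) {
  m <- st$mesh
  m <- if (full) {
    suppressWarnings(remesh(m, edge_target, passes = 2))
  } else {
    suppressWarnings(remesh_smooth(remesh_flip(collapse_slivers(m)), passes = 1))
  }
  out <- minimize_state(m, params, spec, schedule, warm = st$warm)
  out
}

#' Deterministic fixture meshes with reference observables
#'
#' A registry of meshes used throughout the tests: analytic solids with
#' closed-form references and the tubular systems at the scales studied in
#' the sweeps.
#'
#' @param name one of `"unit_sphere"`, `"flat_patch"`, `"cylinder_small"`,
#'   `"junction_small"`, `"junction_fig3"`, `"junction_fig5"`.
#' @param edge_target mesh resolution for the tubular fixtures.
#' @return list with `mesh` and a `reference` list of analytic or nominal
#'   observables (NULL where no closed form exists).
#' @export
make_fixture <- function(name, edge_target = 1 / 3) {
  lam <- 1
  switch(name,
    unit_sphere = list(
      mesh = build_icosphere(1, 4),
      reference = list(area = 4 * pi, volume = 4 * pi / 3, F_B = 8 * pi)),
    flat_patch = list(
      mesh = build_flat_patch(8),
      reference = list(area = 1, F_B = 0)),
    cylinder_small = list(
      mesh = build_cylinder_mesh(lam / sqrt(2), 20 * lam, edge_target),
      reference = list(R = lam / sqrt(2), L = 20 * lam,
                       area = 2 * pi * (lam / sqrt(2)) * 20 * lam,
                       volume = pi * (lam / sqrt(2))^2 * 20 * lam)),
    junction_small = list(
      mesh = build_junction_seed_mesh(lam / sqrt(2), 5 * lam, edge_target),
      reference = list(R = lam / sqrt(2), L_arm = 5 * lam)),
    junction_fig3 = list(
      mesh = build_junction_seed_mesh(lam / sqrt(2), 70 * lam / 3, edge_target),
      reference = list(R = lam / sqrt(2), L_arm = 70 * lam / 3,
                       V_nominal = 111 * lam^3)),
    junction_fig5 = list(
      mesh = build_junction_seed_mesh(lam / sqrt(2), 5.3 * lam, edge_target),
      reference = list(R = lam / sqrt(2), L_arm = 5.3 * lam,
                       V_nominal = 28 * lam^3)),
    stop(sprintf("unknown fixture name '%s'", name)))
}
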