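# Shared lazily-computed fixtures.  Everything is generated in code; the
# expensive solves are cached for the duration of the test run.

.fx <- new.env(parent = emptyenv())

fx_cached <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# converged tether: cylinder clamped (gamma = 1, P = 0), per-arm L = 8,
# edge lambda/4
fx_tether <- function() fx_cached("tether", function() {
  m <- build_cylinder_mesh(0.75, 16, 0.25)
  minimize_state(m, material_params(),
                 ensemble_spec(L = 8, gamma = 1, P = 0), solver_schedule())
})

# small junction initial state at the biomimetic scale
fx_junction_init <- function() fx_cached("junction_init", function() {
  compute_initial_state("junction", material_params(), L0 = 5.3,
                        edge_target = 1 / 3)
})

# slightly perturbed coarse cylinder for gradient checks
fx_bumpy_cylinder <- function(seed = 42) {
  m <- build_cylinder_mesh(1, 6, 0.45)
  set.seed(seed)
  m$vertices <- m$vertices + matrix(stats::rnorm(length(m$vertices), 0, 0.02),
                                    ncol = 3)
  m
}

expect_rel <- function(actual, expected, tol) {
  testthat::expect_lt(abs(actual - expected) / abs(expected), tol)
}
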