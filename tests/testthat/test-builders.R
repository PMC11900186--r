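# Mesh generators and the fixture registry.

test_that("junction seed has pair-of-pants topology and mirror symmetry", {
  jm <- build_junction_seed_mesh(0.71, 5.3, 0.3)
  expect_identical(length(jm$rings), 3L)
  nv <- nrow(jm$vertices)
  ne <- nrow(junctionmech:::edge_table_cpp(jm$faces - 1L, nv))
  nf <- nrow(jm$faces)
  expect_identical(nv - ne + nf, -1L)       # chi = 2 - 2g - b, g = 0, b = 3
  # mirror symmetry about the arm plane before relaxation
  zs <- sort(jm$vertices[, 3])
  expect_lt(max(abs(zs + rev(zs))), 1e-6)
  # area within the sanity envelope of three open tubes
  expect_rel(surface_area(jm), 3 * 2 * pi * 0.71 * 5.3, 0.15)
  expect_error(build_junction_seed_mesh(1, 2.5, 0.3), "exceed")
})

test_that("cylinder builder produces rings, collars and correct geometry", {
  m <- build_cylinder_mesh(0.5, 8, 0.25)
  expect_identical(length(m$rings), 2L)
  for (rg in m$rings) {
    expect_equal(rg$d, 4)
    rel <- sweep(m$vertices[rg$verts, ], 2, rg$anchor + rg$d * rg$axis)
    rad <- sqrt(rowSums(rel^2) - as.numeric(rel %*% rg$axis)^2)
    expect_lt(max(abs(rad - 0.5)), 1e-9)
  }
  validate_mesh(m)
})

test_that("fixture registry returns deterministic meshes with references", {
  us <- make_fixture("unit_sphere")
  expect_equal(us$reference$F_B, 8 * pi)
  expect_rel(bending_energy(us$mesh), 8 * pi, 1e-2)
  cs <- make_fixture("cylinder_small")
  expect_equal(cs$reference$R, 1 / sqrt(2))
  expect_rel(surface_area(cs$mesh), cs$reference$area, 0.04)
  expect_rel(enclosed_volume(cs$mesh), cs$reference$volume, 0.06)
  j5 <- make_fixture("junction_fig5")
  expect_equal(j5$reference$L_arm, 5.3)
  expect_identical(length(j5$mesh$rings), 3L)
  expect_error(make_fixture("nope"), "unknown")
  # determinism
  a <- make_fixture("junction_small")$mesh$vertices
  b <- make_fixture("junction_small")$mesh$vertices
  expect_identical(a, b)
})

test_that("junction initial state reproduces the tether asymptotics", {
  init <- fx_junction_init()
  st <- init$state
  expect_true(st$converged)
  # R0 = sqrt(kappa / 2 gamma0)
  expect_rel(init$R0, sqrt(0.5), 0.02)
  # f0 = 2 pi sqrt(2 kappa gamma0)
  expect_rel(init$f0, 2 * pi * sqrt(2), 0.02)
  # interior arm radius far from the core
  V <- st$mesh$vertices
  pl <- sqrt(V[, 1]^2 + V[, 2]^2)
  sel <- pl > 3 & pl < 4.5
  d_axis <- sapply(which(sel), function(i) {
    p <- V[i, ]
    min(sapply(c(0, 2, 4) * pi / 3, function(a) {
      e <- c(cos(a), sin(a), 0)
      t <- sum(p * e)
      sqrt(sum((p - t * e)^2))
    }))
  })
  expect_rel(mean(d_axis), sqrt(0.5), 0.02)
  # re-minimizing changes the bending energy by < 0.1% (idempotence)
  st2 <- minimize_state(st$mesh, init$params,
                        ensemble_spec(L = 5.3, gamma = 1, P = 0),
                        solver_schedule())
  expect_lt(abs(st2$F_B - st$F_B) / st$F_B, 1e-3)
})

test_that("short arms trigger the validity warning", {
  expect_warning(
    compute_initial_state("cylinder", material_params(), L0 = 3,
                          edge_target = 0.4),
    "5 relaxation lengths")
})
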