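# Remeshing contracts: edge-length control, ring preservation, shape
# preservation.

test_that("remesh controls edge lengths and preserves rings and area", {
  m <- build_cylinder_mesh(0.7071, 10, 0.5)    # coarse: edges ~2x target
  target <- 0.25
  a0 <- surface_area(m)
  ring_sizes <- sapply(m$rings, function(rg) length(rg$verts))
  m2 <- suppressWarnings(remesh(m, target, passes = 3))
  validate_mesh(m2)
  # the bound applies to the remeshable part: ring and collar vertices are
  # preserved exactly, so edges inside the protected boundary band keep
  # their original length
  prot <- junctionmech:::protected_vertices(m2)
  ed <- junctionmech:::edge_df(m2)
  free_edges <- !(prot[ed$v1] & prot[ed$v2])
  expect_lt(max(ed$len[free_edges]), 1.6 * target)
  # boundary ring vertex count unchanged (declared refinement policy)
  expect_identical(sapply(m2$rings, function(rg) length(rg$verts)),
                   ring_sizes)
  # area drift small
  expect_rel(surface_area(m2), a0, 0.02)
})

test_that("remeshing an equilibrium state changes its energy marginally", {
  st <- fx_tether()
  m2 <- suppressWarnings(remesh(st$mesh, 0.25, passes = 1))
  st2 <- minimize_state(m2, st$params, st$spec, solver_schedule())
  expect_lt(abs(st2$F_B - st$F_B) / st$F_B, 5e-3)
})

test_that("sliver collapse removes degenerate faces only", {
  m <- build_cylinder_mesh(0.7071, 8, 0.3)
  # manufacture a sliver by pinching two adjacent free vertices
  lay <- junctionmech:::dof_layout(m, ensemble_spec(L = 4, gamma = 1, P = 0))
  i <- lay$free_idx[10]
  et <- junctionmech:::edge_table_cpp(m$faces - 1L, nrow(m$vertices)) + 1L
  j <- setdiff(c(et[et[, 1] == i, 2], et[et[, 2] == i, 1]), i)
  j <- intersect(j, lay$free_idx)[1]
  m$vertices[j, ] <- m$vertices[i, ] + 1e-4 * (m$vertices[j, ] - m$vertices[i, ])
  nv <- nrow(m$vertices)
  m2 <- junctionmech:::collapse_slivers(m)
  validate_mesh(m2)
  expect_lt(nrow(m2$vertices), nv)
  expect_gt(mesh_quality(m2)$min_angle, 10 * pi / 180)
})
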