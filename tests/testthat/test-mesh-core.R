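# Discrete geometry: areas, volumes, curvature, bending energy, analytic
# gradients, and the mesh invariants.

test_that("surface area matches closed forms", {
  tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)),
                      matrix(c(1, 2, 3), 1), validate = FALSE)
  expect_equal(surface_area(tri), sqrt(3) / 4, tolerance = 1e-12)
  s <- build_icosphere(1, 5)
  expect_rel(surface_area(s), 4 * pi, 1e-3)
  cyl <- build_cylinder_mesh(1, 10, 0.15)
  expect_rel(surface_area(cyl), 2 * pi * 10, 5e-3)
})

test_that("enclosed volume is exact for solids and translation invariant", {
  s <- build_icosphere(1, 5)
  expect_rel(enclosed_volume(s), 4 * pi / 3, 1e-3)
  cyl <- build_cylinder_mesh(1, 10, 0.15)
  expect_rel(enclosed_volume(cyl), pi * 10, 5e-3)
  v0 <- enclosed_volume(cyl)
  cyl$vertices <- sweep(cyl$vertices, 2, c(-100, -100, -100))
  for (k in seq_along(cyl$rings)) cyl$rings[[k]]$anchor <-
    cyl$rings[[k]]$anchor + c(-100, -100, -100)
  expect_rel(enclosed_volume(cyl), v0, 1e-9)
})

test_that("orientation flip negates volume and preserves bending energy", {
  s <- build_icosphere(1, 2)
  v <- enclosed_volume(s); fb <- bending_energy(s)
  s$faces <- s$faces[, c(1, 3, 2)]
  expect_equal(enclosed_volume(s), -v, tolerance = 1e-12)
  expect_equal(bending_energy(s), fb, tolerance = 1e-10)
})

test_that("total curvature matches 1/R on cylinders and 2/r on spheres", {
  cyl <- build_cylinder_mesh(1, 10, 0.25)
  mc <- mean_curvature(cyl)
  iv <- which(abs(cyl$vertices[, 3]) < 2)
  expect_rel(mean(mc$J[iv]), 1, 1e-2)
  sp <- build_icosphere(2, 3)
  mcs <- mean_curvature(sp)
  expect_rel(mean(mcs$J), 1, 1e-2)          # J = 2/r = 1
  fp <- build_flat_patch(6)
  mcf <- mean_curvature(fp)
  inner <- which(apply(fp$vertices[, 1:2], 1, function(p)
    all(p > 0.2 & p < 0.8)))
  expect_lt(max(abs(mcf$J[inner])), 1e-8)
})

test_that("bending energy matches closed forms", {
  s <- build_icosphere(1, 4)
  expect_rel(bending_energy(s), 8 * pi, 1e-2)
  s3 <- build_icosphere(3, 4)               # radius independent
  expect_rel(bending_energy(s3), 8 * pi, 1e-2)
  # cylinder: the discrete energy density over the included area
  cyl <- build_cylinder_mesh(1, 10, 0.2)
  tr <- junctionmech:::mesh_terms(cyl, grad = FALSE)
  expect_rel(tr$fb, 0.5 * 1 * surface_area(cyl), 2e-2)
  expect_lt(bending_energy(build_flat_patch(6)), 1e-8)
})

test_that("analytic gradients agree with central finite differences", {
  m <- fx_bumpy_cylinder()
  gr <- shape_gradients(m)
  h <- 1e-6
  set.seed(3)
  idx <- sample(nrow(m$vertices), 12)
  for (quant in c("g_fb", "g_area", "g_vol")) {
    fn <- switch(quant,
      g_fb = function(mm) junctionmech:::mesh_terms(mm, grad = FALSE)$fb,
      g_area = function(mm) junctionmech:::mesh_terms(mm, grad = FALSE)$area,
      g_vol = function(mm) junctionmech:::mesh_terms(mm, grad = FALSE)$volume)
    worst <- 0
    for (i in idx) for (k in 1:3) {
      mp <- m; mp$vertices[i, k] <- mp$vertices[i, k] + h
      mm2 <- m; mm2$vertices[i, k] <- mm2$vertices[i, k] - h
      fd <- (fn(mp) - fn(mm2)) / (2 * h)
      worst <- max(worst, abs(fd - gr[[quant]][i, k]))
    }
    expect_lt(worst, 1e-4)
  }
  # volume gradient of a closed sphere sums to zero (translation invariance)
  gs <- shape_gradients(build_icosphere(1, 2))
  expect_lt(max(abs(colSums(gs$g_vol))), 1e-8)
  # bending gradient vanishes on a flat patch interior
  gf <- shape_gradients(build_flat_patch(5))
  expect_lt(max(abs(gf$g_fb)), 1e-6)
})

test_that("scale invariance: x -> s x with gamma -> gamma / s^2 leaves F_B fixed", {
  m <- fx_bumpy_cylinder()
  fb1 <- bending_energy(m, material_params(kappa = 1, gamma0 = 1))
  s <- 2.7
  m2 <- m
  m2$vertices <- s * m$vertices
  for (k in seq_along(m2$rings)) {
    m2$rings[[k]]$anchor <- s * m2$rings[[k]]$anchor
    m2$rings[[k]]$d <- s * m2$rings[[k]]$d
  }
  fb2 <- bending_energy(m2, material_params(kappa = 1, gamma0 = 1 / s^2))
  expect_rel(fb2, fb1, 1e-6)
})

test_that("bending energy converges toward the analytic value under refinement", {
  errs <- sapply(2:4, function(r)
    abs(bending_energy(build_icosphere(1, r)) - 8 * pi) / (8 * pi))
  expect_true(all(diff(errs) < 0))
  # roughly second order: error drops by ~4 per refinement
  expect_lt(errs[3], errs[1] / 8)
})

test_that("validator catches broken meshes", {
  s <- build_icosphere(1, 1)
  bad <- s; bad$faces[1, ] <- bad$faces[1, c(1, 3, 2)]
  expect_error(validate_mesh(bad), "orientation")
  bad2 <- s
  tri <- bad2$faces[1, ]
  bad2$vertices[tri[1], ] <- bad2$vertices[tri[2], ]
  expect_error(validate_mesh(bad2), "degenerate")
})
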