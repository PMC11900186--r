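# Sweep machinery contracts: onset detection, contour classification,
# bulge seeding.

test_that("onset detection refines the argmax of p and ignores monotone series", {
  tab <- data.frame(control = 0:4,
                    p = c(0.1, 0.3, 0.41, 0.38, 0.2),
                    gamma = c(1, 1.3, 1.8, 2.0, 2.2),
                    converged = TRUE)
  on <- detect_pearling_onset(tab)
  expect_gt(on$control, 1.5)
  expect_lt(on$control, 2.5)
  expect_gt(on$p_star, 0.38)
  expect_false(is.na(on$gamma_star))

  mono <- data.frame(control = 0:5, p = seq(0.1, 0.6, 0.1),
                     gamma = seq(1, 2, 0.2), converged = TRUE)
  expect_true(is.na(detect_pearling_onset(mono)$control))
  # too few records
  expect_true(is.na(detect_pearling_onset(tab[1:3, ])$control))
})

test_that("contour classification: circle section is convex, junction start concave", {
  # sphere cut at z = 0 gives a circular (convex) silhouette
  s <- build_icosphere(2, 3)
  expect_identical(junction_contour_class(s), "convex")
  # the relaxed initial junction has concave sides
  init <- fx_junction_init()
  expect_identical(junction_contour_class(init$state$mesh), "concave")
})

test_that("arm-seeded bulge inflates one arm midpoint only", {
  init <- fx_junction_init()
  m <- init$state$mesh
  m2 <- junctionmech:::seed_arm_bulge(m, sigma = 1, amplitude = 0.8)
  dV <- enclosed_volume(m2) - enclosed_volume(m)
  expect_gt(dV, 0)
  pos <- junctionmech:::arm_bulge_position(m2)
  expect_gt(pos, 1.5)   # bulge sits out on the arm, not at the center
})

test_that("sweep grids are validated", {
  init <- fx_junction_init()
  expect_error(volume_sweep(init, c(0.1, 0.2)))     # must start at 0
  expect_error(force_sweep(init, c(0.9, 1.2)))      # must start at 1
})

test_that("junction-seeded bulging is favored over (or absorbs) arm-seeded bulging", {
  init <- fx_junction_init()
  cb <- compare_bulge_placement(init, 0.15, steps = 4)
  expect_true(cb$favored %in% c("junction", "merged"))
  if (cb$favored == "junction")
    expect_lte(cb$F_B_junction, cb$F_B_arm)
})
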