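test_that("default geometry realizes the thorax and lung volume targets", {
  g <- default_geom()
  expect_equal(g$volumes$thorax, 23.4e-3, tolerance = 1e-9)
  ## analytic elliptic-cylinder volume is the pinned target
  expect_equal(pi * g$torso$a * g$torso$b * g$torso$h, 23.4e-3,
               tolerance = 1e-12)
  lung_total <- g$volumes$lung_left + g$volumes$lung_right
  expect_lt(abs(lung_total - 4.84e-3) / 4.84e-3, 0.02)
  ## regions must be disjoint and inside the torso
  set.seed(7)
  pts <- cbind(runif(4000, -g$torso$a, g$torso$a),
               runif(4000, -g$torso$b, g$torso$b),
               runif(4000, 0, g$torso$h))
  lab <- classify_points(g, pts)
  expect_true(all(lab %in% c("outside", "soft_tissue", "lung_left",
                             "lung_right", "heart", "rib", "airway")))
  ## heart strictly between the lung solids: no point is both
  expect_false(any(in_heart(g, pts) & (in_lung(g, pts, "left") |
                                         in_lung(g, pts, "right"))))
})

test_that("rib toggle removes rib regions but keeps the outer surface", {
  g <- build_geometry(thorax_params(ribs_enabled = FALSE))
  g0 <- default_geom()
  expect_equal(g$torso, g0$torso)
  set.seed(11)
  pts <- cbind(runif(2000, -g$torso$a, g$torso$a),
               runif(2000, -g$torso$b, g$torso$b),
               runif(2000, 0, g$torso$h))
  expect_false(any(classify_points(g, pts) == "rib"))
  expect_true(any(classify_points(g0, pts) == "rib"))
})

test_that("infeasible parameters fail with a descriptive error", {
  p <- thorax_params()
  p$lungs$right$semi <- c(0.2, 0.2, 0.3)  # protrudes
  expect_error(build_geometry(p), "protrudes")
  p2 <- thorax_params()
  p2$lungs$left$center[1] <- 0.01  # crosses the midline
  expect_error(build_geometry(p2), "midline")
  expect_error(thorax_params(torso_height = -1), "positive")
})

test_that("fluid carving hits the volume target by bisection", {
  g <- default_geom()
  gf <- carve_fluid_region(g, "right", 670e-6)
  fl <- gf$fluid$right
  expect_lt(abs(fl$realized_volume - 670e-6) / 670e-6, 0.01)
  expect_gt(fl$cut_height, lung_base_height(g, "right"))
  ## zero target leaves the geometry unchanged
  expect_identical(carve_fluid_region(g, "right", 0)$fluid$right, NULL)
  ## monotonicity of the cut height in the target volume
  h1 <- carve_fluid_region(g, "right", 300e-6)$fluid$right$cut_height
  h2 <- carve_fluid_region(g, "right", 600e-6)$fluid$right$cut_height
  expect_lt(h1, h2)
  ## infeasible targets
  expect_error(carve_fluid_region(g, "right", 5e-3), "exceeds 90%")
  expect_error(carve_fluid_region(g, "right", -1e-4), "non-negative")
})

test_that("electrode arrays form an 8 cm square anchored at the lung base", {
  g <- geom_right()
  el <- g$electrodes
  ## bottom pair level with the lower lung margin at offset 0
  zb <- lung_base_height(g, "right")
  expect_lt(abs(el$centers_uz$A[2] - zb), 2e-3)
  expect_lt(abs(el$centers_uz$C[2] - zb), 2e-3)
  ## adjacent centre-to-centre distances in the surface metric
  P <- g$arc$perimeter
  duz <- function(p, q) {
    du <- arc_diff(el$centers_uz[[p]][1], el$centers_uz[[q]][1], P)
    dz <- el$centers_uz[[p]][2] - el$centers_uz[[q]][2]
    sqrt(du^2 + dz^2)
  }
  for (pair in list(c("A", "B"), c("C", "D"), c("A", "C"), c("B", "D")))
    expect_lt(abs(duz(pair[1], pair[2]) - 0.08), 1e-3)
  ## vertical offset is a rigid translation
  g2 <- place_electrode_array(default_geom(), "right",
                              vertical_offset = 0.02)
  for (lb in c("A", "B", "C", "D")) {
    expect_equal(g2$electrodes$centers_uz[[lb]][1],
                 el$centers_uz[[lb]][1])
    expect_equal(g2$electrodes$centers_uz[[lb]][2],
                 el$centers_uz[[lb]][2] + 0.02)
  }
})

test_that("invalid electrode placements are rejected", {
  g <- default_geom()
  expect_error(place_electrode_array(g, "right", vertical_offset = 0.4),
               "falls off")
  expect_error(place_electrode_array(g, "right", separation = 0.005),
               "overlap")
  expect_error(place_electrode_array(g, "right", separation = -1),
               "positive")
  expect_error(place_electrode_array(g, "right",
                                     corner_assignment = c(A = "bottom_left",
                                                           B = "bottom_left",
                                                           C = "bottom_right",
                                                           D = "top_right")),
               "corner")
})
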