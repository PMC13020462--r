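test_that("the half-space point-electrode formula matches its derivations", {
  rho <- 1 / 0.18233
  s <- 0.08
  ## square, current along one edge, sense along the opposite edge:
  ## superposition of 1/(2 pi r) potentials gives rho (1 - 1/sqrt(2))/(pi s)
  Z <- halfspace_point_electrode_Z(A = c(0, 0), B = c(0, s),
                                   C = c(s, 0), D = c(s, s), rho = rho)
  expect_equal(Z, rho * (1 - 1 / sqrt(2)) / (pi * s), tolerance = 1e-12)
  expect_equal(Z, 6.3916, tolerance = 1e-4)
  ## collinear Wenner array with spacing a: rho / (2 pi a)
  a <- 0.05
  Zw <- halfspace_point_electrode_Z(A = c(0, 0), B = c(3 * a, 0),
                                    C = c(a, 0), D = c(2 * a, 0), rho = rho)
  expect_equal(Zw, rho / (2 * pi * a), tolerance = 1e-12)
  ## diagonal drive on a square: both sense electrodes equidistant
  Zd <- halfspace_point_electrode_Z(A = c(0, 0), B = c(s, s),
                                    C = c(s, 0), D = c(0, s), rho = rho)
  expect_equal(Zd, 0)
  expect_error(halfspace_point_electrode_Z(c(0, 0), c(0, 0), c(1, 0),
                                           c(0, 1), rho), "coincident")
})

test_that("voltage and integral methods agree and obey reciprocity", {
  sys <- square_box_system()
  sAB <- solve_injection(sys, "A", "B")
  sCD <- solve_injection(sys, "C", "D")
  Zv <- transfer_impedance_voltage(sAB)$Z
  fld <- sensitivity_field(sAB, sCD)
  Zi <- transfer_impedance_integral(fld)$Z
  expect_gt(Zv, 0)
  expect_lt(abs(Zi - Zv) / Zv, 1e-9)         # discrete identity
  ## reciprocity: drive C-D, sense A-B
  Zr <- transfer_impedance_voltage(sCD, "A", "B")$Z
  expect_lt(abs(Zr - Zv) / Zv, 0.005)
  ## swapping the sense pair negates the reading
  expect_equal(transfer_impedance_voltage(sAB, "D", "C")$Z, -Zv)
  ## sensitivity is not sign-definite for a tetrapolar array
  expect_gt(sum(fld$z > 0), 0)
  expect_gt(sum(fld$z < 0), 0)
})

test_that("diagonal drive on a symmetric square array reads zero", {
  sys <- square_box_system()
  sAD <- solve_injection(sys, "A", "D")
  Zadj <- transfer_impedance_voltage(solve_injection(sys, "A", "B"))$Z
  Zdiag <- transfer_impedance_voltage(sAD, "B", "C")$Z
  expect_lt(abs(Zdiag), 1e-3 * abs(Zadj))
})

test_that("FEM matches the analytic half-space impedance", {
  ## box much larger than the array; electrode diameter << separation
  hs <- halfspace_run()
  expect_lt(abs(hs$Z - hs$Z_analytic) / hs$Z_analytic, 0.05)
})

test_that("impedance obeys the conductivity scaling law", {
  bm <- square_box()
  alpha <- 2.5
  tab <- tissue_table()
  tab2 <- tab
  tab2$sigma <- tab2$sigma * alpha
  s1 <- solve_injection(assemble_system(bm, tab, solve_spec()), "A", "B")
  s2 <- solve_injection(assemble_system(bm, tab2, solve_spec()), "A", "B")
  Z1 <- transfer_impedance_voltage(s1)$Z
  Z2 <- transfer_impedance_voltage(s2)$Z
  expect_lt(abs(Z2 - Z1 / alpha) / Z1, 1e-12)
})

test_that("the bipolar power-dissipation identity recovers the bar resistance", {
  sol <- solve_injection(bar_system(), "A", "B")
  fld <- sensitivity_field(sol, sol)  # drive pair = sense pair
  R <- transfer_impedance_integral(fld)$Z
  expect_equal(R, BAR_R, tolerance = 1e-9)
})

test_that("regional contributions are additive and validated", {
  r <- thorax_coarser_run()
  Z <- r$Z
  labs <- c("soft_tissue", "lung_left", "lung_right", "heart", "rib",
            "fluid")
  contribs <- vapply(labs, function(l) regional_contribution(r$field, l), 0)
  expect_lt(abs(sum(contribs) - Z) / Z, 1e-9)
  expect_identical(regional_contribution(r$field, character(0)), 0)
  expect_error(regional_contribution(r$field, "spleen"), "unknown region")
  ## with the array on the right side, the right lung dominates the left
  expect_gt(contribs["lung_right"], contribs["lung_left"])
})

test_that("planar sensitivity maps peak under the array and fade with depth", {
  r <- thorax_coarser_run()
  g <- geom_right()
  m6 <- planar_sensitivity_map(r$field, g, depth = 0.06)
  m8 <- planar_sensitivity_map(r$field, g, depth = 0.08)
  expect_gt(m6$planar_average, m8$planar_average)
  ## the shallow map is dominated by the immediate sub-electrode elements
  m1 <- planar_sensitivity_map(r$field, g, depth = 0.005,
                               half_extent = 0.10)
  gr <- m1$grid[!is.na(m1$grid$z), ]
  near <- sqrt(gr$h^2 + gr$v^2) < 0.08
  expect_gt(max(gr$z[near]), max(0, gr$z[!near]))
  expect_error(planar_sensitivity_map(r$field, g, depth = 5), "outside")
})
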