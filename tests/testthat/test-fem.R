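test_that("the stiffness operator annihilates constants and is linear in kappa", {
  bm <- bar_mesh()
  grads <- element_gradients(bm$nodes, bm$elems)
  K <- assemble_matrix(bm, grads, rep(1, nrow(bm$elems)))
  ones <- rep(1, nrow(bm$nodes))
  expect_lt(max(abs(K %*% ones)), 1e-12 * max(abs(K)))
  K2 <- assemble_matrix(bm, grads, rep(2, nrow(bm$elems)))
  expect_lt(max(abs(K2 - 2 * K)), 1e-12 * max(abs(K)))
})

test_that("a homogeneous bar reproduces the conductance kappa*A/L", {
  sol <- solve_injection(bar_system(), "A", "B")
  Z <- Re(sol$patch_V[["electrode_A"]]) / sol$spec$I0
  expect_equal(Z, BAR_R, tolerance = 1e-9)
})

test_that("solutions scale with I0 and are antisymmetric under pair swap", {
  sys <- bar_system()
  s1 <- solve_injection(sys, "A", "B")
  s2 <- solve_injection(sys, "A", "B", spec = solve_spec(I0 = 2e-3))
  expect_equal(s2$V, 2 * s1$V, tolerance = 1e-12)
  ## swapping source and sink negates V after re-grounding
  s3 <- solve_injection(sys, "B", "A")
  vmax <- max(abs(s1$V))
  expect_lt(max(abs((s1$V - max(s1$V)) + s3$V)), 1e-9 * vmax)
})

test_that("current conservation holds discretely and failures are flagged", {
  sol <- solve_injection(bar_system(), "A", "B")
  cc <- check_current_conservation(sol)
  expect_true(cc$pass)
  expect_lt(max(cc$patches$deviation_frac_I0), 1e-10)
  expect_lt(cc$other_boundary_flux / sol$spec$I0, 1e-10)
  ## a deliberately under-converged iterative solve must be caught
  expect_warning(
    bad <- solve_injection(bar_system(), "A", "B",
                           spec = solve_spec(solver = "iterative",
                                             rel_tolerance = 1e-2),
                           cg_max_iter = 2L),
    "residual")
  expect_false(check_current_conservation(bad)$pass)
})

test_that("iterative and direct solvers agree", {
  sd <- solve_injection(bar_system(), "A", "B")
  si <- solve_injection(bar_system(), "A", "B",
                        spec = solve_spec(solver = "iterative",
                                          rel_tolerance = 1e-8))
  expect_lt(max(abs(sd$V - si$V)) / max(abs(sd$V)), 1e-6)
  expect_lte(si$residual, 1e-8)
})

test_that("the complex solve reduces to the real solve at low frequency", {
  bm <- bar_mesh()
  ## at 5 kHz the displacement term is tiny for soft tissue
  sysc <- assemble_system(bm, spec = solve_spec(frequency = 5e3,
                                                mode = "complex"))
  solc <- solve_injection(sysc, "A", "B")
  sysr <- assemble_system(bm, spec = solve_spec(frequency = 5e3,
                                                mode = "real"))
  solr <- solve_injection(sysr, "A", "B")
  ZR <- Re(solr$patch_V[["electrode_A"]])
  ZC <- Mod(solc$patch_V[["electrode_A"]])
  expect_lt(abs(ZC - ZR) / ZR, 5e-3)
  expect_lt(solc$residual, 1e-9)
})

test_that("the solution is invariant under node reordering", {
  bm <- box_mesh(0.04, 0.04, 0.08, 0.012, end_electrodes = TRUE)
  sol <- solve_injection(assemble_system(bm, spec = solve_spec()), "A", "B")
  set.seed(5)
  perm <- sample(nrow(bm$nodes))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  bm2 <- bm
  bm2$nodes <- bm$nodes[perm, , drop = FALSE]
  bm2$elems <- matrix(inv[bm$elems], ncol = 4)
  bm2$faces <- matrix(inv[bm$faces], ncol = 3)
  sol2 <- solve_injection(assemble_system(bm2, spec = solve_spec()),
                          "A", "B")
  expect_lt(max(abs(sol2$V[inv] - sol$V)), 1e-9)
})
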