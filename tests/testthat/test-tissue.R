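test_that("10 kHz defaults equal the published single-frequency values", {
  vals <- list(lung_inflated = c(0.0932, 17174),
               soft_tissue = c(0.18233, 13497),
               bone_rib = c(0.0515, 1089),
               heart = c(0.1542, 70054),
               body_fluid = c(1.5, 98),
               electrode = c(4e6, 1))
  for (tn in names(vals)) {
    p <- lookup_tissue(tn, 1e4)
    expect_identical(p$sigma, vals[[tn]][1])
    expect_identical(p$eps_r, vals[[tn]][2])
    expect_false(p$interpolated)
  }
})

test_that("lookup interpolates inside the table and refuses outside", {
  p <- lookup_tissue("heart", 2e4)
  expect_true(p$interpolated)
  expect_gt(p$sigma, lookup_tissue("heart", 1e4)$sigma)
  expect_lt(p$sigma, lookup_tissue("heart", 5e4)$sigma)
  expect_lt(p$eps_r, lookup_tissue("heart", 1e4)$eps_r)
  expect_error(lookup_tissue("heart", 2e6), "outside the tabulated range")
  expect_error(lookup_tissue("heart", 1e3), "outside the tabulated range")
  expect_error(lookup_tissue("cartilage", 1e4), "unknown tissue")
})

test_that("admittivity combines conduction and displacement current", {
  p <- lookup_tissue("soft_tissue", 1e4)
  expect_identical(admittivity(p, "real"), 0.18233)
  ## complex admittivity: real part is sigma for every tabulated row
  tab <- tissue_table()
  for (i in seq_len(nrow(tab))) {
    pr <- list(sigma = tab$sigma[i], eps_r = tab$eps_r[i],
               frequency = tab$frequency[i])
    expect_identical(Re(admittivity(pr, "complex")), pr$sigma)
  }
  ## the displacement term vanishes as f -> 0
  pr0 <- list(sigma = 0.1, eps_r = 5e4, frequency = 1e-3)
  expect_lt(Im(admittivity(pr0, "complex")) / pr0$sigma, 1e-7)
  ## heart at 10 kHz: 2*pi*1e4*eps0*70054 = 3.90e-2 S/m
  ph <- lookup_tissue("heart", 1e4)
  expect_equal(Im(admittivity(ph, "complex")),
               2 * pi * 1e4 * 8.8541878128e-12 * 70054, tolerance = 1e-12)
  expect_equal(Im(admittivity(ph, "complex")), 3.90e-2, tolerance = 1e-3)
})

test_that("validate_table passes the shipped table and reports violations", {
  rep0 <- validate_table(tissue_table())
  expect_true(rep0$ok)
  expect_length(rep0$violations, 0)

  tab <- tissue_table()
  tab$eps_r[tab$tissue == "heart" & tab$frequency == 5e4] <- 0
  rep1 <- validate_table(tab)
  expect_false(rep1$ok)
  expect_true(any(grepl("eps_r", rep1$violations)))

  tab2 <- tissue_table()
  tab2 <- tab2[!(tab2$tissue == "bone_rib" & tab2$frequency == 5e5), ]
  rep2 <- validate_table(tab2)
  expect_false(rep2$ok)
  expect_true(any(grepl("bone_rib: missing frequencies 500", rep2$violations)))
})

test_that("property tables round-trip through delimited text", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_property_table(tissue_table(), path)
  back <- read_property_table(path)
  expect_equal(back$sigma, tissue_table()$sigma)
  expect_equal(back$eps_r, tissue_table()$eps_r)
  expect_identical(back$tissue, tissue_table()$tissue)
})
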