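test_that("percent_delta_Z is baseline-referenced", {
  expect_equal(percent_delta_Z(10, 10), 0)
  expect_equal(percent_delta_Z(10, 8), 20)
  expect_equal(percent_delta_Z(c(10, 20), c(9, 22)), c(10, -10))
  expect_error(percent_delta_Z(0, 1), "positive")
})

test_that("linear fits are exact on collinear data and report both units", {
  v <- seq(0, 670e-6, length.out = 6)
  df <- data.frame(volume = v, Z = 15 - 5000 * v)  # -5000 Ohm/m^3
  ft <- linear_fit_volume(df)
  expect_equal(ft$slope_ohm_per_m3, -5000, tolerance = 1e-9)
  expect_equal(ft$slope_mohm_per_100ml, -500, tolerance = 1e-9)
  expect_equal(ft$intercept, 15, tolerance = 1e-9)
  expect_equal(ft$r_squared, 1, tolerance = 1e-12)
  ## unit conversion: -0.0046674 Ohm/mL corresponds to -466.74 mOhm/100 mL
  df2 <- data.frame(volume = v, Z = 15 - 0.0046674e6 * v)
  expect_equal(linear_fit_volume(df2)$slope_mohm_per_100ml, -466.74,
               tolerance = 1e-6)
  expect_error(linear_fit_volume(df[1:2, ]), "at least 3")
})

test_that("OLS matches the brute-force normal-equation solution", {
  set.seed(42)
  for (i in 1:5) {
    v <- sort(runif(6, 0, 7e-4))
    Z <- 14 + rnorm(1, -5000, 1000) * v + rnorm(6, 0, 0.05)
    ft <- linear_fit_volume(data.frame(volume = v, Z = Z))
    X <- cbind(1, v)
    beta <- solve(t(X) %*% X, t(X) %*% Z)
    expect_equal(ft$intercept, beta[1], tolerance = 1e-10)
    expect_equal(ft$slope_ohm_per_m3, beta[2], tolerance = 1e-10)
  }
})

test_that("fits recover a known slope from lightly noisy series", {
  set.seed(9)
  v <- seq(0, 670e-6, length.out = 6)
  slope_true <- -6000
  for (i in 1:10) {
    Z0 <- 14 + slope_true * v
    Z <- Z0 * (1 + rnorm(6, 0, 1e-3))
    ft <- linear_fit_volume(data.frame(volume = v, Z = Z))
    se <- summary(ft$fit)$coefficients["volume", "Std. Error"]
    expect_lt(abs(ft$slope_ohm_per_m3 - slope_true), 3 * se + 1e-9)
  }
})

test_that("convergence deviation statistics match hand arithmetic", {
  ## reference four-level series in Ohm
  Z <- c(15.027, 15.079, 15.082, 15.095)
  st <- convergence_deviation_stats(Z)
  expect_equal(st$max_deviation, abs(15.027 - 15.095) / 15.095,
               tolerance = 1e-12)
  expect_equal(100 * st$max_deviation, 0.450, tolerance = 1e-2)
  expect_equal(st$normal_vs_fine, abs(15.082 - 15.095) / 15.095,
               tolerance = 1e-12)
  expect_equal(100 * st$normal_vs_fine, 0.0861, tolerance = 1e-2)
  expect_lt(st$max_deviation, 0.005)
  expect_lt(st$normal_vs_fine, 0.001)
  ## degenerate series
  expect_equal(convergence_deviation_stats(12)$max_deviation, 0)
  expect_equal(convergence_deviation_stats(numeric(0))$max_deviation,
               NA_real_)
})

test_that("the detectability band flags only genuine differences", {
  base <- data.frame(offset = c(0, 0.02, 0.04), Z = c(12, 11, 10))
  same <- detectability_band(base, base)
  expect_false(any(same$detectable))
  fluid <- base
  fluid$Z <- base$Z - c(1.5, 0.1, 0.05)
  db <- detectability_band(base, fluid, band = 0.02)
  expect_identical(db$detectable, c(TRUE, FALSE, FALSE))
  ## a zero band flags any nonzero difference
  db0 <- detectability_band(base, fluid, band = 0)
  expect_true(all(db0$detectable))
  bad <- base; bad$offset <- bad$offset + 0.01
  expect_error(detectability_band(base, bad), "mismatched")
})

test_that("empty sweep grids give empty results", {
  sw <- vertical_sweep(default_geom(), "right", offsets = numeric(0))
  expect_s3_class(sw, "sweep_result")
  expect_identical(nrow(sw$points), 0L)
  sv <- fluid_volume_sweep(default_geom(), "right", volumes = numeric(0))
  expect_identical(nrow(sv$points), 0L)
})

test_that("vertical sweeps flag failing offsets and continue", {
  expect_warning(
    sw <- vertical_sweep(default_geom(), "right", offsets = c(0, 0.40),
                         refinement_level = "coarser"),
    "failed")
  expect_identical(sw$points$ok, c(TRUE, FALSE))
  expect_false(is.na(sw$points$Z[1]))
  expect_true(is.na(sw$points$Z[2]))
})
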