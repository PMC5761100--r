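make_sites <- function(env, intercept, slope, feather_sd = 0, n_birds = 10) {
  data.frame(site_id = sprintf("S%02d", seq_along(env)),
             lon = 0, lat = 0,
             feather_mean = intercept + slope * env,
             feather_sd = feather_sd, n_birds = n_birds, env_d2h = env)
}

test_that("zero-noise sites collapse the bootstrap to the exact OLS fit", {
  sites <- make_sites(env = c(-100, -80, -60, -40), intercept = -10,
                      slope = 1.2)
  m <- suppressWarnings(bootstrap_rescale(sites, n_boot = 50, seed = 1))
  expect_equal(m$slope_mean, 1.2, tolerance = 1e-12)
  expect_equal(m$intercept_mean, -10, tolerance = 1e-10)
  expect_equal(m$slope_sd, 0, tolerance = 1e-12)
  expect_equal(m$intercept_sd, 0, tolerance = 1e-10)
  expect_equal(m$resid_sd_mean, 0, tolerance = 1e-10)
})

test_that("bootstrap recovers the generating tissue slope within 2 slope SDs", {
  w <- make_world(coarse_config(seed = 31))
  s <- make_calibration_sites(w)
  m <- bootstrap_rescale(s, n_boot = 1000, seed = 2)
  expect_lt(abs(m$slope_mean - w$config$tissue_model$slope), 2 * m$slope_sd)
  expect_lt(abs(m$intercept_mean - w$config$tissue_model$intercept),
            2 * m$intercept_sd)
})

test_that("bootstrap output is bit-reproducible under a fixed seed", {
  sites <- make_sites(env = c(-100, -80, -60), intercept = 0, slope = 1,
                      feather_sd = 3)
  m1 <- bootstrap_rescale(sites, n_boot = 2, seed = 99)
  m2 <- bootstrap_rescale(sites, n_boot = 2, seed = 99)
  expect_identical(m1[c("intercept_mean", "slope_mean", "intercept_sd",
                        "slope_sd", "resid_sd_mean")],
                   m2[c("intercept_mean", "slope_mean", "intercept_sd",
                        "slope_sd", "resid_sd_mean")])
})

test_that("site-size weighting is a no-op under equal weights", {
  sites <- make_sites(env = c(-100, -80, -60, -45), intercept = -5,
                      slope = 1.1, feather_sd = 2, n_birds = 19)
  m_u <- bootstrap_rescale(sites, n_boot = 50, seed = 4)
  m_w <- bootstrap_rescale(sites, n_boot = 50, seed = 4, weight_by_n = TRUE)
  expect_equal(m_w$slope_mean, m_u$slope_mean, tolerance = 1e-12)
  expect_equal(m_w$resid_sd_mean, m_u$resid_sd_mean, tolerance = 1e-12)
})

test_that("degenerate calibration designs are rejected", {
  expect_error(bootstrap_rescale(make_sites(c(-100, -80), 0, 1), 100, 1),
               "insufficient")
  expect_error(bootstrap_rescale(make_sites(rep(-80, 5), 0, 1), 100, 1),
               "degenerate")
  expect_error(bootstrap_rescale(make_sites(c(-9, -8, -7), 0, 1), 1, 1),
               "n_boot")
})

test_that("bootstrap SDs shrink monotonically as site noise vanishes", {
  env <- seq(-110, -40, length.out = 10)
  sds <- vapply(c(6, 2, 0.5), function(s) {
    m <- bootstrap_rescale(make_sites(env, -20, 1, feather_sd = s),
                           n_boot = 500, seed = 7)
    m$slope_sd
  }, numeric(1))
  expect_true(all(diff(sds) < 0))
})

test_that("isoscape conversion applies the rescale map and quadrature SD", {
  ident <- structure(list(intercept_mean = 0, slope_mean = 1,
                          intercept_sd = 0, slope_sd = 0, resid_sd_mean = 0,
                          n_boot = 2L, seed = 1L), class = "rescale_model")
  g <- toy_grid(matrix(c(-100, -80, -60, -40), 2, 2))
  out <- convert_isoscape(g, NULL, ident)
  expect_equal(out$feather$values, g$values)
  expect_equal(out$feather_sd$values, matrix(0, 2, 2))

  affine <- ident; affine$slope_mean <- 2; affine$intercept_mean <- 5
  const <- toy_grid(matrix(-100, 2, 2))
  expect_equal(convert_isoscape(const, NULL, affine)$feather$values,
               matrix(-195, 2, 2))

  # single-cell closed-form check of the quadrature SD
  m <- ident
  m$intercept_sd <- 3; m$slope_sd <- 0.05; m$resid_sd_mean <- 4
  m$slope_mean <- 1.1
  se <- toy_grid(matrix(2, 2, 2))
  out2 <- convert_isoscape(const, se, m)
  expect_equal(out2$feather_sd$values[1, 1],
               sqrt(3^2 + (0.05 * 100)^2 + 4^2 + (1.1 * 2)^2),
               tolerance = 1e-12)

  # nodata propagates
  gg <- const; gg$values[1, 2] <- NA
  out3 <- convert_isoscape(gg, se, m)
  expect_true(is.na(out3$feather$values[1, 2]))
  expect_true(is.na(out3$feather_sd$values[1, 2]))
})

test_that("conversion commutes with affine rescaling of the input grid", {
  # mapping a*x + b through model (i, s) equals mapping x through
  # (i + s*b, s*a): linearity of the rescale function
  g <- toy_grid(matrix(c(-90, -70, -50, -30), 2, 2))
  m <- structure(list(intercept_mean = -12, slope_mean = 0.9,
                      intercept_sd = 0, slope_sd = 0, resid_sd_mean = 0,
                      n_boot = 2L, seed = 1L), class = "rescale_model")
  a <- 2; b <- 5
  g2 <- raster_like(g, a * g$values + b)
  m2 <- m; m2$intercept_mean <- m$intercept_mean + m$slope_mean * b
  m2$slope_mean <- m$slope_mean * a
  expect_equal(convert_isoscape(g2, NULL, m)$feather$values,
               convert_isoscape(g, NULL, m2)$feather$values,
               tolerance = 1e-12)
})
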