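test_that("world generation is bit-deterministic under a fixed seed", {
  w1 <- make_world(coarse_config(seed = 3))
  w2 <- make_world(coarse_config(seed = 3))
  expect_identical(w1$precip_truth$values, w2$precip_truth$values)
  expect_identical(w1$covariates$elevation$values,
                   w2$covariates$elevation$values)
  w3 <- make_world(coarse_config(seed = 4))
  expect_false(identical(w1$precip_truth$values, w3$precip_truth$values))
})

test_that("noiseless latitude-only model yields an exact affine precip grid", {
  cfg <- coarse_config(
    seed = 1,
    precip_model = list(intercept = 20, lat = -1.5, lon = 0, elev = 0,
                        temp = 0, resid_sd = 0))
  w <- make_world(cfg)
  latv <- w$covariates$latitude$values
  expect_equal(w$precip_truth$values, 20 - 1.5 * latv, tolerance = 1e-12)
})

test_that("regressing the emitted grid on its covariates recovers the truth", {
  cfg <- coarse_config(seed = 9)
  w <- make_world(cfg)
  # independent OLS oracle on the same cells
  dat <- data.frame(y = as.vector(w$precip_truth$values),
                    temp = as.vector(w$covariates$temperature$values),
                    elev = as.vector(w$covariates$elevation$values),
                    lat = as.vector(w$covariates$latitude$values),
                    lon = as.vector(w$covariates$longitude$values))
  fit <- lm(y ~ temp + elev + lat + lon, data = dat)
  est <- coef(summary(fit))
  truth <- with(cfg$precip_model, c(intercept, temp, elev, lat, lon))
  expect_true(all(abs(est[, "Estimate"] - truth) < 2 * est[, "Std. Error"]))
})

test_that("calibration sites summarise simulated birds faithfully", {
  # identity tissue model with no site noise: feather mean == env value
  cfg <- coarse_config(seed = 5,
                       tissue_model = list(intercept = 0, slope = 1,
                                           site_sd = 0))
  w <- make_world(cfg)
  s <- make_calibration_sites(w)
  expect_equal(nrow(s), 10)
  expect_equal(sum(s$n_birds), 186)
  expect_equal(s$feather_mean, s$env_d2h, tolerance = 1e-12)
  expect_equal(s$feather_sd, rep(0, 10), tolerance = 1e-12)

  # single-bird sites flag a zero SD
  expect_warning(make_calibration_sites(w, n_sites = 4, birds_per_site = 1),
                 "single bird")

  # pooled regression of site means on env recovers the tissue model
  cfg2 <- coarse_config(seed = 6)
  w2 <- make_world(cfg2)
  s2 <- make_calibration_sites(w2)
  fit <- lm(feather_mean ~ env_d2h, data = s2,
            weights = s2$n_birds)
  est <- coef(summary(fit))
  expect_lt(abs(est[1, "Estimate"] - cfg2$tissue_model$intercept),
            2 * est[1, "Std. Error"])
  expect_lt(abs(est[2, "Estimate"] - cfg2$tissue_model$slope),
            2 * est[2, "Std. Error"])

  expect_error(make_calibration_sites(w, n_sites = 1e5), "config error")
})

test_that("migrant cohorts respect the phenology, window and mass model", {
  cfg <- coarse_config(seed = 7)
  w <- make_world(cfg)
  m <- make_migrants(w)
  expect_equal(nrow(m), 150)
  expect_equal(as.vector(table(m$sex)), c(75, 75))
  expect_equal(sort(unique(m$year)), c(2010, 2011, 2014))
  win <- cfg$phenology_model$window
  expect_true(all(m$ordinal_day >= win[1] & m$ordinal_day <= win[2]))
  expect_identical(ordinal_day(m$capture_date), m$ordinal_day)
  # natal coordinates land inside the range mask
  expect_true(all(m$natal_lat >= 30 & m$natal_lat <= 50))
  # fitted arrival slope within 2 SE of the generating +2 d/deg
  fit <- coef(summary(lm(ordinal_day ~ natal_lat, data = m)))
  expect_lt(abs(fit[2, "Estimate"] - 2), 2 * fit[2, "Std. Error"])
  # mass is fat-free mass plus a nonnegative fuel load
  mm <- cfg$morphometry_model
  ffm <- ifelse(m$sex == "F",
                mm$F$intercept + mm$F$slope * m$wing_chord_mm,
                mm$M$intercept + mm$M$slope * m$wing_chord_mm)
  expect_true(all(m$mass_g >= ffm - 1e-12))
})

test_that("null phenology slope leaves arrival uncorrelated with latitude", {
  cors <- vapply(1:5, function(s) {
    cfg <- coarse_config(seed = 100 + s,
                         phenology_model = list(intercept = 270, slope = 0,
                                                resid_sd = 10,
                                                window = c(237, 305)))
    m <- make_migrants(make_world(cfg))
    cor(m$ordinal_day, m$natal_lat)
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.1)
})

test_that("migrant feather values regress back to the tissue model", {
  cfg <- coarse_config(seed = 21)
  w <- make_world(cfg)
  m <- make_migrants(w)
  env <- extract_at_sites(w$precip_truth, m$natal_lon, m$natal_lat)
  est <- coef(summary(lm(m$feather_d2h ~ env)))
  expect_lt(abs(est[1, "Estimate"] - cfg$tissue_model$intercept),
            2 * est[1, "Std. Error"])
  expect_lt(abs(est[2, "Estimate"] - cfg$tissue_model$slope),
            2 * est[2, "Std. Error"])
})

test_that("truth columns are withheld from the pipeline-facing table", {
  m <- make_migrants(make_world(coarse_config(seed = 2)))
  vis <- migrant_table(m)
  expect_false(any(c("natal_lat", "natal_lon") %in% names(vis)))
  expect_identical(truth_table(m)$bird_id, m$bird_id)
})
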