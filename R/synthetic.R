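#' Configuration for the synthetic study system
#'
#' Bundles every ground-truth parameter the generator needs: the geographic
#' window, the linear model that produces the precipitation d2H surface from
#' its covariates, the tissue (feather) rescaling truth, the arrival
#' phenology, and the morphometric model.  Defaults describe a mid-latitude
#' eastern North American window with a monotone latitudinal d2H gradient,
#' a cohort design of 25 birds per sex per year over three seasons, and a
#' positive arrival-day-per-degree-latitude phenology slope.
#'
#' @param lat_range,lon_range numeric length-2, decimal degrees.
#' @param resolution degrees per cell (same in both axes).
#' @param mask_lat_range latitude band treated as the species breeding
#'   range (the assignment support), degrees.
#' @param precip_model list: `intercept` (permil), `lat`, `lon` (permil per
#'   degree), `elev` (permil per metre), `temp` (permil per degree C),
#'   `resid_sd` (permil).
#' @param temp_model list: `intercept` (deg C), `lat` (deg C per degree
#'   latitude), `noise_sd` (deg C, smoothed field).
#' @param elev_model list: `mean`, `sd` (metres) of the smoothed random
#'   field; values are clipped at zero.
#' @param tissue_model list: `intercept` (permil), `slope` (dimensionless),
#'   `site_sd` (permil, among-bird spread within a site).
#' @param phenology_model list: `intercept` (ordinal day at latitude zero),
#'   `slope` (days per degree natal latitude), `resid_sd` (days),
#'   `window` (length-2 ordinal-day capture season).
#' @param morphometry_model list with per-sex fat-free-mass regressions
#'   (`intercept` grams, `slope` grams per mm wing chord, `chord_mean`,
#'   `chord_sd` mm) and fuel-load gamma parameters (`fuel_shape`,
#'   `fuel_scale`, grams).
#' @param rng_seed integer master seed; identical seed and config give
#'   bit-identical outputs.
#' @return an object of class `world_config` (a validated list).
#' @export
world_config <- function(lat_range = c(25, 55),
                         lon_range = c(-95, -75),
                         resolution = 0.5,
                         mask_lat_range = c(30, 50),
                         precip_model = list(intercept = 20, lat = -1.5,
                                             lon = 0.3, elev = -0.015,
                                             temp = 0.8, resid_sd = 3),
                         temp_model = list(intercept = 42, lat = -0.5,
                                           noise_sd = 1),
                         elev_model = list(mean = 300, sd = 200),
                         tissue_model = list(intercept = -25, slope = 1,
                                             site_sd = 2),
                         phenology_model = list(intercept = 180, slope = 2,
                                                resid_sd = 5,
                                                window = c(237, 305)),
                         morphometry_model = list(
                           F = list(intercept = 0.3, slope = 0.06,
                                    chord_mean = 47, chord_sd = 1.5),
                           M = list(intercept = 0.5, slope = 0.055,
                                    chord_mean = 42, chord_sd = 1.5),
                           fuel_shape = 2, fuel_scale = 0.25),
                         rng_seed = 1L) {
  if (diff(lat_range) <= 0 || diff(lon_range) <= 0)
    stop("lat/lon ranges must be non-degenerate", call. = FALSE)
  assert_positive_scalar(resolution, "resolution")
  for (nm in c("resid_sd")) assert_nonneg(precip_model[[nm]], nm)
  assert_nonneg(tissue_model$site_sd, "tissue site_sd")
  assert_nonneg(phenology_model$resid_sd, "phenology resid_sd")
  if (diff(mask_lat_range) <= 0)
    stop("mask_lat_range must be non-degenerate", call. = FALSE)
  structure(list(lat_range = lat_range, lon_range = lon_range,
                 resolution = resolution, mask_lat_range = mask_lat_range,
                 precip_model = precip_model, temp_model = temp_model,
                 elev_model = elev_model, tissue_model = tissue_model,
                 phenology_model = phenology_model,
                 morphometry_model = morphometry_model,
                 rng_seed = as.integer(rng_seed)),
            class = "world_config")
}

assert_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop(sprintf("`%s` must be a nonnegative finite scalar", name),
         call. = FALSE)
  invisible(TRUE)
}

# Separable Gaussian smoothing of a matrix with edge renormalization,
# so the smoothed white-noise field keeps unit-ish scale near borders.
smooth_matrix <- function(m, sigma_cells = 3) {
  half <- max(1L, ceiling(3 * sigma_cells))
  k <- stats::dnorm(seq(-half, half), sd = sigma_cells)
  k <- k / sum(k)
  conv_cols <- function(x) {
    nr <- nrow(x)
    apply(x, 2L, function(col) {
      padded <- c(rep(col[1], half), col, rep(col[nr], half))
      out <- stats::filter(padded, k, sides = 2)
      out[(half + 1):(half + nr)]
    })
  }
  t(conv_cols(t(conv_cols(m))))
}

#' Generate the synthetic world: covariates, truth isoscape, range mask
#'
#' Emits the four covariate grids the isoscape regression consumes
#' (temperature, elevation, latitude, longitude), the true precipitation
#' d2H surface built as the configured linear combination of those
#' covariates plus iid Gaussian noise, and the species range mask (a
#' latitude band by default).  Elevation is a smoothed Gaussian random
#' field so the covariate matrix is full rank; temperature carries a smooth
#' latitudinal trend plus a smoothed noise field.
#'
#' @param config a [world_config()].
#' @return list with `covariates` (named list of `iso_raster`:
#'   `temperature`, `elevation`, `latitude`, `longitude`),
#'   `precip_truth` (`iso_raster`, permil), `mask` (`iso_range_mask`),
#'   and `config`.
#' @export
make_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  withr::with_seed(derive_seed(config$rng_seed, "world"), {
    nr <- round(diff(config$lat_range) / config$resolution)
    nc <- round(diff(config$lon_range) / config$resolution)
    template <- iso_raster(matrix(0, nr, nc),
                           origin_lon = config$lon_range[1],
                           origin_lat = config$lat_range[2],
                           cell_size_lon = config$resolution,
                           cell_size_lat = -config$resolution)
    cg <- coordinate_grids(template)
    latm <- cg$lat$values; lonm <- cg$lon$values

    tm <- config$temp_model
    tnoise <- smooth_matrix(matrix(stats::rnorm(nr * nc), nr, nc))
    tempm <- tm$intercept + tm$lat * latm +
      tm$noise_sd * tnoise / stats::sd(tnoise)

    em <- config$elev_model
    efield <- smooth_matrix(matrix(stats::rnorm(nr * nc), nr, nc))
    elevm <- em$mean + em$sd * efield / stats::sd(efield)
    elevm[elevm < 0] <- 0

    pm <- config$precip_model
    precipm <- pm$intercept + pm$lat * latm + pm$lon * lonm +
      pm$elev * elevm + pm$temp * tempm +
      matrix(stats::rnorm(nr * nc, sd = pm$resid_sd), nr, nc)

    maskm <- (latm >= config$mask_lat_range[1] &
                latm <= config$mask_lat_range[2]) * 1
    list(covariates = list(temperature = raster_like(template, tempm),
                           elevation = raster_like(template, elevm),
                           latitude = cg$lat,
                           longitude = cg$lon),
         precip_truth = raster_like(template, precipm),
         mask = range_mask(raster_like(template, maskm),
                           "synthetic latitudinal breeding range"),
         config = config)
  })
}

# rows/cols of cells inside the range mask
mask_cells <- function(mask) {
  which(mask$grid$values == 1, arr.ind = TRUE)
}

#' Simulate the known-origin calibration populations
#'
#' Places breeding populations at cells inside the range mask, simulates
#' per-bird feather d2H values around the tissue-model transform of the
#' local precipitation value, and reports per-site summaries in the form the
#' calibration step consumes.  The default design is ten populations
#' totalling 186 birds, split as evenly as possible.
#'
#' @param world output of [make_world()].
#' @param n_sites number of breeding populations (>= 3).
#' @param birds_per_site integer vector of per-site sample sizes, recycled
#'   or `NULL` to split `total_birds` evenly.
#' @param total_birds used only when `birds_per_site` is `NULL`.
#' @return data frame with columns `site_id`, `lon`, `lat`, `feather_mean`,
#'   `feather_sd`, `n_birds`, `env_d2h` (the true precipitation value at
#'   the site cell).
#' @export
make_calibration_sites <- function(world, n_sites = 10, birds_per_site = NULL,
                                   total_birds = 186) {
  assert_count(n_sites, "n_sites", min = 3L)
  cells <- mask_cells(world$mask)
  if (n_sites > nrow(cells))
    stop("config error: n_sites exceeds the number of valid range cells",
         call. = FALSE)
  if (is.null(birds_per_site)) {
    base <- as.integer(total_birds %/% n_sites)
    extra <- as.integer(total_birds %% n_sites)
    birds_per_site <- rep(base, n_sites) +
      c(rep(1L, extra), rep(0L, n_sites - extra))
  } else {
    birds_per_site <- rep_len(as.integer(birds_per_site), n_sites)
  }
  if (any(birds_per_site < 1L))
    stop("birds_per_site must be >= 1", call. = FALSE)
  tmod <- world$config$tissue_model
  withr::with_seed(derive_seed(world$config$rng_seed, "calibration_sites"), {
    pick <- cells[sample.int(nrow(cells), n_sites), , drop = FALSE]
    out <- lapply(seq_len(n_sites), function(i) {
      rc <- pick[i, ]
      ctr <- cell_center(world$precip_truth, rc[1], rc[2])
      env <- world$precip_truth$values[rc[1], rc[2]]
      feathers <- tmod$intercept + tmod$slope * env +
        stats::rnorm(birds_per_site[i], sd = tmod$site_sd)
      sdv <- if (birds_per_site[i] > 1L) stats::sd(feathers) else 0
      data.frame(site_id = sprintf("S%02d", i),
                 lon = unname(ctr["lon"]), lat = unname(ctr["lat"]),
                 feather_mean = mean(feathers), feather_sd = sdv,
                 n_birds = birds_per_site[i], env_d2h = env)
    })
    out <- do.call(rbind, out)
    if (any(out$n_birds == 1L))
      warning("site(s) with a single bird report feather_sd = 0: ",
              paste(out$site_id[out$n_birds == 1L], collapse = ", "),
              call. = FALSE)
    out
  })
}

#' Simulate a migrant cohort with known natal origins
#'
#' Natal cells are drawn uniformly from the range mask.  Arrival ordinal
#' day follows the configured phenology (intercept + slope x natal latitude
#' + noise), with out-of-window draws redrawn rather than truncated so the
#' arrival-latitude slope stays interpretable.  Feather d2H is the tissue
#' transform of the true precipitation value at the natal cell plus
#' within-site noise.  Mass is sex-specific fat-free mass (linear in wing
#' chord) plus a nonnegative gamma fuel load.
#'
#' @param world output of [make_world()].
#' @param per_year named integer vector, year -> number of birds (split
#'   evenly between sexes).  Default mirrors a 25-per-sex-per-year,
#'   three-season design (n = 150).
#' @return data frame of migrants; columns `natal_lat`, `natal_lon` are the
#'   ground truth and must be withheld from the assignment pipeline
#'   (see [migrant_table()] / [truth_table()]).
#' @export
make_migrants <- function(world,
                          per_year = c("2010" = 50, "2011" = 50, "2014" = 50)) {
  if (any(per_year <= 0)) stop("per-year counts must be positive", call. = FALSE)
  cfg <- world$config
  cells <- mask_cells(world$mask)
  ph <- cfg$phenology_model
  tmod <- cfg$tissue_model
  mm <- cfg$morphometry_model
  withr::with_seed(derive_seed(cfg$rng_seed, "migrants"), {
    rows <- list()
    for (yi in seq_along(per_year)) {
      year <- as.integer(names(per_year)[yi])
      n <- per_year[[yi]]
      sexes <- rep(c("F", "M"), length.out = n)
      idx <- cells[sample.int(nrow(cells), n, replace = TRUE), , drop = FALSE]
      ctr <- cell_center(world$precip_truth, idx[, 1], idx[, 2])
      natal_lat <- ctr[, "lat"]; natal_lon <- ctr[, "lon"]
      env <- world$precip_truth$values[idx]
      feather <- tmod$intercept + tmod$slope * env +
        stats::rnorm(n, sd = tmod$site_sd)
      day <- ph$intercept + ph$slope * natal_lat + stats::rnorm(n, sd = ph$resid_sd)
      # redraw out-of-window arrivals (up to a safety cap) instead of clamping
      for (tries in seq_len(200)) {
        bad <- day < ph$window[1] | day > ph$window[2]
        if (!any(bad)) break
        day[bad] <- ph$intercept + ph$slope * natal_lat[bad] +
          stats::rnorm(sum(bad), sd = ph$resid_sd)
      }
      day <- pmin(pmax(round(day), ph$window[1]), ph$window[2])
      chord <- fuel <- ffm <- numeric(n)
      for (s in c("F", "M")) {
        is_s <- sexes == s
        chord[is_s] <- stats::rnorm(sum(is_s), mm[[s]]$chord_mean,
                                    mm[[s]]$chord_sd)
        ffm[is_s] <- mm[[s]]$intercept + mm[[s]]$slope * chord[is_s]
      }
      fuel <- stats::rgamma(n, shape = mm$fuel_shape, scale = mm$fuel_scale)
      rows[[yi]] <- data.frame(
        bird_id = sprintf("%d_%03d", year, seq_len(n)),
        sex = sexes, year = year,
        capture_date = as.Date(day - 1, origin = paste0(year, "-01-01")),
        ordinal_day = as.integer(day),
        mass_g = ffm + fuel,
        wing_chord_mm = chord,
        feather_d2h = feather,
        natal_lat = natal_lat, natal_lon = natal_lon)
    }
    do.call(rbind, rows)
  })
}

#' Pipeline-visible migrant table (ground truth withheld)
#'
#' @param migrants output of [make_migrants()].
#' @return the same data frame without the `natal_lat`/`natal_lon` columns.
#' @export
migrant_table <- function(migrants) {
  migrants[, setdiff(names(migrants), c("natal_lat", "natal_lon")),
           drop = FALSE]
}

#' Ground-truth natal locations of a simulated cohort
#'
#' @param migrants output of [make_migrants()].
#' @return data frame `bird_id`, `natal_lat`, `natal_lon` — for validation
#'   only, never an input to the assignment pipeline.
#' @export
truth_table <- function(migrants) {
  migrants[, c("bird_id", "natal_lat", "natal_lon"), drop = FALSE]
}
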