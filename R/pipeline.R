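#' Pipeline run configuration
#'
#' Collects every stage parameter with defaults matching the study
#' procedure: 1000 bootstrap replicates for the rescaling function, the
#' top 10% of cells resampled to 100 values for each centroid, a 0.05
#' significance level, and a simulated cohort of 25 birds per sex per year
#' over three seasons.
#'
#' @param outdir output directory (created if missing).
#' @param world a [world_config()] describing the synthetic study system.
#' @param per_year named vector, year -> cohort size (split between
#'   sexes).
#' @param n_sites,total_calibration_birds calibration design (ten
#'   populations, 186 birds by default).
#' @param n_boot bootstrap replicates for [bootstrap_rescale()].
#' @param top_fraction,n_resample centroid parameters (see
#'   [centroid_top_fraction()]).
#' @param alpha significance level for the temporal model.
#' @param seed master seed; all stage seeds derive from it.
#' @param write_surfaces also write each bird's probability surface as an
#'   ASCII grid (off by default; 150 grids).
#' @return an object of class `run_config`.
#' @export
pipeline_config <- function(outdir = "isomigrate_run",
                            world = world_config(),
                            per_year = c("2010" = 50, "2011" = 50,
                                         "2014" = 50),
                            n_sites = 10,
                            total_calibration_birds = 186,
                            n_boot = 1000,
                            top_fraction = 0.10,
                            n_resample = 100,
                            alpha = 0.05,
                            seed = 1L,
                            write_surfaces = FALSE) {
  stopifnot(inherits(world, "world_config"))
  assert_count(n_boot, "n_boot", min = 2L)
  assert_count(n_resample, "n_resample")
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must lie in (0, 1]", call. = FALSE)
  structure(list(outdir = outdir, world = world, per_year = per_year,
                 n_sites = n_sites,
                 total_calibration_birds = total_calibration_birds,
                 n_boot = n_boot, top_fraction = top_fraction,
                 n_resample = n_resample, alpha = alpha,
                 seed = as.integer(seed), write_surfaces = write_surfaces),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the `world`
#' key holds [world_config()] arguments.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config error: file not found: %s", path), call. = FALSE)
  y <- yaml::read_yaml(path)
  wargs <- y$world
  y$world <- if (is.null(wargs)) world_config() else do.call(world_config, wargs)
  if (!is.null(y$per_year)) y$per_year <- unlist(y$per_year)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop(sprintf("config error: unknown field(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  do.call(pipeline_config, y)
}

write_csv_ <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  path
}

#' Run the full assignment pipeline
#'
#' Executes simulate -> isoscape -> calibrate -> assign -> morphometrics
#' -> temporal fit, writing every intermediate artifact under
#' `config$outdir` and a JSON manifest (parameter values, derived stage
#' seeds, output checksums, stage timings, and the final migration-pattern
#' classification) sufficient to reproduce the run bit-identically.
#'
#' @param config a [pipeline_config()] or path to a YAML config.
#' @return invisibly, a list with the in-memory stage results
#'   (`world`, `sites`, `migrants`, `isoscape`, `rescale`, `assignment`,
#'   `augmented`, `temporal_fit`, `classification`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  timings <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  # -- simulate ---------------------------------------------------------
  wcfg <- config$world
  wcfg$rng_seed <- derive_seed(config$seed, "simulate")
  world <- stage("simulate", {
    w <- make_world(wcfg)
    for (nm in names(w$covariates))
      write_raster(w$covariates[[nm]], out(paste0("covariate_", nm, ".asc")))
    write_raster(w$precip_truth, out("precip_d2h.asc"))
    write_raster(w$mask$grid, out("range_mask.asc"))
    w
  })
  sites <- stage("calibration_sites", {
    s <- suppressWarnings(
      make_calibration_sites(world, n_sites = config$n_sites,
                             total_birds = config$total_calibration_birds))
    write_csv_(s, out("calibration_sites.csv"))
    s
  })
  migrants_full <- stage("migrants", {
    m <- make_migrants(world, per_year = config$per_year)
    write_csv_(migrant_table(m), out("migrants.csv"))
    write_csv_(truth_table(m), out("truth.csv"))
    m
  })
  migrants <- migrant_table(migrants_full)

  # -- isoscape ---------------------------------------------------------
  iso <- stage("isoscape", {
    model <- fit_isoscape(world$precip_truth, world$covariates)
    surf <- predict_isoscape(model, world$covariates)
    write_isoscape_model(model, out("isoscape_model.txt"))
    write_raster(surf$mean, out("isoscape_mean.asc"))
    write_raster(surf$se, out("isoscape_se.asc"))
    list(model = model, surfaces = surf)
  })

  # -- calibrate --------------------------------------------------------
  rescale <- stage("calibrate", {
    sites$env_d2h <- extract_at_sites(iso$surfaces$mean, sites$lon, sites$lat)
    sites$env_sd <- extract_at_sites(iso$surfaces$se, sites$lon, sites$lat)
    m <- bootstrap_rescale(sites, n_boot = config$n_boot,
                           seed = derive_seed(config$seed, "calibrate"))
    write_rescale_model(m, out("rescale_model.txt"))
    m
  })
  feather <- stage("convert", {
    fs <- convert_isoscape(iso$surfaces$mean, iso$surfaces$se, rescale)
    write_raster(fs$feather, out("feather_isoscape.asc"))
    write_raster(fs$feather_sd, out("feather_isoscape_sd.asc"))
    fs
  })

  # -- assign -----------------------------------------------------------
  assignment <- stage("assign", {
    a <- assign_cohort(migrants, feather$feather, feather$feather_sd,
                       world$mask, top_fraction = config$top_fraction,
                       n_resample = config$n_resample,
                       seed = derive_seed(config$seed, "assign"))
    write_csv_(a$centroids, out("centroids.csv"))
    if (config$write_surfaces)
      for (id in names(a$surfaces))
        write_raster(a$surfaces[[id]]$probs, out(paste0(id, "_assign.asc")))
    a
  })

  # -- morphometrics + temporal model -----------------------------------
  augmented <- stage("morphometrics", {
    mm <- config$world$morphometry_model
    ffm <- fat_free_model(list(F = mm$F[c("intercept", "slope")],
                               M = mm$M[c("intercept", "slope")]),
                          provenance = "synthetic ground-truth coefficients")
    aug <- augment_morphometrics(migrants, ffm)
    aug <- merge(aug, assignment$centroids[, c("bird_id", "lat", "lon")],
                 by = "bird_id", sort = TRUE)
    names(aug)[names(aug) == "lat"] <- "centroid_lat"
    names(aug)[names(aug) == "lon"] <- "centroid_lon"
    aug <- aug[order(aug$bird_id), ]
    write_csv_(aug, out("migrants_augmented.csv"))
    aug
  })
  fit <- stage("temporal_fit", {
    rho <- screen_predictors(augmented)
    f <- fit_latitude_model(augmented, alpha = config$alpha)
    report <- list(n = f$n, alpha = config$alpha,
                   spearman_screen = as.data.frame(rho),
                   terms = f$terms, year_variance = f$year_variance,
                   arrival_direction = f$direction_of_arrival_effect,
                   classification = classify_pattern(f))
    jsonlite::write_json(report, out("temporal_fit.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    f
  })
  classification <- classify_pattern(fit)

  # -- manifest ---------------------------------------------------------
  outputs <- sort(list.files(config$outdir, full.names = TRUE))
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("isomigrate")),
    master_seed = config$seed,
    stage_seeds = list(simulate = wcfg$rng_seed,
                       calibrate = derive_seed(config$seed, "calibrate"),
                       assign = derive_seed(config$seed, "assign")),
    parameters = list(n_boot = config$n_boot,
                      top_fraction = config$top_fraction,
                      n_resample = config$n_resample,
                      alpha = config$alpha,
                      per_year = as.list(config$per_year),
                      n_sites = config$n_sites,
                      total_calibration_birds = config$total_calibration_birds),
    classification = classification,
    outputs = stats::setNames(as.list(tools::md5sum(outputs)),
                              basename(outputs)),
    timings_s = as.list(timings))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(world = world, sites = sites, migrants = migrants_full,
                 isoscape = iso, rescale = rescale, feather = feather,
                 assignment = assignment, augmented = augmented,
                 temporal_fit = fit, classification = classification,
                 manifest = manifest))
}
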