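#' Bootstrap the precipitation-to-feather rescaling function
#'
#' The rescaling function maps environmental (precipitation) d2H to feather
#' d2H using known-origin breeding populations.  Each of `n_boot` replicates
#' draws one feather value per site from Normal(feather_mean, feather_sd)
#' and one environmental value from Normal(env_d2h, env_sd) — `env_sd` is
#' the isoscape prediction SE at the site when available, 0 otherwise —
#' then fits a simple linear regression of feather on environment.  The
#' returned model carries the empirical mean and SD of the intercept, slope
#' and residual SD across replicates.
#'
#' Sites with a single bird (feather_sd = 0) contribute their mean with no
#' feather-side noise; a warning notes them.
#'
#' @param sites data frame with columns `site_id`, `feather_mean`,
#'   `feather_sd`, `env_d2h` and optionally `env_sd` (permil).
#' @param n_boot number of bootstrap replicates (>= 2; the study default
#'   is 1000).
#' @param seed integer seed; results are bit-reproducible under a fixed
#'   seed.
#' @param weight_by_n weight each site's contribution to the per-replicate
#'   regression by its bird count (off by default: plain OLS).
#' @return an object of class `rescale_model` with fields
#'   `intercept_mean`, `slope_mean`, `intercept_sd`, `slope_sd`,
#'   `resid_sd_mean`, `n_boot`, `seed`.
#' @export
bootstrap_rescale <- function(sites, n_boot = 1000, seed = 1L,
                              weight_by_n = FALSE) {
  assert_count(n_boot, "n_boot", min = 2L)
  req <- c("feather_mean", "feather_sd", "env_d2h")
  if (!all(req %in% names(sites)))
    stop("sites table must have columns feather_mean, feather_sd, env_d2h",
         call. = FALSE)
  n_sites <- nrow(sites)
  if (n_sites < 3L)
    stop("insufficient data: at least 3 calibration sites required",
         call. = FALSE)
  if (length(unique(sites$env_d2h)) < 2L)
    stop("degenerate design: all sites share the same environmental d2h",
         call. = FALSE)
  if (any(sites$feather_sd < 0))
    stop("feather_sd must be nonnegative", call. = FALSE)
  if (any(sites$feather_sd == 0))
    warning("site(s) with feather_sd = 0 contribute a fixed mean: ",
            paste(sites$site_id[sites$feather_sd == 0], collapse = ", "),
            call. = FALSE)
  env_sd <- if ("env_sd" %in% names(sites)) sites$env_sd else rep(0, n_sites)
  if (any(!is.finite(env_sd) | env_sd < 0))
    stop("env_sd must be finite and nonnegative", call. = FALSE)
  coefs <- matrix(NA_real_, n_boot, 3L,
                  dimnames = list(NULL, c("intercept", "slope", "resid_sd")))
  if (weight_by_n && !"n_birds" %in% names(sites))
    stop("weight_by_n requires an n_birds column", call. = FALSE)
  sw <- if (weight_by_n) sqrt(sites$n_birds) else rep(1, n_sites)
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(n_boot)) {
      fe <- stats::rnorm(n_sites, sites$feather_mean, sites$feather_sd)
      en <- stats::rnorm(n_sites, sites$env_d2h, env_sd)
      f <- stats::.lm.fit(cbind(1, en) * sw, fe * sw)
      rss <- sum((f$residuals / sw)^2)
      coefs[b, ] <- c(f$coefficients[1], f$coefficients[2],
                      sqrt(rss / (n_sites - 2L)))
    }
  })
  structure(list(intercept_mean = mean(coefs[, "intercept"]),
                 slope_mean = mean(coefs[, "slope"]),
                 intercept_sd = stats::sd(coefs[, "intercept"]),
                 slope_sd = stats::sd(coefs[, "slope"]),
                 resid_sd_mean = mean(coefs[, "resid_sd"]),
                 n_boot = as.integer(n_boot),
                 seed = as.integer(seed)),
            class = "rescale_model")
}

#' @export
print.rescale_model <- function(x, ...) {
  cat(sprintf(paste0("<rescale_model> feather = %.3f + %.4f x precip ",
                     "(%d bootstrap replicates)\n"),
              x$intercept_mean, x$slope_mean, x$n_boot))
  cat(sprintf("  intercept SD %.3f, slope SD %.4f, mean residual SD %.3f permil\n",
              x$intercept_sd, x$slope_sd, x$resid_sd_mean))
  invisible(x)
}

#' Convert the precipitation isoscape to a feather isoscape
#'
#' Applies the bootstrap rescaling cellwise:
#' `feather = intercept_mean + slope_mean * precip`.  The accompanying SD
#' surface combines, in quadrature (independence assumed), the rescaling
#' uncertainty — intercept SD, slope SD scaled by the absolute
#' precipitation value, and the mean residual SD — with the isoscape
#' prediction SE scaled by the absolute slope:
#' `sd^2 = intercept_sd^2 + (slope_sd*|precip|)^2 + resid_sd_mean^2 +
#' (slope_mean*precip_se)^2`.
#'
#' @param precip_surface `iso_raster`, precipitation d2H mean (permil).
#' @param precip_se_surface `iso_raster` of the isoscape prediction SE, or
#'   `NULL` for zero.
#' @param model a `rescale_model`.
#' @return list of two `iso_raster`s: `feather` (permil) and `feather_sd`
#'   (permil).
#' @export
convert_isoscape <- function(precip_surface, precip_se_surface, model) {
  stopifnot(inherits(precip_surface, "iso_raster"),
            inherits(model, "rescale_model"))
  if (is.null(precip_se_surface))
    precip_se_surface <- raster_like(precip_surface,
                                     matrix(0, precip_surface$n_rows,
                                            precip_surface$n_cols))
  stop_if_misaligned(precip_surface, precip_se_surface,
                     "precipitation mean and SE surfaces")
  p <- precip_surface$values
  se <- precip_se_surface$values
  feather <- model$intercept_mean + model$slope_mean * p
  fsd <- sqrt(model$intercept_sd^2 + (model$slope_sd * abs(p))^2 +
                model$resid_sd_mean^2 + (model$slope_mean * se)^2)
  fsd[is.na(p) | is.na(se)] <- NA_real_
  feather[is.na(se)] <- NA_real_
  list(feather = raster_like(precip_surface, feather),
       feather_sd = raster_like(precip_surface, fsd))
}

#' Read / write calibration-site tables
#'
#' CSV with columns `site_id, lon, lat, feather_mean, feather_sd, n_birds`
#' and optionally `env_d2h`, `env_sd`.
#'
#' @param path CSV path.
#' @return data frame of calibration sites.
#' @export
read_calibration_sites <- function(path) {
  sites <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("site_id", "lon", "lat", "feather_mean", "feather_sd", "n_birds")
  missing <- setdiff(req, names(sites))
  if (length(missing))
    stop(sprintf("calibration CSV missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  sites
}

#' Serialize a rescale model to a plain-text key/value file
#'
#' Records the quadrature variance-combination convention alongside the
#' coefficients so downstream users can audit the SD surface.
#'
#' @param model a `rescale_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rescale_model <- function(model, path) {
  stopifnot(inherits(model, "rescale_model"))
  writeLines(c(sprintf("intercept_mean %.17g", model$intercept_mean),
               sprintf("slope_mean %.17g", model$slope_mean),
               sprintf("intercept_sd %.17g", model$intercept_sd),
               sprintf("slope_sd %.17g", model$slope_sd),
               sprintf("resid_sd_mean %.17g", model$resid_sd_mean),
               sprintf("n_boot %d", model$n_boot),
               sprintf("seed %d", model$seed),
               "variance_combination quadrature"),
             path)
  invisible(path)
}
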