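#' Fit the multiple-linear-regression precipitation isoscape
#'
#' Regresses the precipitation d2H grid on any number of aligned covariate
#' grids (the default study design uses temperature, elevation, latitude
#' and longitude) over the valid — optionally range-masked — cells, by
#' ordinary least squares.
#'
#' @param precip_d2h `iso_raster` of precipitation d2H (permil).
#' @param covariates named list of aligned covariate `iso_raster`s.
#' @param mask optional `iso_range_mask` restricting the cells used in the
#'   fit; `NULL` fits on all jointly valid cells.
#' @return an object of class `isoscape_model`: the underlying `lm` fit
#'   plus `coefficients`, `coefficient_ses`, `residual_sd`, `r_squared`,
#'   `n_cells_fit` and the covariate names.
#' @export
fit_isoscape <- function(precip_d2h, covariates, mask = NULL) {
  stopifnot(inherits(precip_d2h, "iso_raster"), is.list(covariates),
            length(covariates) >= 1L)
  if (is.null(names(covariates)) || any(!nzchar(names(covariates))))
    names(covariates) <- paste0("x", seq_along(covariates))
  for (nm in names(covariates))
    stop_if_misaligned(precip_d2h, covariates[[nm]],
                       sprintf("precipitation grid and covariate '%s'", nm))
  y <- as.vector(precip_d2h$values)
  X <- vapply(covariates, function(g) as.vector(g$values), numeric(length(y)))
  keep <- is.finite(y) & apply(is.finite(X), 1L, all)
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "iso_range_mask"))
    stop_if_misaligned(precip_d2h, mask$grid, "precipitation grid and mask")
    keep <- keep & !is.na(as.vector(mask$grid$values)) &
      as.vector(mask$grid$values) == 1
  }
  p <- length(covariates)
  if (sum(keep) < p + 2L)
    stop(sprintf("insufficient data: %d valid cells for %d covariates",
                 sum(keep), p), call. = FALSE)
  dat <- data.frame(.y = y[keep], X[keep, , drop = FALSE])
  names(dat) <- c(".y", names(covariates))
  qrX <- qr(cbind(1, X[keep, , drop = FALSE]))
  if (qrX$rank < p + 1L) {
    dropped <- names(covariates)[qrX$pivot[seq(qrX$rank + 1L, p + 1L)] - 1L]
    stop(sprintf("singular design: collinear covariate(s): %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  fit <- stats::lm(.y ~ ., data = dat)
  # noiseless fixtures legitimately fit perfectly; the usual lm caution
  # about that is noise here
  sm <- suppressWarnings(summary(fit))
  structure(list(fit = fit,
                 covariate_names = names(covariates),
                 coefficients = stats::coef(fit),
                 coefficient_ses = sm$coefficients[, "Std. Error"],
                 residual_sd = sm$sigma,
                 r_squared = sm$r.squared,
                 n_cells_fit = sum(keep)),
            class = "isoscape_model")
}

#' @export
print.isoscape_model <- function(x, ...) {
  cat(sprintf("<isoscape_model> %d covariates, %d cells, R^2 = %.4f, residual SD = %.3f permil\n",
              length(x$covariate_names), x$n_cells_fit, x$r_squared,
              x$residual_sd))
  print(cbind(estimate = x$coefficients, se = x$coefficient_ses))
  invisible(x)
}

#' Predict the isoscape mean and its standard-error surface
#'
#' Cellwise linear prediction from a fitted [fit_isoscape()] model, plus
#' the design-based standard error of the fitted mean at each cell.  Cells
#' where any covariate is nodata are nodata in both outputs.
#'
#' @param model an `isoscape_model`.
#' @param covariates named list of aligned covariate `iso_raster`s matching
#'   the model's covariates.
#' @return list of two `iso_raster`s: `mean` (permil) and `se` (permil).
#' @export
predict_isoscape <- function(model, covariates) {
  stopifnot(inherits(model, "isoscape_model"))
  if (is.null(names(covariates)) || any(!nzchar(names(covariates))))
    names(covariates) <- paste0("x", seq_along(covariates))
  if (!identical(sort(names(covariates)), sort(model$covariate_names)))
    stop("usage error: covariate names do not match the fitted model",
         call. = FALSE)
  template <- covariates[[1]]
  for (nm in names(covariates))
    stop_if_misaligned(template, covariates[[nm]], "covariate grids")
  X <- vapply(covariates[model$covariate_names],
              function(g) as.vector(g$values),
              numeric(template$n_rows * template$n_cols))
  ok <- apply(is.finite(X), 1L, all)
  newdat <- as.data.frame(X[ok, , drop = FALSE])
  names(newdat) <- model$covariate_names
  pr <- stats::predict(model$fit, newdata = newdat, se.fit = TRUE)
  mu <- se <- rep(NA_real_, nrow(X))
  mu[ok] <- pr$fit
  se[ok] <- pr$se.fit
  list(mean = raster_like(template,
                          matrix(mu, template$n_rows, template$n_cols)),
       se = raster_like(template,
                        matrix(se, template$n_rows, template$n_cols)))
}

#' Extract surface values at point locations
#'
#' Containing-cell (cell-center) lookup with no interpolation.
#'
#' @param surface an `iso_raster`.
#' @param lon,lat numeric vectors of site coordinates, decimal degrees.
#' @return numeric vector of cell values, one per site.
#' @export
extract_at_sites <- function(surface, lon, lat) {
  stopifnot(inherits(surface, "iso_raster"), length(lon) == length(lat))
  idx <- cell_index(surface, lon, lat)
  if (is.null(dim(idx))) idx <- matrix(idx, 1L, dimnames = list(NULL, c("row", "col")))
  vals <- surface$values[idx]
  if (any(!is.finite(vals)))
    stop(sprintf("site(s) on nodata cells: %s",
                 paste(which(!is.finite(vals)), collapse = ", ")),
         call. = FALSE)
  vals
}

#' Serialize an isoscape model to a plain-text key/value file
#'
#' @param model an `isoscape_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_isoscape_model <- function(model, path) {
  stopifnot(inherits(model, "isoscape_model"))
  kv <- c(sprintf("covariates %s", paste(model$covariate_names, collapse = ",")),
          sprintf("coef_%s %.17g",
                  c("intercept", model$covariate_names), model$coefficients),
          sprintf("se_%s %.17g",
                  c("intercept", model$covariate_names), model$coefficient_ses),
          sprintf("residual_sd %.17g", model$residual_sd),
          sprintf("r_squared %.17g", model$r_squared),
          sprintf("n_cells_fit %d", model$n_cells_fit))
  writeLines(kv, path)
  invisible(path)
}
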