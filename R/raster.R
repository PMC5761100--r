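#' Georeferenced raster grid
#'
#' `iso_raster()` builds the in-memory grid object used throughout the
#' package: the precipitation and feather isoscapes, their SD surfaces,
#' per-bird assignment probability surfaces, and range masks are all
#' `iso_raster` objects.  The grid uses cell-center value semantics with the
#' origin stored as the *outer corner* of the cell at row 1, column 1 (the
#' ESRI ASCII grid convention).  Rows run north to south by default, so
#' `cell_size_lat` is negative.
#'
#' @param values numeric matrix of cell values (rows = latitude bands,
#'   columns = longitude bands).  Units depend on role: permil for d2H
#'   surfaces, dimensionless for probabilities and masks.
#' @param origin_lon,origin_lat decimal degrees (WGS84 assumed) of the outer
#'   corner of the cell at row 1, column 1.
#' @param cell_size_lon,cell_size_lat degrees per cell; `cell_size_lat`
#'   should be negative when rows run north to south.
#' @param nodata_value sentinel marking invalid cells; stored cells are
#'   either finite or exactly this sentinel (internally held as `NA`).
#' @return an object of class `iso_raster`.
#' @examples
#' r <- iso_raster(matrix(1:6, 2, 3), origin_lon = 0, origin_lat = 0,
#'                 cell_size_lon = 1, cell_size_lat = -1)
#' cell_center(r, 1, 1)
#' @export
iso_raster <- function(values, origin_lon, origin_lat,
                       cell_size_lon, cell_size_lat,
                       nodata_value = -9999) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (!is.finite(origin_lon) || !is.finite(origin_lat))
    stop("origin coordinates must be finite", call. = FALSE)
  if (cell_size_lon == 0 || cell_size_lat == 0)
    stop("cell sizes must be non-zero", call. = FALSE)
  vals <- values
  vals[vals == nodata_value] <- NA_real_
  if (any(is.infinite(vals)))
    stop("cells must be finite or the nodata sentinel", call. = FALSE)
  structure(
    list(values = vals,
         n_rows = nrow(vals), n_cols = ncol(vals),
         origin_lon = as.numeric(origin_lon),
         origin_lat = as.numeric(origin_lat),
         cell_size_lon = as.numeric(cell_size_lon),
         cell_size_lat = as.numeric(cell_size_lat),
         nodata_value = as.numeric(nodata_value)),
    class = "iso_raster")
}

#' @export
print.iso_raster <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<iso_raster> %d x %d cells, cell size %g x %g deg\n",
              x$n_rows, x$n_cols, x$cell_size_lon, x$cell_size_lat))
  cat(sprintf("  origin (outer corner): lon %g, lat %g\n",
              x$origin_lon, x$origin_lat))
  cat(sprintf("  valid cells: %d / %d", length(v), x$n_rows * x$n_cols))
  if (length(v))
    cat(sprintf("; range [%g, %g]", min(v), max(v)))
  cat("\n")
  invisible(x)
}

#' @export
dim.iso_raster <- function(x) c(x$n_rows, x$n_cols)

#' Test two grids for identical shape and georeferencing
#'
#' @param a,b `iso_raster` objects.
#' @param tol tolerance on georeferencing fields, degrees.
#' @return logical scalar.
#' @export
same_geometry <- function(a, b, tol = 1e-9) {
  stopifnot(inherits(a, "iso_raster"), inherits(b, "iso_raster"))
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$origin_lon - b$origin_lon) < tol &&
    abs(a$origin_lat - b$origin_lat) < tol &&
    abs(a$cell_size_lon - b$cell_size_lon) < tol &&
    abs(a$cell_size_lat - b$cell_size_lat) < tol
}

stop_if_misaligned <- function(a, b, what = "grids") {
  if (!same_geometry(a, b))
    stop(sprintf("alignment error: %s differ in shape or georeferencing", what),
         call. = FALSE)
  invisible(TRUE)
}

#' Geographic coordinate of a cell center
#'
#' Inverse of [cell_index()]; the two round-trip exactly on integer indices.
#'
#' @param grid an `iso_raster`.
#' @param row,col 1-based cell indices.
#' @return named numeric vector `c(lon, lat)` of the cell-center coordinate.
#' @export
cell_center <- function(grid, row, col) {
  stopifnot(inherits(grid, "iso_raster"))
  if (any(row < 1L) || any(row > grid$n_rows) ||
      any(col < 1L) || any(col > grid$n_cols))
    stop("index error: cell indices out of bounds", call. = FALSE)
  row <- unname(row); col <- unname(col)
  lon <- grid$origin_lon + (col - 0.5) * grid$cell_size_lon
  lat <- grid$origin_lat + (row - 0.5) * grid$cell_size_lat
  if (length(row) == 1L && length(col) == 1L) c(lon = lon, lat = lat)
  else cbind(lon = lon, lat = lat)
}

#' Cell index containing a geographic coordinate
#'
#' @param grid an `iso_raster`.
#' @param lon,lat decimal degrees.
#' @return named integer vector `c(row, col)`, or a two-column matrix for
#'   vector input.
#' @export
cell_index <- function(grid, lon, lat) {
  stopifnot(inherits(grid, "iso_raster"))
  col <- floor((lon - grid$origin_lon) / grid$cell_size_lon) + 1L
  row <- floor((lat - grid$origin_lat) / grid$cell_size_lat) + 1L
  bad <- row < 1L | row > grid$n_rows | col < 1L | col > grid$n_cols
  if (any(bad))
    stop(sprintf("index error: %d coordinate(s) outside the grid extent",
                 sum(bad)), call. = FALSE)
  if (length(lon) == 1L) c(row = as.integer(row), col = as.integer(col))
  else cbind(row = as.integer(row), col = as.integer(col))
}

#' Latitude and longitude grids matching a template raster
#'
#' Returns two `iso_raster`s whose cell values are the cell-center latitude
#' and longitude; used as covariates in the isoscape regression.
#'
#' @param grid template `iso_raster`.
#' @return list with elements `lat` and `lon`.
#' @export
coordinate_grids <- function(grid) {
  stopifnot(inherits(grid, "iso_raster"))
  lats <- grid$origin_lat + (seq_len(grid$n_rows) - 0.5) * grid$cell_size_lat
  lons <- grid$origin_lon + (seq_len(grid$n_cols) - 0.5) * grid$cell_size_lon
  latm <- matrix(lats, grid$n_rows, grid$n_cols)
  lonm <- matrix(lons, grid$n_rows, grid$n_cols, byrow = TRUE)
  list(lat = raster_like(grid, latm), lon = raster_like(grid, lonm))
}

#' New raster sharing a template's georeferencing
#'
#' @param grid template `iso_raster`.
#' @param values numeric matrix of the template's shape.
#' @return an `iso_raster`.
#' @export
raster_like <- function(grid, values) {
  stopifnot(inherits(grid, "iso_raster"))
  if (!all(dim(values) == c(grid$n_rows, grid$n_cols)))
    stop("alignment error: values shape does not match template", call. = FALSE)
  out <- grid
  v <- values
  v[is.infinite(v)] <- NA_real_
  out$values <- v
  out
}

#' Species range mask
#'
#' A 0/1 raster restricting assignment surfaces to the species' breeding
#' range.  Validated against any grid it is applied to.
#'
#' @param grid an `iso_raster` whose valid values are all 0 or 1.
#' @param description free-text provenance.
#' @return an object of class `iso_range_mask`.
#' @export
range_mask <- function(grid, description = "") {
  stopifnot(inherits(grid, "iso_raster"))
  v <- grid$values
  ok <- is.na(v) | v == 0 | v == 1
  if (!all(ok))
    stop("mask values must be 0, 1, or nodata", call. = FALSE)
  if (!any(v == 1, na.rm = TRUE))
    stop("mask has no cells equal to 1", call. = FALSE)
  structure(list(grid = grid, description = description),
            class = "iso_range_mask")
}

#' @export
print.iso_range_mask <- function(x, ...) {
  cat(sprintf("<iso_range_mask> %d of %d cells inside range; %s\n",
              sum(x$grid$values == 1, na.rm = TRUE),
              x$grid$n_rows * x$grid$n_cols,
              if (nzchar(x$description)) x$description else "no description"))
  invisible(x)
}

#' Constrain a surface to a range mask
#'
#' Cells where the mask is 0 (or nodata) become nodata; cells where the mask
#' is 1 pass through unchanged.
#'
#' @param surface an `iso_raster`.
#' @param mask an `iso_range_mask` with identical shape and georeferencing.
#' @return masked `iso_raster`.
#' @export
apply_mask <- function(surface, mask) {
  stopifnot(inherits(surface, "iso_raster"), inherits(mask, "iso_range_mask"))
  stop_if_misaligned(surface, mask$grid, "surface and mask")
  v <- surface$values
  keep <- !is.na(mask$grid$values) & mask$grid$values == 1
  v[!keep] <- NA_real_
  raster_like(surface, v)
}

#' Read a gridded surface from disk
#'
#' ESRI ASCII grid is the supported on-disk raster format (plain text,
#' header of `ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value`
#' followed by rows north to south).
#'
#' @param path file path.
#' @param format `"ascii_grid"`.
#' @return an `iso_raster`.
#' @export
read_raster <- function(path, format = "ascii_grid") {
  format <- match.arg(format, c("ascii_grid", "geotiff"))
  if (format == "geotiff")
    stop("usage error: GeoTIFF I/O is not supported in this build; ",
         "use format = \"ascii_grid\"", call. = FALSE)
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (!(key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                     "cellsize", "dx", "dy", "nodata_value"))) break
    hdr[[key]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  for (f in c("ncols", "nrows", "xllcorner", "yllcorner"))
    if (is.null(hdr[[f]]) || is.na(hdr[[f]]))
      stop(sprintf("format error: missing or malformed header field '%s'", f),
           call. = FALSE)
  if (is.null(hdr$cellsize) && (is.null(hdr$dx) || is.null(hdr$dy)))
    stop("format error: missing or malformed header field 'cellsize'",
         call. = FALSE)
  dx <- if (!is.null(hdr$cellsize)) hdr$cellsize else hdr$dx
  dy <- if (!is.null(hdr$cellsize)) hdr$cellsize else hdr$dy
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  body <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(body) != nr * nc)
    stop(sprintf("format error: expected %d values, found %d",
                 nr * nc, length(body)), call. = FALSE)
  vals <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  # ASCII rows run north->south; top-left outer corner is
  # (xllcorner, yllcorner + nrows*dy) with negative lat step
  iso_raster(vals,
             origin_lon = hdr$xllcorner,
             origin_lat = hdr$yllcorner + nr * dy,
             cell_size_lon = dx, cell_size_lat = -dy,
             nodata_value = nodata)
}

#' Write a raster to disk as an ESRI ASCII grid
#'
#' Values are written with full `digits = 17` precision so that a
#' write/read round-trip is bit-exact.  Only grids with north-to-south row
#' order (negative `cell_size_lat`) and square-compatible cell sizes are
#' representable in the single-`cellsize` header form; rectangular cells use
#' the `dx/dy` header variant.
#'
#' @param grid an `iso_raster` with `cell_size_lat < 0`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path) {
  stopifnot(inherits(grid, "iso_raster"))
  if (grid$cell_size_lat >= 0)
    stop("only north-to-south grids (negative cell_size_lat) are writable",
         call. = FALSE)
  dx <- grid$cell_size_lon; dy <- -grid$cell_size_lat
  hdr <- c(sprintf("ncols %d", grid$n_cols),
           sprintf("nrows %d", grid$n_rows),
           sprintf("xllcorner %s", format(grid$origin_lon, digits = 17)),
           sprintf("yllcorner %s",
                   format(grid$origin_lat + grid$n_rows * grid$cell_size_lat,
                          digits = 17)))
  hdr <- c(hdr,
           if (isTRUE(all.equal(dx, dy)))
             sprintf("cellsize %s", format(dx, digits = 17))
           else c(sprintf("dx %s", format(dx, digits = 17)),
                  sprintf("dy %s", format(dy, digits = 17))),
           sprintf("NODATA_value %s", format(grid$nodata_value, digits = 17)))
  v <- grid$values
  v[is.na(v)] <- grid$nodata_value
  rows <- apply(v, 1L, function(r)
    paste(format(r, digits = 17, trim = TRUE), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Summary line for a raster file
#'
#' @param path path to an ASCII grid.
#' @return a one-row data frame of grid metadata (printed as a side effect).
#' @export
raster_info <- function(path) {
  g <- read_raster(path)
  v <- g$values[is.finite(g$values)]
  out <- data.frame(path = path, n_rows = g$n_rows, n_cols = g$n_cols,
                    origin_lon = g$origin_lon, origin_lat = g$origin_lat,
                    cell_size_lon = g$cell_size_lon,
                    cell_size_lat = g$cell_size_lat,
                    n_valid = length(v),
                    min = if (length(v)) min(v) else NA_real_,
                    max = if (length(v)) max(v) else NA_real_)
  print(g)
  invisible(out)
}
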