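# Shared fixtures: small grids and a coarse synthetic world so unit tests
# stay fast; the acceptance tests use the full default configuration.

# simple north-to-south grid with unit cells
toy_grid <- function(values, origin_lon = 0, origin_lat = 0) {
  iso_raster(values, origin_lon = origin_lon, origin_lat = origin_lat,
             cell_size_lon = 1, cell_size_lat = -1)
}

all_ones_mask <- function(grid) {
  range_mask(raster_like(grid, matrix(1, grid$n_rows, grid$n_cols)),
             "all cells")
}

# coarse world (1 degree cells, 30 x 20) for module-level recovery tests
coarse_config <- function(seed = 1L, ...) {
  world_config(resolution = 1, rng_seed = seed, ...)
}

# brute-force assignment oracle: normal density at each enumerated cell,
# renormalized -- independent of the package's log-space path
oracle_assignment <- function(y, mu, sigma) {
  d <- stats::dnorm(y, mu, sigma)
  d / sum(d)
}
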