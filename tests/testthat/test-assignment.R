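test_that("constant surfaces give the uniform distribution over the range", {
  g <- toy_grid(matrix(-80, 4, 5))
  sd <- toy_grid(matrix(10, 4, 5))
  s <- likelihood_surface(-100, g, sd, all_ones_mask(g))
  expect_equal(s$probs$values, matrix(1 / 20, 4, 5), tolerance = 1e-12)
})

test_that("the observation's matching cell attains the maximum probability", {
  g <- toy_grid(matrix(seq(-140, -45, length.out = 20), 4, 5))
  sd <- toy_grid(matrix(3, 4, 5))
  s <- likelihood_surface(-80, g, sd, all_ones_mask(g))
  expect_equal(which.max(s$probs$values), which.min(abs(g$values + 80)))
})

test_that("probabilities match a brute-force density oracle on toy grids", {
  # the stated 3-cell case
  mu3 <- c(-60, -100, -140)
  g <- toy_grid(matrix(mu3, 1, 3))
  sd <- toy_grid(matrix(10, 1, 3))
  s <- likelihood_surface(-100, g, sd, all_ones_mask(g))
  expect_equal(as.vector(s$probs$values), oracle_assignment(-100, mu3, 10),
               tolerance = 1e-12)
  # heterogeneous SDs on a 10-cell grid
  set.seed(12)
  mu <- rnorm(10, -90, 25); sg <- runif(10, 2, 12)
  g10 <- toy_grid(matrix(mu, 2, 5))
  sd10 <- toy_grid(matrix(sg, 2, 5))
  s10 <- likelihood_surface(-85, g10, sd10, all_ones_mask(g10))
  oracle <- oracle_assignment(-85, mu, sg)
  expect_equal(as.vector(s10$probs$values), oracle, tolerance = 1e-12)
})

test_that("masking and degenerate SDs are policed at the input", {
  g <- toy_grid(matrix(-80, 3, 3))
  sd0 <- toy_grid(matrix(0, 3, 3))
  expect_error(likelihood_surface(-80, g, sd0, all_ones_mask(g)),
               "positive SD")
  empty <- matrix(0, 3, 3); empty[1, 1] <- 1
  m <- range_mask(toy_grid(empty))
  mm <- m; mm$grid$values[1, 1] <- NA
  expect_error(likelihood_surface(-80, g, toy_grid(matrix(NA_real_, 3, 3)),
                                  all_ones_mask(g)),
               "empty support")
})

test_that("halving all SDs sharpens the surface mode", {
  g <- toy_grid(matrix(seq(-120, -40, length.out = 25), 5, 5))
  m <- all_ones_mask(g)
  p1 <- likelihood_surface(-75, g, toy_grid(matrix(8, 5, 5)), m)
  p2 <- likelihood_surface(-75, g, toy_grid(matrix(4, 5, 5)), m)
  expect_gt(max(p2$probs$values), max(p1$probs$values))
})

test_that("single-cell support pins the centroid to that cell center", {
  vals <- matrix(NA_real_, 3, 3); vals[2, 2] <- 1
  s <- structure(list(bird_id = "b", probs = toy_grid(vals)),
                 class = "assignment_surface")
  for (seed in c(1, 99)) {
    ctr <- centroid_top_fraction(s, top_fraction = 1, seed = seed)
    expect_equal(c(ctr$lon, ctr$lat), c(1.5, -1.5))
  }
  expect_error(centroid_top_fraction(s, top_fraction = 0), "usage error")
  expect_error(centroid_top_fraction(s, top_fraction = 1.2), "usage error")
})

test_that("symmetric surfaces give a centroid on the axis of symmetry", {
  # probabilities symmetric about the central meridian of a 5-wide grid
  g <- toy_grid(matrix(rep(c(1, 2, 4, 2, 1), each = 4), 4, 5))
  p <- raster_like(g, g$values / sum(g$values))
  s <- structure(list(bird_id = "b", probs = p),
                 class = "assignment_surface")
  ctr <- centroid_top_fraction(s, top_fraction = 1, n_resample = 4000,
                               seed = 5)
  # axis at lon = 2.5; Monte-Carlo SE of the weighted mean ~ 0.02
  expect_lt(abs(ctr$lon - 2.5), 0.06)
})

test_that("centroid converges to the closed-form weighted mean of top cells", {
  probs <- c(0.30, 0.25, 0.10, 0.08, 0.07, 0.06, 0.05, 0.04, 0.03, 0.02)
  g <- toy_grid(matrix(probs, 2, 5))  # column-major fill
  s <- structure(list(bird_id = "b", probs = g),
                 class = "assignment_surface")
  # top 20% of 10 cells = 2 cells: the 0.30 at (1,1) and 0.25 at (2,1)
  ctr <- centroid_top_fraction(s, top_fraction = 0.2, n_resample = 2,
                               seed = 3)
  w <- c(0.30, 0.25) / 0.55
  expect_equal(ctr$lat, w[1] * -0.5 + w[2] * -1.5, tolerance = 1e-12)
  expect_equal(ctr$lon, 0.5, tolerance = 1e-12)
  expect_equal(ctr$n_cells_top, 2)
  # deterministic under seed
  ctr2 <- centroid_top_fraction(s, top_fraction = 0.2, n_resample = 2,
                                seed = 3)
  expect_identical(ctr$lat, ctr2$lat)
})

test_that("cohort assignment matches the single-bird path and collects failures", {
  g <- toy_grid(matrix(seq(-120, -40, length.out = 25), 5, 5))
  sd <- toy_grid(matrix(6, 5, 5))
  m <- all_ones_mask(g)
  birds <- data.frame(bird_id = c("a", "b"), feather_d2h = c(-80, -80))
  res <- assign_cohort(birds, g, sd, m, seed = 11)
  # identical observations give identical surfaces
  expect_identical(res$surfaces[["a"]]$probs$values,
                   res$surfaces[["b"]]$probs$values)
  # cohort path equals the single-bird path with the derived seed
  solo <- likelihood_surface(-80, g, sd, m, bird_id = "a")
  expect_identical(res$surfaces[["a"]]$probs$values, solo$probs$values)
  ctr <- centroid_top_fraction(solo, seed = isomigrate:::derive_seed(11, "a"))
  expect_equal(res$centroids$lat[res$centroids$bird_id == "a"], ctr$lat)
  # a bird with a non-finite feather value fails alone, not the cohort
  birds2 <- rbind(birds, data.frame(bird_id = "c", feather_d2h = NaN))
  expect_warning(res2 <- assign_cohort(birds2, g, sd, m, seed = 11),
                 "failed for 1 bird")
  expect_equal(res2$failed$bird_id, "c")
  expect_equal(nrow(res2$centroids), 2)
})

test_that("surfaces always normalize to unit mass with no leakage off-range", {
  set.seed(42)
  for (i in 1:25) {
    nr <- sample(3:7, 1); nc <- sample(3:7, 1)
    g <- toy_grid(matrix(rnorm(nr * nc, -90, 20), nr, nc))
    sd <- toy_grid(matrix(runif(nr * nc, 1, 10), nr, nc))
    mv <- matrix(rbinom(nr * nc, 1, 0.6), nr, nc)
    if (!any(mv == 1)) mv[1, 1] <- 1
    mask <- range_mask(toy_grid(mv))
    s <- likelihood_surface(rnorm(1, -90, 20), g, sd, mask)
    expect_equal(sum(s$probs$values, na.rm = TRUE), 1, tolerance = 1e-9)
    expect_true(all(is.na(s$probs$values[mv == 0])))
    expect_true(all(s$probs$values[mv == 1] >= 0))
  }
})
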