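test_that("NDVI from bands: symmetry, forced arithmetic, zero denominator", {
  red <- make_raster(matrix(c(0.4, 0.2, 0, 0.1), 2))
  nir <- make_raster(matrix(c(0.4, 0.8, 0, 0.3), 2))
  nd <- ndvi_from_bands(red, nir)
  expect_equal(nd$values[1, 1], 0)
  expect_equal(nd$values[2, 1], 0.6)
  expect_true(is.na(nd$values[1, 2]))
  expect_equal(nd$values[2, 2], 0.5)
  expect_error(ndvi_from_bands(red, make_raster(matrix(1, 3, 3))), "shape")
})

test_that("NDVI is bounded in [-1, 1] for nonnegative reflectances", {
  set.seed(42)
  red <- make_raster(matrix(runif(400), 20))
  nir <- make_raster(matrix(runif(400), 20))
  nd <- ndvi_from_bands(red, nir)
  expect_true(all(nd$values >= -1 & nd$values <= 1, na.rm = TRUE))
})

test_that("EVI: zero numerator, direct evaluation, NDVI correlation", {
  b <- make_raster(matrix(0.05, 1, 1))
  r <- make_raster(matrix(0.1, 1, 1))
  n <- make_raster(matrix(0.5, 1, 1))
  expect_equal(evi_from_bands(b, r, n)$values[1, 1], 1 / 1.725)
  # NIR = Red -> 0 regardless of blue
  expect_equal(
    evi_from_bands(make_raster(matrix(0.9, 1, 1)), r,
                   make_raster(matrix(0.1, 1, 1)))$values[1, 1], 0)
  # bands built from a common vegetation signal: NDVI and EVI co-vary
  set.seed(7)
  v <- matrix(runif(2500), 50)
  red <- make_raster(0.35 - 0.25 * v + matrix(rnorm(2500, 0, 0.01), 50))
  nir <- make_raster(0.2 + 0.5 * v + matrix(rnorm(2500, 0, 0.01), 50))
  blue <- make_raster(matrix(0.08, 50, 50))
  nd <- ndvi_from_bands(red, nir); ev <- evi_from_bands(blue, red, nir)
  expect_gt(cor(as.vector(nd$values), as.vector(ev$values)), 0.9)
})

test_that("vegetation volume layer: arithmetic, empty mask, loop oracle", {
  h <- make_raster(matrix(10, 1, 1), res = 0.5)
  m <- make_raster(matrix(1, 1, 1), res = 0.5)
  expect_equal(veg_volume_layer(h, m)$values[1, 1], 2.5)
  # empty mask -> all nodata, zero total
  m0 <- make_raster(matrix(0, 1, 1), res = 0.5)
  expect_true(is.na(veg_volume_layer(h, m0)$values[1, 1]))
  # random 8x8 vs brute force
  set.seed(1)
  hv <- matrix(runif(64, 0, 30), 8)
  mk <- matrix(rbinom(64, 1, 0.6), 8)
  vol <- veg_volume_layer(make_raster(hv, res = 2), make_raster(mk, res = 2))
  brute <- 0
  for (i in 1:8) for (j in 1:8) if (mk[i, j] == 1) brute <- brute + hv[i, j] * 4
  expect_equal(sum(vol$values, na.rm = TRUE), brute)
  # negative heights clipped with warning
  expect_warning(
    v2 <- veg_volume_layer(make_raster(matrix(c(-1, 2), 1), res = 1),
                           make_raster(matrix(1, 1, 2), res = 1)),
    "clipped")
  expect_equal(v2$values[1, 1], 0)
})

test_that("block aggregation: constants, forced block mean, loop oracle,
           conservation, non-integer ratio", {
  const <- make_raster(matrix(0.3, 12, 12), res = 5)
  expect_equal(as.vector(aggregate_raster(const, 30, "mean")$values),
               rep(0.3, 4))
  blk <- make_raster(matrix(c(1, 3, 2, 4), 2), res = 1)
  expect_equal(aggregate_raster(blk, 2, "mean")$values[1, 1], 2.5)
  set.seed(3)
  big <- make_raster(matrix(rnorm(10000), 100), res = 1)
  agg <- aggregate_raster(big, 10, "sum")
  for (bi in c(1, 4, 10)) for (bj in c(2, 7)) {
    expect_equal(agg$values[bi, bj],
                 sum(big$values[(bi - 1) * 10 + 1:10, (bj - 1) * 10 + 1:10]))
  }
  # sum-aggregation conserves the total (nodata as absent)
  vals <- matrix(rnorm(900), 30)
  vals[sample(900, 100)] <- NA
  r <- make_raster(vals, res = 2)
  expect_equal(sum(aggregate_raster(r, 12, "sum")$values, na.rm = TRUE),
               sum(vals, na.rm = TRUE))
  expect_error(aggregate_raster(r, 5, "mean"), "integer multiple")
  expect_error(aggregate_raster(r, 1, "mean"), ">=")
})

test_that("aggregation: all-nodata blocks stay nodata", {
  v <- matrix(NA_real_, 4, 4); v[1, 1] <- 5
  a <- aggregate_raster(make_raster(v), 2, "mean")
  expect_equal(a$values[1, 1], 5)
  expect_true(all(is.na(a$values[-1])))
})

test_that("buffer mean: constants, single pixel, loop oracle, errors", {
  const <- make_raster(matrix(0.42, 30, 30), res = 1)
  expect_equal(buffer_mean(const, c(15, 15), 7), 0.42)
  r <- make_raster(matrix(1:16, 4), res = 10)
  # point exactly on the centre of cell (row 2, col 3), radius < resolution
  expect_equal(buffer_mean(r, c(25, 25), 4), r$values[2, 3])
  set.seed(11)
  big <- make_raster(matrix(rnorm(2500), 50), res = 2)
  pt <- c(47.3, 51.8)
  expect_equal(buffer_mean(big, pt, 14), oracle_buffer_mean(big, pt, 14))
  expect_error(buffer_mean(big, c(-500, -500), 3), "no cell centres")
  expect_warning(buffer_mean(big, c(1, 1), 10), "beyond the raster")
})

test_that("buffer volume density: nodata as zero, uniform canopy, oracle", {
  allna <- make_raster(matrix(NA_real_, 20, 20), res = 1)
  expect_equal(buffer_volume_density(allna, c(10, 10), 5), 0)
  # 1 m of vegetation on every cell of area a: density 1 m^3/m^2
  unif <- make_raster(matrix(1 * 4, 40, 40), res = 2) # height x area per cell
  expect_equal(buffer_volume_density(unif, c(40, 40), 15), 1)
  set.seed(5)
  v <- matrix(runif(900, 0, 50), 30)
  v[sample(900, 300)] <- NA
  r <- make_raster(v, res = 3)
  pt <- c(44, 46)
  expect_equal(buffer_volume_density(r, pt, 20),
               oracle_buffer_density(r, pt, 20))
})

test_that("buffer extractors match the all-pixel scan on random instances", {
  set.seed(99)
  for (rep in 1:15) {
    res <- sample(c(1, 2, 5), 1)
    n <- sample(15:40, 1)
    v <- matrix(rnorm(n * n), n)
    v[sample(n * n, round(n * n / 5))] <- NA
    r <- make_raster(v, res = res)
    pt <- runif(2, 0.3 * n * res, 0.7 * n * res)
    rad <- runif(1, 1.2 * res, 0.25 * n * res)
    expect_equal(buffer_mean(r, pt, rad, warn_partial = FALSE),
                 oracle_buffer_mean(r, pt, rad))
    expect_equal(buffer_volume_density(r, pt, rad, warn_partial = FALSE),
                 oracle_buffer_density(r, pt, rad))
  }
})

test_that("site buffer table: constant landscape, range shrink on gradients,
           crafted hand-check", {
  const_ndvi <- make_raster(matrix(0.5, 60, 60), res = 10)
  const_vol <- make_raster(matrix(20, 60, 60), res = 10)
  sites <- data.frame(site_id = c("a", "b"), x = c(250, 350), y = c(250, 350))
  bt <- site_buffer_table(sites, const_ndvi, const_vol, radii = c(25, 50))
  expect_equal(length(unique(round(bt$mean_ndvi, 12))), 1)
  expect_equal(length(unique(round(bt$veg_volume_density, 12))), 1)

  # radial gradient: wider buffers average away the extremes
  land <- generate_landscape(landscape_config(grid_size_m = 2000, seed = 4))
  vol <- veg_volume_layer(land$ndsm, land$veg_mask)
  s2 <- place_sites(25, 2000, min_separation_m = 100, margin_m = 420,
                    seed = 5)
  b2 <- suppressWarnings(
    site_buffer_table(s2, land$ndvi, vol, radii = c(25, 100, 400)))
  rng <- tapply(b2$mean_ndvi, b2$radius_m, function(v) diff(range(v)))
  expect_true(rng[["400"]] <= rng[["100"]])
  expect_true(rng[["100"]] <= rng[["25"]] + 1e-9)

  # one site, two radii, hand-computed on a crafted raster
  vals <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3)
  nd <- make_raster(vals, res = 10)
  vl <- make_raster(vals * 100, res = 10) # volumes per cell
  s3 <- data.frame(site_id = "z", x = 15, y = 15)
  b3 <- site_buffer_table(s3, nd, vl, radii = c(5, 12))
  expect_equal(b3$mean_ndvi[b3$radius_m == 5], vals[2, 2])
  inbuf <- c(vals[2, 2], vals[1, 2], vals[3, 2], vals[2, 1], vals[2, 3])
  expect_equal(b3$mean_ndvi[b3$radius_m == 12], mean(inbuf))
  expect_equal(b3$veg_volume_density[b3$radius_m == 12],
               sum(inbuf * 100) / (5 * 100))
  expect_equal(b3$log_veg_volume, log(b3$veg_volume_density))
})

test_that("zero-density sites get the epsilon log rule with a warning", {
  nd <- make_raster(matrix(0.5, 20, 20), res = 1)
  v <- matrix(NA_real_, 20, 20); v[1, 1] <- 8
  vol <- make_raster(v, res = 1)
  sites <- data.frame(site_id = c("veg", "bare"), x = c(2, 15), y = c(18, 5))
  expect_warning(bt <- site_buffer_table(sites, nd, vol, radii = 3,
                                         warn_partial = FALSE),
                 "zero vegetation")
  pos <- bt$veg_volume_density[bt$site_id == "veg"]
  expect_equal(bt$log_veg_volume[bt$site_id == "bare"],
               log(0 + pos * 1e-3))
})

test_that("distance to centre: origin, 3-4-5 triangle, grid oracle", {
  expect_equal(distance_to_centre(cbind(10, 20), c(10, 20)), 0)
  expect_equal(distance_to_centre(cbind(3000, 4000), c(0, 0)), 5000)
  set.seed(2)
  pts <- cbind(runif(30, 0, 100), runif(30, 0, 100))
  ctr <- c(40, 60)
  brute <- apply(pts, 1, function(p) sqrt(sum((p - ctr)^2)))
  expect_equal(distance_to_centre(pts, ctr), brute)
})

test_that("ASCII grid round-trips values, extent and nodata", {
  set.seed(8)
  v <- matrix(rnorm(120), 10)
  v[c(3, 50)] <- NA
  r <- raster_layer(v, xmin = 100, ymax = 400, res = 25)
  f <- tempfile(fileext = ".asc")
  write_ascii_grid(r, f)
  r2 <- read_ascii_grid(f)
  expect_equal(r2$values, r$values)
  expect_equal(r2$xmin, r$xmin)
  expect_equal(r2$ymax, r$ymax)
  expect_equal(r2$res, r$res)
})
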