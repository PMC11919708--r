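test_that("static layers are deterministic and geometrically consistent", {
  a <- gen_static_layers(c(16, 16), 500, seed = 7)
  b <- gen_static_layers(c(16, 16), 500, seed = 7)
  expect_identical(a$depth$values, b$depth$values)
  expect_identical(a$dist_shore$values, b$dist_shore$values)

  # every water cell is below sea level, the land margin above
  expect_true(all(a$depth$values[!a$land] < 0))
  expect_true(all(a$depth$values[a$land] > 0))

  # a water cell 4-adjacent to land is exactly one cell size from shore
  land <- a$land
  found <- FALSE
  for (r in seq_len(nrow(land))) for (cc in seq_len(ncol(land) - 1)) {
    if (!land[r, cc] && land[r, cc + 1]) {
      expect_equal(a$dist_shore$values[r, cc], 500)
      found <- TRUE
      break
    }
  }
  expect_true(found)
  expect_error(gen_static_layers(c(1, 16), 500), "at least 2")
  expect_error(gen_static_layers(c(4, 4), 500), "8 x 8")
})

test_that("slope equals the central finite-difference oracle in degrees", {
  a <- gen_static_layers(c(16, 16), 500, seed = 7)
  d <- a$depth$values
  r <- 8; cc <- 5  # interior water cell
  dzdx <- (d[r, cc + 1] - d[r, cc - 1]) / (2 * 500)
  dzdy <- (d[r + 1, cc] - d[r - 1, cc]) / (2 * 500)
  expect_equal(a$slope$values[r, cc],
               atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi, tolerance = 1e-12)
})

test_that("dynamic layers are reproducible, ranged, and autocorrelated", {
  a <- gen_dynamic_layer(c(20, 20), 500, "2019-06", "sst", seed = 3)
  b <- gen_dynamic_layer(c(20, 20), 500, "2019-06", "sst", seed = 3)
  expect_identical(a$values, b$values)
  expect_false(identical(
    a$values, gen_dynamic_layer(c(20, 20), 500, "2019-07", "sst",
                                seed = 3)$values))
  expect_true(all(a$values >= -1 & a$values <= 14))
  chl <- gen_dynamic_layer(c(20, 20), 500, "2019-06", "chlorophyll_a",
                           seed = 3)
  expect_true(all(chl$values >= 0.05 & chl$values <= 20))
  expect_error(gen_dynamic_layer(c(20, 20), 500, "2019-06", "wind"),
               "unknown layer_name")
  expect_error(gen_dynamic_layer(c(20, 20), 500, "June", "sst"), "YYYY-MM")

  # lag-1 spatial neighbor correlation beats that of a random permutation
  v <- a$values
  lag_cor <- function(m) stats::cor(as.vector(m[, -1]),
                                    as.vector(m[, -ncol(m)]))
  set.seed(42)
  perm <- matrix(sample(v), nrow(v), ncol(v))
  expect_gt(lag_cor(v), lag_cor(perm))

  # smoothing radius 0 degenerates to unsmoothed noise (no autocorrelation
  # beyond chance): the smoothed field is strictly more correlated
  raw <- gen_dynamic_layer(c(20, 20), 500, "2019-06", "sst", seed = 3,
                           smooth_radius = 0)
  expect_gt(lag_cor(a$values), lag_cor(raw$values))
})

test_that("true suitability is the inverse logit of the covariates", {
  stk <- tiny_world(5)$stack
  zero <- make_true_suitability(stk, c(sst = 0), intercept = 0)
  ok <- !zero$surface$nodata_mask
  expect_true(all(zero$surface$values[ok] == 0.5))

  sat <- make_true_suitability(stk, c(sst = 0), intercept = 20)
  expect_true(all(sat$surface$values[ok] > 0.999))

  # single positive coefficient on depth: suitability ranks = depth ranks
  dep <- make_true_suitability(stk, c(depth = 1), intercept = 0)
  d <- stk$layers$depth$values[ok]
  expect_identical(order(dep$surface$values[ok]), order(d))

  expect_error(make_true_suitability(stk, c(wind = 1)), "unknown layers")
})

test_that("tours respect effort arithmetic and stay inside the grid", {
  w <- tiny_world(9)
  grid <- w$static$depth
  harbor <- c(grid_extent(grid)["xmax"] - 3000,
              grid_extent(grid)["ymax"] / 2)

  t0 <- simulate_tours(harbor, grid, "2019-06", n_tours = 0, seed = 1)
  expect_length(t0$tracklines, 0)
  expect_equal(t0$effort$effort_hours, 0)
  expect_equal(t0$effort$search_days, 0L)

  t40 <- simulate_tours(harbor, grid, "2019-06", n_tours = 40, seed = 1)
  expect_equal(t40$effort$effort_hours, 120)
  ext <- grid_extent(grid)
  for (tl in t40$tracklines) {
    expect_true(all(tl$vertices[, 1] >= ext["xmin"] &
                      tl$vertices[, 1] <= ext["xmax"]))
    expect_true(all(tl$vertices[, 2] >= ext["ymin"] &
                      tl$vertices[, 2] <= ext["ymax"]))
    expect_gte(nrow(tl$vertices), 2)
  }

  expect_error(simulate_tours(c(-1e6, 0), grid, "2019-06", 1), "outside")
  expect_error(simulate_tours(harbor, grid, "2019-06", -1), "non-negative")
})

test_that("rate-driven tours average about 1.43 per day over a month", {
  w <- tiny_world(9)
  harbor <- c(grid_extent(w$static$depth)["xmax"] - 3000,
              grid_extent(w$static$depth)["ymax"] / 2)
  t <- simulate_tours(harbor, w$static$depth, "2019-06", n_tours = NULL,
                      seed = 4)
  mean_per_day <- length(t$tour_days) / 28
  expect_lt(abs(mean_per_day - 1.43), 0.3)
  expect_equal(t$effort$search_days, length(unique(t$tour_days)))
})

test_that("presence sampling reflects suitability and observation effort", {
  w <- tiny_world(11)
  expect_equal(nrow(sample_presences(w$truth, w$tours$tracklines, 0)), 0)

  p <- sample_presences(w$truth, w$tours$tracklines, 80, seed = 2,
                        month_id = "2019-06")
  expect_equal(nrow(p), 80)
  # all points inside the extent and off land
  rc <- point_to_cell(w$truth$surface, p$x, p$y)
  expect_false(anyNA(rc))
  expect_true(all(!w$truth$surface$nodata_mask[rc]))

  # uniform suitability: sampled density tracks trackline density
  unif <- make_true_suitability(w$stack, c(sst = 0), intercept = 0)
  pu <- sample_presences(unif, w$tours$tracklines, 400, seed = 3,
                         month_id = "2019-06")
  rcu <- point_to_cell(unif$surface, pu$x, pu$y)
  counts <- matrix(0, 24, 24)
  for (i in seq_len(nrow(rcu)))
    counts[rcu[i, 1], rcu[i, 2]] <- counts[rcu[i, 1], rcu[i, 2]] + 1
  dens <- w$density$values$values
  on <- dens > 0
  expect_gt(stats::cor(counts[on], dens[on], method = "spearman"), 0)
})

test_that("suitability concentrated in one quadrant attracts the points", {
  # suitability high only in the north-west quadrant, uniform effort
  nr <- 20; nc <- 20
  s <- matrix(0.001, nr, nc)
  s[1:10, 1:10] <- 0.999
  grid <- raster_grid(s, 500)
  truth <- structure(list(coefficients = c(sst = 0), intercept = 0,
                          surface = grid), class = "true_suitability")
  p <- sample_presences(truth, list(), 200, seed = 5, month_id = "2020-01")
  rc <- point_to_cell(grid, p$x, p$y)
  in_quadrant <- rc[, "row"] <= 10 & rc[, "col"] <= 10
  expect_gt(mean(in_quadrant), 0.8)
})
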