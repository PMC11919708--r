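test_that("hinge basis places mirrored, rescaled features at the knots", {
  # x = (0, 5, 10), one knot at the median 5: forward hinge is (0, 0, 1)
  tt <- data.frame(sst = c(0, 5, 10), label = c(1L, 0L, 0L),
                   month_id = "2019-06")
  basis <- build_hinge_basis(tt, 1)
  f <- hinge_features(basis, tt)
  fwd <- which(vapply(basis$features, `[[`, character(1),
                      "direction") == "forward")
  expect_equal(unname(f[, fwd]), c(0, 0, 1))
  rev <- which(vapply(basis$features, `[[`, character(1),
                      "direction") == "reverse")
  expect_equal(unname(f[, rev]), c(1, 0, 0))

  # symmetric sample: forward and reverse features are mirror images
  xs <- c(-3, -1, 0, 1, 3)
  tt2 <- data.frame(sst = xs, label = c(1L, 1L, 0L, 0L, 0L),
                    month_id = "m")
  b2 <- build_hinge_basis(tt2, 1)
  f2 <- hinge_features(b2, tt2)
  expect_equal(f2[, 1], base::rev(f2[, 2]))

  # constant covariates are dropped without error
  tt3 <- data.frame(sst = c(1, 2, 3), depth = c(-5, -5, -5),
                    label = c(1L, 0L, 0L), month_id = "m")
  expect_message(b3 <- build_hinge_basis(tt3, 2), "constant covariate")
  covs <- vapply(b3$features, `[[`, character(1), "covariate")
  expect_false("depth" %in% covs)
  expect_true(all(hinge_features(b3, tt3) >= 0 &
                    hinge_features(b3, tt3) <= 1))
})

test_that("gain matches hand arithmetic and its structural identities", {
  # 2 presences, 3 backgrounds, 1 manual feature, eta = 0.5
  basis <- manual_basis(list(list(covariate = "sst", direction = "forward",
                                  knot = 2, scale = 8, lo = 0, hi = 10)))
  tt <- data.frame(sst = c(9, 7, 1, 4, 6), label = c(1L, 1L, 0L, 0L, 0L),
                   month_id = "m")
  f <- pmax(0, tt$sst - 2) / 8            # (0.875, 0.625, 0, 0.25, 0.5)
  eta <- 0.5; beta <- 1; m <- 2; n <- 3
  lam <- beta * sqrt(stats::var(f[1:2]) / m)
  by_hand <- mean(eta * f[1:2]) -
    log(sum((1 / n) * exp(eta * f[3:5]))) - lam * abs(eta)
  expect_equal(gain(eta, tt, basis, beta), by_hand, tolerance = 1e-12)

  # zero weights give exactly zero gain
  expect_equal(gain(0, tt, basis, beta), 0)

  # doubling beta lowers the gain by exactly the extra penalty
  g1 <- gain(eta, tt, basis, 1)
  g2 <- gain(eta, tt, basis, 2)
  expect_equal(g1 - g2, lam * abs(eta), tolerance = 1e-12)

  expect_error(gain(c(1, 2), tt, basis, 1), "features")
})

test_that("the fit maximizes the gain from zero weights, monotonically", {
  tt <- toy_table(m = 40, n = 60, shift = 3, seed = 2)
  basis <- build_hinge_basis(tt, 4)
  fit <- fit_maxent(tt, basis, beta = 0.5, max_iterations = 3000)
  expect_false(is.unsorted(fit$gain_history))
  expect_gte(fit$gain, 0)          # never worse than eta = 0
  expect_gt(fit$gain, 0.1)         # a separable signal is exploited

  # the Gibbs density over background points sums to one
  Fb <- hinge_features(basis, tt[tt$label == 0L, ])
  lp <- as.vector(Fb %*% fit$eta)
  q <- exp(lp - fit$linear_predictor_normalizer) / fit$density_normalizer
  expect_equal(sum(q), 1, tolerance = 1e-9)

  # no-signal data: weights shrink toward zero under strong regularization
  null_tt <- toy_table(m = 40, n = 60, shift = 0, seed = 3)
  nb <- build_hinge_basis(null_tt, 4)
  weak <- fit_maxent(null_tt, nb, beta = 0.05, max_iterations = 3000)
  strong <- fit_maxent(null_tt, nb, beta = 10)
  expect_lt(sum(abs(strong$eta)), 1e-6)
  expect_lte(sum(abs(strong$eta)), sum(abs(weak$eta)))
})

test_that("a discriminating feature is fitted to the grid-search optimum", {
  # presences sit high on the feature; the background spans the full range
  # (effort covers suitable habitat too), so the penalized optimum is finite
  basis <- manual_basis(list(list(covariate = "sst", direction = "forward",
                                  knot = 0, scale = 10, lo = -10, hi = 10)))
  tt <- data.frame(sst = c(8, 9, 7, -8, -9, -7, -6, 6, 9.5),
                   month_id = "m", label = c(rep(1L, 3), rep(0L, 6)))
  fit <- fit_maxent(tt, basis, beta = 0.1, max_iterations = 2000,
                    tolerance = 1e-9)
  expect_gt(fit$eta[1], 0)
  expect_gt(fit$gain, 0)
  # brute-force 1-D grid search confirms the maximizer
  grid_eta <- seq(-2, 8, by = 0.01)
  grid_gain <- vapply(grid_eta, function(e) gain(e, tt, basis, 0.1),
                      numeric(1))
  best <- grid_eta[which.max(grid_gain)]
  expect_gte(fit$gain + 1e-6, max(grid_gain))
  expect_lt(abs(fit$eta[1] - best), 0.01 + 1e-6)
})

test_that("two-feature fits match a dense brute-force grid search", {
  basis <- manual_basis(list(
    list(covariate = "sst", direction = "forward", knot = 0, scale = 5,
         lo = -5, hi = 5),
    list(covariate = "depth", direction = "reverse", knot = 0, scale = 5,
         lo = -5, hi = 5)))
  set.seed(8)
  pres <- data.frame(sst = rnorm(15, 2), depth = rnorm(15, -2))
  bg <- rbind(data.frame(sst = rnorm(20, -1), depth = rnorm(20, 1)),
              data.frame(sst = rnorm(8, 2), depth = rnorm(8, -2)))
  tt <- rbind(cbind(pres, label = 1L), cbind(bg, label = 0L))
  tt$sst <- pmin(pmax(tt$sst, -5), 5)
  tt$depth <- pmin(pmax(tt$depth, -5), 5)
  tt$month_id <- "m"
  fit <- fit_maxent(tt, basis, beta = 0.5, max_iterations = 2000,
                    tolerance = 1e-9)
  step <- 0.05
  gr <- as.matrix(expand.grid(e1 = seq(-1, 4, by = step),
                              e2 = seq(-1, 4, by = step)))
  gains <- apply(gr, 1, function(e) gain(e, tt, basis, 0.5))
  expect_gte(fit$gain + 1e-6, max(gains))
  best <- gr[which.max(gains), ]
  expect_lt(max(abs(fit$eta - best)), 2 * step)
})

test_that("the weight norm is non-increasing in the regularization", {
  tt <- toy_table(m = 50, n = 80, shift = 2, seed = 5)
  basis <- build_hinge_basis(tt, 4)
  norms <- vapply(c(0.1, 1, 10), function(b)
    sum(abs(fit_maxent(tt, basis, beta = b,
                       max_iterations = 3000)$eta)), numeric(1))
  expect_true(all(diff(norms) <= 1e-9))
})

test_that("prediction is a monotone [0,1] map of the linear predictor", {
  w <- tiny_world(31)
  tt <- make_training_table(w$stack, w$presences, w$absences)
  basis <- build_hinge_basis(tt, 6)
  fit <- fit_maxent(tt, basis)
  map <- predict_maxent(fit, w$stack)
  ok <- !map$nodata_mask
  expect_true(all(map$values[ok] >= 0 & map$values[ok] <= 1))

  valid <- which(ok)
  nd <- as.data.frame(lapply(w$stack$layers, function(l) l$values[valid]))
  names(nd) <- names(w$stack$layers)
  lp <- as.vector(hinge_features(basis, nd) %*% fit$eta)
  expect_identical(order(map$values[valid]), order(lp))

  # raw output ranks identically to cloglog
  raw <- predict_maxent(fit, w$stack, output = "raw")
  expect_identical(order(raw$values[valid]), order(map$values[valid]))

  # a constant stack maps to a constant surface
  cs <- constant_stack()
  cmap <- predict_maxent(fit, cs)
  expect_equal(length(unique(cmap$values[!cmap$nodata_mask])), 1L)
})

test_that("fitted suitability recovers the true surface's ranking", {
  w <- tiny_world(41)
  tt <- make_training_table(w$stack, w$presences, w$absences)
  fit <- fit_maxent(tt, build_hinge_basis(tt, 6))
  map <- predict_maxent(fit, w$stack)
  ok <- !map$nodata_mask & !w$truth$surface$nodata_mask
  rho <- stats::cor(map$values[ok], w$truth$surface$values[ok],
                    method = "spearman")
  expect_gt(rho, 0.7)
})
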