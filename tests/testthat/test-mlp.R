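test_that("initialization is seeded, scaled by fan-in, and architecture-true", {
  a <- init_mlp(3)
  b <- init_mlp(3)
  expect_identical(a$W, b$W)
  expect_false(identical(a$W, init_mlp(4)$W))

  expect_equal(a$layer_sizes, c(6L, 16L, 32L, 64L, 1L))
  expect_equal(dim(a$W[[1]]), c(16L, 6L))
  expect_equal(dim(a$W[[3]]), c(64L, 32L))
  expect_true(all(vapply(a$b, function(bb) all(bb == 0), logical(1))))

  # He scaling: empirical sd of each layer's weights ~ sqrt(2 / fan_in)
  for (l in 1:3) {
    fan_in <- a$layer_sizes[l]
    expect_lt(abs(stats::sd(a$W[[l]]) / sqrt(2 / fan_in) - 1), 0.25)
  }
})

test_that("the forward pass reduces to hand calculations", {
  m <- init_mlp(1)
  # zero network: sigmoid(0) = 0.5
  for (l in seq_along(m$W)) m$W[[l]][] <- 0
  expect_equal(forward(m, rep(0.3, 6)), 0.5)

  # ReLU dead zone: strongly negative first-layer biases kill all hidden
  # activity, leaving sigmoid(output bias)
  m2 <- init_mlp(1)
  m2$b[[1]][] <- -1e6
  m2$b[[4]] <- 0.7
  expect_equal(forward(m2, rep(0.1, 6)), 1 / (1 + exp(-0.7)),
               tolerance = 1e-12)

  # 2-2-1 harness vs pencil-and-paper, same code path
  h <- init_mlp(1, layer_sizes = c(2, 2, 1))
  h$W[[1]] <- matrix(c(1, -1, 0.5, 2), 2, 2)
  h$b[[1]] <- c(0.1, -0.2)
  h$W[[2]] <- matrix(c(1.5, -0.5), 1, 2)
  h$b[[2]] <- 0.25
  x <- c(0.4, 0.3)
  z1 <- h$W[[1]] %*% x + h$b[[1]]
  a1 <- pmax(z1, 0)
  z2 <- h$W[[2]] %*% a1 + h$b[[2]]
  expect_equal(forward(h, x), as.numeric(1 / (1 + exp(-z2))),
               tolerance = 1e-12)

  expect_error(forward(h, c(NA, 1)), "non-finite")
  expect_error(forward(h, c(1, 2, 3)), "expects")
})

test_that("the cost is cross-entropy plus an exact L1 term", {
  m <- init_mlp(1, layer_sizes = c(2, 2, 1))
  expect_equal(bce_l1_cost(1, 1, m, 0), 0, tolerance = 1e-9)
  expect_equal(bce_l1_cost(0.5, 0, m, 0), log(2), tolerance = 1e-12)
  expect_equal(bce_l1_cost(c(0.9, 0.2), c(1, 0), m, 0),
               mean(c(-log(0.9), -log(0.8))), tolerance = 1e-12)
  s <- 0.37
  w1 <- sum(abs(m$W[[1]])) + sum(abs(m$W[[2]]))
  expect_equal(bce_l1_cost(0.5, 1, m, s) - bce_l1_cost(0.5, 1, m, 0),
               s * w1, tolerance = 1e-12)
  # clipping keeps the cost finite at the boundary
  expect_true(is.finite(bce_l1_cost(0, 1, m, 0)))
})

test_that("backpropagation matches central finite differences", {
  set.seed(5)
  h <- init_mlp(2, layer_sizes = c(2, 2, 1))
  X <- matrix(rnorm(12), 6, 2)
  y <- c(1, 0, 1, 0, 1, 0)
  l1 <- 0.01
  gr <- fjordSDM:::mlp_gradients(h, X, y, l1)
  eps <- 1e-6
  cost_at <- function(model) {
    bce_l1_cost(forward(model, X), y, model, l1)
  }
  for (l in seq_along(h$W)) {
    for (i in seq_along(h$W[[l]])) {
      hp <- h; hp$W[[l]][i] <- hp$W[[l]][i] + eps
      hm <- h; hm$W[[l]][i] <- hm$W[[l]][i] - eps
      fd <- (cost_at(hp) - cost_at(hm)) / (2 * eps)
      expect_lt(abs(gr$dW[[l]][i] - fd) / max(abs(fd), 1e-8), 1e-6)
    }
    for (i in seq_along(h$b[[l]])) {
      hp <- h; hp$b[[l]][i] <- hp$b[[l]][i] + eps
      hm <- h; hm$b[[l]][i] <- hm$b[[l]][i] - eps
      fd <- (cost_at(hp) - cost_at(hm)) / (2 * eps)
      expect_lt(abs(gr$db[[l]][i] - fd) / max(abs(fd), 1e-8), 1e-6)
    }
  }
})

test_that("training descends, early-stops, and returns the history minimum", {
  tt <- toy_table(m = 10, n = 10, shift = 4, seed = 7)
  cfg <- mlp_config(seed = 2, learning_rate = 0.3, max_iterations = 400)
  fit <- train_mlp(tt, cfg)
  expect_lt(min(fit$history), fit$history[1])

  # separable data is ranked perfectly on the training rows
  sc <- predict_mlp_points(fit, tt)
  expect_equal(auc(sc[tt$label == 1L], sc[tt$label == 0L]), 1.0)

  # the returned parameters achieve the minimum recorded cost
  X <- fjordSDM:::standardize_rows(tt, fit$standardization)
  final_cost <- bce_l1_cost(forward(fit, X), tt$label, fit,
                            cfg$l1_strength)
  expect_equal(final_cost, min(fit$history), tolerance = 1e-12)

  # one-iteration training from a warm start is a no-op on the weights
  noop <- train_mlp(tt, mlp_config(seed = 2, max_iterations = 1,
                                   patience = 1), warm_start = fit)
  expect_identical(noop$W, fit$W)
  expect_identical(noop$b, fit$b)
})

test_that("L1 regularization shrinks the trained weight norm", {
  tt <- toy_table(m = 30, n = 30, shift = 1, seed = 9)
  free <- train_mlp(tt, mlp_config(seed = 4, l1_strength = 0,
                                   max_iterations = 300))
  shrunk <- train_mlp(tt, mlp_config(seed = 4, l1_strength = 10,
                                     max_iterations = 300))
  norm1 <- function(m) sum(vapply(m$W, function(w) sum(abs(w)), numeric(1)))
  expect_lt(norm1(shrunk), norm1(free))
})

test_that("monthly warm starts chain provenance and freeze standardization", {
  tt1 <- toy_table(m = 15, n = 20, shift = 2, seed = 1)
  tt2 <- toy_table(m = 15, n = 20, shift = 2, seed = 2)
  tt2$month_id <- "2019-07"
  cfg <- mlp_config(seed = 6, max_iterations = 50)
  m1 <- update_monthly(NULL, tt1, cfg)
  m2 <- update_monthly(m1, tt2, cfg)
  expect_equal(m2$provenance, c("2019-06", "2019-07"))
  expect_identical(m2$standardization, m1$standardization)
  expect_warning(m3 <- update_monthly(m2, tt2[0, ], cfg), "empty")
  expect_identical(m3$W, m2$W)
})

test_that("raster prediction agrees with pointwise forward passes", {
  w <- tiny_world(51)
  tt <- make_training_table(w$stack, w$presences, w$absences)
  fit <- train_mlp(tt, mlp_config(seed = 3, max_iterations = 150))
  map <- predict_mlp(fit, w$stack)
  ok <- !map$nodata_mask
  expect_true(all(map$values[ok] > 0 & map$values[ok] < 1))

  valid <- which(ok)
  pick <- valid[round(seq(1, length(valid), length.out = 5))]
  nd <- as.data.frame(lapply(w$stack$layers, function(l) l$values[pick]))
  names(nd) <- names(w$stack$layers)
  expect_equal(map$values[pick], predict_mlp_points(fit, nd),
               tolerance = 1e-12)

  cs <- constant_stack()
  cmap <- predict_mlp(fit, cs)
  expect_equal(length(unique(cmap$values[!cmap$nodata_mask])), 1L)

  expect_error(predict_mlp(init_mlp(1), w$stack), "standardization")
})
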