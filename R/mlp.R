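#' Training configuration for the feedforward network
#'
#' @param l1_strength L1 penalty on weights (default 1e-4 — far weaker than
#'   the maximum-entropy model's multiplier, as befits the much larger
#'   weight network).
#' @param learning_rate fixed step size for full-batch gradient descent.
#' @param max_iterations iteration cap (default 500).
#' @param patience stop after this many consecutive non-improving
#'   iterations (default 5).
#' @param seed integer seed for initialization.
#' @param standardization optional list(mean, sd) per covariate; computed
#'   from the first training table and then frozen when absent.
#' @return object of class `mlp_config`.
#' @export
mlp_config <- function(l1_strength = 1e-4, learning_rate = 0.05,
                       max_iterations = 500, patience = 5, seed = 1,
                       standardization = NULL) {
  if (patience < 1) stop_invalid("patience must be >= 1")
  if (max_iterations < patience)
    stop_invalid("max_iterations must be >= patience")
  if (learning_rate <= 0) stop_invalid("learning_rate must be positive")
  if (l1_strength < 0) stop_invalid("l1_strength must be non-negative")
  structure(list(l1_strength = l1_strength, learning_rate = learning_rate,
                 max_iterations = as.integer(max_iterations),
                 patience = as.integer(patience), seed = as.integer(seed),
                 standardization = standardization),
            class = "mlp_config")
}

#' Initialize the feedforward network
#'
#' Architecture 6-16-32-64-1: six covariate inputs, three ReLU hidden
#' layers, one sigmoid output. Weights use He initialization (normal with
#' standard deviation sqrt(2 / fan_in), the standard choice for ReLU
#' layers); biases start at zero.
#'
#' @param seed integer seed.
#' @param layer_sizes integer vector of layer widths; the default is the
#'   study architecture, but any sizes are accepted (small harnesses share
#'   this code path in the tests).
#' @return object of class `mlp_model`.
#' @export
init_mlp <- function(seed = 1, layer_sizes = c(6, 16, 32, 64, 1)) {
  set.seed(derive_seed(seed, "mlp-init"))
  L <- length(layer_sizes) - 1
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- layer_sizes[l]
    W[[l]] <- matrix(stats::rnorm(layer_sizes[l + 1] * fan_in,
                                  sd = sqrt(2 / fan_in)),
                     layer_sizes[l + 1], fan_in)
    b[[l]] <- numeric(layer_sizes[l + 1])
  }
  structure(list(layer_sizes = as.integer(layer_sizes), W = W, b = b,
                 standardization = NULL, history = numeric(0),
                 provenance = character(0), seed = as.integer(seed)),
            class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model %s, %d months trained%s>\n",
              paste(x$layer_sizes, collapse = "-"),
              length(x$provenance),
              if (length(x$history))
                sprintf(", final cost %.5f", min(x$history)) else ""))
  invisible(x)
}

relu <- function(z) pmax(z, 0)
sigmoid <- function(z) 1 / (1 + exp(-z))

# forward pass with cached pre-activations (X is N x d, rows = examples)
mlp_forward_full <- function(model, X) {
  L <- length(model$W)
  A <- list(t(X))                       # layers stored as d x N
  Z <- vector("list", L)
  for (l in seq_len(L)) {
    Z[[l]] <- model$W[[l]] %*% A[[l]] + model$b[[l]]
    A[[l + 1]] <- if (l < L) relu(Z[[l]]) else sigmoid(Z[[l]])
  }
  list(yhat = as.vector(A[[L + 1]]), A = A, Z = Z)
}

#' Forward pass: predicted presence probability
#'
#' @param model an `mlp_model`.
#' @param x numeric vector of one standardized input row, or a matrix with
#'   one row per example.
#' @return predicted probabilities in (0, 1).
#' @export
forward <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (any(!is.finite(x))) stop_invalid("non-finite network input")
  if (ncol(x) != model$layer_sizes[1])
    stop_invalid("input has %d columns, network expects %d", ncol(x),
                 model$layer_sizes[1])
  mlp_forward_full(model, x)$yhat
}

#' Binary cross-entropy cost with L1 weight penalty
#'
#' Mean of `-(y log yhat + (1 - y) log(1 - yhat))` over rows, plus
#' `l1_strength` times the sum of absolute weights (biases unpenalized).
#' Predictions exactly at 0 or 1 are clipped to `[1e-12, 1 - 1e-12]`.
#'
#' @param yhat predicted probabilities.
#' @param y binary labels.
#' @param model the network (supplies the weights for the penalty).
#' @param l1_strength penalty multiplier.
#' @return scalar cost.
#' @export
bce_l1_cost <- function(yhat, y, model, l1_strength = 0) {
  eps <- 1e-12
  yhat <- pmin(pmax(yhat, eps), 1 - eps)
  ce <- -mean(y * log(yhat) + (1 - y) * log(1 - yhat))
  ce + l1_strength * sum(vapply(model$W, function(w) sum(abs(w)), numeric(1)))
}

# analytic gradients of bce_l1_cost wrt every weight and bias
mlp_gradients <- function(model, X, y, l1_strength) {
  L <- length(model$W)
  N <- nrow(X)
  fw <- mlp_forward_full(model, X)
  dW <- vector("list", L); db <- vector("list", L)
  # sigmoid + BCE gives the usual (yhat - y)/N output delta
  delta <- matrix(fw$yhat - y, 1, N) / N
  for (l in rev(seq_len(L))) {
    dW[[l]] <- delta %*% t(fw$A[[l]]) + l1_strength * sign(model$W[[l]])
    db[[l]] <- rowSums(delta)
    if (l > 1) delta <- (t(model$W[[l]]) %*% delta) * (fw$Z[[l - 1]] > 0)
  }
  list(dW = dW, db = db, yhat = fw$yhat)
}

standardize_rows <- function(tt, st) {
  X <- as.matrix(tt[COVARIATE_NAMES])
  unname(sweep(sweep(X, 2, st$mean, "-"), 2, st$sd, "/"))
}

#' Train the network by full-batch gradient descent
#'
#' Minimizes the binary cross-entropy plus L1 cost with plain gradient
#' descent and backpropagation. Training stops when the cost has not
#' strictly decreased (tolerance 1e-12) for `patience` consecutive
#' iterations, or at `max_iterations`; the parameters with the lowest cost
#' seen are returned. Inputs are standardized with per-covariate mean/sd
#' taken from the first table the model ever sees and frozen thereafter, so
#' warm-started models keep a stable input scale.
#'
#' @param training_table presence/background table from
#'   [make_training_table()].
#' @param config an `mlp_config`.
#' @param warm_start optional `mlp_model` to continue from (the previous
#'   month's model); when NULL a fresh network is initialized.
#' @return a trained `mlp_model` with `history` (cost per iteration) and
#'   provenance.
#' @export
train_mlp <- function(training_table, config = mlp_config(),
                      warm_start = NULL) {
  table_counts(training_table)
  model <- if (is.null(warm_start)) init_mlp(config$seed) else warm_start
  st <- model$standardization
  if (is.null(st)) st <- config$standardization
  if (is.null(st)) {
    X0 <- as.matrix(training_table[COVARIATE_NAMES])
    st <- list(mean = colMeans(X0),
               sd = pmax(apply(X0, 2, stats::sd), 1e-8))
  }
  model$standardization <- st
  X <- standardize_rows(training_table, st)
  y <- training_table$label

  lr <- config$learning_rate
  best <- model; best_cost <- Inf
  history <- numeric(0)
  stall <- 0L
  for (it in seq_len(config$max_iterations)) {
    gr <- mlp_gradients(model, X, y, config$l1_strength)
    cost <- bce_l1_cost(gr$yhat, y, model, config$l1_strength)
    if (!is.finite(cost))
      stop("training cost became non-finite; try a smaller learning_rate",
           call. = FALSE)
    history <- c(history, cost)
    if (cost < best_cost - 1e-12) {
      best_cost <- cost; stall <- 0L
      best$W <- model$W; best$b <- model$b
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
    for (l in seq_along(model$W)) {
      model$W[[l]] <- model$W[[l]] - lr * gr$dW[[l]]
      model$b[[l]] <- model$b[[l]] - lr * gr$db[[l]]
    }
  }
  best$history <- history
  best$provenance <- c(model$provenance, unique(training_table$month_id))
  best$standardization <- st
  best
}

#' Warm-start the network on a new month
#'
#' Continues training from the previous month's parameters on the new
#' month's rows only (the warm start is what carries the accumulated
#' signal). An empty table returns the previous model unchanged with a
#' warning.
#'
#' @param previous the previous month's `mlp_model` (NULL for the first
#'   month, which is equivalent to a fresh fit).
#' @param month_table the new month's training table.
#' @param config an `mlp_config`.
#' @param cumulative train on all rows supplied instead (off by default;
#'   callers wanting the cumulative reading pass a concatenated table).
#' @return updated `mlp_model` with the month appended to its provenance.
#' @export
update_monthly <- function(previous, month_table, config = mlp_config(),
                           cumulative = FALSE) {
  if (is.null(month_table) || nrow(month_table) == 0) {
    warning("empty month table: model returned unchanged", call. = FALSE)
    return(previous)
  }
  train_mlp(month_table, config, warm_start = previous)
}

#' Predict presence probability over a covariate stack
#'
#' @param model a trained `mlp_model` (must carry standardization
#'   parameters).
#' @param stack an `env_stack`.
#' @return a `raster_grid` of probabilities in (0, 1); nodata propagates.
#' @export
predict_mlp <- function(model, stack) {
  if (is.null(model$standardization))
    stop("model has no standardization parameters; train it first",
         call. = FALSE)
  mask <- stack_nodata(stack)
  valid <- which(!mask)
  newdata <- as.data.frame(lapply(stack$layers, function(l) l$values[valid]))
  names(newdata) <- names(stack$layers)
  X <- standardize_rows(newdata, model$standardization)
  ref <- stack$layers[[1]]
  m <- matrix(0, nrow(ref$values), ncol(ref$values))
  m[valid] <- forward(model, X)
  raster_grid(m, ref$cell_size, ref$origin, nodata_mask = mask)
}

#' Predict presence probability at covariate rows
#' @param model a trained `mlp_model`.
#' @param newdata data.frame with the covariate columns.
#' @return probabilities in (0, 1).
#' @export
predict_mlp_points <- function(model, newdata) {
  if (is.null(model$standardization))
    stop("model has no standardization parameters; train it first",
         call. = FALSE)
  forward(model, standardize_rows(newdata, model$standardization))
}
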