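#' Assemble a presence/background training table
#'
#' Extracts the six covariates at presence and pseudo-absence locations and
#' stacks them with a binary label (1 = presence, 0 = background). Points on
#' nodata cells are dropped by [extract_at_points()] and never reach the
#' models.
#'
#' @param stack an `env_stack`.
#' @param presences data.frame with `x`, `y` columns.
#' @param absences data.frame with `x`, `y` columns.
#' @return data.frame with the covariate columns, `label`, `month_id`;
#'   attributes `m` (presences) and `n` (background).
#' @export
make_training_table <- function(stack, presences, absences) {
  p <- extract_at_points(stack, presences)
  a <- extract_at_points(stack, absences)
  p$label <- 1L; a$label <- 0L
  out <- rbind(p, a)
  out$month_id <- stack$month_id
  attr(out, "m") <- nrow(p)
  attr(out, "n") <- nrow(a)
  out
}

table_counts <- function(tt) {
  m <- sum(tt$label == 1L); n <- sum(tt$label == 0L)
  if (m < 1 || n < 1)
    stop_invalid("training table needs at least one presence and one background row (m=%d, n=%d)",
                 m, n)
  c(m = m, n = n)
}

#' Build a hinge feature basis
#'
#' For each covariate, places `knots_per_covariate` knots at empirical
#' quantiles strictly inside the observed training range and generates a
#' forward hinge `max(0, x - k)` and a reverse hinge `max(0, k - x)` at each
#' knot, each rescaled to [0, 1] over the training range. Constant
#' covariates contribute no features.
#'
#' @param training_table table from [make_training_table()].
#' @param knots_per_covariate number of interior knots (>= 1; default 30,
#'   hinge bases are conventionally dense).
#' @return object of class `hinge_basis`.
#' @export
build_hinge_basis <- function(training_table, knots_per_covariate = 30) {
  if (knots_per_covariate < 1)
    stop_invalid("knots_per_covariate must be >= 1")
  cols <- intersect(COVARIATE_NAMES, names(training_table))
  feats <- list()
  dropped <- character(0)
  for (nm in cols) {
    x <- training_table[[nm]]
    lo <- min(x); hi <- max(x)
    if (hi <= lo) { dropped <- c(dropped, nm); next }
    probs <- seq_len(knots_per_covariate) / (knots_per_covariate + 1)
    knots <- unique(as.numeric(stats::quantile(x, probs, type = 7)))
    knots <- knots[knots > lo & knots < hi]
    for (k in knots) {
      feats[[length(feats) + 1L]] <- list(covariate = nm, knot = k,
                                          direction = "forward",
                                          scale = hi - k, lo = lo, hi = hi)
      feats[[length(feats) + 1L]] <- list(covariate = nm, knot = k,
                                          direction = "reverse",
                                          scale = k - lo, lo = lo, hi = hi)
    }
  }
  if (length(dropped))
    message("constant covariate(s) contribute no hinge features: ",
            paste(dropped, collapse = ", "))
  structure(list(features = feats, covariates = cols, dropped = dropped),
            class = "hinge_basis")
}

#' Evaluate hinge features on covariate rows
#'
#' Covariates are clamped to the training range before evaluation
#' ("clamping"), so projection onto novel conditions never extrapolates a
#' hinge beyond [0, 1].
#'
#' @param basis a `hinge_basis`.
#' @param newdata data.frame with the covariate columns.
#' @return numeric matrix, one column per hinge feature.
#' @export
hinge_features <- function(basis, newdata) {
  n <- nrow(newdata)
  p <- length(basis$features)
  out <- matrix(0, n, p)
  for (j in seq_len(p)) {
    f <- basis$features[[j]]
    x <- pmin(pmax(newdata[[f$covariate]], f$lo), f$hi)
    out[, j] <- if (f$direction == "forward")
      pmax(0, x - f$knot) / f$scale
    else
      pmax(0, f$knot - x) / f$scale
  }
  if (any(!is.finite(out)))
    stop_invalid("non-finite hinge feature values")
  out
}

# per-feature L1 penalty scales: beta * sqrt(var_presence(f_j) / m),
# falling back to the all-rows variance for presence-constant features;
# the variance is floored so no feature is ever penalty-free.
hinge_lambda <- function(F_pres, F_all, beta) {
  m <- nrow(F_pres)
  v <- apply(F_pres, 2, stats::var)
  v0 <- apply(F_all, 2, stats::var)
  v[!is.finite(v) | v == 0] <- v0[!is.finite(v) | v == 0]
  beta * sqrt(pmax(v, 1e-4) / max(m, 1))
}

# log( sum_i (1/n) exp(lp_i) ), numerically stable
log_mean_exp <- function(lp) {
  mx <- max(lp)
  mx + log(mean(exp(lp - mx)))
}

#' Penalized maximum-entropy gain
#'
#' The objective maximized by the model: the mean linear predictor over
#' presences, minus the log of the background-averaged exponential of the
#' linear predictor (the uniform prior Q = 1/n), minus the L1 penalty
#' `sum_j lambda_j |eta_j|` with `lambda_j = beta * sqrt(var_j / m)`.
#' Zero weights give exactly zero gain.
#'
#' @param eta numeric weight vector, one per hinge feature.
#' @param training_table presence/background table.
#' @param basis a `hinge_basis`.
#' @param beta L1 regularization multiplier (default 1).
#' @return scalar gain.
#' @export
gain <- function(eta, training_table, basis, beta = 1) {
  cnt <- table_counts(training_table)
  F_all <- hinge_features(basis, training_table)
  if (length(eta) != ncol(F_all))
    stop_invalid("eta has %d entries but the basis has %d features",
                 length(eta), ncol(F_all))
  Fp <- F_all[training_table$label == 1L, , drop = FALSE]
  Fb <- F_all[training_table$label == 0L, , drop = FALSE]
  lam <- hinge_lambda(Fp, F_all, beta)
  gain_parts(eta, Fp, Fb, lam)
}

gain_parts <- function(eta, Fp, Fb, lam) {
  mean(Fp %*% eta) - log_mean_exp(as.vector(Fb %*% eta)) -
    sum(lam * abs(eta))
}

#' Fit the penalized maximum-entropy model
#'
#' Iterative ascent from all-zero weights using a monotone proximal-gradient
#' scheme (soft-thresholding handles the non-smooth L1 term; backtracking
#' guarantees the gain never decreases). Stops when the gain improves by
#' less than `tolerance` or after `max_iterations`.
#'
#' @param training_table presence/background table.
#' @param basis a `hinge_basis` (built from the table if NULL).
#' @param beta L1 multiplier (default 1).
#' @param max_iterations iteration cap (default 500).
#' @param tolerance convergence threshold on gain change (default 1e-5).
#' @return object of class `maxent_model` with fields `eta`, `basis`,
#'   `beta`, `lambda`, `gain_history`, `converged`, the background
#'   normalizers, and the background-density entropy used by the cloglog
#'   output.
#' @export
fit_maxent <- function(training_table, basis = NULL, beta = 1,
                       max_iterations = 500, tolerance = 1e-5) {
  cnt <- table_counts(training_table)
  if (is.null(basis)) basis <- build_hinge_basis(training_table)
  F_all <- hinge_features(basis, training_table)
  Fp <- F_all[training_table$label == 1L, , drop = FALSE]
  Fb <- F_all[training_table$label == 0L, , drop = FALSE]
  lam <- hinge_lambda(Fp, F_all, beta)
  p <- ncol(F_all)
  fbar <- colMeans(Fp)

  eta <- numeric(p)
  smooth_val <- function(e) mean(Fp %*% e) - log_mean_exp(as.vector(Fb %*% e))
  smooth_grad <- function(e) {
    lp <- as.vector(Fb %*% e)
    w <- exp(lp - max(lp)); w <- w / sum(w)
    fbar - as.vector(t(Fb) %*% w)
  }
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

  g_hist <- numeric(0)
  g_cur <- gain_parts(eta, Fp, Fb, lam)
  step <- 1
  converged <- FALSE
  for (it in seq_len(max_iterations)) {
    gr <- smooth_grad(eta)
    s <- smooth_val(eta)
    repeat {
      cand <- soft(eta + step * gr, step * lam)
      d <- cand - eta
      # majorization test for the concave smooth part (ascent version)
      if (smooth_val(cand) >= s + sum(gr * d) - sum(d^2) / (2 * step) ||
          step < 1e-12) break
      step <- step / 2
    }
    g_new <- gain_parts(cand, Fp, Fb, lam)
    if (g_new < g_cur) { g_hist <- c(g_hist, g_cur); break }  # numerical floor
    eta <- cand
    improved <- g_new - g_cur
    g_cur <- g_new
    g_hist <- c(g_hist, g_cur)
    step <- min(step * 2, 1e6)
    if (improved < tolerance) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("maxent fit stopped at %d iterations without meeting tolerance %g",
                    length(g_hist), tolerance), call. = FALSE)

  lp_bg <- as.vector(Fb %*% eta)
  lp_max <- max(lp_bg)
  z <- sum(exp(lp_bg - lp_max))
  q <- exp(lp_bg - lp_max) / z                 # Gibbs density over background
  entropy <- -sum(q * log(pmax(q, 1e-300)))
  structure(
    list(eta = eta, basis = basis, beta = beta, lambda = lam,
         m = cnt["m"], n = cnt["n"],
         gain_history = g_hist, gain = g_cur, converged = converged,
         linear_predictor_normalizer = lp_max, density_normalizer = z,
         entropy = entropy),
    class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "<maxent_model: %d features, %d nonzero weights, beta=%g, gain=%.4f, %s>\n",
    length(x$eta), sum(x$eta != 0), x$beta, x$gain,
    if (x$converged) "converged" else "iteration-capped"))
  invisible(x)
}

# Gibbs density relative to the background sample; sums to 1 over the
# background points by construction.
maxent_raw <- function(model, F_new) {
  lp <- as.vector(F_new %*% model$eta)
  exp(lp - model$linear_predictor_normalizer) / model$density_normalizer
}

#' Suitability scores at covariate rows
#'
#' @param model a fitted `maxent_model`.
#' @param newdata data.frame with the covariate columns.
#' @param output `"cloglog"` (default, a 0-1 habitat-suitability index:
#'   `1 - exp(-exp(H) * raw)` with H the background-density entropy) or
#'   `"raw"` (the relative occurrence rate itself).
#' @return numeric score vector.
#' @export
predict_maxent_points <- function(model, newdata,
                                  output = c("cloglog", "raw")) {
  output <- match.arg(output)
  raw <- maxent_raw(model, hinge_features(model$basis, newdata))
  if (output == "raw") raw else 1 - exp(-exp(model$entropy) * raw)
}

#' Project a maximum-entropy model over a covariate stack
#'
#' Applies the fitted model cell-wise. Covariates outside the training range
#' are clamped. Output is a [0, 1] suitability index (or the raw relative
#' occurrence rate); nodata propagates.
#'
#' @param model a fitted `maxent_model`.
#' @param stack an `env_stack`.
#' @param output `"cloglog"` or `"raw"`.
#' @return a `raster_grid` of suitability.
#' @export
predict_maxent <- function(model, stack, output = c("cloglog", "raw")) {
  output <- match.arg(output)
  mask <- stack_nodata(stack)
  valid <- which(!mask)
  newdata <- as.data.frame(lapply(stack$layers, function(l) l$values[valid]))
  names(newdata) <- names(stack$layers)
  sc <- predict_maxent_points(model, newdata, output = output)
  ref <- stack$layers[[1]]
  m <- matrix(0, nrow(ref$values), ncol(ref$values))
  m[valid] <- sc
  raster_grid(m, ref$cell_size, ref$origin, nodata_mask = mask)
}
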