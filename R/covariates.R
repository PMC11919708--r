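#' Monthly environmental covariate stack
#'
#' Bundles the six covariate layers (sst degC, chlorophyll_a mg/m3, salinity
#' PSU, depth m, slope deg, dist_shore m) for one month on a shared grid.
#' The depth layer is masked at construction so no at-or-above-sea-level
#' cell survives.
#'
#' @param month_id "YYYY-MM" label.
#' @param layers named list of `raster_grid`, containing at least the six
#'   canonical covariates.
#' @return object of class `env_stack`.
#' @export
env_stack <- function(month_id, layers) {
  missing <- setdiff(COVARIATE_NAMES, names(layers))
  if (length(missing))
    stop_invalid("env_stack is missing layers: %s",
                 paste(missing, collapse = ", "))
  layers <- layers[COVARIATE_NAMES]
  ref <- layers[[1]]
  for (nm in names(layers)) {
    l <- layers[[nm]]
    if (!identical(dim(l$values), dim(ref$values)) ||
        l$cell_size != ref$cell_size || !identical(l$origin, ref$origin))
      stop_invalid("layer '%s' is not on the shared grid", nm)
  }
  layers$depth <- mask_depth(layers$depth)
  structure(list(month_id = month_id, layers = layers), class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack %s: %d layers, %d x %d cells>\n", x$month_id,
              length(x$layers), nrow(x$layers[[1]]$values),
              ncol(x$layers[[1]]$values)))
  invisible(x)
}

#' Combined nodata mask across all layers of a stack
#' @param stack an `env_stack`.
#' @return logical matrix, TRUE where any layer lacks data.
#' @export
stack_nodata <- function(stack) {
  Reduce(`|`, lapply(stack$layers, function(l) l$nodata_mask))
}

#' Extract covariate values at point locations
#'
#' Each point receives the value of its containing cell for every layer.
#' Points that fall outside the extent raise an error; points on any nodata
#' cell are excluded from the returned table and counted in the
#' `n_excluded` attribute (they must never enter training).
#'
#' @param stack an `env_stack`.
#' @param points data.frame with columns `x`, `y`.
#' @return data.frame with the six covariate columns plus `x`, `y`;
#'   attributes `n_excluded` and `excluded_idx`.
#' @export
extract_at_points <- function(stack, points) {
  ref <- stack$layers[[1]]
  rc <- point_to_cell(ref, points$x, points$y)
  if (anyNA(rc))
    stop_invalid("%d point(s) fall outside the grid extent",
                 sum(is.na(rc[, "row"])))
  mask <- stack_nodata(stack)
  on_nodata <- mask[rc]
  keep <- which(!on_nodata)
  out <- as.data.frame(lapply(stack$layers, function(l)
    l$values[rc[keep, , drop = FALSE]]))
  names(out) <- names(stack$layers)
  out$x <- points$x[keep]
  out$y <- points$y[keep]
  attr(out, "n_excluded") <- sum(on_nodata)
  attr(out, "excluded_idx") <- which(on_nodata)
  out
}

#' Screen covariates for collinearity
#'
#' Pairwise Pearson correlations and variance inflation factors over the six
#' covariate columns of a training table. Pairs with |r| at or above
#' `flag_threshold` are flagged but never dropped — strongly correlated
#' variables can still carry unique information, which the VIF quantifies.
#' Zero-variance columns get NA correlations/VIF with a warning.
#'
#' @param training_table data.frame containing the covariate columns.
#' @param flag_threshold |r| at which a pair is flagged (default 0.7).
#' @return object of class `screening_report` with fields `pearson`
#'   (6 x 6 matrix), `vif` (named vector), and `flags` (data.frame).
#' @export
screen_collinearity <- function(training_table, flag_threshold = 0.7) {
  cols <- intersect(COVARIATE_NAMES, names(training_table))
  x <- as.data.frame(training_table)[cols]
  if (nrow(x) < 3) stop_invalid("need at least 3 rows to screen collinearity")
  if (anyNA(x)) stop_invalid("training table contains missing values")
  sds <- vapply(x, stats::sd, numeric(1))
  degenerate <- sds == 0
  if (any(degenerate))
    warning(sprintf("zero-variance covariate(s): %s; correlations and VIF undefined",
                    paste(cols[degenerate], collapse = ", ")), call. = FALSE)
  pear <- suppressWarnings(stats::cor(x))
  diag(pear) <- 1
  vif <- stats::setNames(rep(NA_real_, length(cols)), cols)
  for (j in seq_along(cols)) {
    if (degenerate[j]) next
    others <- cols[-j][!degenerate[-j]]
    if (!length(others)) { vif[j] <- 1; next }
    fit <- stats::lm(stats::reformulate(others, response = cols[j]), data = x)
    r2 <- suppressWarnings(summary(fit)$r.squared)
    vif[j] <- if (r2 >= 1 - 1e-12) NA_real_ else 1 / (1 - r2)
  }
  pairs <- which(upper.tri(pear) & abs(pear) >= flag_threshold, arr.ind = TRUE)
  flags <- data.frame(var1 = cols[pairs[, 1]], var2 = cols[pairs[, 2]],
                      r = pear[pairs])
  structure(list(pearson = pear, vif = vif, flags = flags),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat("<screening_report>\nPearson correlations:\n")
  print(round(x$pearson, 3))
  cat("VIF:\n"); print(round(x$vif, 3))
  if (nrow(x$flags)) {
    cat("Flagged pairs (|r| above threshold; retained):\n")
    print(x$flags)
  }
  invisible(x)
}

#' Nodata-aware mean of raster scenes
#'
#' Arithmetic mean across a list of co-registered layers; a cell is nodata
#' only when it is nodata in every input. Used to reduce multiple scenes to
#' a monthly mean and to average the same calendar month across years for
#' projections.
#'
#' @param layers list of `raster_grid` on a common grid.
#' @return a `raster_grid`.
#' @export
mean_layer <- function(layers) {
  if (!length(layers)) stop_invalid("need at least one layer to average")
  ref <- layers[[1]]
  acc <- matrix(0, nrow(ref$values), ncol(ref$values))
  cnt <- matrix(0, nrow(ref$values), ncol(ref$values))
  for (l in layers) {
    if (!identical(dim(l$values), dim(ref$values)) ||
        l$cell_size != ref$cell_size || !identical(l$origin, ref$origin))
      stop_invalid("layers are not co-registered")
    ok <- !l$nodata_mask
    acc[ok] <- acc[ok] + l$values[ok]
    cnt[ok] <- cnt[ok] + 1
  }
  mask <- cnt == 0
  vals <- ifelse(mask, 0, acc / pmax(cnt, 1))
  raster_grid(vals, ref$cell_size, ref$origin, nodata_mask = mask)
}
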