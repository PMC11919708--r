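#' Georeferenced raster layer
#'
#' A minimal single-band raster on a planar grid: a numeric matrix (rows run
#' north to south), a square cell size in meters, the (x, y) coordinate of the
#' grid's top-left corner, and a logical nodata mask. Cells are half-open
#' `[x, x + cell_size)` horizontally and `(y - cell_size, y]` vertically, so a
#' point on a shared edge belongs to the cell to the right/below.
#'
#' @param values numeric matrix of cell values.
#' @param cell_size cell edge length in meters (> 0).
#' @param origin numeric length-2, (x, y) of the top-left corner. Defaults to
#'   `c(0, nrow(values) * cell_size)` so the grid occupies positive
#'   coordinates with y increasing northwards.
#' @param nodata_mask logical matrix, `TRUE` where the cell carries no data.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, cell_size,
                        origin = c(0, nrow(values) * cell_size),
                        nodata_mask = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop_invalid("cell_size must be a single positive number, got %s",
                 format(cell_size))
  if (length(origin) != 2 || !is.numeric(origin))
    stop_invalid("origin must be a numeric (x, y) pair")
  if (is.null(nodata_mask)) nodata_mask <- !is.finite(values)
  if (!identical(dim(nodata_mask), dim(values)))
    stop_invalid("nodata_mask shape must match values")
  if (any(!is.finite(values[!nodata_mask])))
    stop_invalid("non-finite values outside the nodata mask")
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), nodata_mask = nodata_mask),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[!x$nodata_mask]
  cat(sprintf("<raster_grid %d x %d, cell %g m, origin (%g, %g), %d nodata>\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2], sum(x$nodata_mask)))
  if (length(v))
    cat(sprintf("  range [%g, %g]\n", min(v), max(v)))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' Grid extent as (xmin, xmax, ymin, ymax)
#' @param grid a `raster_grid`.
#' @return numeric length-4 vector.
#' @export
grid_extent <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values); cs <- grid$cell_size
  c(xmin = grid$origin[1], xmax = grid$origin[1] + nc * cs,
    ymin = grid$origin[2] - nr * cs, ymax = grid$origin[2])
}

#' Map planar coordinates to (row, col) cell indices
#'
#' Points outside the extent get NA indices. The shared-edge convention puts
#' a point on a cell boundary into the cell to the right/below, except on the
#' extent's own right/bottom edge which closes the last cell.
#'
#' @param grid a `raster_grid`.
#' @param x,y numeric coordinate vectors.
#' @return integer matrix with columns `row`, `col`.
#' @export
point_to_cell <- function(grid, x, y) {
  cs <- grid$cell_size
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  col <- floor((x - grid$origin[1]) / cs) + 1
  row <- floor((grid$origin[2] - y) / cs) + 1
  # close the far edges so extent-boundary points remain inside
  col[x == grid$origin[1] + nc * cs] <- nc
  row[y == grid$origin[2] - nr * cs] <- nr
  bad <- col < 1 | col > nc | row < 1 | row > nr | !is.finite(x) | !is.finite(y)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Coordinates of cell centers
#' @param grid a `raster_grid`.
#' @param row,col integer cell indices.
#' @return matrix with columns `x`, `y`.
#' @export
cell_center <- function(grid, row, col) {
  cs <- grid$cell_size
  cbind(x = grid$origin[1] + (col - 0.5) * cs,
        y = grid$origin[2] - (row - 0.5) * cs)
}

#' Bilinear interpolation of a layer at arbitrary coordinates
#'
#' Interpolates between the four surrounding cell centers, clamping beyond
#' the outermost centers. Any nodata cell among the four contributors makes
#' the result NA.
#'
#' @param grid a `raster_grid`.
#' @param x,y coordinates.
#' @return numeric vector of interpolated values.
#' @export
raster_value_at <- function(grid, x, y) {
  cs <- grid$cell_size
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  # fractional position in cell-center units: center of col j is at j
  gx <- (x - grid$origin[1]) / cs + 0.5
  gy <- (grid$origin[2] - y) / cs + 0.5
  gx <- pmin(pmax(gx, 1), nc)
  gy <- pmin(pmax(gy, 1), nr)
  c0 <- pmin(floor(gx), nc - 1L); c0[nc == 1L] <- 1L
  r0 <- pmin(floor(gy), nr - 1L); r0[nr == 1L] <- 1L
  c1 <- pmin(c0 + 1L, nc); r1 <- pmin(r0 + 1L, nr)
  tx <- gx - c0; ty <- gy - r0
  v <- grid$values; v[grid$nodata_mask] <- NA_real_
  id <- function(r, c) (c - 1L) * nr + r
  unname((1 - tx) * (1 - ty) * v[id(r0, c0)] +
           tx * (1 - ty) * v[id(r0, c1)] +
           (1 - tx) * ty * v[id(r1, c0)] + tx * ty * v[id(r1, c1)])
}

#' Resample a raster to a new cell size
#'
#' The output covers the same extent at the target resolution; continuous
#' values are interpolated bilinearly (`method = "bilinear"`) or copied from
#' the containing cell (`method = "nearest"`, for masks). Nodata propagates.
#'
#' @param layer a `raster_grid`.
#' @param target_cell_size desired cell edge in meters.
#' @param method `"bilinear"` or `"nearest"`.
#' @return a `raster_grid` on the target grid.
#' @export
resample_layer <- function(layer, target_cell_size,
                           method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (target_cell_size <= 0)
    stop_invalid("target_cell_size must be positive")
  ext <- grid_extent(layer)
  w <- ext["xmax"] - ext["xmin"]; h <- ext["ymax"] - ext["ymin"]
  if (target_cell_size > max(w, h))
    stop_invalid("target cell size %g m exceeds the layer extent (%g x %g m)",
                 target_cell_size, w, h)
  nc <- max(1L, as.integer(round(w / target_cell_size)))
  nr <- max(1L, as.integer(round(h / target_cell_size)))
  rows <- rep(seq_len(nr), times = nc)
  cols <- rep(seq_len(nc), each = nr)
  out <- raster_grid(matrix(0, nr, nc), target_cell_size,
                     origin = layer$origin)
  ctr <- cell_center(out, rows, cols)
  if (method == "bilinear") {
    vals <- raster_value_at(layer, ctr[, "x"], ctr[, "y"])
  } else {
    rc <- point_to_cell(layer, ctr[, "x"], ctr[, "y"])
    v <- layer$values; v[layer$nodata_mask] <- NA_real_
    vals <- v[cbind(rc[, "row"], rc[, "col"])]
  }
  m <- matrix(NA_real_, nr, nc)
  m[cbind(rows, cols)] <- vals
  raster_grid(ifelse(is.na(m), 0, m), target_cell_size,
              origin = layer$origin, nodata_mask = is.na(m))
}

#' Mask non-negative depth values
#'
#' Any cell at or above sea level (value >= 0 m) becomes nodata, so land or
#' resampling artifacts never enter the training data. Idempotent.
#'
#' @param depth a `raster_grid` of depth in meters (negative under water).
#' @return a `raster_grid` with the mask applied.
#' @export
mask_depth <- function(depth) {
  bad <- !depth$nodata_mask & depth$values >= 0
  mask <- depth$nodata_mask | bad
  vals <- depth$values
  vals[bad] <- 0
  raster_grid(vals, depth$cell_size, depth$origin, nodata_mask = mask)
}
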