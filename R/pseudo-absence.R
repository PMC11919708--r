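#' Monthly search-effort record
#'
#' @param month_id "YYYY-MM".
#' @param effort_hours total search effort in hours (>= 0).
#' @param search_days number of days with at least one search (>= 0).
#' @return object of class `effort_record`.
#' @export
effort_record <- function(month_id, effort_hours, search_days) {
  if (effort_hours < 0 || search_days < 0)
    stop_invalid("effort_hours and search_days must be non-negative")
  if (search_days == 0 && effort_hours > 0)
    stop_invalid("search_days = 0 implies effort_hours = 0 (got %g h)",
                 effort_hours)
  structure(list(month_id = month_id, effort_hours = effort_hours,
                 search_days = as.integer(search_days)),
            class = "effort_record")
}

#' Effort-proportional pseudo-absence count
#'
#' The number of pseudo-absence points for a month is tied directly to the
#' search effort: four points per effort hour plus five per search day,
#' rounded half-up to the nearest integer. This keeps the background sample
#' proportional to how hard (and how often) the area was surveyed.
#'
#' @param effort an `effort_record`, or effort hours when `search_days` is
#'   given.
#' @param search_days number of search days (when `effort` is numeric).
#' @return integer pseudo-absence count.
#' @examples
#' n_pseudo_absences(117, 30)  # 618
#' @export
n_pseudo_absences <- function(effort, search_days = NULL) {
  if (inherits(effort, "effort_record")) {
    h <- effort$effort_hours; d <- effort$search_days
  } else {
    if (is.null(search_days))
      stop_invalid("supply an effort_record or both hours and days")
    h <- effort; d <- search_days
  }
  if (h < 0 || d < 0) stop_invalid("effort inputs must be non-negative")
  as.integer(round_half_up(h * 4 + d * 5))
}

# Apportion one segment's length to the grid cells it crosses.
# Returns a matrix (row, col, length); exact split at grid lines.
segment_cell_lengths <- function(grid, p0, p1) {
  cs <- grid$cell_size
  ox <- grid$origin[1]; oy <- grid$origin[2]
  dx <- p1[1] - p0[1]; dy <- p1[2] - p0[2]
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) return(NULL)
  int_range <- function(lo, hi) {
    a <- ceiling(lo); b <- floor(hi)
    if (a > b) numeric(0) else a:b
  }
  ts <- c(0, 1)
  if (dx != 0) {
    ks <- int_range((min(p0[1], p1[1]) - ox) / cs, (max(p0[1], p1[1]) - ox) / cs)
    ts <- c(ts, ((ox + ks * cs) - p0[1]) / dx)
  }
  if (dy != 0) {
    ks <- int_range((oy - max(p0[2], p1[2])) / cs, (oy - min(p0[2], p1[2])) / cs)
    ts <- c(ts, ((oy - ks * cs) - p0[2]) / dy)
  }
  ts <- sort(unique(pmin(pmax(ts, 0), 1)))
  if (length(ts) < 2) return(NULL)
  mid_t <- (ts[-length(ts)] + ts[-1]) / 2
  seg_len <- (ts[-1] - ts[-length(ts)]) * len
  mx <- p0[1] + mid_t * dx
  my <- p0[2] + mid_t * dy
  rc <- point_to_cell(grid, mx, my)
  keep <- !is.na(rc[, "row"]) & seg_len > 0
  if (!any(keep)) return(NULL)
  cbind(rc[keep, , drop = FALSE], length = seg_len[keep])
}

#' Kernel-smoothed trackline density surface
#'
#' Accumulates, per cell, the exact length of trackline traversing it, then
#' smooths with a Gaussian kernel of the given bandwidth (in cells), zeroes
#' land/nodata cells, and normalizes so the water-cell mass sums to one.
#' This surface is the sampling distribution for pseudo-absence points and
#' the effort proxy used when placing synthetic sightings.
#'
#' @param tracklines list of `trackline`.
#' @param grid a `raster_grid` defining the target grid (its nodata mask
#'   marks land).
#' @param bandwidth Gaussian kernel standard deviation in cells (0 = no
#'   smoothing).
#' @return object of class `density_surface` wrapping a `raster_grid` whose
#'   valid cells sum to 1.
#' @export
trackline_density <- function(tracklines, grid, bandwidth = 2) {
  if (!length(tracklines)) stop_invalid("need at least one trackline")
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  acc <- matrix(0, nr, nc)
  for (tl in tracklines) {
    v <- tl$vertices
    for (i in seq_len(nrow(v) - 1)) {
      seg <- segment_cell_lengths(grid, v[i, ], v[i + 1, ])
      if (is.null(seg)) next
      for (j in seq_len(nrow(seg)))
        acc[seg[j, 1], seg[j, 2]] <- acc[seg[j, 1], seg[j, 2]] + seg[j, 3]
    }
  }
  if (sum(acc) == 0)
    stop_invalid("all tracklines fall outside the grid")
  dens <- gauss_smooth(acc, bandwidth)
  dens[grid$nodata_mask] <- 0
  dens[dens < 0] <- 0
  if (sum(dens) == 0)
    stop_invalid("trackline density is zero on every water cell")
  dens <- dens / sum(dens)
  structure(
    list(values = raster_grid(dens, grid$cell_size, grid$origin,
                              nodata_mask = grid$nodata_mask)),
    class = "density_surface")
}

#' Sample pseudo-absence points from a density surface
#'
#' Cells are drawn with replacement with probability proportional to the
#' density; each point is then placed uniformly at random inside its cell.
#' Optionally, cells known to hold presences can be excluded (off by
#' default: the effort density is the faithful background model and
#' presences do occur in surveyed cells).
#'
#' @param density a `density_surface`.
#' @param count number of points (e.g. from [n_pseudo_absences()]).
#' @param seed integer seed.
#' @param presence_cells optional two-column matrix of (row, col) cells to
#'   exclude.
#' @param month_id label for the output table.
#' @return data.frame with columns `month_id`, `x`, `y` and attribute
#'   `seed`.
#' @export
sample_absences <- function(density, count, seed = 1, presence_cells = NULL,
                            month_id = "0000-00") {
  if (count < 0) stop_invalid("count must be non-negative")
  grid <- density$values
  w <- grid$values
  if (!is.null(presence_cells))
    w[as.matrix(presence_cells)] <- 0
  if (count == 0) {
    out <- data.frame(month_id = character(0), x = numeric(0), y = numeric(0))
    attr(out, "seed") <- seed
    return(out)
  }
  if (sum(w) <= 0)
    stop("absence generation failed: density has no positive mass",
         call. = FALSE)
  set.seed(derive_seed(seed, "absence", month_id))
  idx <- sample.int(length(w), count, replace = TRUE, prob = as.vector(w))
  nr <- nrow(w)
  rows <- ((idx - 1) %% nr) + 1
  cols <- ((idx - 1) %/% nr) + 1
  ctr <- cell_center(grid, rows, cols)
  cs <- grid$cell_size
  out <- data.frame(
    month_id = month_id,
    x = ctr[, "x"] + stats::runif(count, -0.5, 0.5) * cs,
    y = ctr[, "y"] + stats::runif(count, -0.5, 0.5) * cs)
  attr(out, "seed") <- seed
  out
}
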