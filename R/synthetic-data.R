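#' Synthetic fjord study system
#'
#' Generators for a fully synthetic coastal study area: a bathymetry with a
#' land margin on the eastern edge (the harbor sits on its coastline),
#' derived slope and distance-to-shore layers, spatially autocorrelated
#' dynamic covariates with seasonal cycles, a known ("true") suitability
#' surface, whale-watching tour tracklines with month-varying effort, and
#' presence points drawn from suitability times trackline proximity — so the
#' effort-bias correction downstream has a real bias to correct.
#'
#' @name synthetic_data
NULL

# physical ranges for the dynamic layers (plausible North Atlantic values)
DYNAMIC_RANGES <- list(
  sst           = c(-1, 14),    # degC
  chlorophyll_a = c(0.05, 20),  # mg/m^3, generated on log scale
  salinity      = c(30, 36)     # PSU
)

month_number <- function(month_id) {
  m <- suppressWarnings(as.integer(sub("^\\d{4}-", "", month_id)))
  if (any(is.na(m) | m < 1 | m > 12))
    stop_invalid("month_id must look like 'YYYY-MM', got '%s'", month_id)
  m
}

#' Generate the static layers: depth, slope, distance to shore
#'
#' Builds a smooth synthetic basin deepening away from a land margin on the
#' eastern grid edge, then derives seabed slope (finite-difference gradient
#' magnitude, degrees) and Euclidean distance to the nearest land cell
#' (meters, center to center).
#'
#' @param shape integer length-2, (rows, cols), at least 8 x 8.
#' @param cell_size cell edge in meters.
#' @param seed integer seed.
#' @param land_frac fraction of columns forming the land margin.
#' @return list with `raster_grid` elements `depth`, `slope`, `dist_shore`
#'   and the logical `land` matrix.
#' @export
gen_static_layers <- function(shape, cell_size = 500, seed = 1,
                              land_frac = 0.15) {
  if (length(shape) != 2 || any(shape < 2))
    stop_invalid("shape must give at least 2 cells per axis")
  if (any(shape < 8))
    stop_invalid("shape must be at least 8 x 8 for a usable basin")
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  set.seed(derive_seed(seed, "static"))
  # wiggly coastline: land occupies the columns east of a smooth boundary
  margin <- max(2L, as.integer(round(nc * land_frac)))
  wiggle <- gauss_smooth(matrix(rnorm(nr), nr, 1), 2)[, 1]
  coast_col <- nc - margin + round(2 * (wiggle - mean(wiggle)))
  coast_col <- pmin(pmax(coast_col, nc - 2L * margin + 1L), nc - 1L)
  land <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) land[r, (coast_col[r] + 1L):nc] <- TRUE

  # distance transform (cell centers, meters); land cells are distance 0
  land_idx <- which(land, arr.ind = TRUE)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d2 <- matrix(Inf, nr, nc)
  for (i in seq_len(nrow(land_idx))) {
    d2 <- pmin(d2, (rows - land_idx[i, 1])^2 + (cols - land_idx[i, 2])^2)
  }
  dist_m <- sqrt(d2) * cell_size

  # bathymetry: deepens with distance from shore plus a smooth random field
  bumps <- gauss_smooth(matrix(rnorm(nr * nc, sd = 30), nr, nc), 3)
  depth <- -(8 + 0.012 * dist_m) + bumps
  depth <- pmin(depth, -1)       # keep every water cell below sea level
  depth[land] <- 10              # land margin above sea level

  # slope from central differences of depth, degrees
  dzdx <- matrix(0, nr, nc); dzdy <- matrix(0, nr, nc)
  run2 <- 2 * cell_size
  dzdx[, 2:(nc - 1)] <- (depth[, 3:nc] - depth[, 1:(nc - 2)]) / run2
  dzdx[, 1] <- (depth[, 2] - depth[, 1]) / cell_size
  dzdx[, nc] <- (depth[, nc] - depth[, nc - 1]) / cell_size
  dzdy[2:(nr - 1), ] <- (depth[3:nr, ] - depth[1:(nr - 2), ]) / run2
  dzdy[1, ] <- (depth[2, ] - depth[1, ]) / cell_size
  dzdy[nr, ] <- (depth[nr, ] - depth[nr - 1, ]) / cell_size
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi

  origin <- c(0, nr * cell_size)
  list(
    depth = raster_grid(depth, cell_size, origin),
    slope = raster_grid(slope, cell_size, origin, nodata_mask = land),
    dist_shore = raster_grid(dist_m, cell_size, origin, nodata_mask = land),
    land = land)
}

#' Generate one month's dynamic covariate layer
#'
#' A spatially autocorrelated random field (Gaussian-smoothed white noise)
#' plus a sinusoidal seasonal mean for the calendar month, clipped to a
#' plausible physical range per layer. Chlorophyll-a is generated on the log
#' scale and exponentiated, giving the right-skewed distribution typical of
#' ocean-color data.
#'
#' @param shape (rows, cols).
#' @param cell_size meters.
#' @param month_id "YYYY-MM" label; drives the seasonal offset and the RNG.
#' @param layer_name one of "sst", "chlorophyll_a", "salinity".
#' @param seed integer seed.
#' @param smooth_radius autocorrelation radius in cells (0 = white noise).
#' @param nodata_mask optional logical matrix (e.g. the land margin).
#' @return a `raster_grid`.
#' @export
gen_dynamic_layer <- function(shape, cell_size = 500, month_id, layer_name,
                              seed = 1, smooth_radius = 3,
                              nodata_mask = NULL) {
  if (!layer_name %in% DYNAMIC_LAYERS)
    stop_invalid("unknown layer_name '%s' (expected one of %s)", layer_name,
                 paste(DYNAMIC_LAYERS, collapse = ", "))
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  mo <- month_number(month_id)
  set.seed(derive_seed(seed, "dyn", layer_name, month_id))
  noise <- matrix(rnorm(nr * nc), nr, nc)
  field <- gauss_smooth(noise, smooth_radius)
  if (smooth_radius > 0) field <- field / stats::sd(field)  # unit variance
  season <- sin(2 * pi * (mo - 3) / 12)  # peaks in June, trough in December
  rng <- DYNAMIC_RANGES[[layer_name]]
  raw <- switch(layer_name,
    sst = 4 + 5 * season + 1.5 * field,
    chlorophyll_a = exp(0.3 + 0.9 * season + 0.6 * field),
    salinity = 33.5 - 0.8 * season + 0.4 * field)
  vals <- pmin(pmax(raw, rng[1]), rng[2])
  if (is.null(nodata_mask)) nodata_mask <- matrix(FALSE, nr, nc)
  vals[nodata_mask] <- 0
  raster_grid(vals, cell_size, c(0, nr * cell_size),
              nodata_mask = nodata_mask)
}

#' True suitability surface from known coefficients
#'
#' The ground-truth habitat suitability used by the synthetic study: the
#' inverse logit of a linear combination of the (standardized) covariate
#' layers. Used for parameter-recovery style checks; real analyses never see
#' this surface.
#'
#' @param stack an `env_stack`.
#' @param coefficients named numeric vector, one entry per covariate layer
#'   (missing names default to 0).
#' @param intercept scalar intercept on the logit scale.
#' @param standardize standardize each layer over valid cells before
#'   combining (default TRUE, so coefficients are per-SD effects).
#' @return list of class `true_suitability` with fields `coefficients`,
#'   `intercept`, and `surface` (a `raster_grid` of probabilities).
#' @export
make_true_suitability <- function(stack, coefficients, intercept = 0,
                                  standardize = TRUE) {
  extra <- setdiff(names(coefficients), names(stack$layers))
  if (length(extra))
    stop_invalid("coefficients name unknown layers: %s",
                 paste(extra, collapse = ", "))
  if (is.null(names(coefficients)) && length(coefficients) != length(stack$layers))
    stop_invalid("need one coefficient per covariate layer (%d), got %d",
                 length(stack$layers), length(coefficients))
  if (is.null(names(coefficients)))
    names(coefficients) <- names(stack$layers)
  ref <- stack$layers[[1]]
  lin <- matrix(intercept, nrow(ref$values), ncol(ref$values))
  mask <- Reduce(`|`, lapply(stack$layers, function(l) l$nodata_mask))
  for (nm in names(stack$layers)) {
    if (!nm %in% names(coefficients)) next
    b <- coefficients[[nm]]
    if (is.na(b) || b == 0) next
    v <- stack$layers[[nm]]$values
    if (standardize) {
      ok <- !mask
      mu <- mean(v[ok]); s <- stats::sd(v[ok])
      if (!is.finite(s) || s == 0) s <- 1
      v <- (v - mu) / s
    }
    lin <- lin + b * v
  }
  surf <- stats::plogis(lin)
  surf[mask] <- 0
  structure(
    list(coefficients = coefficients, intercept = intercept,
         surface = raster_grid(surf, ref$cell_size, ref$origin,
                               nodata_mask = mask)),
    class = "true_suitability")
}

#' Simulate whale-watching tours and their effort summary
#'
#' Each tour is a random out-and-back trackline starting at the harbor. If
#' `n_tours` is NULL, per-day tour counts over a 28-day month are drawn
#' Poisson with mean `tours_per_day`; otherwise the requested tours are
#' spread uniformly over days 1..28. Effort hours are
#' `hours_per_tour * n_tours`; search days count days with at least one tour.
#'
#' @param harbor (x, y) of the harbor, inside the grid extent.
#' @param grid a `raster_grid` supplying the extent (e.g. depth).
#' @param month_id "YYYY-MM".
#' @param n_tours number of tours, or NULL to draw from the daily rate.
#' @param seed integer seed.
#' @param hours_per_tour hours per tour (default 3).
#' @param tours_per_day mean daily tour rate when `n_tours` is NULL
#'   (default 1.43).
#' @param n_steps vertices per outbound leg.
#' @param step_len step length in meters (default 2 cells).
#' @return list with `tracklines` (list of `trackline`), `effort` (an
#'   `effort_record`), and `tour_days`.
#' @export
simulate_tours <- function(harbor, grid, month_id, n_tours = NULL, seed = 1,
                           hours_per_tour = 3, tours_per_day = 1.43,
                           n_steps = 20, step_len = NULL) {
  ext <- grid_extent(grid)
  if (harbor[1] < ext["xmin"] || harbor[1] > ext["xmax"] ||
      harbor[2] < ext["ymin"] || harbor[2] > ext["ymax"])
    stop_invalid("harbor (%g, %g) lies outside the grid extent",
                 harbor[1], harbor[2])
  if (!is.null(n_tours) && n_tours < 0)
    stop_invalid("n_tours must be non-negative")
  if (is.null(step_len)) step_len <- 2 * grid$cell_size
  set.seed(derive_seed(seed, "tours", month_id))
  if (is.null(n_tours)) {
    per_day <- stats::rpois(28, tours_per_day)
    tour_days <- rep(seq_len(28), per_day)
  } else if (n_tours == 0) {
    tour_days <- integer(0)
  } else {
    tour_days <- sort(sample.int(28, n_tours, replace = TRUE))
  }
  n <- length(tour_days)
  clamp <- function(p) c(
    min(max(p[1], ext["xmin"]), ext["xmax"] - 1e-6),
    min(max(p[2], ext["ymin"] + 1e-6), ext["ymax"]))
  tracklines <- vector("list", n)
  for (i in seq_len(n)) {
    # outbound leg: biased random walk heading away from the harbor (west,
    # into the bay), then the boat retraces its path home
    heading <- stats::runif(1, pi * 0.6, pi * 1.4)  # roughly westward
    pos <- harbor
    pts <- matrix(0, n_steps + 1, 2)
    pts[1, ] <- harbor
    for (s in seq_len(n_steps)) {
      heading <- heading + stats::rnorm(1, sd = 0.35)
      pos <- clamp(pos + step_len * c(cos(heading), sin(heading)))
      pts[s + 1, ] <- pos
    }
    verts <- rbind(pts, pts[n_steps:1, , drop = FALSE])  # out and back
    tracklines[[i]] <- trackline(verts, month_id)
  }
  days <- length(unique(tour_days))
  list(tracklines = tracklines,
       effort = effort_record(month_id, hours_per_tour * n, days),
       tour_days = tour_days)
}

#' Trackline constructor
#' @param vertices two-column matrix of (x, y) vertices, at least 2 rows.
#' @param month_id "YYYY-MM".
#' @return object of class `trackline`.
#' @export
trackline <- function(vertices, month_id) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 2 || ncol(vertices) != 2)
    stop_invalid("a trackline needs at least 2 (x, y) vertices")
  structure(list(vertices = unname(vertices), month_id = month_id),
            class = "trackline")
}

#' Sample presence points under effort-biased detection
#'
#' Cells are drawn with probability proportional to true suitability times a
#' trackline-proximity weight (the same kernel-smoothed line density used for
#' pseudo-absences, so the synthetic observation bias and its downstream
#' correction are commensurable). Points are placed uniformly inside their
#' cell; only water cells are eligible.
#'
#' @param suitability a `true_suitability`.
#' @param tracklines list of `trackline` (may be empty for unbiased
#'   sampling).
#' @param n_sightings number of presence points.
#' @param seed integer seed.
#' @param bandwidth density kernel bandwidth in cells.
#' @param month_id label attached to the returned points.
#' @return data.frame with columns `month_id`, `x`, `y`.
#' @export
sample_presences <- function(suitability, tracklines, n_sightings, seed = 1,
                             bandwidth = 2, month_id = NULL) {
  if (n_sightings < 0) stop_invalid("n_sightings must be non-negative")
  surf <- suitability$surface
  if (is.null(month_id))
    month_id <- if (length(tracklines)) tracklines[[1]]$month_id else "0000-00"
  if (n_sightings == 0)
    return(data.frame(month_id = character(0), x = numeric(0),
                      y = numeric(0)))
  w <- surf$values
  w[surf$nodata_mask] <- 0
  if (length(tracklines)) {
    dens <- trackline_density(tracklines, surf, bandwidth = bandwidth)
    w <- w * dens$values$values
  }
  if (sum(w) <= 0)
    stop("presence generation failed: no water cells with positive weight under the tracklines",
         call. = FALSE)
  set.seed(derive_seed(seed, "presence", month_id))
  idx <- sample.int(length(w), n_sightings, replace = TRUE, prob = as.vector(w))
  nr <- nrow(w)
  rows <- ((idx - 1) %% nr) + 1
  cols <- ((idx - 1) %/% nr) + 1
  ctr <- cell_center(surf, rows, cols)
  cs <- surf$cell_size
  data.frame(
    month_id = month_id,
    x = ctr[, "x"] + stats::runif(n_sightings, -0.5, 0.5) * cs,
    y = ctr[, "y"] + stats::runif(n_sightings, -0.5, 0.5) * cs)
}
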