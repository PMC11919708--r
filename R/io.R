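#' Write a raster layer as an ESRI ASCII grid
#'
#' Plain-text single-band raster format (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header followed by rows north to south), readable
#' by any GIS. Values are written with 17 significant digits so the
#' write/read round trip is exact.
#'
#' @param grid a `raster_grid`.
#' @param path output file path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  nodata <- -9999
  v <- grid$values
  v[grid$nodata_mask] <- nodata
  ext <- grid_extent(grid)
  hdr <- c(sprintf("ncols %d", nc), sprintf("nrows %d", nr),
           sprintf("xllcorner %.10f", ext["xmin"]),
           sprintf("yllcorner %.10f", ext["ymin"]),
           sprintf("cellsize %.10f", grid$cell_size),
           sprintf("NODATA_value %d", nodata))
  rows <- apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid raster
#'
#' @param path file written by [write_raster()] (or any conforming ASCII
#'   grid).
#' @return a `raster_grid`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop_invalid("raster file not found: %s", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop_invalid("malformed ASCII grid %s: missing header field(s) %s", path,
                 paste(miss, collapse = ", "))
  nr <- hdr$nrows; nc <- hdr$ncols
  body <- lines[i:length(lines)]
  vals <- as.numeric(unlist(strsplit(trimws(body), "\\s+")))
  if (length(vals) != nr * nc)
    stop_invalid("malformed ASCII grid %s: expected %d values, found %d",
                 path, nr * nc, length(vals))
  m <- matrix(vals, nr, nc, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  mask <- m == nodata
  m[mask] <- 0
  origin <- c(hdr$xllcorner %||% 0,
              (hdr$yllcorner %||% 0) + nr * hdr$cellsize)
  raster_grid(m, hdr$cellsize, origin, nodata_mask = mask)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read or write point tables (presences, pseudo-absences)
#'
#' CSV with mandatory header `month_id,x,y` (comma-separated, UTF-8, "."
#' decimals). Malformed rows (non-numeric coordinates) are rejected with
#' their line numbers reported in the `n_rejected` / `rejected_lines`
#' attributes.
#'
#' @param path CSV file path.
#' @return data.frame with `month_id`, `x`, `y`.
#' @export
read_points <- function(path) {
  if (!file.exists(path)) stop_invalid("point file not found: %s", path)
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("month_id", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_invalid("point file %s is missing column(s): %s", path,
                 paste(miss, collapse = ", "))
  x <- suppressWarnings(as.numeric(df$x))
  y <- suppressWarnings(as.numeric(df$y))
  bad <- is.na(x) | is.na(y)
  out <- data.frame(month_id = df$month_id[!bad], x = x[!bad], y = y[!bad])
  attr(out, "n_rejected") <- sum(bad)
  attr(out, "rejected_lines") <- which(bad) + 1L  # +1 for the header line
  out
}

#' @rdname read_points
#' @param points data.frame with `month_id`, `x`, `y`.
#' @export
write_points <- function(points, path) {
  utils::write.csv(points[c("month_id", "x", "y")], path, row.names = FALSE)
  invisible(path)
}

#' Read or write monthly effort tables
#'
#' CSV with header `month_id,effort_hours,search_days`.
#'
#' @param path CSV file path.
#' @return list of `effort_record`.
#' @export
read_effort <- function(path) {
  if (!file.exists(path)) stop_invalid("effort file not found: %s", path)
  df <- utils::read.csv(path)
  need <- c("month_id", "effort_hours", "search_days")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_invalid("effort file %s is missing column(s): %s", path,
                 paste(miss, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    effort_record(df$month_id[i], df$effort_hours[i], df$search_days[i]))
}

#' @rdname read_effort
#' @param records list of `effort_record`.
#' @export
write_effort <- function(records, path) {
  df <- data.frame(
    month_id = vapply(records, `[[`, character(1), "month_id"),
    effort_hours = vapply(records, `[[`, numeric(1), "effort_hours"),
    search_days = vapply(records, `[[`, integer(1), "search_days"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read or write tracklines as GeoJSON
#'
#' A FeatureCollection of LineString features, each carrying a `month_id`
#' property, in planar grid coordinates.
#'
#' @param path GeoJSON file path.
#' @return list of `trackline`.
#' @export
read_tracklines <- function(path) {
  if (!file.exists(path)) stop_invalid("trackline file not found: %s", path)
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features))
    stop_invalid("trackline file %s is not a GeoJSON FeatureCollection", path)
  lapply(gj$features, function(ft) {
    coords <- do.call(rbind, lapply(ft$geometry$coordinates, function(c2)
      c(c2[[1]], c2[[2]])))
    trackline(coords, ft$properties$month_id %||% "0000-00")
  })
}

#' @rdname read_tracklines
#' @param tracklines list of `trackline`.
#' @export
write_tracklines <- function(tracklines, path) {
  features <- lapply(tracklines, function(tl) {
    list(type = "Feature",
         properties = list(month_id = tl$month_id),
         geometry = list(
           type = "LineString",
           coordinates = lapply(seq_len(nrow(tl$vertices)), function(i)
             as.list(unname(tl$vertices[i, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

fmt_num <- function(x) sprintf("%.17g", x)

write_matrix_block <- function(con, name, m) {
  writeLines(sprintf("matrix %s %d %d", name, nrow(m), ncol(m)), con)
  writeLines(apply(m, 1, function(r) paste(fmt_num(r), collapse = " ")), con)
}

#' Serialize a fitted model to a structured text file
#'
#' Plain-text key/value + matrix-block format with 17-significant-digit
#' doubles, so the round trip reproduces every parameter exactly. Covers
#' both model classes.
#'
#' @param model a `maxent_model` or `mlp_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(model, "maxent_model")) {
    writeLines("model maxent", con)
    writeLines(sprintf("beta %s", fmt_num(model$beta)), con)
    writeLines(sprintf("m %d", model$m), con)
    writeLines(sprintf("n %d", model$n), con)
    writeLines(sprintf("lp_normalizer %s",
                       fmt_num(model$linear_predictor_normalizer)), con)
    writeLines(sprintf("density_normalizer %s",
                       fmt_num(model$density_normalizer)), con)
    writeLines(sprintf("entropy %s", fmt_num(model$entropy)), con)
    writeLines(sprintf("converged %d", as.integer(model$converged)), con)
    writeLines(sprintf("n_features %d", length(model$eta)), con)
    for (j in seq_along(model$basis$features)) {
      f <- model$basis$features[[j]]
      writeLines(sprintf("feature %s %s %s %s %s %s %s %s",
                         f$covariate, f$direction, fmt_num(f$knot),
                         fmt_num(f$scale), fmt_num(f$lo), fmt_num(f$hi),
                         fmt_num(model$eta[j]), fmt_num(model$lambda[j])),
                 con)
    }
  } else if (inherits(model, "mlp_model")) {
    writeLines("model mlp", con)
    writeLines(sprintf("layer_sizes %s",
                       paste(model$layer_sizes, collapse = " ")), con)
    writeLines(sprintf("seed %d", model$seed), con)
    writeLines(sprintf("provenance %s",
                       paste(model$provenance, collapse = " ")), con)
    if (!is.null(model$standardization)) {
      writeLines(sprintf("std_mean %s",
                         paste(fmt_num(model$standardization$mean),
                               collapse = " ")), con)
      writeLines(sprintf("std_sd %s",
                         paste(fmt_num(model$standardization$sd),
                               collapse = " ")), con)
    }
    for (l in seq_along(model$W)) {
      write_matrix_block(con, sprintf("W%d", l), model$W[[l]])
      write_matrix_block(con, sprintf("b%d", l),
                         matrix(model$b[[l]], nrow = 1))
    }
  } else stop_invalid("unknown model class: %s", class(model)[1])
  invisible(path)
}

#' Read a model serialized by [write_model()]
#' @param path file path.
#' @return a `maxent_model` or `mlp_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop_invalid("model file not found: %s", path)
  lines <- readLines(path)
  kind <- strsplit(lines[1], " ")[[1]][2]
  kv <- function(key) {
    ln <- grep(paste0("^", key, " "), lines, value = TRUE)
    if (!length(ln)) return(NULL)
    sub(paste0("^", key, " "), "", ln[1])
  }
  if (kind == "maxent") {
    fl <- grep("^feature ", lines, value = TRUE)
    feats <- list(); eta <- numeric(0); lambda <- numeric(0)
    for (ln in fl) {
      p <- strsplit(ln, " ")[[1]]
      feats[[length(feats) + 1L]] <- list(
        covariate = p[2], direction = p[3], knot = as.numeric(p[4]),
        scale = as.numeric(p[5]), lo = as.numeric(p[6]),
        hi = as.numeric(p[7]))
      eta <- c(eta, as.numeric(p[8]))
      lambda <- c(lambda, as.numeric(p[9]))
    }
    basis <- structure(
      list(features = feats,
           covariates = unique(vapply(feats, `[[`, character(1),
                                      "covariate")),
           dropped = character(0)),
      class = "hinge_basis")
    structure(
      list(eta = eta, basis = basis, beta = as.numeric(kv("beta")),
           lambda = lambda, m = as.integer(kv("m")), n = as.integer(kv("n")),
           gain_history = numeric(0), gain = NA_real_,
           converged = kv("converged") == "1",
           linear_predictor_normalizer = as.numeric(kv("lp_normalizer")),
           density_normalizer = as.numeric(kv("density_normalizer")),
           entropy = as.numeric(kv("entropy"))),
      class = "maxent_model")
  } else if (kind == "mlp") {
    sizes <- as.integer(strsplit(kv("layer_sizes"), " ")[[1]])
    W <- list(); b <- list()
    i <- 1
    while (i <= length(lines)) {
      if (grepl("^matrix ", lines[i])) {
        p <- strsplit(lines[i], " ")[[1]]
        nr <- as.integer(p[3]); nc <- as.integer(p[4])
        block <- lines[(i + 1):(i + nr)]
        m <- matrix(as.numeric(unlist(strsplit(block, " "))), nr, nc,
                    byrow = TRUE)
        if (grepl("^W", p[2])) W[[length(W) + 1L]] <- m
        else b[[length(b) + 1L]] <- as.vector(m)
        i <- i + nr + 1
      } else i <- i + 1
    }
    st <- NULL
    if (!is.null(kv("std_mean")))
      st <- list(
        mean = stats::setNames(as.numeric(strsplit(kv("std_mean"), " ")[[1]]),
                               COVARIATE_NAMES),
        sd = stats::setNames(as.numeric(strsplit(kv("std_sd"), " ")[[1]]),
                             COVARIATE_NAMES))
    prov <- kv("provenance")
    structure(
      list(layer_sizes = sizes, W = W, b = b, standardization = st,
           history = numeric(0),
           provenance = if (is.null(prov) || prov == "") character(0)
                        else strsplit(prov, " ")[[1]],
           seed = as.integer(kv("seed"))),
      class = "mlp_model")
  } else stop_invalid("unknown serialized model kind: %s", kind)
}

#' Ingest a downloaded copy of the study's deposited dataset
#'
#' Optional adapter for a local directory holding the deposited survey data
#' (never fetched over the network). The expected layout, finalized against
#' the deposit's own README, is documented here as the adapter's contract:
#' `sightings.csv` (month_id, x, y), `effort.csv` (month_id, effort_hours,
#' search_days), `tracklines.geojson`, and a `rasters/` directory with one
#' `<layer>_<month_id>.asc` per covariate per month (static layers may omit
#' the month suffix). Pre-projection to one planar grid is the caller's
#' responsibility.
#'
#' @param directory path to the unpacked deposit.
#' @return list with `sightings`, `effort`, `tracklines`, `raster_dir`.
#' @export
zenodo_adapter <- function(directory) {
  if (!dir.exists(directory))
    stop("optional adapter, dataset not present: directory does not exist: ",
         directory, call. = FALSE)
  expected <- c("sightings.csv", "effort.csv", "tracklines.geojson",
                "rasters")
  found <- list.files(directory)
  missing <- setdiff(expected, found)
  if (length(missing))
    stop_invalid(paste0(
      "deposit layout mismatch in %s\n  expected: %s\n  found: %s\n",
      "  missing: %s"),
      directory, paste(expected, collapse = ", "),
      paste(found, collapse = ", "), paste(missing, collapse = ", "))
  list(sightings = read_points(file.path(directory, "sightings.csv")),
       effort = read_effort(file.path(directory, "effort.csv")),
       tracklines = read_tracklines(file.path(directory,
                                              "tracklines.geojson")),
       raster_dir = file.path(directory, "rasters"))
}

#' Write a plain-text run manifest
#'
#' Records the configuration snapshot, the seed registry, every output file
#' with its md5 checksum, and per-stage row/cell counts, so a finished run
#' is auditable and reproducible.
#'
#' @param path manifest file path.
#' @param config named list (config snapshot).
#' @param seeds named list or vector of seeds.
#' @param files character vector of output file paths.
#' @param counts named list of stage counts.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seeds, files, counts = list()) {
  lines <- c("# run manifest", "", "[config]")
  for (nm in names(config))
    lines <- c(lines, sprintf("%s = %s", nm,
                              paste(format(config[[nm]]), collapse = " ")))
  lines <- c(lines, "", "[seeds]")
  for (nm in names(seeds))
    lines <- c(lines, sprintf("%s = %s", nm, format(seeds[[nm]])))
  lines <- c(lines, "", "[counts]")
  for (nm in names(counts))
    lines <- c(lines, sprintf("%s = %s", nm, format(counts[[nm]])))
  lines <- c(lines, "", "[files]")
  for (f in files) {
    sum <- unname(tools::md5sum(f))
    lines <- c(lines, sprintf("%s md5=%s", f, sum))
  }
  writeLines(lines, path)
  invisible(path)
}
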