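#' Construct a bathymetry grid
#'
#' A regular lon/lat grid of seafloor depth, metres positive-down. The value
#' matrix is stored with rows running south to north and columns west to
#' east, so `depth[i, j]` sits at cell centre
#' (`xmin + (j - 0.5) * cellsize`, `ymin + (i - 0.5) * cellsize`).
#'
#' @param depth Numeric matrix of depths (m, >= 0), rows south->north.
#' @param xmin,ymin Longitude/latitude of the grid's south-west corner
#'   (cell edge, not centre), decimal degrees.
#' @param cellsize Cell size in decimal degrees (> 0).
#' @return An object of class `bathy_grid`.
#' @export
bathy_grid <- function(depth, xmin, ymin, cellsize) {
  if (!is.matrix(depth)) depth <- as.matrix(depth)
  if (cellsize <= 0) stop_divetrip("cellsize must be > 0", "divetrip_config_error")
  if (any(!is.finite(depth)) || any(depth < 0)) {
    stop_divetrip("depths must be finite and >= 0 (positive-down)", "divetrip_config_error")
  }
  structure(list(depth = depth, xmin = xmin, ymin = ymin, cellsize = cellsize,
                 n_rows = nrow(depth), n_cols = ncol(depth)),
            class = "bathy_grid")
}

#' @export
print.bathy_grid <- function(x, ...) {
  cat(sprintf("bathy_grid: %d x %d cells of %g deg, origin (%.4f, %.4f), depth %.1f-%.1f m\n",
              x$n_rows, x$n_cols, x$cellsize, x$xmin, x$ymin,
              min(x$depth), max(x$depth)))
  invisible(x)
}

# cell-centre coordinate vectors
bathy_x <- function(g) g$xmin + (seq_len(g$n_cols) - 0.5) * g$cellsize
bathy_y <- function(g) g$ymin + (seq_len(g$n_rows) - 0.5) * g$cellsize

#' Seafloor depth at arbitrary points, bilinear interpolation
#'
#' Interpolates between the four surrounding cell centres; points within half
#' a cell of the grid edge use the edge value. Points outside the grid
#' extent return `NA` (the caller decides whether that is an error).
#'
#' @param grid A [bathy_grid()].
#' @param lon,lat Query coordinates, decimal degrees.
#' @return Numeric vector of depths (m), `NA` outside the grid.
#' @export
bathy_depth_at <- function(grid, lon, lat) {
  nx <- grid$n_cols; ny <- grid$n_rows; cs <- grid$cellsize
  # fractional index into cell-centre space
  fx <- (lon - grid$xmin) / cs - 0.5
  fy <- (lat - grid$ymin) / cs - 0.5
  out <- rep(NA_real_, length(fx))
  inside <- lon >= grid$xmin & lon <= grid$xmin + nx * cs &
    lat >= grid$ymin & lat <= grid$ymin + ny * cs
  if (!any(inside)) return(out)
  fx <- pmin(pmax(fx[inside], 0), nx - 1)
  fy <- pmin(pmax(fy[inside], 0), ny - 1)
  j0 <- pmin(floor(fx) + 1, nx - 1); i0 <- pmin(floor(fy) + 1, ny - 1)
  tx <- fx - (j0 - 1); ty <- fy - (i0 - 1)
  d <- grid$depth
  v <- d[cbind(i0, j0)] * (1 - tx) * (1 - ty) +
    d[cbind(i0, j0 + 1)] * tx * (1 - ty) +
    d[cbind(i0 + 1, j0)] * (1 - tx) * ty +
    d[cbind(i0 + 1, j0 + 1)] * tx * ty
  out[inside] <- v
  out
}

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) {
    stop_divetrip(sprintf("file not found: %s", path), "divetrip_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_divetrip(sprintf("%s: missing column(s): %s", path,
                          paste(missing, collapse = ", ")),
                  "divetrip_format_error")
  }
  df
}

sort_validate_series <- function(df, what) {
  df <- df[order(df$timestamp), , drop = FALSE]
  rownames(df) <- NULL
  if (anyDuplicated(as.numeric(df$timestamp))) {
    stop_divetrip(sprintf("%s: duplicate timestamps", what), "divetrip_integrity_error")
  }
  df
}

#' Read a GPS track CSV
#'
#' Expects columns `individual_id,timestamp,lon,lat` with timezone-aware
#' ISO-8601 timestamps. Rows may arrive unsorted; they are sorted by time.
#' Duplicate timestamps are an integrity error, never silently dropped.
#'
#' @param path CSV file path.
#' @return A data.frame of class `track` with `individual_id`, `timestamp`
#'   (POSIXct UTC), `lon`, `lat`.
#' @export
read_track_csv <- function(path) {
  df <- read_checked_csv(path, c("individual_id", "timestamp", "lon", "lat"))
  df$timestamp <- parse_iso8601(df$timestamp)
  if (any(!is.finite(df$lon)) || any(!is.finite(df$lat)) ||
      any(abs(df$lat) > 90) || any(abs(df$lon) > 360)) {
    stop_divetrip(sprintf("%s: invalid coordinates", path), "divetrip_format_error")
  }
  df <- sort_validate_series(df, path)
  class(df) <- c("track", "data.frame")
  df
}

#' Read a pressure/depth series CSV
#'
#' Expects columns `individual_id,timestamp,depth_m` (depth positive-down).
#' Same sorting and duplicate rules as [read_track_csv()].
#'
#' @param path CSV file path.
#' @return A data.frame of class `pressure_series`.
#' @export
read_pressure_csv <- function(path) {
  df <- read_checked_csv(path, c("individual_id", "timestamp", "depth_m"))
  df$timestamp <- parse_iso8601(df$timestamp)
  if (any(!is.finite(df$depth_m))) {
    stop_divetrip(sprintf("%s: non-numeric depth_m", path), "divetrip_format_error")
  }
  df <- sort_validate_series(df, path)
  class(df) <- c("pressure_series", "data.frame")
  df
}

#' Read a diet sample CSV
#'
#' Columns `sample_id,individual_id,sex,year,species,count,length_cm,identifiable`;
#' one row per prey item record. `length_cm` is `NA` unless the item was whole
#' and measurable. Samples with no identifiable remains appear as a single row
#' with empty `species`, `count` 0 and `identifiable` FALSE.
#'
#' @param path CSV file path.
#' @return A data.frame of class `diet_samples`.
#' @export
read_diet_csv <- function(path) {
  df <- read_checked_csv(path, c("sample_id", "individual_id", "sex", "year",
                                 "species", "count", "length_cm", "identifiable"))
  df$identifiable <- as.logical(df$identifiable)
  if (any(df$count < 0, na.rm = TRUE)) {
    stop_divetrip(sprintf("%s: negative prey counts", path), "divetrip_format_error")
  }
  class(df) <- c("diet_samples", "data.frame")
  df
}

#' Write a track / pressure series / diet table to CSV
#'
#' Writers emit exactly the dialect the readers accept, so every write->read
#' round-trip reproduces the in-memory value.
#'
#' @param x Object to write.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(x, path) {
  out <- data.frame(individual_id = x$individual_id,
                    timestamp = format_iso8601(x$timestamp),
                    lon = x$lon, lat = x$lat)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_track_csv
#' @export
write_pressure_csv <- function(x, path) {
  out <- data.frame(individual_id = x$individual_id,
                    timestamp = format_iso8601(x$timestamp),
                    depth_m = x$depth_m)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_track_csv
#' @export
write_diet_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read bathymetry from an ESRI ASCII grid
#'
#' Values are interpreted as elevation (sea negative) and converted to
#' positive-down depth. Land cells (elevation > 0) are clamped to depth 0;
#' their count is attached as attribute `n_land_clamped` and reported in a
#' warning. Grids whose coordinates cannot be geographic (|x| > 360 or
#' |y| > 90) are rejected: projected rasters are not supported.
#'
#' @param path `.asc` file path.
#' @return A [bathy_grid()].
#' @export
read_bathymetry <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop_divetrip(sprintf("%s: incomplete ESRI ASCII header", path),
                  "divetrip_format_error")
  }
  xmax <- hdr$xllcorner + hdr$ncols * hdr$cellsize
  ymax <- hdr$yllcorner + hdr$nrows * hdr$cellsize
  if (abs(hdr$xllcorner) > 360 || abs(xmax) > 360 ||
      abs(hdr$yllcorner) > 90 || abs(ymax) > 90) {
    stop_divetrip(sprintf(
      "%s: coordinates outside lon/lat range; projected rasters unsupported", path),
      "divetrip_crs_error")
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop_divetrip(sprintf("%s: expected %d values, found %d", path,
                          hdr$ncols * hdr$nrows, length(vals)),
                  "divetrip_format_error")
  }
  nodata <- hdr[["nodata_value"]]
  if (!is.null(nodata)) vals[vals == nodata] <- NA
  if (anyNA(vals)) {
    stop_divetrip(sprintf("%s: NODATA cells inside extent", path),
                  "divetrip_format_error")
  }
  # ASCII rows run north->south; flip to internal south->north
  elev <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  elev <- elev[hdr$nrows:1, , drop = FALSE]
  n_land <- sum(elev > 0)
  if (n_land > 0) {
    warning(sprintf("%d land cell(s) (elevation > 0) clamped to depth 0", n_land))
  }
  depth <- pmax(-elev, 0)
  g <- bathy_grid(depth, hdr$xllcorner, hdr$yllcorner, hdr$cellsize)
  attr(g, "n_land_clamped") <- n_land
  g
}

#' Write bathymetry as an ESRI ASCII grid
#'
#' Depths are written as negative elevations so [read_bathymetry()] recovers
#' the same grid (depth-0 cells round-trip as elevation 0).
#'
#' @param grid A [bathy_grid()].
#' @param path Destination `.asc` path.
#' @return `path`, invisibly.
#' @export
write_bathymetry <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.10g", grid$xmin),
    sprintf("yllcorner %.10g", grid$ymin),
    sprintf("cellsize %.10g", grid$cellsize),
    "NODATA_value -9999"
  ), con)
  elev <- -grid$depth
  for (i in grid$n_rows:1) {
    writeLines(paste(format(elev[i, ], trim = TRUE, scientific = FALSE),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Export points or grid-cell polygons as GeoJSON
#'
#' Minimal GeoJSON writers for dive locations (points) and 95% contour masks
#' (one square polygon per selected cell; cells are not dissolved).
#'
#' @param lon,lat Point coordinates.
#' @param properties Optional data.frame of per-point properties.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_points_geojson <- function(lon, lat, properties = NULL, path) {
  feats <- lapply(seq_along(lon), function(k) {
    props <- if (is.null(properties)) {
      structure(list(), names = character(0))
    } else {
      as.list(properties[k, , drop = FALSE])
    }
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = c(lon[k], lat[k])),
         properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_points_geojson
#' @param ud A utilization distribution (see [fit_kde()]).
#' @param mask Logical matrix of cells to export (e.g. from [contour_95()]).
#' @export
write_contour_geojson <- function(ud, mask, path) {
  cs <- ud$cellsize
  idx <- which(mask, arr.ind = TRUE)
  feats <- lapply(seq_len(nrow(idx)), function(k) {
    i <- idx[k, 1]; j <- idx[k, 2]
    x0 <- ud$xmin + (j - 1) * cs; y0 <- ud$ymin + (i - 1) * cs
    ring <- list(c(x0, y0), c(x0 + cs, y0), c(x0 + cs, y0 + cs),
                 c(x0, y0 + cs), c(x0, y0))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = list(mass = ud$mass[i, j]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
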