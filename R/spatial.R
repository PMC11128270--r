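#' Grid specification for utilization distributions
#'
#' @param xmin,ymin South-west corner (cell edge), decimal degrees.
#' @param cellsize Cell size, degrees (> 0).
#' @param n_cols,n_rows Grid dimensions.
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(xmin, ymin, cellsize, n_cols, n_rows) {
  if (cellsize <= 0) stop_divetrip("cellsize must be > 0", "divetrip_config_error")
  structure(list(xmin = xmin, ymin = ymin, cellsize = cellsize,
                 n_cols = n_cols, n_rows = n_rows), class = "grid_spec")
}

#' Common grid covering a set of points with a kernel margin
#'
#' Bounding box of the points expanded by `margin_h` smoothing bandwidths on
#' each side, divided into `n_cells` columns (rows scaled by aspect ratio).
#'
#' @param lon,lat Point coordinates.
#' @param h Smoothing bandwidth (degrees).
#' @param margin_h Margin in units of `h`, default 5.
#' @param n_cells Target cells along the longer axis, default 200.
#' @return A [grid_spec()].
#' @export
grid_for_points <- function(lon, lat, h, margin_h = 5, n_cells = 200) {
  xr <- range(lon) + c(-1, 1) * margin_h * h
  yr <- range(lat) + c(-1, 1) * margin_h * h
  long <- max(diff(xr), diff(yr))
  cs <- long / n_cells
  grid_spec(xr[1], yr[1], cs,
            n_cols = ceiling(diff(xr) / cs), n_rows = ceiling(diff(yr) / cs))
}

#' Kernel utilization distribution on a grid
#'
#' Bivariate isotropic Gaussian kernel density of the points, evaluated at
#' cell centres and normalized to unit total mass over the grid (the
#' discretized utilization distribution). The bandwidth `h` is in the same
#' units as the coordinates — decimal degrees here, matching the common
#' practice of smoothing unprojected coordinates with a fixed h (e.g. 0.01);
#' for new studies an equal-area projection is preferable.
#'
#' @param lon,lat Point coordinates (>= 5 points).
#' @param h Smoothing bandwidth (> 0), default 0.01 degrees.
#' @param grid A [grid_spec()]; defaults to [grid_for_points()].
#' @return List of class `ud`: grid fields plus `mass` (n_rows x n_cols
#'   matrix summing to 1) and `n_points`.
#' @export
fit_kde <- function(lon, lat, h = 0.01, grid = NULL) {
  if (length(lon) < 5) {
    stop_divetrip("need >= 5 points for a kernel UD", "divetrip_insufficient_data")
  }
  if (h <= 0) stop_divetrip("h must be > 0", "divetrip_config_error")
  if (is.null(grid)) grid <- grid_for_points(lon, lat, h)
  gx <- grid$xmin + (seq_len(grid$n_cols) - 0.5) * grid$cellsize
  gy <- grid$ymin + (seq_len(grid$n_rows) - 0.5) * grid$cellsize
  # separable Gaussian kernel: density(y_i, x_j) = sum_k Ky[i,k] Kx[j,k]
  Kx <- exp(-outer(gx, lon, "-")^2 / (2 * h^2))
  Ky <- exp(-outer(gy, lat, "-")^2 / (2 * h^2))
  dens <- Ky %*% t(Kx)
  total <- sum(dens)
  if (total <= 0) {
    stop_divetrip("all kernel mass outside the grid", "divetrip_config_error")
  }
  structure(c(unclass(grid)[c("xmin", "ymin", "cellsize", "n_cols", "n_rows")],
              list(mass = dens / total, h = h, n_points = length(lon))),
            class = "ud")
}

#' @export
print.ud <- function(x, ...) {
  cat(sprintf("ud: %d x %d cells of %g deg, h = %g, %d points\n",
              x$n_rows, x$n_cols, x$cellsize, x$h, x$n_points))
  invisible(x)
}

#' 95% (or other level) kernel home-range contour
#'
#' The smallest set of cells, by descending density, whose cumulative mass
#' reaches the level. By construction the mask's mass lies in
#' \[level, level + max cell mass\].
#'
#' @param ud A `ud` from [fit_kde()].
#' @param level Cumulative mass level, default 0.95.
#' @return List: `mask` (logical matrix), `mass` (mass inside the mask),
#'   `area_cells` (cell count), `area_deg2`.
#' @export
contour_95 <- function(ud, level = 0.95) {
  o <- order(ud$mass, decreasing = TRUE)
  cum <- cumsum(ud$mass[o])
  k <- which(cum >= level)[1]
  mask <- matrix(FALSE, ud$n_rows, ud$n_cols)
  mask[o[seq_len(k)]] <- TRUE
  list(mask = mask, mass = cum[k], area_cells = k,
       area_deg2 = k * ud$cellsize^2)
}

#' Bhattacharyya affinity between two utilization distributions
#'
#' `BA = sum_cells sqrt(p_i q_i)`, the discretized Bhattacharyya coefficient:
#' 0 for disjoint support, 1 for identical distributions. Both UDs must live
#' on the identical grid; mismatched grids are an error (no silent
#' resampling).
#'
#' @param ud_a,ud_b Two `ud` objects on the same grid.
#' @return BA in \[0, 1\].
#' @export
bhattacharyya_affinity <- function(ud_a, ud_b) {
  same <- isTRUE(all.equal(ud_a[c("xmin", "ymin", "cellsize", "n_cols", "n_rows")],
                           ud_b[c("xmin", "ymin", "cellsize", "n_cols", "n_rows")]))
  if (!same) {
    stop_divetrip("utilization distributions are on different grids",
                  "divetrip_grid_mismatch")
  }
  sum(sqrt(ud_a$mass * ud_b$mass))
}

#' Male-female foraging overlap by year
#'
#' Pools each sex's dive locations per year, fits both kernel UDs on a common
#' per-year grid, and reports Bhattacharyya affinity. Optionally the UDs are
#' first masked to their 95% contours (and renormalized), since "overlap of
#' home ranges" is sometimes computed that way; the full-UD value is the
#' default and standard definition.
#'
#' @param dives Classified dive table with `lon`, `lat`, plus `sex`, `year`.
#' @param h Smoothing bandwidth, default 0.01 degrees.
#' @param n_cells Grid resolution (cells along the longer axis), default 200.
#' @param mask_to_95 Mask UDs to their 95% contours before BA, default FALSE.
#' @param min_points Minimum dive locations per sex per year, default 5.
#' @return data.frame: `year`, `ba`, `n_male`, `n_female`. Years missing a
#'   sex are skipped with a warning.
#' @export
sex_overlap_by_year <- function(dives, h = 0.01, n_cells = 200,
                                mask_to_95 = FALSE, min_points = 5) {
  out <- list()
  for (yr in sort(unique(dives$year))) {
    sub <- dives[dives$year == yr & !is.na(dives$lon), , drop = FALSE]
    m <- sub[sub$sex == "M", ]; f <- sub[sub$sex == "F", ]
    if (nrow(m) < min_points || nrow(f) < min_points) {
      warning(sprintf("year %s: a sex has < %d dive locations; skipped",
                      yr, min_points))
      next
    }
    grid <- grid_for_points(c(m$lon, f$lon), c(m$lat, f$lat), h,
                            n_cells = n_cells)
    ud_m <- fit_kde(m$lon, m$lat, h, grid)
    ud_f <- fit_kde(f$lon, f$lat, h, grid)
    if (mask_to_95) {
      for (nm in c("ud_m", "ud_f")) {
        u <- get(nm)
        msk <- contour_95(u)$mask
        u$mass[!msk] <- 0
        u$mass <- u$mass / sum(u$mass)
        assign(nm, u)
      }
    }
    out[[as.character(yr)]] <- data.frame(
      year = yr, ba = bhattacharyya_affinity(ud_m, ud_f),
      n_male = nrow(m), n_female = nrow(f))
  }
  res <- do.call(rbind, out) %||% data.frame(year = integer(), ba = numeric(),
                                             n_male = integer(),
                                             n_female = integer())
  rownames(res) <- NULL
  res
}
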