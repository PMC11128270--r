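#' Zero-offset correction of a pressure series
#'
#' Pressure sensors drift, so the "surface" reads a slowly varying non-zero
#' depth. The correction estimates a rolling surface baseline as a low
#' quantile of depth within a sliding window, subtracts it, and clips the
#' result at 0. The baseline is computed per block (`window_s / 12` wide) as
#' the block's `quantile`, then the running minimum of block quantiles over
#' the full window, linearly interpolated between block centres — any window
#' this long contains genuine surface samples, so dive-dense blocks cannot
#' inflate the baseline. Applying the correction twice is a no-op (after the
#' first pass the surface sits at exactly 0).
#'
#' @param series A `pressure_series` data.frame (`timestamp`, `depth_m`).
#' @param window_s Sliding window width in seconds (default 2 h).
#' @param quantile Lower quantile taken as the surface (default 0.05).
#' @return The corrected `pressure_series`.
#' @export
zero_offset_correct <- function(series, window_s = 7200, quantile = 0.05) {
  if (nrow(series) == 0) {
    stop_divetrip("empty pressure series", "divetrip_validation_error")
  }
  if (window_s <= 0) stop_divetrip("window_s must be > 0", "divetrip_config_error")
  t <- as.numeric(series$timestamp)
  d <- series$depth_m
  block_s <- max(window_s / 12, 60)
  blk <- floor((t - t[1]) / block_s)
  q <- tapply(d, blk, stats::quantile, probs = quantile, names = FALSE)
  centres <- (as.numeric(names(q)) + 0.5) * block_s + t[1]
  half <- ceiling((window_s / block_s - 1) / 2)
  n <- length(q)
  base <- vapply(seq_len(n), function(i) {
    min(q[max(1, i - half):min(n, i + half)])
  }, 0)
  baseline <- if (n == 1) rep(base, length(t)) else {
    stats::approx(centres, base, xout = t, rule = 2)$y
  }
  out <- series
  out$depth_m <- pmax(d - baseline, 0)
  out
}

#' Detect dives by threshold segmentation
#'
#' A dive is a maximal run of consecutive samples with depth strictly greater
#' than `min_depth_m`. Single-sample dives are retained: discarding them
#' would bias the shallow tail of the depth distribution, which matters for
#' shallow-diving females. Edge refinement is a separate step
#' ([interpolate_dive_edges()]).
#'
#' @param series A corrected `pressure_series`.
#' @param min_depth_m Detection threshold in metres (default 1).
#' @return data.frame, one row per dive: `dive_id`, sample index range
#'   (`i_first`, `i_last`), raw first/last sample times, raw `max_depth_m`.
#' @export
detect_dives <- function(series, min_depth_m = 1) {
  if (min_depth_m <= 0) stop_divetrip("min_depth_m must be > 0", "divetrip_config_error")
  wet <- series$depth_m > min_depth_m
  if (!any(wet)) {
    return(data.frame(dive_id = integer(), i_first = integer(), i_last = integer(),
                      raw_first = as.POSIXct(character(), tz = "UTC"),
                      raw_last = as.POSIXct(character(), tz = "UTC"),
                      max_depth_m = numeric()))
  }
  r <- rle(wet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  i1 <- starts[keep]; i2 <- ends[keep]
  data.frame(dive_id = seq_along(i1), i_first = i1, i_last = i2,
             raw_first = series$timestamp[i1], raw_last = series$timestamp[i2],
             max_depth_m = vapply(seq_along(i1), function(k) {
               max(series$depth_m[i1[k]:i2[k]])
             }, 0))
}

#' Refine dive edges by linear interpolation to the surface
#'
#' With a 4-s sampling interval the first in-dive sample is already well below
#' the surface, so raw sample spans underestimate dive duration. The start is
#' taken as the zero-depth crossing of the straight line through the first two
#' in-dive samples, clamped to the interval \[previous surface sample time,
#' first in-dive sample time\]; the end symmetrically uses the last two
#' samples and the following surface sample. Degenerate slopes (vertical edge,
#' equal depths) clamp to the neighbouring surface sample. Single-sample dives
#' fall back to the raw sample span widened by half a sampling interval each
#' side and are flagged `edge_fallback`.
#'
#' @param series The corrected `pressure_series` the dives were detected in.
#' @param dives Output of [detect_dives()].
#' @return `dives` with columns `start`, `end`, `duration_s`, `edge_fallback`.
#' @export
interpolate_dive_edges <- function(series, dives) {
  t <- as.numeric(series$timestamp)
  d <- series$depth_m
  dt <- if (length(t) > 1) stats::median(diff(t)) else 4
  n <- nrow(dives)
  start <- numeric(n); end <- numeric(n); fb <- logical(n)
  for (k in seq_len(n)) {
    i1 <- dives$i_first[k]; i2 <- dives$i_last[k]
    prev_t <- if (i1 > 1) t[i1 - 1] else t[i1] - dt
    next_t <- if (i2 < length(t)) t[i2 + 1] else t[i2] + dt
    if (i2 == i1) {
      start[k] <- t[i1] - dt / 2
      end[k] <- t[i1] + dt / 2
      fb[k] <- TRUE
      next
    }
    # descent line through first two in-dive samples
    s1 <- (d[i1 + 1] - d[i1]) / (t[i1 + 1] - t[i1])
    start[k] <- if (s1 > 0) t[i1] - d[i1] / s1 else prev_t
    start[k] <- min(max(start[k], prev_t), t[i1])
    # ascent line through last two in-dive samples
    s2 <- (d[i2 - 1] - d[i2]) / (t[i2] - t[i2 - 1])
    end[k] <- if (s2 > 0) t[i2] + d[i2] / s2 else next_t
    end[k] <- max(min(end[k], next_t), t[i2])
  }
  dives$start <- as.POSIXct(start, origin = "1970-01-01", tz = "UTC")
  dives$end <- as.POSIXct(end, origin = "1970-01-01", tz = "UTC")
  dives$duration_s <- end - start
  dives$edge_fallback <- fb
  dives
}

#' Per-dive summary statistics
#'
#' Maximum depth, duration (from interpolated edges) and vertical distance.
#' Vertical distance sums absolute depth changes over consecutive in-dive
#' samples plus the two interpolated edge legs (surface down to the first
#' sample, last sample back to the surface). Both depth and vertical distance
#' are underestimates at a 4-s cadence; no correction is attempted.
#'
#' @param series The corrected `pressure_series`.
#' @param dives Output of [interpolate_dive_edges()].
#' @return `dives` with `vertical_distance_m` added and `max_depth_m` updated.
#' @export
summarize_dives <- function(series, dives) {
  d <- series$depth_m
  dives$vertical_distance_m <- vapply(seq_len(nrow(dives)), function(k) {
    i1 <- dives$i_first[k]; i2 <- dives$i_last[k]
    prof <- d[i1:i2]
    prof[1] + prof[length(prof)] + sum(abs(diff(prof)))
  }, 0)
  dives
}

#' Post-dive surface intervals
#'
#' `interval_i = start_{i+1} - end_i` between consecutive dives; the last dive
#' has no defined interval (`NA`). Clamped edge interpolation guarantees
#' non-negative intervals; overlap indicates corrupted input and raises an
#' integrity error.
#'
#' @param dives Output of [interpolate_dive_edges()], sorted by start.
#' @return `dives` with column `post_dive_s` (`NA` for the last dive).
#' @export
post_dive_intervals <- function(dives) {
  n <- nrow(dives)
  if (n == 0) {
    dives$post_dive_s <- numeric(0)
    return(dives)
  }
  s <- as.numeric(dives$start); e <- as.numeric(dives$end)
  pdi <- c(s[-1] - e[-n], NA_real_)
  if (any(pdi < 0, na.rm = TRUE)) {
    stop_divetrip("overlapping dives", "divetrip_integrity_error")
  }
  dives$post_dive_s <- pdi
  dives
}

#' Full dive extraction for one deployment
#'
#' Convenience wrapper: zero-offset correction, threshold detection, edge
#' interpolation, summary statistics and post-dive intervals.
#'
#' @param series Raw `pressure_series`.
#' @param min_depth_m Dive detection threshold (m).
#' @param zoc_window_s,zoc_quantile Zero-offset correction settings.
#' @return List with `series` (corrected) and `dives` (full dive table).
#' @export
extract_dives <- function(series, min_depth_m = 1, zoc_window_s = 7200,
                          zoc_quantile = 0.05) {
  corrected <- zero_offset_correct(series, zoc_window_s, zoc_quantile)
  dives <- detect_dives(corrected, min_depth_m)
  dives <- interpolate_dive_edges(corrected, dives)
  dives <- summarize_dives(corrected, dives)
  dives <- post_dive_intervals(dives)
  if (nrow(dives) > 0 && "individual_id" %in% names(series)) {
    dives$individual_id <- series$individual_id[1]
  }
  list(series = corrected, dives = dives)
}
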