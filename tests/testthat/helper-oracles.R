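# Independent oracles and fixture builders shared across test files.

# Brute-force dive scan: walks the series sample by sample, opening a dive on
# the first sample above threshold and closing it on the first at/below.
# Deliberately naive and loop-based; detect_dives must match it exactly.
brute_force_dives <- function(depths, min_depth_m = 1) {
  out <- list()
  open <- FALSE
  for (i in seq_along(depths)) {
    if (!open && depths[i] > min_depth_m) {
      open <- TRUE
      first <- i
    } else if (open && depths[i] <= min_depth_m) {
      out[[length(out) + 1]] <- c(first, i - 1)
      open <- FALSE
    }
  }
  if (open) out[[length(out) + 1]] <- c(first, length(depths))
  if (length(out) == 0) matrix(integer(), ncol = 2) else do.call(rbind, out)
}

# Pressure series fixture from a depth vector at a fixed cadence.
make_series <- function(depths, interval_s = 4, t0 = "2021-10-01T00:00:00Z",
                        id = "TEST") {
  df <- data.frame(
    individual_id = rep(id, length(depths)),
    timestamp = divetrip:::parse_iso8601(t0) + (seq_along(depths) - 1) * interval_s,
    depth_m = depths)
  class(df) <- c("pressure_series", "data.frame")
  df
}

# Track fixture from lon/lat vectors at a fixed cadence.
make_track <- function(lon, lat, interval_s = 300, t0 = "2021-10-01T00:00:00Z",
                       id = "TEST") {
  df <- data.frame(
    individual_id = id,
    timestamp = divetrip:::parse_iso8601(t0) + (seq_along(lon) - 1) * interval_s,
    lon = lon, lat = lat)
  class(df) <- c("track", "data.frame")
  df
}

# Analytic Gaussian UD discretized on a grid (closed-form oracle, no KDE).
analytic_gaussian_ud <- function(mu, sd, grid) {
  gx <- grid$xmin + (seq_len(grid$n_cols) - 0.5) * grid$cellsize
  gy <- grid$ymin + (seq_len(grid$n_rows) - 0.5) * grid$cellsize
  m <- outer(stats::dnorm(gy, mu[2], sd), stats::dnorm(gx, mu[1], sd))
  structure(c(unclass(grid)[c("xmin", "ymin", "cellsize", "n_cols", "n_rows")],
              list(mass = m / sum(m), h = 0, n_points = 0)),
            class = "ud")
}

# Hand-built 5-sample toy diet table: 4 identifiable samples, 1 without
# remains. Expected values are computed by hand in the tests that use it.
toy_diet <- function() {
  df <- data.frame(
    sample_id = c("S1", "S1", "S2", "S2", "S3", "S4", "S5"),
    individual_id = paste0("B", c(1, 1, 2, 2, 3, 4, 5)),
    sex = c("M", "M", "M", "M", "F", "F", "F"),
    year = 2021L,
    species = c("soldierfish", "goby", "soldierfish", "soldierfish",
                "goby", "soldierfish", ""),
    count = c(1L, 2L, 1L, 1L, 3L, 1L, 0L),
    length_cm = c(10, NA, 12, 14, NA, 9, NA),
    identifiable = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  class(df) <- c("diet_samples", "data.frame")
  df
}

# Small cohort with truth, used by several recovery tests.
cohort_with_truth <- function(seed, n_males = 2, n_females = 2, n_days = 2,
                              ...) {
  cfg <- sim_config(n_males = n_males, n_females = n_females, n_days = n_days,
                    ...)
  simulate_cohort(cfg, seed = seed)
}

truth_dive_table <- function(cohort) {
  do.call(rbind, lapply(names(cohort$deployments), function(id) {
    d <- cohort$deployments[[id]]$truth$dives
    if (nrow(d) == 0) return(NULL)
    d$individual_id <- id
    d$sex <- substr(id, 1, 1)
    d$year <- cohort$individuals$year[cohort$individuals$individual_id == id]
    d
  }))
}
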