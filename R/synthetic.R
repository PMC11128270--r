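#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator, with defaults set to
#' the field conditions the pipeline is designed for: a temperate colonial
#' cormorant colony in a shelf sea, pressure logged every 4 s, GPS fixes
#' every 5 min, overwhelmingly benthic diving (96%), sex-specific foraging
#' depths (median 18 m for males, 8 m for females), mean foraging trip
#' duration 11.5 h, and an aerobic dive limit (ADL) that scales linearly with
#' body mass.
#'
#' @param seed Default RNG seed used when a generator call does not receive
#'   its own.
#' @param n_males,n_females Cohort composition (counts >= 0).
#' @param colony_lonlat Colony position, `c(lon, lat)` decimal degrees.
#' @param year Nominal study year attached to simulated deployments.
#' @param start_date Local calendar date the deployments begin (chick-rearing
#'   season).
#' @param n_days Deployment length in days.
#' @param tz_offset_h Local clock offset from UTC in hours (11 = AEDT).
#' @param gps_interval_s GPS fix cadence, seconds (> 0).
#' @param pressure_interval_s Pressure sampling cadence, seconds (> 0).
#' @param benthic_fraction Probability a generated dive is benthic, in \[0,1\].
#' @param male_depth_median_m,female_depth_median_m Target foraging depths
#'   (m) steering sex-specific destination-patch choice.
#' @param adl_intercept_s,adl_mass_slope_s_per_kg True ADL model:
#'   `adl = intercept + slope * mass_kg` (seconds).
#' @param depth_noise_sd_m SD of the depth deviation of a benthic dive's
#'   maximum depth around the local seafloor depth (m).
#' @param gps_noise_sd_m Isotropic GPS position noise, metres (applied in
#'   metres, then converted to degrees at the colony latitude).
#' @param sensor_noise_sd_m Per-sample pressure sensor noise (m).
#' @param sensor_drift_m Linear zero-offset drift of the pressure sensor over
#'   the whole deployment (m); exercised by zero-offset correction.
#' @param trip_duration_mean_h,trip_duration_sd_h Day-trip duration
#'   distribution (hours).
#' @param overnight_roost_prob Probability a trip extends overnight with the
#'   bird roosting stationary away from the colony.
#' @param sex_mixing In \[0,1\]: probability a trip's destination is drawn
#'   from a shared shallow habitat pool rather than the sex-typical pool.
#'   0 reproduces strong spatial sex segregation; 1 a high-overlap year.
#' @param patch_dist_range_km Admissible colony-to-patch distance (km).
#' @param flight_speed_kmh Commuting flight speed.
#' @param descent_rate_ms Vertical transit rate within dives (m/s).
#' @param bottom_time_range_s Uniform range of dive bottom-phase duration (s).
#' @param pdi_intercept_s,pdi_slope,pdi_hinge_slope,pdi_noise_mean_s
#'   Post-dive surface interval model: below the true ADL the interval is
#'   `intercept + slope * duration` plus exponential noise (mean
#'   `pdi_noise_mean_s`); above the ADL an extra `hinge_slope * (duration -
#'   adl)` recovery cost applies, producing the lower-envelope inflection the
#'   ADL estimator looks for.
#' @param rest_every_n_dives,rest_duration_s Occasional long surface rests
#'   interleaved in dive bouts.
#' @param male_mass_mean_kg,female_mass_mean_kg,mass_sd_kg Body mass model.
#' @param bathy_cellsize_deg Synthetic bathymetry resolution (degrees > 0).
#' @param bathy_halfwidth_deg,bathy_halfheight_deg Bathymetry half-extent
#'   around the colony (degrees).
#' @param flat_depth_m If non-NULL, the bathymetry is a constant field of
#'   this depth (diagnostics only).
#' @param diet_n_samples Number of regurgitate samples to simulate.
#' @param diet_years Years over which diet samples are spread.
#' @param identifiable_fraction Fraction of samples with identifiable remains.
#' @param whole_prey_prob Probability an identifiable prey item is whole
#'   (and so carries a length).
#' @param male_prey_length_cm,female_prey_length_cm,prey_length_sd_cm Whole
#'   prey length model (cm).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_males = 5L, n_females = 5L,
                       colony_lonlat = c(146.6758, -38.9403),
                       year = 2021L,
                       start_date = "2021-10-01",
                       n_days = 3L,
                       tz_offset_h = 11,
                       gps_interval_s = 300,
                       pressure_interval_s = 4,
                       benthic_fraction = 0.96,
                       male_depth_median_m = 18,
                       female_depth_median_m = 8,
                       adl_intercept_s = 20,
                       adl_mass_slope_s_per_kg = 20,
                       depth_noise_sd_m = 0.2,
                       gps_noise_sd_m = 30,
                       sensor_noise_sd_m = 0.03,
                       sensor_drift_m = 0.5,
                       trip_duration_mean_h = 11.5,
                       trip_duration_sd_h = 2,
                       overnight_roost_prob = 0.4,
                       sex_mixing = 0,
                       patch_dist_range_km = c(2, 25),
                       flight_speed_kmh = 45,
                       descent_rate_ms = 1.2,
                       bottom_time_range_s = c(4, 45),
                       pdi_intercept_s = 8,
                       pdi_slope = 0.25,
                       pdi_hinge_slope = 2,
                       pdi_noise_mean_s = 6,
                       rest_every_n_dives = 30,
                       rest_duration_s = 1200,
                       male_mass_mean_kg = 1.9,
                       female_mass_mean_kg = 1.5,
                       mass_sd_kg = 0.15,
                       bathy_cellsize_deg = 0.005,
                       bathy_halfwidth_deg = 0.35,
                       bathy_halfheight_deg = 0.22,
                       flat_depth_m = NULL,
                       diet_n_samples = 79L,
                       diet_years = 2020:2023,
                       identifiable_fraction = 0.86,
                       whole_prey_prob = 0.7,
                       male_prey_length_cm = 12.4,
                       female_prey_length_cm = 9.6,
                       prey_length_sd_cm = 2) {
  cfg <- as.list(environment())
  if (cfg$benthic_fraction < 0 || cfg$benthic_fraction > 1) {
    stop_divetrip("benthic_fraction must be in [0,1]", "divetrip_config_error")
  }
  if (cfg$sex_mixing < 0 || cfg$sex_mixing > 1) {
    stop_divetrip("sex_mixing must be in [0,1]", "divetrip_config_error")
  }
  if (cfg$identifiable_fraction < 0 || cfg$identifiable_fraction > 1) {
    stop_divetrip("identifiable_fraction must be in [0,1]", "divetrip_config_error")
  }
  for (f in c("gps_interval_s", "pressure_interval_s", "bathy_cellsize_deg")) {
    if (cfg[[f]] <= 0) {
      stop_divetrip(sprintf("%s must be > 0", f), "divetrip_config_error")
    }
  }
  if (cfg$n_males < 0 || cfg$n_females < 0) {
    stop_divetrip("counts must be >= 0", "divetrip_config_error")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic bathymetry grid
#'
#' Emulates the structure of a shelf-sea colony neighbourhood: a contiguous
#' shallow (1-15 m) basin to the north-west of the colony (a Corner-Inlet-like
#' embayment) grading into a 20-40 m offshore shelf to the south-east, with
#' mild deterministic texture. The field is a deterministic function of the
#' configuration, so identical configurations give bit-identical grids.
#'
#' @param config A [sim_config()].
#' @return A [bathy_grid()] whose extent contains the colony.
#' @export
generate_bathymetry <- function(config) {
  cs <- config$bathy_cellsize_deg
  if (cs <= 0) stop_divetrip("bathy_cellsize_deg must be > 0", "divetrip_config_error")
  lon0 <- config$colony_lonlat[1]; lat0 <- config$colony_lonlat[2]
  xmin <- lon0 - config$bathy_halfwidth_deg
  ymin <- lat0 - config$bathy_halfheight_deg
  n_cols <- ceiling(2 * config$bathy_halfwidth_deg / cs)
  n_rows <- ceiling(2 * config$bathy_halfheight_deg / cs)
  if (!is.null(config$flat_depth_m)) {
    return(bathy_grid(matrix(config$flat_depth_m, n_rows, n_cols), xmin, ymin, cs))
  }
  x <- xmin + (seq_len(n_cols) - 0.5) * cs
  y <- ymin + (seq_len(n_rows) - 0.5) * cs
  xn <- (x - xmin) / (n_cols * cs)           # 0 at west edge
  yn <- (y - ymin) / (n_rows * cs)           # 0 at south edge
  # NW (xn=0, yn=1) -> u=0 shallow; SE (xn=1, yn=0) -> u=1 deep
  u <- outer(1 - yn, xn, function(a, b) (a + b) / 2)
  depth <- 1 + 42 * u^1.3
  texture <- 0.8 * outer(sin(6 * pi * yn), cos(6 * pi * xn))
  depth <- pmax(depth + texture, 0.5)
  bathy_grid(depth, xmin, ymin, cs)
}

#' Simulate an instrumented cohort's metadata
#'
#' @param config A [sim_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return data.frame with `individual_id`, `sex`, `mass_kg`, `tarsus_mm`,
#'   `year`, and the true aerobic dive limit `adl_true_s`.
#' @export
simulate_individuals <- function(config, seed = config$seed) {
  set.seed(seed)
  n <- config$n_males + config$n_females
  sex <- rep(c("M", "F"), c(config$n_males, config$n_females))
  id <- sprintf("%s%02d", sex, c(seq_len(config$n_males),
                                 seq_len(config$n_females)))
  mass <- stats::rnorm(n, ifelse(sex == "M", config$male_mass_mean_kg,
                                 config$female_mass_mean_kg),
                       config$mass_sd_kg)
  mass <- pmax(mass, 0.8)
  data.frame(individual_id = id, sex = sex, mass_kg = mass,
             tarsus_mm = stats::rnorm(n, ifelse(sex == "M", 63, 59), 1.5),
             year = rep(config$year, n),
             adl_true_s = config$adl_intercept_s +
               config$adl_mass_slope_s_per_kg * mass)
}

# Eligible destination cells for a sex; `shared` pools both sexes into the
# shallow basin (high-overlap scenario).
eligible_patch_cells <- function(config, bathy, sex, shared = FALSE) {
  x <- bathy_x(bathy); y <- bathy_y(bathy)
  lon0 <- config$colony_lonlat[1]; lat0 <- config$colony_lonlat[2]
  band <- if (shared) {
    c(4, 14)
  } else if (sex == "F") {
    c(max(1, 0.5 * config$female_depth_median_m), 1.6 * config$female_depth_median_m)
  } else {
    c(0.7 * config$male_depth_median_m, 2.2 * config$male_depth_median_m)
  }
  idx <- which(bathy$depth >= band[1] & bathy$depth <= band[2], arr.ind = TRUE)
  if (nrow(idx) == 0) {
    stop_divetrip(sprintf("no bathymetry cells in depth band [%.1f, %.1f] m",
                          band[1], band[2]), "divetrip_config_error")
  }
  lon <- x[idx[, 2]]; lat <- y[idx[, 1]]
  d_km <- great_circle_distance(lon, lat, lon0, lat0) / 1000
  keep <- d_km >= config$patch_dist_range_km[1] &
    d_km <= config$patch_dist_range_km[2]
  if (!any(keep)) {
    stop_divetrip("no destination cells within patch_dist_range_km",
                  "divetrip_config_error")
  }
  # weight cells toward the sex-typical median depth so the realized depth
  # distribution centres on the configured median, not the band midpoint
  med <- if (shared) 9 else if (sex == "F") config$female_depth_median_m else
    config$male_depth_median_m
  dep <- bathy$depth[idx][keep]
  if (shared) {
    # high-overlap years arise from both sexes converging on the same few
    # prey patches, so the shared pool is a small deterministic hotspot set
    ord <- order(abs(dep - med))
    cand <- ord[seq_len(min(40, length(ord)))]
    hot <- cand[unique(round(seq(1, length(cand), length.out = 3)))]
    return(cbind(lon = lon[keep][hot], lat = lat[keep][hot],
                 w = rep(1, length(hot))))
  }
  cbind(lon = lon[keep], lat = lat[keep],
        w = stats::dnorm(dep, med, 0.35 * med) + 1e-12)
}

rtruncnorm1 <- function(mean, sd, lo, hi) {
  for (i in 1:50) {
    v <- stats::rnorm(1, mean, sd)
    if (v >= lo && v <= hi) return(v)
  }
  min(max(mean, lo), hi)
}

#' Simulate one GPS + pressure deployment with ground truth
#'
#' Generates an out-and-back central-place foraging deployment: daily trips
#' from the colony to a sex-typical destination patch (females in the shallow
#' basin, males on the deeper shelf, optionally mixed), a correlated random
#' walk at the patch, dive bouts restricted to daylight, and optional
#' overnight roosts (stationary away from the colony over local midnight).
#' Dives are benthic with probability `benthic_fraction` (maximum depth within
#' sensor noise of the seafloor at the dive's true location) and otherwise
#' pelagic (well clear of the seafloor, generated only where the seafloor is
#' deep enough to leave >5 m clearance). Post-dive surface intervals follow
#' the hinge model described in [sim_config()], so their lower envelope
#' inflects at the individual's true ADL.
#'
#' @param individual One row of [simulate_individuals()] (or an equivalent
#'   list with `individual_id`, `sex`, `mass_kg`).
#' @param config A [sim_config()].
#' @param bathy A [bathy_grid()] containing the colony.
#' @param seed RNG seed.
#' @return List with `track` (noisy GPS fixes), `pressure` (raw depth record
#'   including sensor drift and noise) and `truth` (true dives, trips, roost
#'   episodes and ADL).
#' @export
simulate_deployment <- function(individual, config, bathy, seed = config$seed) {
  if (is.null(individual$mass_kg) || individual$mass_kg <= 0) {
    stop_divetrip("individual mass must be > 0", "divetrip_validation_error")
  }
  lon0 <- config$colony_lonlat[1]; lat0 <- config$colony_lonlat[2]
  if (is.na(bathy_depth_at(bathy, lon0, lat0))) {
    stop_divetrip("colony outside bathymetry grid", "divetrip_validation_error")
  }
  set.seed(seed)
  id <- individual$individual_id
  adl <- config$adl_intercept_s + config$adl_mass_slope_s_per_kg * individual$mass_kg

  t0 <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC") -
    config$tz_offset_h * 3600
  record_end <- t0 + config$n_days * 86400
  days <- lapply(seq_len(config$n_days + 1) - 1, function(d) {
    solar_crossings(t0 + d * 86400, lon0, lat0)
  })

  # ---- trip schedule -------------------------------------------------------
  trips <- list(); d <- 0
  while (d < config$n_days) {
    sun <- days[[d + 1]]
    dep <- sun$sunrise + 900 + stats::rnorm(1, 0, 2700)
    dep <- min(max(dep, sun$sunrise - 1800), sun$sunrise + 4 * 3600)
    roost <- stats::runif(1) < config$overnight_roost_prob
    if (!roost) {
      dur_h <- rtruncnorm1(config$trip_duration_mean_h, config$trip_duration_sd_h,
                           3, 15)
      ret <- min(dep + dur_h * 3600, days[[d + 1]]$sunset + 1.5 * 3600)
      d_next <- d + 1
    } else {
      ret <- days[[d + 2]]$sunrise + 3600 + stats::rnorm(1, 0, 1800)
      d_next <- d + 2
    }
    shared <- stats::runif(1) < config$sex_mixing
    cells <- eligible_patch_cells(config, bathy, individual$sex, shared)
    pc <- if (shared) {
      # in a high-overlap year every bird tracks the same few prey
      # aggregations: successive trips cycle the common hotspots rather than
      # sampling them, so both sexes cover the full hotspot set
      cells[1 + length(trips) %% nrow(cells), c("lon", "lat")]
    } else {
      cells[sample.int(nrow(cells), 1, prob = cells[, "w"]), c("lon", "lat")]
    }
    trips[[length(trips) + 1]] <- list(departure = dep, return = ret,
                                       roost = roost, patch = pc,
                                       day = d)
    d <- d_next
  }

  # ---- true track (piecewise linear between true fixes) --------------------
  fix_times <- seq(from = as.numeric(t0), to = as.numeric(record_end),
                   by = config$gps_interval_s)
  lon <- rep(lon0, length(fix_times)); lat <- rep(lat0, length(fix_times))
  speed_ms <- config$flight_speed_kmh / 3.6
  mlat <- m_per_deg_lat(); mlon <- m_per_deg_lon(lat0)
  truth_trips <- data.frame()
  for (k in seq_along(trips)) {
    tr <- trips[[k]]
    dep <- as.numeric(tr$departure); ret <- as.numeric(tr$return)
    ret <- min(ret, as.numeric(record_end))
    dist_m <- great_circle_distance(tr$patch["lon"], tr$patch["lat"], lon0, lat0)
    transit_s <- dist_m / speed_ms
    arr <- dep + transit_s; leave <- ret - transit_s
    sel <- which(fix_times >= dep & fix_times <= ret)
    # OU walk at patch evaluated at fix times
    psd <- 150 / mlat
    cur <- c(tr$patch["lon"], tr$patch["lat"])
    roost_from <- if (tr$roost) as.numeric(days[[tr$day + 1]]$sunset) else Inf
    roost_to <- if (tr$roost) as.numeric(days[[tr$day + 2]]$sunrise) else -Inf
    roost_pos <- NULL
    for (s in sel) {
      tt <- fix_times[s]
      if (tt <= arr) {
        f <- (tt - dep) / transit_s
        lon[s] <- lon0 + f * (tr$patch["lon"] - lon0)
        lat[s] <- lat0 + f * (tr$patch["lat"] - lat0)
      } else if (tt >= leave) {
        f <- (ret - tt) / transit_s
        lon[s] <- lon0 + f * (tr$patch["lon"] - lon0)
        lat[s] <- lat0 + f * (tr$patch["lat"] - lat0)
      } else if (tt >= roost_from && tt <= roost_to) {
        if (is.null(roost_pos)) roost_pos <- cur
        lon[s] <- roost_pos[1] + stats::rnorm(1, 0, 3 / mlon)
        lat[s] <- roost_pos[2] + stats::rnorm(1, 0, 3 / mlat)
      } else {
        cur <- c(tr$patch["lon"], tr$patch["lat"]) +
          0.9 * (cur - c(tr$patch["lon"], tr$patch["lat"])) +
          c(stats::rnorm(1, 0, psd * mlat / mlon), stats::rnorm(1, 0, psd))
        lon[s] <- cur[1]; lat[s] <- cur[2]
      }
    }
    truth_trips <- rbind(truth_trips, data.frame(
      trip_id = sprintf("%s_T%02d", id, k),
      departure = as.POSIXct(dep, origin = "1970-01-01", tz = "UTC"),
      return = as.POSIXct(ret, origin = "1970-01-01", tz = "UTC"),
      roost = tr$roost,
      complete = ret < as.numeric(record_end),
      patch_lon = unname(tr$patch["lon"]), patch_lat = unname(tr$patch["lat"])))
  }

  interp_pos <- function(tt) {
    i <- findInterval(tt, fix_times, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1), length(fix_times) - 1)
    f <- (tt - fix_times[i]) / (fix_times[i + 1] - fix_times[i])
    cbind(lon = lon[i] + f * (lon[i + 1] - lon[i]),
          lat = lat[i] + f * (lat[i + 1] - lat[i]))
  }

  # ---- dives ---------------------------------------------------------------
  dives <- list()
  for (k in seq_len(nrow(truth_trips))) {
    tr <- trips[[k]]
    dep <- as.numeric(tr$departure); ret <- as.numeric(tr$return)
    dist_m <- great_circle_distance(tr$patch["lon"], tr$patch["lat"], lon0, lat0)
    transit_s <- dist_m / speed_ms
    windows <- list(c(max(dep + transit_s,
                          as.numeric(days[[tr$day + 1]]$sunrise) + 600),
                      min(ret - transit_s,
                          as.numeric(days[[tr$day + 1]]$sunset) - 600)))
    if (tr$roost && tr$day + 2 <= length(days)) {
      windows[[2]] <- c(as.numeric(days[[tr$day + 2]]$sunrise) + 600,
                        min(ret - transit_s, as.numeric(record_end)))
    }
    n_in_bout <- 0
    for (w in windows) {
      tt <- w[1]
      while (tt < w[2]) {
        pos <- interp_pos(tt)
        sf <- bathy_depth_at(bathy, pos[1], pos[2])
        if (is.na(sf)) break
        # pelagic dives need >5 m seafloor clearance to be generable at all;
        # over very shallow cells every dive necessarily touches the bottom
        benthic <- stats::runif(1) < config$benthic_fraction || sf < 12
        if (benthic) {
          # noise truncated at +/- 3 sd: a benthic dive's max depth is the
          # seafloor plus bounded sensor/posture error, never an outlier
          eps <- max(-3, min(3, stats::rnorm(1))) * config$depth_noise_sd_m
          z <- max(1.5, sf + eps)
        } else {
          z <- stats::runif(1, 0.25, 0.55) * sf
          z <- max(1.5, min(z, sf - 6.5))
        }
        bt <- stats::runif(1, config$bottom_time_range_s[1],
                           config$bottom_time_range_s[2])
        dur <- 2 * z / config$descent_rate_ms + bt
        pdi <- config$pdi_intercept_s + config$pdi_slope * dur +
          config$pdi_hinge_slope * max(0, dur - adl) +
          stats::rexp(1, 1 / config$pdi_noise_mean_s)
        n_in_bout <- n_in_bout + 1
        if (config$rest_every_n_dives > 0 &&
            n_in_bout %% config$rest_every_n_dives == 0) {
          pdi <- pdi + config$rest_duration_s
        }
        if (tt + dur > w[2]) break
        dives[[length(dives) + 1]] <- data.frame(
          trip_id = truth_trips$trip_id[k],
          start = tt, duration_s = dur, max_depth_m = z,
          bottom_s = bt, class = if (benthic) "benthic" else "pelagic",
          lon = pos[1], lat = pos[2], seafloor_m = sf, postdive_s = pdi)
        tt <- tt + dur + pdi
      }
    }
  }
  truth_dives <- if (length(dives)) do.call(rbind, dives) else
    data.frame(trip_id = character(), start = numeric(), duration_s = numeric(),
               max_depth_m = numeric(), bottom_s = numeric(), class = character(),
               lon = numeric(), lat = numeric(), seafloor_m = numeric(),
               postdive_s = numeric())
  if (nrow(truth_dives)) {
    truth_dives$dive_id <- sprintf("%s_D%05d", id, seq_len(nrow(truth_dives)))
    truth_dives$end <- truth_dives$start + truth_dives$duration_s
  } else {
    truth_dives$dive_id <- character(); truth_dives$end <- numeric()
  }

  # ---- pressure series -----------------------------------------------------
  p_times <- seq(from = as.numeric(t0), to = as.numeric(record_end),
                 by = config$pressure_interval_s)
  depth <- numeric(length(p_times))
  for (j in seq_len(nrow(truth_dives))) {
    s <- truth_dives$start[j]; dur <- truth_dives$duration_s[j]
    z <- truth_dives$max_depth_m[j]; bt <- truth_dives$bottom_s[j]
    td <- (dur - bt) / 2
    i1 <- ceiling((s - p_times[1]) / config$pressure_interval_s) + 1
    i2 <- floor((s + dur - p_times[1]) / config$pressure_interval_s) + 1
    if (i2 < i1) next
    rel <- p_times[i1:i2] - s
    prof <- ifelse(rel <= td, z * rel / td,
                   ifelse(rel >= dur - td, z * (dur - rel) / td, z))
    depth[i1:i2] <- pmax(prof, 0)
  }
  drift <- config$sensor_drift_m * (p_times - p_times[1]) /
    (p_times[length(p_times)] - p_times[1])
  raw <- depth + drift + stats::rnorm(length(depth), 0, config$sensor_noise_sd_m)

  pressure <- data.frame(
    individual_id = id,
    timestamp = as.POSIXct(p_times, origin = "1970-01-01", tz = "UTC"),
    depth_m = raw)
  class(pressure) <- c("pressure_series", "data.frame")

  # ---- observed (noisy) track ---------------------------------------------
  obs_lon <- lon + stats::rnorm(length(lon), 0, config$gps_noise_sd_m) / mlon
  obs_lat <- lat + stats::rnorm(length(lat), 0, config$gps_noise_sd_m) / mlat
  track <- data.frame(
    individual_id = id,
    timestamp = as.POSIXct(fix_times, origin = "1970-01-01", tz = "UTC"),
    lon = obs_lon, lat = obs_lat)
  class(track) <- c("track", "data.frame")

  truth_dives$start <- as.POSIXct(truth_dives$start, origin = "1970-01-01", tz = "UTC")
  truth_dives$end <- as.POSIXct(truth_dives$end, origin = "1970-01-01", tz = "UTC")
  list(track = track, pressure = pressure,
       truth = list(individual_id = id, adl_s = adl,
                    dives = truth_dives, trips = truth_trips,
                    true_fixes = data.frame(
                      timestamp = as.POSIXct(fix_times, origin = "1970-01-01",
                                             tz = "UTC"),
                      lon = lon, lat = lat)))
}

#' Simulate a whole cohort of deployments
#'
#' @param config A [sim_config()].
#' @param bathy Optional [bathy_grid()]; generated from `config` if missing.
#' @param seed Master seed; each individual gets a distinct derived seed.
#' @return List with `individuals`, `bathy`, and one entry per deployment
#'   (`deployments`, each as returned by [simulate_deployment()]).
#' @export
simulate_cohort <- function(config, bathy = NULL, seed = config$seed) {
  if (is.null(bathy)) bathy <- generate_bathymetry(config)
  ind <- simulate_individuals(config, seed)
  deps <- lapply(seq_len(nrow(ind)), function(k) {
    simulate_deployment(ind[k, ], config, bathy,
                        seed = (seed * 131 + k * 7919) %% .Machine$integer.max)
  })
  names(deps) <- ind$individual_id
  list(individuals = ind, bathy = bathy, deployments = deps)
}

#' Simulate dive-duration / post-dive-interval pairs
#'
#' Direct draws from the generator's post-dive interval model (no track or
#' pressure machinery), for fast parameter-recovery tests of the ADL
#' estimator.
#'
#' @param n Number of pairs.
#' @param adl_s True ADL (s); `Inf` gives a no-inflection control.
#' @param config A [sim_config()] supplying the interval model parameters.
#' @param duration_range_s Uniform range of dive durations (s).
#' @param seed RNG seed.
#' @return data.frame with `duration_s`, `postdive_s`.
#' @export
simulate_postdive_pairs <- function(n, adl_s, config = sim_config(),
                                    duration_range_s = c(15, 120),
                                    seed = config$seed) {
  set.seed(seed)
  dur <- stats::runif(n, duration_range_s[1], duration_range_s[2])
  pdi <- config$pdi_intercept_s + config$pdi_slope * dur +
    config$pdi_hinge_slope * pmax(0, dur - adl_s) +
    stats::rexp(n, 1 / config$pdi_noise_mean_s)
  data.frame(duration_s = dur, postdive_s = pdi)
}

#' Default synthetic prey species pool
#'
#' A small pool of mostly benthic shelf prey with sex-biased occurrence
#' probabilities (a soldierfish-like species commoner in female diets, a
#' perch-like species commoner in male diets, rare pelagic schooling prey).
#' All names are synthetic placeholders, not a published diet table.
#'
#' @return data.frame with `species`, `habitat`, `p_male`, `p_female`,
#'   `lambda` (mean extra count when present).
#' @export
default_species_pool <- function() {
  data.frame(
    species = c("soldierfish", "reef_perch", "flathead", "goby", "leatherjacket",
                "weedfish", "cod_small", "pipefish", "pelagic_schooler",
                "clupeiform"),
    habitat = c(rep("benthic", 8), "pelagic", "pelagic"),
    p_male = c(0.25, 0.40, 0.20, 0.10, 0.12, 0.05, 0.08, 0.04, 0.03, 0.02),
    p_female = c(0.50, 0.15, 0.15, 0.20, 0.08, 0.10, 0.05, 0.06, 0.02, 0.02),
    lambda = c(1.5, 1.0, 0.6, 2.0, 0.5, 0.8, 0.5, 0.5, 3.0, 3.0))
}

#' Simulate regurgitate diet samples
#'
#' One sample per (simulated) individual; a configurable fraction carries no
#' identifiable remains. Identifiable samples contain each pool species with
#' its sex-specific occurrence probability; item counts are 1 + Poisson, and
#' whole items carry a length drawn from the sex-specific length model. The
#' output is item-level (one row per prey item) in the diet CSV dialect.
#'
#' @param config A [sim_config()].
#' @param species_pool As [default_species_pool()]; per-sex probabilities must
#'   lie in \[0,1\].
#' @param seed RNG seed.
#' @return A `diet_samples` data.frame (see [read_diet_csv()]).
#' @export
simulate_diet_samples <- function(config, species_pool = default_species_pool(),
                                  seed = config$seed) {
  p <- c(species_pool$p_male, species_pool$p_female)
  if (any(p < 0 | p > 1)) {
    stop_divetrip("species occurrence probabilities must be in [0,1]",
                  "divetrip_validation_error")
  }
  set.seed(seed)
  n <- config$diet_n_samples
  sex <- sample(c("M", "F"), n, replace = TRUE)
  year <- sample(config$diet_years, n, replace = TRUE)
  ident <- stats::runif(n) < config$identifiable_fraction
  rows <- list()
  for (i in seq_len(n)) {
    sid <- sprintf("S%03d", i)
    iid <- sprintf("DIET%03d", i)
    if (!ident[i]) {
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sid, individual_id = iid, sex = sex[i], year = year[i],
        species = "", count = 0L, length_cm = NA_real_, identifiable = FALSE)
      next
    }
    pr <- if (sex[i] == "M") species_pool$p_male else species_pool$p_female
    present <- stats::runif(nrow(species_pool)) < pr
    if (!any(present)) present[sample.int(nrow(species_pool), 1, prob = pr + 1e-9)] <- TRUE
    for (s in which(present)) {
      cnt <- 1L + stats::rpois(1, species_pool$lambda[s])
      whole <- stats::runif(cnt) < config$whole_prey_prob
      mu <- if (sex[i] == "M") config$male_prey_length_cm else config$female_prey_length_cm
      len <- ifelse(whole, pmax(2, stats::rnorm(cnt, mu, config$prey_length_sd_cm)),
                    NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sid, individual_id = iid, sex = sex[i], year = year[i],
        species = species_pool$species[s], count = 1L, length_cm = len,
        identifiable = TRUE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("diet_samples", "data.frame")
  out
}
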