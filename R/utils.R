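#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6,371,000 m. Inputs are recycled,
#' so one end may be a single point (e.g. the colony) and the other a vector
#' of fixes.
#'
#' @param lon1,lat1 Numeric, decimal degrees of the first point(s).
#' @param lon2,lat2 Numeric, decimal degrees of the second point(s).
#' @return Distance(s) in metres.
#' @examples
#' great_circle_distance(146.6758, -38.9403, 146.6758, -38.9358)
#' @export
great_circle_distance <- function(lon1, lat1, lon2, lat2) {
  r <- 6371000
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dlat <- (lat2 - lat1) * pi / 180
  dlon <- (lon2 - lon1) * pi / 180
  a <- sin(dlat / 2)^2 + cos(p1) * cos(p2) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Solar elevation angle
#'
#' NOAA-style solar position approximation. Accurate to well under a degree,
#' which is ample for a day/night flag ("day" is defined as elevation > 0,
#' i.e. geometric sunrise/sunset, refraction ignored).
#'
#' @param time POSIXct (UTC).
#' @param lon,lat Decimal degrees.
#' @return Solar elevation in degrees above the horizon.
#' @export
solar_elevation <- function(time, lon, lat) {
  stopifnot(inherits(time, "POSIXct"))
  tt <- as.POSIXlt(time, tz = "UTC")
  doy <- tt$yday + 1
  frac_hour <- tt$hour + tt$min / 60 + tt$sec / 3600
  # fractional year (radians)
  gamma <- 2 * pi / 365 * (doy - 1 + (frac_hour - 12) / 24)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(gamma) - 0.032077 * sin(gamma) -
    0.014615 * cos(2 * gamma) - 0.040849 * sin(2 * gamma))
  decl <- 0.006918 - 0.399912 * cos(gamma) + 0.070257 * sin(gamma) -
    0.006758 * cos(2 * gamma) + 0.000907 * sin(2 * gamma) -
    0.002697 * cos(3 * gamma) + 0.00148 * sin(3 * gamma)
  time_offset <- eqtime + 4 * lon              # minutes
  tst <- frac_hour * 60 + time_offset          # true solar time, minutes
  ha <- (tst / 4 - 180) * pi / 180             # hour angle, radians
  latr <- lat * pi / 180
  cosz <- sin(latr) * sin(decl) + cos(latr) * cos(decl) * cos(ha)
  90 - acos(pmax(-1, pmin(1, cosz))) * 180 / pi
}

#' Day/night flag at given instants and positions
#'
#' @param times POSIXct (UTC).
#' @param lon,lat Decimal degrees (recycled against `times`).
#' @return Logical vector, `TRUE` where the sun is above the horizon.
#' @export
daylight_flags <- function(times, lon, lat) {
  solar_elevation(times, lon, lat) > 0
}

# Sunrise/sunset (UTC) within the 24 h starting at `window_start` (typically
# a local midnight expressed in UTC), found by a coarse scan + linear
# interpolation of the elevation zero crossing.
solar_crossings <- function(window_start, lon, lat) {
  t0 <- as.POSIXct(window_start, tz = "UTC")
  grid <- t0 + seq(0, 86400, by = 300)
  el <- solar_elevation(grid, lon, lat)
  s <- which(diff(sign(el)) != 0)
  out <- lapply(s, function(i) {
    f <- el[i] / (el[i] - el[i + 1])
    list(time = grid[i] + f * 300, rising = el[i + 1] > el[i])
  })
  rise <- vapply(out, function(x) if (x$rising) as.numeric(x$time) else NA_real_, 0)
  set <- vapply(out, function(x) if (!x$rising) as.numeric(x$time) else NA_real_, 0)
  list(
    sunrise = as.POSIXct(min(rise, na.rm = TRUE), origin = "1970-01-01", tz = "UTC"),
    sunset = as.POSIXct(max(set, na.rm = TRUE), origin = "1970-01-01", tz = "UTC")
  )
}

# Local clock hour-of-day (0..23) given a fixed UTC offset in hours.
local_hour <- function(times, tz_offset_h) {
  secs <- as.numeric(times) + tz_offset_h * 3600
  floor((secs %% 86400) / 3600)
}

# Local calendar day index (days since epoch in local clock time).
local_day <- function(times, tz_offset_h) {
  floor((as.numeric(times) + tz_offset_h * 3600) / 86400)
}

# metres <-> degrees at a reference latitude (small-offset approximation,
# used for GPS noise and local random walks, never for distance reporting)
m_per_deg_lat <- function() 111320
m_per_deg_lon <- function(lat) 111320 * cos(lat * pi / 180)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_divetrip <- function(msg, class) {
  stop(structure(class = c(class, "divetrip_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Format times as ISO-8601 UTC
#' @param x POSIXct vector.
#' @return Character vector like `"2021-10-01T06:30:00Z"`.
#' @keywords internal
format_iso8601 <- function(x) {
  format(as.POSIXct(x, tz = "UTC"), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

#' Parse ISO-8601 timezone-aware timestamps
#'
#' Accepts a trailing `Z` or a numeric offset (`+10:00`, `+1000`). Timestamps
#' without timezone information are rejected: logger clocks and local clocks
#' differ by many hours here and a silent assumption would corrupt every
#' daylight computation downstream.
#'
#' @param x Character vector.
#' @return POSIXct in UTC.
#' @keywords internal
parse_iso8601 <- function(x) {
  x <- trimws(x)
  has_tz <- grepl("(Z|[+-][0-9]{2}:?[0-9]{2})$", x)
  if (!all(has_tz)) {
    stop_divetrip(sprintf(
      "timestamps must be timezone-aware ISO-8601; first offender: '%s'",
      x[!has_tz][1]
    ), "divetrip_format_error")
  }
  y <- sub("Z$", "+0000", x)
  y <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", y)
  y <- sub("[Tt]", " ", y)
  out <- as.POSIXct(y, format = "%Y-%m-%d %H:%M:%OS%z", tz = "UTC")
  if (anyNA(out)) {
    stop_divetrip(sprintf(
      "unparseable timestamp: '%s'", x[which(is.na(out))[1]]
    ), "divetrip_format_error")
  }
  out
}
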