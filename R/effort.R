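#' Hourly dive-rate foraging effort index
#'
#' Dive rate (m h^-1) is the vertical distance travelled per hour of the
#' local clock hour observed — an index of foraging effort. For each
#' individual and local hour-of-day, the vertical distances of dives whose
#' midpoint falls in that hour are summed and divided by the total time (in
#' hours) the deployment record covers that clock hour. Covered hours without
#' dives are retained at rate 0; clock hours never covered by the record are
#' excluded, not zero-filled.
#'
#' @param dives Dive table with `start`, `end`, `vertical_distance_m` and
#'   `individual_id`.
#' @param record_span List or data.frame per individual with `individual_id`,
#'   `start`, `end` (POSIXct) of the pressure record.
#' @param tz_offset_h Local clock offset from UTC (hours).
#' @return data.frame: `individual_id`, `hour` (0-23),
#'   `dive_rate_m_per_h`, `vertical_m`, `record_hours`.
#' @export
hourly_dive_rate <- function(dives, record_span, tz_offset_h) {
  record_span <- as.data.frame(record_span)
  out <- list()
  for (r in seq_len(nrow(record_span))) {
    id <- record_span$individual_id[r]
    t0 <- as.numeric(record_span$start[r]) + tz_offset_h * 3600
    t1 <- as.numeric(record_span$end[r]) + tz_offset_h * 3600
    # coverage of each local clock hour by [t0, t1], in hours
    cov <- numeric(24)
    a <- t0
    while (a < t1) {
      b <- min(t1, (floor(a / 3600) + 1) * 3600)
      hr <- floor(a / 3600) %% 24
      cov[hr + 1] <- cov[hr + 1] + (b - a) / 3600
      a <- b
    }
    sub <- dives[dives$individual_id == id, , drop = FALSE]
    mid <- (as.numeric(sub$start) + as.numeric(sub$end)) / 2
    hr <- local_hour(as.POSIXct(mid, origin = "1970-01-01", tz = "UTC"),
                     tz_offset_h)
    vert <- vapply(0:23, function(h) sum(sub$vertical_distance_m[hr == h]), 0)
    keep <- cov > 0
    out[[r]] <- data.frame(individual_id = id, hour = (0:23)[keep],
                           dive_rate_m_per_h = vert[keep] / cov[keep],
                           vertical_m = vert[keep], record_hours = cov[keep])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Plot hourly mean dive rate by sex
#'
#' Hourly means with +/- one standard error across individuals, per sex — the
#' descriptive view of the diel foraging effort pattern (no smoothing or
#' inference is applied).
#'
#' @param effort Output of [hourly_dive_rate()] with a `sex` column merged in.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_hourly_effort <- function(effort, ...) {
  sexes <- unique(effort$sex)
  cols <- stats::setNames(c("steelblue", "tomato")[seq_along(sexes)], sexes)
  agg <- do.call(rbind, lapply(sexes, function(s) {
    sub <- effort[effort$sex == s, ]
    do.call(rbind, lapply(sort(unique(sub$hour)), function(h) {
      v <- sub$dive_rate_m_per_h[sub$hour == h]
      data.frame(sex = s, hour = h, mean = mean(v),
                 se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0)
    }))
  }))
  graphics::plot(NA, xlim = c(0, 23), ylim = c(0, max(agg$mean + agg$se)),
                 xlab = "local hour", ylab = "dive rate (m/h)", ...)
  for (s in sexes) {
    sub <- agg[agg$sex == s, ]
    graphics::lines(sub$hour, sub$mean, col = cols[s], lwd = 2)
    graphics::arrows(sub$hour, sub$mean - sub$se, sub$hour, sub$mean + sub$se,
                     length = 0.02, angle = 90, code = 3, col = cols[s])
  }
  graphics::legend("topright", legend = sexes, col = cols[sexes], lwd = 2,
                   bty = "n")
  invisible(agg)
}
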