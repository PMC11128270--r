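#' Lower envelope of post-dive interval vs dive duration
#'
#' Bins dive durations and takes a low quantile (default 0.05) of the
#' post-dive surface interval within each bin; bins with fewer than
#' `min_per_bin` points are dropped. The envelope is the empirical lower
#' boundary that the constraint-lines breakpoint fit operates on: points far
#' above it (long rests, inter-trip gaps) carry no information about
#' physiological recovery and do not influence it.
#'
#' @param durations_s Dive durations (s).
#' @param postdive_s Matching post-dive surface intervals (s).
#' @param bin_width_s Duration bin width (s), default 8 (two 4-s sampling
#'   intervals).
#' @param quantile Lower quantile per bin, default 0.05.
#' @param min_per_bin Minimum points per retained bin, default 5.
#' @param min_pairs Minimum pairs to attempt an envelope, default 50.
#' @param max_postdive_s Pairs with longer surface intervals are discarded
#'   first (rests/night gaps, not recovery), default 600.
#' @return data.frame with `mid` (bin centre, s), `q` (envelope value, s),
#'   `n` (points in bin); zero rows with attribute `reason` if there is too
#'   little data.
#' @export
lower_envelope <- function(durations_s, postdive_s, bin_width_s = 8,
                           quantile = 0.05, min_per_bin = 5, min_pairs = 50,
                           max_postdive_s = 600) {
  if (bin_width_s <= 0) stop_divetrip("bin_width_s must be > 0", "divetrip_config_error")
  keep <- is.finite(durations_s) & is.finite(postdive_s) &
    postdive_s <= max_postdive_s
  x <- durations_s[keep]; y <- postdive_s[keep]
  empty <- data.frame(mid = numeric(), q = numeric(), n = integer())
  if (length(x) < min_pairs) {
    attr(empty, "reason") <- sprintf("only %d usable pairs (< %d)", length(x), min_pairs)
    return(empty)
  }
  b <- floor(x / bin_width_s)
  qs <- tapply(y, b, stats::quantile, probs = quantile, names = FALSE)
  ns <- tapply(y, b, length)
  keep_bin <- ns >= min_per_bin
  out <- data.frame(mid = (as.numeric(names(qs)) + 0.5) * bin_width_s,
                    q = as.numeric(qs), n = as.integer(ns))[keep_bin, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# continuous two-segment least squares at a fixed breakpoint
two_segment_fit <- function(x, y, bp) {
  X <- cbind(1, x, pmax(0, x - bp))
  fit <- stats::lm.fit(X, y)
  sse <- sum(fit$residuals^2)
  b <- fit$coefficients
  list(sse = sse, slope1 = b[2], slope2 = b[2] + b[3], intercept = b[1])
}

#' Fit a constraint-lines breakpoint to an envelope
#'
#' Continuous two-segment piecewise-linear least squares over candidate
#' breakpoints on the grid of envelope bin centres (excluding the outer two
#' on each side, so both segments always have support). Detection requires
#' BOTH: the second slope exceeds `slope_ratio` times the first (a genuine
#' acceleration in recovery cost), and the two-segment fit improves on the
#' single-line fit by an F-ratio of at least `f_threshold` (2 extra
#' parameters: breakpoint and second slope). The breakpoint is the estimated
#' behavioural aerobic dive limit when detected.
#'
#' @param envelope Output of [lower_envelope()].
#' @param slope_ratio Required slope2/slope1 factor, default 3.
#' @param f_threshold Required F-ratio, default 10.
#' @param min_points Minimum envelope points, default 6.
#' @return List: `detected`, `adl_s` (NA unless detected), `breakpoint_s`,
#'   `slope1`, `slope2`, `f_ratio`, `reason` (when not detected).
#' @export
fit_constraint_breakpoint <- function(envelope, slope_ratio = 3,
                                      f_threshold = 10, min_points = 6) {
  n <- nrow(envelope)
  fail <- function(reason) {
    list(detected = FALSE, adl_s = NA_real_, breakpoint_s = NA_real_,
         slope1 = NA_real_, slope2 = NA_real_, f_ratio = NA_real_,
         reason = reason)
  }
  if (n < min_points) {
    return(fail(attr(envelope, "reason") %||%
                  sprintf("%d envelope points (< %d)", n, min_points)))
  }
  x <- envelope$mid; y <- envelope$q
  one <- stats::lm.fit(cbind(1, x), y)
  sse1 <- sum(one$residuals^2)
  cands <- x[3:(n - 2)]
  if (length(cands) == 0) return(fail("too few interior candidate breakpoints"))
  fits <- lapply(cands, function(bp) two_segment_fit(x, y, bp))
  sses <- vapply(fits, `[[`, 0, "sse")
  best <- which.min(sses)
  f2 <- fits[[best]]
  df2 <- n - 4
  if (df2 <= 0) return(fail("too few points for F test"))
  f_ratio <- ((sse1 - f2$sse) / 2) / (f2$sse / df2)
  slope_ok <- f2$slope2 > slope_ratio * max(f2$slope1, 0) &&
    f2$slope2 > f2$slope1
  detected <- isTRUE(slope_ok) && is.finite(f_ratio) && f_ratio >= f_threshold
  list(detected = detected,
       adl_s = if (detected) cands[best] else NA_real_,
       breakpoint_s = cands[best],
       slope1 = unname(f2$slope1), slope2 = unname(f2$slope2),
       f_ratio = f_ratio,
       reason = if (detected) NA_character_ else "no envelope inflection")
}

#' Estimate the behavioural ADL for one individual
#'
#' Lower envelope plus constraint-lines breakpoint on a dive table carrying
#' `duration_s` and `post_dive_s`.
#'
#' @param dives Dive table (e.g. from [extract_dives()]).
#' @param ... Passed to [lower_envelope()] and [fit_constraint_breakpoint()]
#'   (matched by name).
#' @return List of class `adl_estimate`: the breakpoint fit plus the
#'   `envelope` and `n_pairs` used.
#' @export
estimate_adl <- function(dives, ...) {
  args <- list(...)
  env_args <- args[names(args) %in% names(formals(lower_envelope))]
  fit_args <- args[names(args) %in% names(formals(fit_constraint_breakpoint))]
  ok <- !is.na(dives$post_dive_s)
  env <- do.call(lower_envelope, c(list(dives$duration_s[ok],
                                        dives$post_dive_s[ok]), env_args))
  fit <- do.call(fit_constraint_breakpoint, c(list(env), fit_args))
  fit$envelope <- env
  fit$n_pairs <- sum(ok)
  class(fit) <- "adl_estimate"
  fit
}

#' @export
print.adl_estimate <- function(x, ...) {
  if (x$detected) {
    cat(sprintf("ADL detected at %.1f s (slopes %.2f -> %.2f, F = %.1f, %d pairs)\n",
                x$adl_s, x$slope1, x$slope2, x$f_ratio, x$n_pairs))
  } else {
    cat(sprintf("no ADL detected (%s; %d pairs)\n", x$reason, x$n_pairs))
  }
  invisible(x)
}

#' Diagnostic plot of an ADL estimate
#'
#' Duration vs post-dive interval scatter with the envelope points and, when
#' detected, the fitted two-segment envelope and breakpoint.
#'
#' @param x An `adl_estimate`.
#' @param durations_s,postdive_s The underlying pairs (optional scatter).
#' @param ... Passed to [graphics::plot()].
#' @export
plot_adl <- function(x, durations_s = NULL, postdive_s = NULL, ...) {
  env <- x$envelope
  if (!is.null(durations_s)) {
    graphics::plot(durations_s, postdive_s, pch = 16, cex = 0.3,
                   col = "grey60", xlab = "dive duration (s)",
                   ylab = "post-dive interval (s)", ...)
    graphics::points(env$mid, env$q, pch = 19, col = "blue")
  } else {
    graphics::plot(env$mid, env$q, pch = 19, col = "blue",
                   xlab = "dive duration (s)", ylab = "envelope (s)", ...)
  }
  if (isTRUE(x$detected)) {
    graphics::abline(v = x$adl_s, lty = 2, col = "red")
  }
  invisible(x)
}

#' Regress detected ADL on body mass
#'
#' Ordinary least squares of ADL (s) on body mass (kg) across individuals
#' with a detected ADL.
#'
#' @param adl_s Detected ADL values (s).
#' @param mass_kg Matching body masses (kg).
#' @return List: `slope`, `intercept`, `r2`, `p` (slope t-test), `n`.
#' @export
adl_mass_regression <- function(adl_s, mass_kg) {
  ok <- is.finite(adl_s) & is.finite(mass_kg)
  if (sum(ok) < 3) {
    stop_divetrip("need >= 3 detected ADL estimates with masses",
                  "divetrip_insufficient_data")
  }
  if (stats::var(mass_kg[ok]) == 0) {
    stop_divetrip("mass constant across individuals: slope undefined",
                  "divetrip_degenerate_design")
  }
  fit <- stats::lm(adl_s[ok] ~ mass_kg[ok])
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = sm$r.squared,
       p = sm$coefficients[2, 4],
       n = sum(ok))
}
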