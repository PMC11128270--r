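#' Validate a pipeline configuration
#'
#' The configuration is a JSON object (see the package README for the
#' schema): either `simulate: true` with an optional `sim` block of
#' [sim_config()] overrides, or explicit input paths. Violations raise a
#' configuration error naming the offending field.
#'
#' @param config A list (parsed JSON).
#' @return The validated config with defaults filled in.
#' @export
validate_config <- function(config) {
  defaults <- list(simulate = TRUE, seed = 1L, out_dir = "divetrip_out",
                   buffer_m = 500, min_depth_m = 1, zoc_window_s = 7200,
                   zoc_quantile = 0.05, h = 0.01, grid_cells = 200,
                   mask_to_95 = FALSE, tz_offset_h = 11, sim = list(),
                   inputs = list())
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  num_pos <- c("buffer_m", "min_depth_m", "zoc_window_s", "h", "grid_cells")
  for (nm in num_pos) {
    if (!is.numeric(config[[nm]]) || length(config[[nm]]) != 1 ||
        config[[nm]] <= 0) {
      stop_divetrip(sprintf("config field '%s' must be a positive number", nm),
                    "divetrip_config_error")
    }
  }
  if (!config$simulate) {
    need <- c("metadata_csv", "bathymetry_asc")
    for (nm in need) {
      p <- config$inputs[[nm]]
      if (is.null(p)) {
        stop_divetrip(sprintf("config field 'inputs.%s' required when simulate is false", nm),
                      "divetrip_config_error")
      }
      if (!file.exists(p)) {
        stop_divetrip(sprintf("input not found: %s", p), "divetrip_io_error")
      }
    }
  }
  config
}

#' Run the full analysis pipeline
#'
#' Simulate (or ingest) deployments, extract dives, split trips, classify
#' dives against bathymetry, estimate ADLs, compute yearly male-female
#' overlap, summarize diet, and compute hourly effort; write every stage's
#' table as CSV plus a machine-readable JSON run report. With a fixed seed
#' the whole run, including every output file, is byte-identical across
#' re-runs.
#'
#' @param config_path Path to a JSON configuration file, or a config list.
#' @return The run report (invisibly); side effect: output files under
#'   `out_dir`.
#' @export
run_pipeline <- function(config_path) {
  config <- if (is.character(config_path)) {
    jsonlite::fromJSON(config_path, simplifyVector = TRUE)
  } else config_path
  config <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed, parameters = config,
                 stages = list(), counts = list(), outputs = character())
  t_last <- proc.time()[["elapsed"]]
  tick <- function(name) {
    now <- proc.time()[["elapsed"]]
    report$stages[[name]] <<- list(wall_s = round(now - t_last, 3))
    t_last <<- now
  }
  emit <- function(df, name) {
    p <- file.path(config$out_dir, name)
    df2 <- df
    for (cl in names(df2)) {
      if (inherits(df2[[cl]], "POSIXct")) df2[[cl]] <- format_iso8601(df2[[cl]])
    }
    utils::write.csv(df2, p, row.names = FALSE, quote = FALSE)
    report$outputs <<- c(report$outputs, p)
  }

  # ---- inputs --------------------------------------------------------------
  if (isTRUE(config$simulate)) {
    scfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))
    bathy <- generate_bathymetry(scfg)
    cohort <- simulate_cohort(scfg, bathy, seed = config$seed)
    individuals <- cohort$individuals
    deployments <- cohort$deployments
    diet <- simulate_diet_samples(scfg, seed = config$seed + 1)
    write_bathymetry(bathy, file.path(config$out_dir, "bathymetry.asc"))
    truth_dives <- do.call(rbind, lapply(deployments, function(d) {
      cbind(individual_id = d$truth$individual_id,
            d$truth$dives[, c("dive_id", "trip_id", "start", "end",
                              "duration_s", "max_depth_m", "class",
                              "lon", "lat")])
    }))
    if (!is.null(truth_dives)) emit(truth_dives, "truth_dives.csv")
    truth_trips <- do.call(rbind, lapply(deployments, function(d) {
      cbind(individual_id = d$truth$individual_id, d$truth$trips)
    }))
    if (!is.null(truth_trips)) emit(truth_trips, "truth_trips.csv")
    colony <- scfg$colony_lonlat
  } else {
    individuals <- utils::read.csv(config$inputs$metadata_csv,
                                   stringsAsFactors = FALSE)
    bathy <- read_bathymetry(config$inputs$bathymetry_asc)
    tracks <- lapply(config$inputs$track_csv, read_track_csv)
    pressures <- lapply(config$inputs$pressure_csv, read_pressure_csv)
    deployments <- lapply(seq_along(tracks), function(k) {
      list(track = tracks[[k]], pressure = pressures[[k]])
    })
    names(deployments) <- vapply(tracks, function(x) x$individual_id[1], "")
    diet <- if (!is.null(config$inputs$diet_csv)) {
      read_diet_csv(config$inputs$diet_csv)
    } else NULL
    colony <- unlist(config$colony_lonlat)
  }
  tick("inputs")
  report$counts$individuals <- length(deployments)

  if (length(deployments) == 0) {
    report$counts[c("fixes", "dives", "trips", "classified_dives",
                    "unclassifiable_dives", "adl_detections")] <- 0L
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(report))
  }

  sex_of <- stats::setNames(individuals$sex, individuals$individual_id)
  year_of <- stats::setNames(individuals$year, individuals$individual_id)
  mass_of <- stats::setNames(individuals$mass_kg, individuals$individual_id)

  all_dives <- list(); all_trips <- list(); spans <- list(); adl_rows <- list()
  n_unclass <- 0L; n_fixes <- 0L
  for (id in names(deployments)) {
    dep <- deployments[[id]]
    n_fixes <- n_fixes + nrow(dep$track)
    ex <- extract_dives(dep$pressure, config$min_depth_m,
                        config$zoc_window_s, config$zoc_quantile)
    trips <- split_trips(dep$track, colony, config$buffer_m)
    trips <- trip_stats(dep$track, trips, colony)
    trips <- detect_overnight_roost(dep$track, trips, config$tz_offset_h)
    trips$individual_id <- id
    trips$sex <- unname(sex_of[id])
    cl <- classify_deployment(ex$dives, dep$track, trips, bathy)
    cl$dives$sex <- unname(sex_of[id])
    cl$dives$year <- unname(year_of[id])
    n_unclass <- n_unclass + cl$n_unclassifiable
    all_dives[[id]] <- cl$dives
    all_trips[[id]] <- trips
    spans[[id]] <- data.frame(individual_id = id,
                              start = dep$pressure$timestamp[1],
                              end = dep$pressure$timestamp[nrow(dep$pressure)])
    est <- estimate_adl(cl$dives)
    adl_rows[[id]] <- data.frame(
      individual_id = id, detected = est$detected, adl_s = est$adl_s,
      n_pairs = est$n_pairs, mass_kg = unname(mass_of[id]))
  }
  tick("extract_segment_classify")
  dives <- do.call(rbind, all_dives); rownames(dives) <- NULL
  trips <- do.call(rbind, all_trips); rownames(trips) <- NULL
  adl <- do.call(rbind, adl_rows); rownames(adl) <- NULL

  report$counts$fixes <- n_fixes
  report$counts$dives <- nrow(dives)
  report$counts$trips <- nrow(trips)
  report$counts$classified_dives <- sum(!is.na(dives$dive_class))
  report$counts$unclassifiable_dives <- n_unclass
  report$counts$adl_detections <- sum(adl$detected)

  dive_cols <- c("individual_id", "dive_id", "trip_id", "start", "end",
                 "duration_s", "max_depth_m", "vertical_distance_m",
                 "post_dive_s", "lon", "lat", "seafloor_m", "dive_class",
                 "criterion_fired")
  emit(dives[, intersect(dive_cols, names(dives))], "dives.csv")
  emit(trips[, c("individual_id", "trip_id", "departure_time", "return_time",
                 "duration_h", "total_distance_km", "max_distance_km",
                 "complete", "overnight_roost", "sex")], "trips.csv")
  emit(adl, "adl.csv")
  emit(departure_return_histograms(trips, config$tz_offset_h),
       "departure_return_histograms.csv")

  if (sum(adl$detected) >= 3 && stats::var(adl$mass_kg[adl$detected]) > 0) {
    reg <- adl_mass_regression(adl$adl_s[adl$detected], adl$mass_kg[adl$detected])
    report$adl_mass_regression <- reg
  }

  tick("adl")
  ov <- sex_overlap_by_year(dives, h = config$h, n_cells = config$grid_cells,
                            mask_to_95 = isTRUE(config$mask_to_95))
  emit(ov, "overlap_by_year.csv")

  tick("overlap")
  effort <- hourly_dive_rate(dives, do.call(rbind, spans), config$tz_offset_h)
  effort$sex <- unname(sex_of[effort$individual_id])
  emit(effort, "hourly_effort.csv")

  if (!is.null(diet)) {
    emit(as.data.frame(diet), "diet_samples.csv")
    emit(foo_table(diet), "diet_foo.csv")
    emit(numerical_abundance(diet), "diet_abundance.csv")
    emit(prey_length_summary(diet), "diet_prey_length.csv")
  }

  tick("effort_diet")
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
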