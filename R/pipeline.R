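# Configuration-driven end-to-end runner: filter -> segment -> interpolate
# -> dives -> profiles -> variance components -> clustering -> isotope/diet
# summaries, with structured logging and deterministic outputs (no
# timestamps are written, so identical seed + config gives byte-identical
# files).

#' Default pipeline configuration
#'
#' All thresholds surfaced as named keys: speed filter 18 m/s, dive
#' threshold 1 m, 1-km analysis grid with 0.5/1/2/5-km sensitivity grids,
#' 0.2-km colony radius and 10-min / 5-fix trip minima.
#'
#' @param out_dir Output directory.
#' @param seed Seed for any simulation step.
#' @return Named list of configuration defaults.
#' @export
pipeline_defaults <- function(out_dir = "foragespec_out", seed = 1) {
  list(
    colony = c(lat = -49.4333, lon = 70.4333),
    vmax_ms = 18,
    dive_threshold_m = 1,
    cell_km = 1,
    cell_sizes_km = c(0.5, 1, 2, 5),
    colony_radius_km = 0.2,
    min_duration_min = 10,
    min_fixes = 5,
    k_max = 8,
    out_dir = out_dir,
    seed = seed,
    log_level = "info"
  )
}

log_stage <- function(cfg, stage, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full specialisation pipeline
#'
#' Accepts either a config list (see [pipeline_defaults()]) augmented with
#' input paths (`gps`, and optionally `tdr`, `isotopes`, `diet`) or a
#' `simulate` block of [sim_config()] arguments, or a path to a YAML file
#' with the same structure. Writes trips.csv, dives.csv, profiles.csv,
#' variance_components.csv, clusters.csv, diet_composition.csv,
#' tracks.geojson and report.json into `out_dir`.
#'
#' @param config List or YAML path.
#' @return The run report (list), invisibly-readable: counts per stage,
#'   parameters used, chosen k, warnings.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(pipeline_defaults(), config)
  cfg$colony <- unlist(cfg$colony)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character()
  note <- function(w) warnings_log <<- c(warnings_log, w)

  # --- acquire inputs -------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    if (is.null(sim_args$colony)) sim_args$colony <- cfg$colony
    sim <- do.call(sim_config, sim_args)
    sim <- simulate_population(sim)
    gps <- sim$gps; tdr <- sim$tdr; isotopes <- sim$isotopes; diet <- sim$diet
    log_stage(cfg, "simulate", "%d individuals, %d fixes, %s TDR samples",
              length(unique(gps$individual_id)), nrow(gps),
              if (is.null(tdr)) "no" else nrow(tdr))
  } else {
    if (is.null(cfg$gps)) stop("run_pipeline: need either `gps` path or `simulate` block")
    gps <- read_gps_csv(cfg$gps)
    tdr <- if (!is.null(cfg$tdr)) read_tdr_csv(cfg$tdr) else NULL
    isotopes <- if (!is.null(cfg$isotopes)) read_isotope_csv(cfg$isotopes) else NULL
    diet <- if (!is.null(cfg$diet)) read_diet_csv(cfg$diet) else NULL
    sim <- NULL
    log_stage(cfg, "read", "%d fixes from %s", nrow(gps), cfg$gps)
  }

  # --- tracks ---------------------------------------------------------
  proc <- withCallingHandlers(
    process_gps(gps, cfg$colony, vmax_ms = cfg$vmax_ms,
                colony_radius_km = cfg$colony_radius_km,
                min_duration_min = cfg$min_duration_min,
                min_fixes = cfg$min_fixes, cell_km = cfg$cell_km),
    warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
  trips <- proc$trips
  log_stage(cfg, "segment", "%d trips from %d deployments", nrow(trips),
            nrow(unique(gps[, c("individual_id", "stage")])))
  utils::write.csv(trips, file.path(cfg$out_dir, "trips.csv"),
                   row.names = FALSE)
  write_tracks_geojson(proc$tracks, trips,
                       file.path(cfg$out_dir, "tracks.geojson"))

  # --- dives ----------------------------------------------------------
  dives <- NULL
  if (!is.null(tdr) && nrow(trips) > 0) {
    dives <- process_dives(tdr, proc$tracks, trips,
                           threshold_m = cfg$dive_threshold_m)
    log_stage(cfg, "dives", "%d dives detected", nrow(dives))
    dv_out <- dives
    dv_out$start <- format(dv_out$start, "%Y-%m-%dT%H:%M:%OS2", tz = "UTC")
    dv_out$end <- format(dv_out$end, "%Y-%m-%dT%H:%M:%OS2", tz = "UTC")
    utils::write.csv(dv_out, file.path(cfg$out_dir, "dives.csv"),
                     row.names = FALSE)
  } else {
    log_stage(cfg, "dives", "no TDR data; dive sections absent")
  }

  # --- profiles -------------------------------------------------------
  profiles <- NULL
  clusters <- NULL
  vc_list <- list()
  if (nrow(trips) > 0) {
    profiles <- withCallingHandlers(
      build_profiles(trips, proc$cells, dives),
      warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
    utils::write.csv(profiles, file.path(cfg$out_dir, "profiles.csv"),
                     row.names = FALSE)
    log_stage(cfg, "profiles", "%d individual x stage profiles", nrow(profiles))

    # --- variance components -----------------------------------------
    trip_label <- paste(trips$individual_id, trips$stage, trips$trip_index,
                        sep = "|")
    if (length(unique(trips$individual_id)) >= 2) {
      vc_list$total_distance_km <- fit_variance_components(
        trips$total_distance_km, trips$individual_id, trip_label)
      vc_list$heading_deg <- fit_variance_components(
        trips$heading_deg, trips$individual_id, trip_label)
    }
    if (!is.null(dives) && nrow(dives) > 0) {
      ok <- !is.na(dives$trip_index)
      dd <- dives[ok, , drop = FALSE]
      if (length(unique(dd$individual_id)) >= 2) {
        vc_list$max_depth_m <- fit_variance_components(
          dd$max_depth_m, dd$individual_id,
          paste(dd$individual_id, dd$stage, dd$trip_index, sep = "|"))
      }
    }
    if (length(vc_list)) {
      write_variance_components_csv(vc_list,
                                    file.path(cfg$out_dir, "variance_components.csv"))
      log_stage(cfg, "varcomp", "variance components for: %s",
                paste(names(vc_list), collapse = ", "))
    }

    # --- clustering ---------------------------------------------------
    complete <- profiles[stats::complete.cases(
      profiles[, c("mean_total_distance_km", "cv_total_distance",
                   "sd_heading", "consistency_index")]), , drop = FALSE]
    if (nrow(complete) >= 3) {
      cl <- withCallingHandlers(
        cluster_profiles(complete, k_max = cfg$k_max),
        warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
      clusters <- cl$assignments
      utils::write.csv(clusters, file.path(cfg$out_dir, "clusters.csv"),
                       row.names = FALSE)
      write_dendrogram_newick(cl$hclust,
                              file.path(cfg$out_dir, "dendrogram.nwk"))
      log_stage(cfg, "cluster", "k = %d over %d profiles", cl$k, nrow(complete))
    } else {
      note("clustering skipped: fewer than 3 complete profiles")
    }
  } else {
    note("empty trip set: downstream sections zeroed")
  }

  # --- isotopes and diet ----------------------------------------------
  iso_summary <- NULL
  if (!is.null(isotopes) && nrow(isotopes)) {
    qc <- qc_isotopes(isotopes)
    iso_summary <- list(
      n_samples = nrow(isotopes),
      n_flagged = nrow(qc$flagged),
      mean_d13C_blood = mean(qc$passed$d13C[qc$passed$tissue == "blood"]),
      mean_d15N_blood = mean(qc$passed$d15N[qc$passed$tissue == "blood"]))
  }
  diet_rows <- 0L
  if (!is.null(diet) && nrow(diet)) {
    comp <- diet_composition(diet)
    utils::write.csv(comp, file.path(cfg$out_dir, "diet_composition.csv"),
                     row.names = FALSE)
    diet_rows <- nrow(comp)
    log_stage(cfg, "diet", "%d prey species across %d samples", nrow(comp),
              attr(comp, "total_samples"))
  }

  report <- list(
    parameters = cfg[c("colony", "vmax_ms", "dive_threshold_m", "cell_km",
                       "colony_radius_km", "min_duration_min", "min_fixes",
                       "k_max", "seed")],
    counts = list(
      fixes = nrow(gps),
      deployments = nrow(unique(gps[, c("individual_id", "stage")])),
      trips = nrow(trips),
      dives = if (is.null(dives)) 0L else nrow(dives),
      profiles = if (is.null(profiles)) 0L else nrow(profiles),
      clustered = if (is.null(clusters)) 0L else nrow(clusters),
      diet_species = diet_rows),
    chosen_k = if (is.null(clusters)) NA_integer_ else max(clusters$cluster),
    isotopes = iso_summary,
    warnings = warnings_log)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null")
  invisible(report)
}
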