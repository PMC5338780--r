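# Dive detection from 1-Hz time-depth records: surface-drift correction,
# threshold-crossing detection, per-dive metrics, and georeferencing onto
# interpolated GPS tracks.

#' Read a TDR depth table
#'
#' Expects columns `individual_id`, `timestamp` (ISO-8601 UTC), `depth_m`
#' (metres, positive down).
#'
#' @param path Path to a CSV file.
#' @return Data.frame with `individual_id`, `time` (POSIXct UTC), `depth_m`.
#' @export
read_tdr_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "timestamp", "depth_m")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("read_tdr_csv: missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df$time <- as.POSIXct(df$timestamp, tz = "UTC",
                        tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(df$time)) stop("read_tdr_csv: unparseable timestamp(s)")
  df <- df[order(df$individual_id, df$time),
           c("individual_id", "time", "depth_m")]
  rownames(df) <- NULL
  df
}

#' Zero-offset (surface drift) correction for a depth series
#'
#' TDR pressure sensors drift, so the apparent surface depth wanders away
#' from zero. The series is split into blocks of `window_s`, a lower
#' `quantile` of depth is taken per block as the surface baseline, the
#' baseline is linearly interpolated to every sample and subtracted.
#'
#' @param series Data.frame with `time` (POSIXct), `depth_m`.
#' @param window_s Baseline window, seconds.
#' @param quantile Lower quantile treated as surface.
#' @return The series with `depth_m` corrected.
#' @export
zero_offset_correct <- function(series, window_s = 600, quantile = 0.05) {
  tt <- as.numeric(series$time)
  span <- tt[length(tt)] - tt[1]
  if (span < window_s) {
    message("zero_offset_correct: series shorter than window; correction skipped")
    return(series)
  }
  block <- floor((tt - tt[1]) / window_s)
  base <- tapply(series$depth_m, block, stats::quantile,
                 probs = quantile, names = FALSE)
  mid <- tapply(tt, block, mean)
  baseline <- if (length(base) == 1L) rep(base, length(tt)) else
    stats::approx(mid, base, xout = tt, rule = 2)$y
  out <- series
  out$depth_m <- series$depth_m - baseline
  if (any(out$depth_m < -0.5)) {
    warning("zero_offset_correct: corrected depths below -0.5 m remain")
  }
  out
}

#' Detect dives in a depth series
#'
#' A dive is a maximal run of samples deeper than `threshold_m`, extended to
#' the bracketing threshold crossings by linear interpolation of the
#' crossing times. Only dives deeper than the 1-m default threshold count,
#' excluding surface splashes and sensor noise.
#'
#' @param series Zero-offset-corrected data.frame with `time`, `depth_m`.
#' @param threshold_m Dive depth threshold, metres.
#' @return Data.frame of dive events: `start`, `end` (POSIXct), `duration_s`,
#'   `max_depth_m`, `vertical_distance_m`; zero rows when no dives.
#' @export
detect_dives <- function(series, threshold_m = 1.0) {
  tt <- as.numeric(series$time)
  z <- series$depth_m
  wet <- z > threshold_m
  empty <- data.frame(start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      duration_s = numeric(), max_depth_m = numeric(),
                      vertical_distance_m = numeric())
  if (!any(wet)) return(empty)
  r <- rle(wet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    s <- starts[k]; e <- ends[k]
    # interpolated crossing times at the threshold depth
    if (s > 1L) {
      f <- (threshold_m - z[s - 1L]) / (z[s] - z[s - 1L])
      t0 <- tt[s - 1L] + f * (tt[s] - tt[s - 1L])
    } else t0 <- tt[s]
    if (e < length(z)) {
      f <- (z[e] - threshold_m) / (z[e] - z[e + 1L])
      t1 <- tt[e] + f * (tt[e + 1L] - tt[e])
    } else t1 <- tt[e]
    zz <- c(threshold_m, z[s:e], threshold_m)
    if (s == 1L) zz <- zz[-1L]
    if (e == length(z)) zz <- zz[-length(zz)]
    out[[length(out) + 1L]] <- data.frame(
      start = t0, end = t1, duration_s = t1 - t0,
      max_depth_m = max(z[s:e]),
      vertical_distance_m = sum(abs(diff(zz))))
  }
  res <- do.call(rbind, out)
  res$start <- as.POSIXct(res$start, origin = "1970-01-01", tz = "UTC")
  res$end <- as.POSIXct(res$end, origin = "1970-01-01", tz = "UTC")
  res
}

#' Metrics of a single dive
#'
#' @param times Sample times (POSIXct or numeric seconds) of one dive.
#' @param depth_m Depths of the same samples, metres positive down.
#' @return List: `max_depth_m`, `duration_s`, `vertical_distance_m` (the sum
#'   of absolute depth changes over the dive).
#' @export
dive_metrics <- function(times, depth_m) {
  if (length(depth_m) < 2) stop("dive_metrics: need at least 2 samples")
  tt <- as.numeric(times)
  list(max_depth_m = max(depth_m),
       duration_s = tt[length(tt)] - tt[1],
       vertical_distance_m = sum(abs(diff(depth_m))))
}

#' Georeference dives onto an interpolated track
#'
#' Each dive is assigned the track position interpolated at its start time
#' (the surface position before descent). Dives outside the track's time
#' coverage are flagged ungeolocated (`lat`/`lon` NA, `geolocated` FALSE).
#'
#' @param dives Dive-event data.frame from [detect_dives()].
#' @param track Interpolated trip data.frame (`time`, `lat`, `lon`).
#' @return `dives` with `lat`, `lon`, `geolocated` columns added.
#' @export
georeference_dives <- function(dives, track) {
  dives$lat <- NA_real_; dives$lon <- NA_real_; dives$geolocated <- FALSE
  if (nrow(dives) == 0) return(dives)
  tt <- as.numeric(track$time)
  ts <- as.numeric(dives$start)
  inside <- ts >= tt[1] & ts <= tt[length(tt)]
  if (!any(inside)) {
    warning("georeference_dives: no temporal overlap between dives and track")
    return(dives)
  }
  dives$lat[inside] <- stats::approx(tt, track$lat, xout = ts[inside])$y
  dives$lon[inside] <- stats::approx(tt, track$lon, xout = ts[inside])$y
  dives$geolocated <- inside
  dives
}

#' Detect and georeference dives for a set of deployments
#'
#' Runs zero-offset correction and dive detection per individual, then
#' georeferences each dive onto the 1-Hz interpolation of the trip whose
#' time span contains the dive start.
#'
#' @param tdr TDR table (`individual_id`, `time`, `depth_m`).
#' @param tracks List of trip fix data.frames (from [process_gps()]).
#' @param trips Matching trips metrics data.frame.
#' @param threshold_m Dive threshold, metres.
#' @param correct Logical; apply [zero_offset_correct()] first.
#' @return Data.frame of dives with `individual_id`, `stage`, `trip_index`
#'   (NA when the dive falls outside any trip), metrics and georeference.
#' @export
process_dives <- function(tdr, tracks = NULL, trips = NULL,
                          threshold_m = 1.0, correct = TRUE) {
  out <- list()
  for (id in unique(tdr$individual_id)) {
    series <- tdr[tdr$individual_id == id, , drop = FALSE]
    if (correct) series <- zero_offset_correct(series)
    dv <- detect_dives(series, threshold_m)
    if (nrow(dv) == 0) next
    dv$individual_id <- id
    dv$stage <- NA_character_
    dv$trip_index <- NA_integer_
    dv$lat <- NA_real_; dv$lon <- NA_real_; dv$geolocated <- FALSE
    if (!is.null(tracks) && length(tracks)) {
      idx <- which(trips$individual_id == id)
      for (k in idx) {
        tr <- tracks[[k]]
        t0 <- as.numeric(tr$time[1]); t1 <- as.numeric(tr$time[nrow(tr)])
        hit <- which(as.numeric(dv$start) >= t0 & as.numeric(dv$start) <= t1)
        if (!length(hit)) next
        itr <- interpolate_trip(tr, dt_s = 1)
        geo <- georeference_dives(dv[hit, , drop = FALSE], itr)
        dv$lat[hit] <- geo$lat; dv$lon[hit] <- geo$lon
        dv$geolocated[hit] <- geo$geolocated
        dv$stage[hit] <- trips$stage[k]
        dv$trip_index[hit] <- trips$trip_index[k]
      }
    }
    out[[length(out) + 1L]] <- dv
  }
  if (!length(out)) return(data.frame())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
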