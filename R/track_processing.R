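# GPS track cleaning, trip segmentation and per-trip spatial metrics for a
# central-place forager. Distances are great-circle on a sphere of radius
# 6371 km; gridding uses a colony-anchored equirectangular projection, which
# is accurate to well under a cell width over coastal foraging ranges
# (<= a few tens of km).

EARTH_RADIUS_KM <- 6371.0
KM_PER_DEG_LAT <- 110.574
KM_PER_DEG_LON_EQ <- 111.320

#' Great-circle distance between two points
#'
#' Haversine distance on a sphere of radius 6371.0 km. Inputs are recycled,
#' so one end may be a single point (e.g. the colony) and the other a track.
#'
#' @param lat1,lon1 Coordinates of the first point(s), decimal degrees WGS84.
#' @param lat2,lon2 Coordinates of the second point(s), decimal degrees WGS84.
#' @return Distance(s) in kilometres.
#' @examples
#' haversine_km(0, 0, 0, 1) # one degree of longitude at the equator
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (!all(is.finite(c(lat1, lon1, lat2, lon2)))) {
    stop("haversine_km: coordinates must be finite")
  }
  n <- max(length(lat1), length(lat2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM)
}

#' Initial great-circle bearing
#'
#' Bearing from point a to point b, clockwise from true north, in
#' (-180, 180]. Used for the heading of a trip: the angle between the colony
#' and the most distal point of the track.
#'
#' @inheritParams haversine_km
#' @return Bearing(s) in degrees in (-180, 180].
#' @export
initial_bearing_deg <- function(lat1, lon1, lat2, lon2) {
  if (!all(is.finite(c(lat1, lon1, lat2, lon2)))) {
    stop("initial_bearing_deg: coordinates must be finite")
  }
  n <- max(length(lat1), length(lat2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  if (any(p1[, 1] == p2[, 1] & p1[, 2] == p2[, 2])) {
    stop("initial_bearing_deg: bearing undefined for coincident points")
  }
  b <- geosphere::bearing(p1, p2)
  # geosphere returns (-180, 180]; make the convention explicit anyway
  b <- ((b + 180) %% 360) - 180
  b[b == -180] <- 180
  b
}

#' Read a GPS fix table
#'
#' Expects columns `individual_id`, `stage`, `timestamp` (ISO-8601, UTC),
#' `lat`, `lon`. Fixes are sorted by individual, stage and time.
#'
#' @param path Path to a CSV file.
#' @return A data.frame of fixes with `time` as POSIXct (UTC).
#' @export
read_gps_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "stage", "timestamp", "lat", "lon")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("read_gps_csv: missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df$time <- as.POSIXct(df$timestamp, tz = "UTC",
                        tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(df$time)) stop("read_gps_csv: unparseable timestamp(s)")
  df <- df[order(df$individual_id, df$stage, df$time),
           c("individual_id", "stage", "time", "lat", "lon")]
  rownames(df) <- NULL
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_fixes <- function(fixes) {
  stopifnot(is.data.frame(fixes), all(c("time", "lat", "lon") %in% names(fixes)))
  if (nrow(fixes) >= 2 && any(diff(as.numeric(fixes$time)) <= 0)) {
    stop("fix times must be strictly increasing within a deployment")
  }
  if (any(fixes$lat < -90 | fixes$lat > 90) ||
      any(fixes$lon <= -180 | fixes$lon > 180)) {
    stop("coordinates out of range")
  }
  invisible(fixes)
}

#' Speed-filter a deployment
#'
#' Iterative forward pass: a fix is removed when the implied speed from the
#' last retained fix exceeds `vmax_ms`. The first fix is always retained, so
#' all consecutive retained speeds are below the threshold on exit and the
#' filter is idempotent. The default 18 m/s removes erroneous locations
#' beyond plausible shag flight speed.
#'
#' @param fixes Data.frame with `time` (POSIXct), `lat`, `lon`.
#' @param vmax_ms Speed threshold in m/s.
#' @return The fixes data.frame with offending rows removed.
#' @export
speed_filter <- function(fixes, vmax_ms = 18) {
  validate_fixes(fixes)
  n <- nrow(fixes)
  if (n < 2) return(fixes)
  keep <- logical(n)
  keep[1] <- TRUE
  last <- 1L
  tt <- as.numeric(fixes$time)
  for (k in 2:n) {
    dt <- tt[k] - tt[last]
    d_m <- haversine_km(fixes$lat[last], fixes$lon[last],
                        fixes$lat[k], fixes$lon[k]) * 1000
    if (d_m / dt <= vmax_ms) {
      keep[k] <- TRUE
      last <- k
    }
  }
  if (sum(keep) == 1L && n > 1L) {
    warning("speed_filter: all fixes but the first removed")
  }
  out <- fixes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Segment a deployment into central-place trips
#'
#' A trip is a maximal run of fixes farther than `colony_radius_km` from the
#' colony, padded with the nearest bounding at-colony fix on each side when
#' one exists. Runs shorter than `min_duration_min` or with fewer than
#' `min_fixes` fixes are discarded. This deterministic rule replaces the
#' visual inspection traditionally used for trip delimitation.
#'
#' @param fixes Speed-filtered fixes data.frame (`time`, `lat`, `lon`).
#' @param colony Numeric `c(lat, lon)` of the central place.
#' @param colony_radius_km Radius defining "at the colony".
#' @param min_duration_min Minimum trip duration, minutes.
#' @param min_fixes Minimum number of fixes per trip.
#' @return A list of trip data.frames; each has attributes `trip_index`.
#' @export
segment_trips <- function(fixes, colony, colony_radius_km = 0.2,
                          min_duration_min = 10, min_fixes = 5) {
  validate_fixes(fixes)
  d <- haversine_km(colony[1], colony[2], fixes$lat, fixes$lon)
  at_sea <- d > colony_radius_km
  if (!any(at_sea)) {
    message("segment_trips: track never leaves the colony radius")
    return(list())
  }
  r <- rle(at_sea)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  trips <- list()
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    s <- starts[i]; e <- ends[i]
    # pad with bounding at-colony fixes when available
    if (s > 1L) s <- s - 1L
    if (e < nrow(fixes)) e <- e + 1L
    tr <- fixes[s:e, , drop = FALSE]
    dur_min <- diff(range(as.numeric(tr$time))) / 60
    if (dur_min < min_duration_min || nrow(tr) < min_fixes) next
    rownames(tr) <- NULL
    trips[[length(trips) + 1L]] <- tr
  }
  for (k in seq_along(trips)) attr(trips[[k]], "trip_index") <- k
  trips
}

#' Linearly interpolate a trip to a regular time grid
#'
#' Latitude and longitude are interpolated independently in raw degrees at
#' `dt_s` intervals between the first and last fix; the final fix is kept
#' even when the span is not a multiple of `dt_s`. Gaps longer than
#' `max_gap_min` are flagged with a message but still interpolated.
#'
#' @param trip Trip data.frame (`time`, `lat`, `lon`), >= 2 fixes.
#' @param dt_s Output time step in seconds (default 1 Hz, matching TDR
#'   cadence so dives can be georeferenced).
#' @param max_gap_min Gap length that triggers a flag, minutes.
#' @return Data.frame `time`, `lat`, `lon` on the regular grid.
#' @export
interpolate_trip <- function(trip, dt_s = 1, max_gap_min = 30) {
  stopifnot(nrow(trip) >= 2)
  tt <- as.numeric(trip$time)
  gaps <- diff(tt)
  if (any(gaps > max_gap_min * 60)) {
    message(sprintf("interpolate_trip: %d gap(s) longer than %g min interpolated",
                    sum(gaps > max_gap_min * 60), max_gap_min))
  }
  grid <- seq(tt[1], tt[length(tt)], by = dt_s)
  if (grid[length(grid)] < tt[length(tt)]) grid <- c(grid, tt[length(tt)])
  out <- data.frame(
    time = as.POSIXct(grid, origin = "1970-01-01", tz = "UTC"),
    lat = stats::approx(tt, trip$lat, xout = grid)$y,
    lon = stats::approx(tt, trip$lon, xout = grid)$y
  )
  attr(out, "trip_index") <- attr(trip, "trip_index")
  out
}

#' Per-trip spatial metrics
#'
#' Duration in hours, cumulative path length, maximum range from the colony,
#' and trip heading: the initial bearing from the colony to the most distal
#' fix of the trip.
#'
#' @param trip Trip data.frame (`time`, `lat`, `lon`).
#' @param colony Numeric `c(lat, lon)`.
#' @return One-row data.frame: `duration_h`, `max_distance_km`,
#'   `total_distance_km`, `heading_deg`.
#' @export
trip_metrics <- function(trip, colony) {
  stopifnot(nrow(trip) >= 2)
  tt <- as.numeric(trip$time)
  dcol <- haversine_km(colony[1], colony[2], trip$lat, trip$lon)
  imax <- which.max(dcol)
  if (dcol[imax] == 0) {
    stop("trip_metrics: distal point coincides with the colony; heading undefined")
  }
  n <- nrow(trip)
  seg <- haversine_km(trip$lat[-n], trip$lon[-n], trip$lat[-1], trip$lon[-1])
  data.frame(
    duration_h = (tt[n] - tt[1]) / 3600,
    max_distance_km = dcol[imax],
    total_distance_km = sum(seg),
    heading_deg = initial_bearing_deg(colony[1], colony[2],
                                      trip$lat[imax], trip$lon[imax])
  )
}

#' Grid-cell occupancy of a trip
#'
#' Positions are projected to local east/north km offsets from the colony
#' (equirectangular: x = dlon * 111.320 * cos(colony lat), y = dlat *
#' 110.574) and binned into square cells with the colony at a cell corner
#' (floor convention). Returns the deduplicated set of integer cell indices.
#'
#' @param trip Trip data.frame (raw or interpolated).
#' @param colony Numeric `c(lat, lon)`.
#' @param cell_km Cell edge length in km; 1x1 km is the headline analysis
#'   grid, with 0.5-5 km used for sensitivity.
#' @return Integer matrix with columns `i`, `j`, one row per occupied cell.
#' @export
rasterize_trip <- function(trip, colony, cell_km = 1.0) {
  if (!is.numeric(cell_km) || length(cell_km) != 1 || !is.finite(cell_km) ||
      cell_km <= 0) {
    stop("rasterize_trip: cell_km must be a positive number")
  }
  x <- (trip$lon - colony[2]) * KM_PER_DEG_LON_EQ * cos(colony[1] * pi / 180)
  y <- (trip$lat - colony[1]) * KM_PER_DEG_LAT
  ij <- unique(cbind(i = as.integer(floor(x / cell_km)),
                     j = as.integer(floor(y / cell_km))))
  ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
}

# canonical string keys for a cell index matrix, used for set operations
cell_keys <- function(cells) {
  if (is.character(cells)) return(unique(cells))
  paste(cells[, 1], cells[, 2], sep = ":")
}

#' Process GPS deployments into trips
#'
#' Convenience wrapper running the speed filter, trip segmentation, metrics
#' and gridding for every individual x stage deployment in a fix table.
#'
#' @param gps Fix table as returned by [read_gps_csv()] (or the simulator).
#' @param colony Numeric `c(lat, lon)`.
#' @param vmax_ms Speed-filter threshold, m/s.
#' @param colony_radius_km,min_duration_min,min_fixes Trip segmentation
#'   parameters, see [segment_trips()].
#' @param cell_km Grid cell size for occupancy, km.
#' @return List with `trips` (one-row-per-trip data.frame of ids and
#'   metrics, including `n_cells`), `cells` (list of cell-key vectors, one
#'   per trip row) and `tracks` (list of trip fix data.frames).
#' @export
process_gps <- function(gps, colony, vmax_ms = 18, colony_radius_km = 0.2,
                        min_duration_min = 10, min_fixes = 5, cell_km = 1.0) {
  keyfun <- interaction(gps$individual_id, gps$stage, drop = TRUE)
  rows <- list(); cells <- list(); tracks <- list()
  for (key in levels(keyfun)) {
    dep <- gps[keyfun == key, , drop = FALSE]
    dep <- dep[order(dep$time), , drop = FALSE]
    dep <- speed_filter(dep, vmax_ms)
    trips <- segment_trips(dep, colony, colony_radius_km,
                           min_duration_min, min_fixes)
    for (tr in trips) {
      m <- trip_metrics(tr, colony)
      cc <- rasterize_trip(tr, colony, cell_km)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(individual_id = dep$individual_id[1],
                   stage = dep$stage[1],
                   trip_index = attr(tr, "trip_index"),
                   stringsAsFactors = FALSE),
        m, data.frame(n_cells = nrow(cc), cell_km = cell_km))
      cells[[length(cells) + 1L]] <- cell_keys(cc)
      tracks[[length(tracks) + 1L]] <- tr
    }
  }
  trips_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(individual_id = character(), stage = character(),
               trip_index = integer(), duration_h = numeric(),
               max_distance_km = numeric(), total_distance_km = numeric(),
               heading_deg = numeric(), n_cells = integer(),
               cell_km = numeric())
  list(trips = trips_df, cells = cells, tracks = tracks)
}

#' Export trips as GeoJSON LineStrings
#'
#' @param tracks List of trip data.frames (from [process_gps()]).
#' @param trips Matching trips metrics data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tracks_geojson <- function(tracks, trips, path) {
  features <- lapply(seq_along(tracks), function(k) {
    tr <- tracks[[k]]
    list(
      type = "Feature",
      properties = list(
        individual_id = trips$individual_id[k],
        stage = trips$stage[k],
        trip_index = trips$trip_index[k]
      ),
      geometry = list(
        type = "LineString",
        coordinates = lapply(seq_len(nrow(tr)),
                             function(i) c(tr$lon[i], tr$lat[i]))
      )
    )
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
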