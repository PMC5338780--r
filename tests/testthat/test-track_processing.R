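test_that("haversine distance matches closed forms and the law-of-cosines oracle", {
  expect_equal(haversine_km(0, 0, 0, 0), 0)
  expect_equal(haversine_km(0, 0, 0, 1), 2 * pi * 6371 / 360, tolerance = 1e-6)
  # independent spherical law-of-cosines oracle
  locos <- function(lat1, lon1, lat2, lon2) {
    p <- pi / 180
    6371 * acos(sin(lat1 * p) * sin(lat2 * p) +
                  cos(lat1 * p) * cos(lat2 * p) * cos((lon2 - lon1) * p))
  }
  for (pts in list(c(0, 0, 1, 1), c(-49.43, 70.43, -49.2, 70.9),
                   c(10, -20, -15, 30))) {
    expect_equal(haversine_km(pts[1], pts[2], pts[3], pts[4]),
                 locos(pts[1], pts[2], pts[3], pts[4]),
                 tolerance = 1e-6)
  }
  expect_true(abs(haversine_km(3, 4, 5, 6) - haversine_km(5, 6, 3, 4)) < 1e-12)
  expect_error(haversine_km(NA, 0, 0, 1), "finite")
})

test_that("initial bearing follows the (-180, 180] clockwise-from-north convention", {
  expect_equal(initial_bearing_deg(0, 0, 0, 1), 90)
  expect_equal(initial_bearing_deg(0, 0, 1, 0), 0)
  expect_equal(initial_bearing_deg(0, 0, 0, -1), -90)
  expect_equal(initial_bearing_deg(0, 0, -1, 0), 180)
  expect_error(initial_bearing_deg(1, 1, 1, 1), "undefined")
})

test_that("speed filter removes displaced fixes, is idempotent and respects the no-op limit", {
  # middle fix displaced ~5 km from both neighbours at 60 s spacing (~83 m/s)
  fx <- make_fixes(c(0, 60, 120), c(0, 0.045, 0), c(0, 0, 0.001))
  out <- speed_filter(fx, vmax_ms = 18)
  expect_equal(nrow(out), 2)
  expect_equal(out$lat, c(0, 0))
  # stationary fixes untouched
  still <- make_fixes(c(0, 60, 120), rep(0, 3), rep(0, 3))
  expect_identical(speed_filter(still), still)
  # infinite threshold is a no-op
  expect_identical(speed_filter(fx, vmax_ms = Inf), fx)
  # idempotence on a noisy random walk
  set.seed(1)
  walk <- make_fixes(seq(0, 3600, 60), cumsum(rnorm(61, 0, 0.02)),
                     cumsum(rnorm(61, 0, 0.02)))
  once <- speed_filter(walk)
  expect_identical(speed_filter(once), once)
})

test_that("trip segmentation finds colony-separated excursions and drops short ones", {
  colony <- c(0, 0)
  # two ~13-min excursions (0.1 deg ~ 11 km out) separated by a colony visit
  lat <- c(0, rep(0.1, 12), 0, 0, rep(0.1, 12), 0)
  sec <- seq_along(lat) * 60
  fx <- make_fixes(sec, lat, rep(0, length(lat)))
  trips <- segment_trips(fx, colony)
  expect_length(trips, 2)
  expect_equal(attr(trips[[1]], "trip_index"), 1)
  # padded with bounding at-colony fixes
  expect_equal(trips[[1]]$lat[1], 0)
  expect_equal(trips[[1]]$lat[nrow(trips[[1]])], 0)
  # never leaving the radius
  expect_length(suppressMessages(
    segment_trips(make_fixes(sec, rep(0, length(sec)), rep(0, length(sec))),
                  colony)), 0)
  # 5-minute excursion below the 10-min minimum
  short <- make_fixes(seq(0, 300, 60), c(0, 0.05, 0.1, 0.05, 0, 0),
                      rep(0, 6))
  expect_length(segment_trips(short, colony, min_duration_min = 10), 0)
})

test_that("interpolation is linear, idempotent and endpoint-preserving", {
  tr <- make_fixes(c(0, 10), c(0, 0), c(0, 0.002))
  out <- interpolate_trip(tr, dt_s = 1)
  expect_equal(nrow(out), 11)
  expect_equal(out$lon[6], 0.001)
  expect_equal(out$lon[11], 0.002)
  # already at 1 Hz: unchanged positions
  again <- interpolate_trip(out, dt_s = 1)
  expect_equal(again$lat, out$lat)
  expect_equal(again$lon, out$lon)
  # long gaps flagged but interpolated
  gappy <- make_fixes(c(0, 3600), c(0, 1), c(0, 1))
  expect_message(interpolate_trip(gappy, dt_s = 600, max_gap_min = 30),
                 "gap")
})

test_that("trip metrics match an out-and-back constructed track", {
  colony <- c(0, 0)
  # straight out 10 km east and back at colony latitude
  lon10 <- 10 / haversine_km(0, 0, 0, 1)
  lons <- c(seq(0, lon10, length.out = 6), rev(seq(0, lon10, length.out = 6))[-1])
  tr <- make_fixes(seq(0, 3600, length.out = 11), rep(0, 11), lons)
  m <- trip_metrics(tr, colony)
  expect_equal(m$max_distance_km, 10, tolerance = 1e-6)
  expect_equal(m$total_distance_km, 20, tolerance = 1e-6)
  expect_equal(m$heading_deg, 90, tolerance = 1e-6)
  expect_equal(m$duration_h, 1)
  # duplicated fixes at identical time/place leave metrics unchanged
  # (zero-length segments)
  tr2 <- tr[rep(seq_len(nrow(tr)), each = 2), ]
  tr2 <- tr2[!duplicated(tr2$time) | c(FALSE, diff(as.numeric(tr2$time)) > 0), ]
  m2 <- trip_metrics(tr, colony)
  expect_equal(m2$total_distance_km, m$total_distance_km)
})

test_that("rasterization follows the floor convention and refines monotonically", {
  colony <- c(0, 0)
  # single point at the colony occupies exactly one cell
  single <- make_fixes(0, 0, 0)
  expect_equal(nrow(rasterize_trip(single, colony)), 1)
  # 3.5 km due-east transect at 1-km cells covers 4 cells
  km_per_deg <- 111.320
  lons <- seq(0, 3.5 / km_per_deg, length.out = 200)
  tr <- make_fixes(seq_along(lons), rep(0, length(lons)), lons)
  expect_equal(nrow(rasterize_trip(tr, colony, cell_km = 1)), 4)
  # refinement: halving the cell size cannot reduce the cell count
  expect_gte(nrow(rasterize_trip(tr, colony, cell_km = 0.5)),
             nrow(rasterize_trip(tr, colony, cell_km = 1)))
  expect_error(rasterize_trip(tr, colony, cell_km = 0), "positive")
})

test_that("per-trip invariants hold on simulated deployments", {
  cfg <- sim_config(seed = 5, n_individuals = 4, trips_per_individual = c(3, 5),
                    stages = "chick_rearing", tdr_stage = character(0))
  sim <- simulate_population(cfg)
  proc <- process_gps(sim$gps, cfg$colony)
  expect_gt(nrow(proc$trips), 0)
  # segmentation recovers the simulated trip count exactly
  expect_equal(nrow(proc$trips), nrow(sim$truth$trips))
  for (k in seq_len(nrow(proc$trips))) {
    tr <- proc$tracks[[k]]
    expect_lte(proc$trips$max_distance_km[k],
               proc$trips$total_distance_km[k])
    n <- nrow(tr)
    expect_gte(proc$trips$total_distance_km[k],
               haversine_km(tr$lat[1], tr$lon[1], tr$lat[n], tr$lon[n]))
  }
})
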