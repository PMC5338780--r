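# Seeded simulator of a central-place-foraging seabird population with
# known ground truth for every downstream estimator. Individuals hold
# persistent trip bearings (von Mises), individual-specific dive depths
# under a two-level nested Gaussian model, correlated isotope values across
# tissues/stages and multinomial diets dominated by one prey species.
# Trips are simulated as out-and-back walks in colony-anchored planar km
# and back-projected to latitude/longitude with the same equirectangular
# constants the gridding uses.

#' Simulator configuration
#'
#' Defaults emulate a subantarctic shag colony study: GPS fixes every 60 s,
#' TDR at 1 Hz during chick-rearing, 4-10 trips per individual, four
#' planted foraging strategies with distinct mean headings and trip
#' distances, and dive depths following the nested model
#' `depth = mu + a_ind + b_trip + e` (variances in m^2).
#'
#' @param n_individuals Number of individuals.
#' @param trips_per_individual Length-2 integer range; trips per individual
#'   per stage are drawn uniformly from it.
#' @param stages Breeding stages each individual is tracked in.
#' @param colony `c(lat, lon)` of the colony.
#' @param strategies Data.frame of planted strategies: `heading_deg` (mean
#'   heading), `distance_km` (one-way foraging range), `weight` (sampling
#'   probability).
#' @param heading_sd_within_strategy_deg SD of individual mean headings
#'   around their strategy heading.
#' @param distance_sdlog_between,distance_sdlog_within Lognormal SDs of
#'   individual ranges around the strategy range and of trip ranges around
#'   the individual range.
#' @param kappa_meanlog,kappa_sdlog Lognormal parameters of the per-
#'   individual von Mises heading concentration.
#' @param speed_mps Commuting speed, m/s.
#' @param fix_interval_s GPS fix cadence, seconds.
#' @param track_noise_km Per-fix cross-track noise SD during commuting, km.
#' @param dive_depth_mu Population mean maximum dive depth, m.
#' @param sigma2_ind,sigma2_trip,sigma2_resid Variance components of
#'   maximum dive depth (individual / trip-within-individual / dive), m^2.
#' @param dives_per_trip Length-2 range of dives per trip.
#' @param tdr_stage Stage(s) in which individuals carry a TDR.
#' @param surface_interval_s Length-2 range of post-dive surface intervals.
#' @param descent_rate_mps Vertical descent/ascent rate, m/s.
#' @param bottom_s Bottom-phase duration per dive, seconds.
#' @param dwell_range_s Range of time spent at the distal patch for trips
#'   without dive records, seconds.
#' @param isotope_means Named list of tissue means: `d13C_blood`,
#'   `d15N_blood`, `d13C_feather`, `d15N_feather` (per mil).
#' @param isotope_sd_between Between-individual SD of latent isotope values.
#' @param isotope_rho Correlation of values across tissues/stages induced by
#'   the individual latent.
#' @param d15N_incubation_shift Additive shift of blood d15N at incubation.
#' @param prey_species Species pool for diets.
#' @param diet_alpha_base,diet_alpha_dominant Dirichlet concentration for
#'   non-dominant and dominant species of an individual's preference.
#' @param seed Master seed (mandatory).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_individuals = 12,
                       trips_per_individual = c(4, 10),
                       stages = c("incubation", "chick_rearing"),
                       colony = c(lat = -49.4333, lon = 70.4333),
                       strategies = data.frame(
                         heading_deg = c(35.6, 82.2, 155.0, -21.2),
                         distance_km = c(22.7, 16.8, 8.2, 1.1),
                         weight = c(15, 10, 2, 2)),
                       heading_sd_within_strategy_deg = 8,
                       distance_sdlog_between = 0.15,
                       distance_sdlog_within = 0.1,
                       kappa_meanlog = log(50), kappa_sdlog = 0.5,
                       speed_mps = 5, fix_interval_s = 60,
                       track_noise_km = 0.03,
                       dive_depth_mu = 40,
                       sigma2_ind = 140, sigma2_trip = 30, sigma2_resid = 4,
                       dives_per_trip = c(6, 12),
                       tdr_stage = "chick_rearing",
                       surface_interval_s = c(20, 60),
                       descent_rate_mps = 1.5, bottom_s = 20,
                       dwell_range_s = c(900, 2400),
                       isotope_means = list(d13C_blood = -16.3,
                                            d15N_blood = 14.6,
                                            d13C_feather = -15.2,
                                            d15N_feather = 15.3),
                       isotope_sd_between = c(d13C = 1.3, d15N = 1.0),
                       isotope_rho = 0.9,
                       d15N_incubation_shift = 0.56,
                       prey_species = c("Notothenia cyanobrancha",
                                        "Harpagifer kerguelensis/spinosus",
                                        "Lepidonotothen mizops",
                                        "Paranotothenia magellanica",
                                        "Polynoidae sp.",
                                        "Benthoctopus thielei"),
                       diet_alpha_base = 0.3, diet_alpha_dominant = 8,
                       seed = NULL) {
  if (is.null(seed)) stop("sim_config: seed is mandatory")
  cfg <- as.list(environment())
  stopifnot(cfg$sigma2_ind >= 0, cfg$sigma2_trip >= 0, cfg$sigma2_resid >= 0,
            cfg$isotope_rho >= 0, cfg$isotope_rho <= 1,
            all(cfg$strategies$distance_km > 0))
  class(cfg) <- "sim_config"
  cfg
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler; at kappa = 0 the distribution is uniform
#' on the circle.
#'
#' @param n Number of draws.
#' @param mu_deg Mean direction, degrees.
#' @param kappa Concentration (>= 0).
#' @return Angles in degrees in (-180, 180].
#' @export
rvonmises_deg <- function(n, mu_deg, kappa) {
  if (kappa < 1e-8) {
    th <- stats::runif(n, -pi, pi)
  } else {
    a <- 1 + sqrt(1 + 4 * kappa^2)
    b <- (a - sqrt(2 * a)) / (2 * kappa)
    r <- (1 + b^2) / (2 * b)
    th <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        u <- stats::runif(3)
        z <- cos(pi * u[1])
        f <- (1 + r * z) / (r + z)
        cc <- kappa * (r - f)
        if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
          th[i] <- sign(u[3] - 0.5) * acos(f)
          break
        }
      }
    }
  }
  deg <- (th + mu_deg * pi / 180) * 180 / pi
  deg <- ((deg + 180) %% 360) - 180
  deg[deg == -180] <- 180
  deg
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# planar km offsets -> lat/lon around the colony (inverse of the
# equirectangular projection used by rasterize_trip)
planar_to_lonlat <- function(x_km, y_km, colony) {
  lat <- unname(colony[1]) + y_km / KM_PER_DEG_LAT
  lon <- unname(colony[2]) + x_km / (KM_PER_DEG_LON_EQ * cos(colony[1] * pi / 180))
  cbind(lat = lat, lon = lon)
}

#' Simulate one foraging trip
#'
#' Out-and-back walk in colony-anchored planar km: commute along a drawn
#' bearing with small cross-track noise, dwell at the distal patch (where
#' dives, if any, take place), and return. Departs from and ends at the
#' colony. With a dive schedule, a 1-Hz depth series covering the trip is
#' generated: ramp descent, flat bottom phase at the target depth, ramp
#' ascent, plus surface noise and a sensor offset removed later by
#' zero-offset correction.
#'
#' @param bearing_deg Trip bearing from the colony, degrees.
#' @param distance_km One-way trip distance, km.
#' @param t_start Trip start time (POSIXct).
#' @param config `sim_config` (speeds, cadences, dive profile shape).
#' @param dive_depths_m Numeric vector of target maximum depths; `NULL` for
#'   a trip without dive records.
#' @param sensor_offset_m Constant depth-sensor offset, m.
#' @return List: `fixes` (time/lat/lon), `depth` (time/depth_m, NULL when no
#'   dives), `dive_starts` (POSIXct), `duration_s`.
#' @export
simulate_trip <- function(bearing_deg, distance_km, t_start, config,
                          dive_depths_m = NULL, sensor_offset_m = 0) {
  v_kms <- config$speed_mps / 1000
  dt <- config$fix_interval_s
  th <- bearing_deg * pi / 180
  u <- c(sin(th), cos(th))                  # east, north unit vector
  t_out <- distance_km / v_kms
  n_dives <- length(dive_depths_m)
  if (n_dives > 0) {
    dive_dur <- 2 * dive_depths_m / config$descent_rate_mps + config$bottom_s
    surf <- stats::runif(n_dives, config$surface_interval_s[1],
                         config$surface_interval_s[2])
    dwell_s <- sum(dive_dur + surf) + 60
  } else {
    dwell_s <- stats::runif(1, config$dwell_range_s[1], config$dwell_range_s[2])
  }
  total_s <- 2 * t_out + dwell_s
  times <- seq(0, total_s, by = dt)
  if (times[length(times)] < total_s) times <- c(times, total_s)
  pos <- matrix(0, length(times), 2)
  dest <- distance_km * u
  for (k in seq_along(times)) {
    tt <- times[k]
    if (tt <= t_out) {
      f <- tt / t_out
      base <- f * dest
      noise <- if (tt == 0) c(0, 0) else
        stats::rnorm(2, 0, config$track_noise_km * sqrt(f * (1 - f) + 1e-12))
    } else if (tt <= t_out + dwell_s) {
      base <- dest
      noise <- stats::rnorm(2, 0, 1.5 * config$track_noise_km)
    } else {
      f <- (total_s - tt) / t_out
      base <- f * dest
      noise <- if (tt == total_s) c(0, 0) else
        stats::rnorm(2, 0, config$track_noise_km * sqrt(f * (1 - f) + 1e-12))
    }
    pos[k, ] <- base + noise
  }
  ll <- planar_to_lonlat(pos[, 1], pos[, 2], config$colony)
  fixes <- data.frame(
    time = t_start + times,
    lat = ll[, "lat"], lon = ll[, "lon"])
  depth <- NULL
  dive_starts <- NULL
  if (n_dives > 0) {
    sec <- seq(0, floor(total_s))
    z <- stats::rnorm(length(sec), 0, 0.01)
    cursor <- t_out + 30
    starts <- numeric(n_dives)
    for (d in seq_len(n_dives)) {
      starts[d] <- cursor
      ramp <- dive_depths_m[d] / config$descent_rate_mps
      prof_t <- sec - cursor
      inside <- prof_t >= 0 & prof_t <= dive_dur[d]
      pt <- prof_t[inside]
      zd <- ifelse(pt <= ramp, pt * config$descent_rate_mps,
            ifelse(pt <= ramp + config$bottom_s, dive_depths_m[d],
                   pmax(0, (dive_dur[d] - pt) * config$descent_rate_mps)))
      z[inside] <- z[inside] + zd
      cursor <- cursor + dive_dur[d] + surf[d]
    }
    depth <- data.frame(time = t_start + sec,
                        depth_m = z + sensor_offset_m)
    dive_starts <- t_start + starts
  }
  list(fixes = fixes, depth = depth, dive_starts = dive_starts,
       duration_s = total_s)
}

#' Simulate a central-place-foraging population
#'
#' Fully reproducible given `config$seed` (per-individual substreams are
#' derived deterministically from the master seed, so one individual's data
#' do not depend on how many trips another individual made). Returns GPS,
#' TDR, isotope and diet tables in the same schemas the readers consume,
#' plus the ground truth of every latent quantity.
#'
#' @param config A [sim_config()].
#' @return List of class `foragespec_sim`: `gps`, `tdr`, `isotopes`, `diet`
#'   data.frames and `truth` (list with `individuals`, `trips`, `dives`
#'   data.frames and the variance components used).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed %% 2147483647)
  ns <- nrow(config$strategies)
  strat <- sample.int(ns, config$n_individuals, replace = TRUE,
                      prob = config$strategies$weight)
  ids <- sprintf("bird_%02d", seq_len(config$n_individuals))
  ind_seed <- (config$seed + 7919 * seq_len(config$n_individuals)) %% 2147483647
  t0 <- as.POSIXct("2014-12-01 06:00:00", tz = "UTC")
  gps <- list(); tdr <- list(); iso <- list(); diet <- list()
  truth_ind <- list(); truth_trip <- list(); truth_dive <- list()
  for (i in seq_len(config$n_individuals)) {
    set.seed(ind_seed[i])
    s <- strat[i]
    mu_head <- config$strategies$heading_deg[s] +
      stats::rnorm(1, 0, config$heading_sd_within_strategy_deg)
    mu_head <- ((mu_head + 180) %% 360) - 180
    kappa <- stats::rlnorm(1, config$kappa_meanlog, config$kappa_sdlog)
    dist_ind <- config$strategies$distance_km[s] *
      stats::rlnorm(1, 0, config$distance_sdlog_between)
    a_i <- stats::rnorm(1, 0, sqrt(config$sigma2_ind))
    z13 <- stats::rnorm(1); z15 <- stats::rnorm(1)
    dominant <- sample(config$prey_species, 1)
    alpha <- rep(config$diet_alpha_base, length(config$prey_species))
    alpha[config$prey_species == dominant] <- config$diet_alpha_dominant
    pref <- rdirichlet1(alpha)
    truth_ind[[i]] <- data.frame(
      individual_id = ids[i], strategy = s, mu_heading_deg = mu_head,
      kappa = kappa, distance_km = dist_ind, depth_effect = a_i,
      d13C_latent = z13, d15N_latent = z15, dominant_prey = dominant,
      stringsAsFactors = FALSE)
    day <- 0
    for (stage in config$stages) {
      n_trips <- sample(seq(config$trips_per_individual[1],
                            config$trips_per_individual[2]), 1)
      has_tdr <- stage %in% config$tdr_stage
      t_cursor <- t0 + day * 86400 + (i - 1) * 3600
      # a couple of at-colony fixes before the first trip
      pre <- data.frame(time = t_cursor + c(-240, -120),
                        lat = unname(config$colony[1]), lon = unname(config$colony[2]))
      dep_fixes <- list(pre)
      offset <- stats::runif(1, -0.2, 0.4)
      for (tr in seq_len(n_trips)) {
        bearing <- rvonmises_deg(1, mu_head, kappa)
        dist_trip <- dist_ind * stats::rlnorm(1, 0, config$distance_sdlog_within)
        b_ij <- stats::rnorm(1, 0, sqrt(config$sigma2_trip))
        dive_depths <- NULL
        if (has_tdr) {
          nd <- sample(seq(config$dives_per_trip[1],
                           config$dives_per_trip[2]), 1)
          dive_depths <- pmax(2, config$dive_depth_mu + a_i + b_ij +
                                stats::rnorm(nd, 0, sqrt(config$sigma2_resid)))
        }
        sim <- simulate_trip(bearing, dist_trip, t_cursor, config,
                             dive_depths_m = dive_depths,
                             sensor_offset_m = offset)
        dep_fixes[[length(dep_fixes) + 1L]] <- sim$fixes
        if (!is.null(sim$depth)) {
          sim$depth$individual_id <- ids[i]
          tdr[[length(tdr) + 1L]] <- sim$depth
        }
        truth_trip[[length(truth_trip) + 1L]] <- data.frame(
          individual_id = ids[i], stage = stage, trip_index = tr,
          bearing_deg = bearing, distance_km = dist_trip,
          trip_depth_effect = b_ij, n_dives = length(dive_depths),
          stringsAsFactors = FALSE)
        if (length(dive_depths)) {
          truth_dive[[length(truth_dive) + 1L]] <- data.frame(
            individual_id = ids[i], stage = stage, trip_index = tr,
            dive_number = seq_along(dive_depths),
            target_depth_m = dive_depths,
            start = sim$dive_starts, stringsAsFactors = FALSE)
        }
        t_end <- t_cursor + sim$duration_s
        # at-colony rest between trips
        rest <- stats::runif(1, 1800, 5400)
        gap_fix <- data.frame(time = t_end + c(rest / 2, rest - 60),
                              lat = unname(config$colony[1]), lon = unname(config$colony[2]))
        dep_fixes[[length(dep_fixes) + 1L]] <- gap_fix
        t_cursor <- t_end + rest
      }
      all_fix <- do.call(rbind, dep_fixes)
      all_fix$individual_id <- ids[i]
      all_fix$stage <- stage
      gps[[length(gps) + 1L]] <-
        all_fix[, c("individual_id", "stage", "time", "lat", "lon")]
      day <- day + 30
      # blood isotope sample at each tracked stage
      shift15 <- if (stage == "incubation") config$d15N_incubation_shift else 0
      rho <- config$isotope_rho
      iso[[length(iso) + 1L]] <- data.frame(
        individual_id = ids[i], tissue = "blood", stage = stage,
        d13C = config$isotope_means$d13C_blood +
          unname(config$isotope_sd_between["d13C"]) *
          (sqrt(rho) * z13 + sqrt(1 - rho) * stats::rnorm(1)),
        d15N = config$isotope_means$d15N_blood + shift15 +
          unname(config$isotope_sd_between["d15N"]) *
          (sqrt(rho) * z15 + sqrt(1 - rho) * stats::rnorm(1)),
        cn_ratio = stats::rnorm(1, 3.39, 0.04), stringsAsFactors = FALSE)
      # one diet sample per tracked stage
      n_items <- 1 + stats::rpois(1, 7)
      cts <- as.integer(stats::rmultinom(1, n_items, pref))
      keep <- cts > 0
      diet[[length(diet) + 1L]] <- data.frame(
        sample_id = paste(ids[i], stage, sep = "_"),
        individual_id = ids[i], stage = stage,
        species = config$prey_species[keep],
        prey_group = ifelse(grepl("Polynoidae", config$prey_species[keep]),
                            "annelid",
                     ifelse(grepl("octopus|Benthoctopus",
                                  config$prey_species[keep]),
                            "cephalopod", "fish")),
        count = cts[keep], stringsAsFactors = FALSE)
    }
    # feather sample (moult period)
    rho <- config$isotope_rho
    iso[[length(iso) + 1L]] <- data.frame(
      individual_id = ids[i], tissue = "feather", stage = "moult",
      d13C = config$isotope_means$d13C_feather +
        unname(config$isotope_sd_between["d13C"]) *
        (sqrt(rho) * z13 + sqrt(1 - rho) * stats::rnorm(1)),
      d15N = config$isotope_means$d15N_feather +
        unname(config$isotope_sd_between["d15N"]) *
        (sqrt(rho) * z15 + sqrt(1 - rho) * stats::rnorm(1)),
      cn_ratio = stats::rnorm(1, 3.20, 0.05), stringsAsFactors = FALSE)
  }
  gps_df <- do.call(rbind, gps)
  gps_df <- gps_df[order(gps_df$individual_id, gps_df$stage, gps_df$time), ]
  rownames(gps_df) <- NULL
  tdr_df <- if (length(tdr)) {
    d <- do.call(rbind, tdr)[, c("individual_id", "time", "depth_m")]
    d <- d[order(d$individual_id, d$time), ]
    rownames(d) <- NULL
    d
  } else NULL
  out <- list(
    gps = gps_df, tdr = tdr_df,
    isotopes = do.call(rbind, iso), diet = do.call(rbind, diet),
    truth = list(individuals = do.call(rbind, truth_ind),
                 trips = do.call(rbind, truth_trip),
                 dives = if (length(truth_dive)) do.call(rbind, truth_dive)
                         else NULL,
                 variance_components = c(individual = config$sigma2_ind,
                                         trip = config$sigma2_trip,
                                         residual = config$sigma2_resid)),
    config = config)
  class(out) <- "foragespec_sim"
  out
}

#' Draw responses from the nested two-level model
#'
#' Direct draws of `y = mu + a_ind + b_trip(ind) + e` without the movement
#' layer; the sharp test bed for [fit_variance_components()].
#'
#' @param n_individuals,n_trips,obs_per_trip Design sizes.
#' @param mu Grand mean.
#' @param sigma2_ind,sigma2_trip,sigma2_resid True variance components.
#' @return Data.frame: `y`, `individual`, `trip` (labels unique across
#'   individuals).
#' @export
simulate_nested_responses <- function(n_individuals, n_trips, obs_per_trip,
                                      mu = 0, sigma2_ind = 4,
                                      sigma2_trip = 2, sigma2_resid = 1) {
  a <- stats::rnorm(n_individuals, 0, sqrt(sigma2_ind))
  rows <- list()
  for (i in seq_len(n_individuals)) {
    b <- stats::rnorm(n_trips, 0, sqrt(sigma2_trip))
    for (j in seq_len(n_trips)) {
      e <- stats::rnorm(obs_per_trip, 0, sqrt(sigma2_resid))
      rows[[length(rows) + 1L]] <- data.frame(
        y = mu + a[i] + b[j] + e,
        individual = sprintf("i%02d", i),
        trip = sprintf("i%02d_t%02d", i, j), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write simulated data in the reader CSV schemas
#'
#' @param sim A `foragespec_sim` object.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_sim_csv <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  g <- sim$gps; g$timestamp <- fmt(g$time); g$time <- NULL
  utils::write.csv(g[, c("individual_id", "stage", "timestamp", "lat", "lon")],
                   file.path(dir, "gps.csv"), row.names = FALSE)
  if (!is.null(sim$tdr)) {
    d <- sim$tdr; d$timestamp <- fmt(d$time); d$time <- NULL
    utils::write.csv(d[, c("individual_id", "timestamp", "depth_m")],
                     file.path(dir, "tdr.csv"), row.names = FALSE)
  }
  utils::write.csv(sim$isotopes, file.path(dir, "isotopes.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$diet, file.path(dir, "diet.csv"), row.names = FALSE)
  utils::write.csv(sim$truth$individuals, file.path(dir, "truth_individuals.csv"),
                   row.names = FALSE)
  invisible(dir)
}
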