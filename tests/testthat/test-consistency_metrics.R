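test_that("cv matches the two-pass sample formula", {
  expect_equal(cv(c(5, 5, 5)), 0)
  expect_equal(cv(c(1, 2, 3)), 0.5)
  # hand-computed two-pass oracle
  x <- c(2, 4, 4, 4, 5, 5, 7, 9)
  m <- sum(x) / length(x)
  s <- sqrt(sum((x - m)^2) / (length(x) - 1))
  expect_equal(cv(x), s / m)
  expect_error(cv(5), "2 values")
  expect_error(cv(c(-1, 1)), "zero mean")
})

test_that("circular mean and SD handle wrap-around and the antipodal degenerate case", {
  out <- circular_mean_sd(c(90, 90, 90))
  expect_equal(out$mean_deg, 90)
  expect_equal(out$sd_rad, 0)
  # wrap-around: mean of 350 and 10 is 0, sd from the resultant length
  out2 <- circular_mean_sd(c(350, 10))
  expect_equal(out2$mean_deg, 0, tolerance = 1e-9)
  expect_equal(out2$sd_rad, sqrt(-2 * log(cos(10 * pi / 180))))
  # antipodal headings: zero resultant, infinite dispersion
  out3 <- circular_mean_sd(c(0, 180))
  expect_equal(out3$sd_rad, Inf)
  expect_error(circular_mean_sd(numeric(0)), "empty")
})

test_that("space-use consistency index reproduces closed-form cases", {
  A <- c("0:0", "0:1", "1:1")
  expect_equal(space_use_consistency_index(list(A, A)), 1)
  expect_equal(space_use_consistency_index(list(A, c("5:5", "6:6", "9:9"))), 0)
  # {A,B,C} vs {B,C,D}: one pair sharing 2 cells, mean size 3
  expect_equal(space_use_consistency_index(
    list(c("A", "B", "C"), c("B", "C", "D"))), 2 / 3)
  # alternative normalisation agrees here (equal sizes)
  expect_equal(space_use_consistency_index(
    list(c("A", "B", "C"), c("B", "C", "D")), method = "mean_ratio"), 2 / 3)
  # accepts integer cell matrices from rasterize_trip
  m1 <- cbind(i = c(0L, 1L), j = c(0L, 0L))
  expect_equal(space_use_consistency_index(list(m1, m1)), 1)
  expect_error(space_use_consistency_index(list(A)), "2 trips")
})

test_that("consistency index is permutation/relabelling invariant and duplication never lowers it", {
  set.seed(4)
  sets <- lapply(1:5, function(i) {
    as.character(sample(1:30, sample(3:10, 1)))
  })
  base <- space_use_consistency_index(sets)
  expect_equal(space_use_consistency_index(rev(sets)), base)
  relab <- lapply(sets, function(s) paste0("cell_", s))
  expect_equal(space_use_consistency_index(relab), base)
  for (k in seq_along(sets)) {
    dup <- c(sets, sets[k])
    expect_gte(space_use_consistency_index(dup) + 1e-12, base)
  }
})

test_that("index agreement recovers OLS r-squared and slope", {
  a <- c(0.1, 0.4, 0.5, 0.8, 0.9)
  expect_equal(index_agreement(a, a)$r_squared, 1)
  expect_equal(index_agreement(a, a)$slope, 1)
  aff <- index_agreement(a, 2 * a + 3)
  expect_equal(aff$r_squared, 1)
  expect_equal(aff$slope, 2)
  # normal-equations oracle on noisy data
  set.seed(5)
  b <- 0.8 * a + rnorm(5, 0, 0.1)
  fit <- index_agreement(a, b)
  sl <- sum((a - mean(a)) * (b - mean(b))) / sum((a - mean(a))^2)
  r2 <- sl^2 * var(a) / var(b)
  expect_equal(fit$slope, sl)
  expect_equal(fit$r_squared, r2)
  expect_error(index_agreement(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("profiles aggregate per individual x stage with sane edge cases", {
  trips <- data.frame(
    individual_id = c("a", "a", "a", "b", "b"),
    stage = "chick_rearing",
    trip_index = c(1, 2, 3, 1, 2),
    duration_h = c(2, 2, 2, 3, 5),
    max_distance_km = c(5, 5, 5, 8, 10),
    total_distance_km = c(10, 10, 10, 18, 22),
    heading_deg = c(90, 90, 90, 10, 30),
    n_cells = c(3, 3, 3, 4, 5), cell_km = 1)
  cells <- list(c("A", "B", "C"), c("A", "B", "C"), c("A", "B", "C"),
                c("A", "B", "D", "E"), c("A", "B", "C", "F", "G"))
  prof <- build_profiles(trips, cells)
  expect_equal(nrow(prof), 2)
  a_row <- prof[prof$individual_id == "a", ]
  expect_equal(a_row$cv_duration, 0)
  expect_equal(a_row$consistency_index, 1)
  expect_equal(a_row$sd_heading, 0)
  expect_equal(a_row$mean_heading_deg, 90)
  # single-trip individual: NA CVs with a warning
  solo <- trips[c(1, 4), ]
  solo$individual_id <- c("a", "b")
  expect_warning(p2 <- build_profiles(solo, cells[c(1, 4)]), "single-trip")
  expect_true(all(is.na(p2$cv_duration)))
})

test_that("indices from full tracks and dive locations are positively correlated on synthetic birds", {
  cfg <- sim_config(seed = 31, n_individuals = 10, trips_per_individual = c(4, 6),
                    stages = "chick_rearing")
  sim <- simulate_population(cfg)
  proc <- process_gps(sim$gps, cfg$colony)
  dives <- process_dives(sim$tdr, proc$tracks, proc$trips)
  prof <- build_profiles(proc$trips, proc$cells)
  # dive-location-only index: rasterize dive positions per trip
  key <- paste(proc$trips$individual_id, proc$trips$stage, proc$trips$trip_index)
  dive_idx <- vapply(unique(proc$trips$individual_id), function(id) {
    sel <- which(proc$trips$individual_id == id)
    cells <- lapply(sel, function(k) {
      dsel <- dives$individual_id == id &
        dives$trip_index == proc$trips$trip_index[k] & dives$geolocated
      if (!sum(dsel)) return(character(0))
      cell_keys(rasterize_trip(
        data.frame(lat = dives$lat[dsel], lon = dives$lon[dsel]),
        cfg$colony, cell_km = 1))
    })
    cells <- cells[vapply(cells, length, 1L) > 0]
    if (length(cells) < 2) return(NA_real_)
    space_use_consistency_index(cells)
  }, 1.0)
  full_idx <- prof$consistency_index[match(names(dive_idx), prof$individual_id)]
  ok <- is.finite(dive_idx) & is.finite(full_idx)
  expect_gte(sum(ok), 8)
  expect_gt(cor(full_idx[ok], dive_idx[ok], method = "spearman"), 0.5)
})
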