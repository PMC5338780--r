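# Individual-level consistency statistics: coefficients of variation,
# circular heading statistics, and the grid-overlap space-use consistency
# index (mean shared cells across trip pairs over mean cells per trip).

#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the mean.
#'
#' @param values Numeric vector, length >= 2, non-zero mean.
#' @return Dimensionless CV.
#' @export
cv <- function(values) {
  if (length(values) < 2) stop("cv: need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("cv: undefined for zero mean")
  stats::sd(values) / m
}

#' Circular mean and standard deviation of headings
#'
#' The mean direction is the angle of the mean resultant vector, reported in
#' degrees in (-180, 180]. Dispersion is the circular standard deviation
#' sqrt(-2 log Rbar) in radians, where Rbar is the mean resultant length;
#' for a perfectly balanced (antipodal) sample Rbar = 0 and the SD is Inf.
#'
#' @param headings_deg Headings in degrees (any wrap).
#' @return List: `mean_deg`, `sd_rad`, `rbar`.
#' @export
circular_mean_sd <- function(headings_deg) {
  if (length(headings_deg) < 1) stop("circular_mean_sd: empty input")
  th <- headings_deg * pi / 180
  S <- mean(sin(th)); C <- mean(cos(th))
  rbar <- sqrt(S^2 + C^2)
  mean_deg <- atan2(S, C) * 180 / pi
  if (mean_deg <= -180) mean_deg <- mean_deg + 360
  sd_rad <- if (rbar <= .Machine$double.eps) Inf else sqrt(-2 * log(rbar))
  list(mean_deg = mean_deg, sd_rad = sd_rad, rbar = rbar)
}

#' Space-use consistency index
#'
#' For every unordered pair of an individual's trips the number of shared
#' grid cells is counted; the mean shared count over pairs is divided by the
#' mean number of cells used per trip. 1 means every trip used exactly the
#' same cells, 0 means no two trips shared a cell. The ratio-of-averages
#' form is the default; `method = "mean_ratio"` instead averages the
#' per-pair ratio of shared cells to the pair's mean cell count.
#'
#' @param cell_sets List (>= 2) of cell sets: character key vectors or
#'   integer `(i, j)` matrices as returned by [rasterize_trip()].
#' @param method `"ratio_of_means"` (default) or `"mean_ratio"`.
#' @return Index in `[0, 1]`.
#' @export
space_use_consistency_index <- function(cell_sets,
                                        method = c("ratio_of_means", "mean_ratio")) {
  method <- match.arg(method)
  if (length(cell_sets) < 2) {
    stop("space_use_consistency_index: need at least 2 trips")
  }
  sets <- lapply(cell_sets, cell_keys)
  if (any(vapply(sets, length, 1L) == 0)) {
    stop("space_use_consistency_index: every trip needs at least 1 cell")
  }
  n <- length(sets)
  pairs <- utils::combn(n, 2)
  shared <- apply(pairs, 2, function(p) {
    length(intersect(sets[[p[1]]], sets[[p[2]]]))
  })
  sizes <- vapply(sets, length, 1L)
  if (method == "ratio_of_means") {
    mean(shared) / mean(sizes)
  } else {
    pair_means <- apply(pairs, 2, function(p) mean(sizes[p]))
    mean(shared / pair_means)
  }
}

#' Agreement between two per-individual index vectors
#'
#' Ordinary least-squares regression of `index_b` on `index_a`; used to
#' compare the consistency index computed from full GPS tracks with the one
#' computed from dive locations only.
#'
#' @param index_a,index_b Paired numeric vectors, n >= 3.
#' @return List: `r_squared`, `slope`, `intercept`, `n`.
#' @export
index_agreement <- function(index_a, index_b) {
  ok <- is.finite(index_a) & is.finite(index_b)
  a <- index_a[ok]; b <- index_b[ok]
  if (length(a) < 3) stop("index_agreement: need at least 3 complete pairs")
  if (stats::var(a) == 0) stop("index_agreement: zero variance in predictor")
  fit <- stats::lm(b ~ a)
  # summary.lm warns on numerically perfect fits; R^2 and slope remain exact
  list(r_squared = suppressWarnings(summary(fit))$r.squared,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = length(a))
}

#' Build individual x stage behavioural profiles
#'
#' One row per individual and breeding stage: trip-metric means, CVs,
#' circular heading statistics, space-use consistency index, and (when dive
#' data are supplied) mean and CV of maximum dive depth. Individuals with a
#' single trip get NA CVs and index, with a warning.
#'
#' @param trips Trips metrics data.frame from [process_gps()].
#' @param cells List of per-trip cell sets matching `trips` rows.
#' @param dives Optional dive data.frame from [process_dives()].
#' @param index_method Passed to [space_use_consistency_index()].
#' @return Data.frame of profiles.
#' @export
build_profiles <- function(trips, cells, dives = NULL,
                           index_method = "ratio_of_means") {
  stopifnot(nrow(trips) == length(cells))
  keyfun <- interaction(trips$individual_id, trips$stage, drop = TRUE)
  singletons <- character()
  rows <- lapply(levels(keyfun), function(key) {
    sel <- which(keyfun == key)
    tr <- trips[sel, , drop = FALSE]
    n <- nrow(tr)
    circ <- circular_mean_sd(tr$heading_deg)
    if (n >= 2) {
      idx <- space_use_consistency_index(cells[sel], method = index_method)
      cvs <- c(cv(tr$duration_h), cv(tr$max_distance_km),
               cv(tr$total_distance_km))
    } else {
      singletons <<- c(singletons, key)
      idx <- NA_real_
      cvs <- rep(NA_real_, 3)
    }
    out <- data.frame(
      individual_id = tr$individual_id[1], stage = tr$stage[1],
      n_trips = n,
      mean_duration_h = mean(tr$duration_h),
      mean_max_distance_km = mean(tr$max_distance_km),
      mean_total_distance_km = mean(tr$total_distance_km),
      mean_heading_deg = circ$mean_deg,
      cv_duration = cvs[1], cv_max_distance = cvs[2],
      cv_total_distance = cvs[3],
      sd_heading = if (n >= 2) circ$sd_rad else NA_real_,
      consistency_index = idx,
      mean_max_depth_m = NA_real_, cv_max_depth = NA_real_,
      n_dives = 0L,
      stringsAsFactors = FALSE)
    if (!is.null(dives) && nrow(dives)) {
      dsel <- dives$individual_id == tr$individual_id[1] &
        (is.na(dives$stage) | dives$stage == tr$stage[1])
      dd <- dives$max_depth_m[dsel]
      if (length(dd)) {
        out$mean_max_depth_m <- mean(dd)
        out$n_dives <- length(dd)
        if (length(dd) >= 2 && mean(dd) != 0) out$cv_max_depth <- cv(dd)
      }
    }
    out
  })
  if (length(singletons)) {
    warning("build_profiles: single-trip profile(s) with NA CVs/index: ",
            paste(singletons, collapse = ", "))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
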