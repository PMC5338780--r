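# Small programmatic fixtures shared across test files.

t_utc <- function(s) as.POSIXct(s, origin = "1970-01-01", tz = "UTC")

# fixes data.frame from vectors of seconds-since-epoch, lat, lon
make_fixes <- function(sec, lat, lon) {
  data.frame(time = t_utc(sec), lat = lat, lon = lon)
}

# square-wave depth series: baseline with excursions to given depths,
# each excursion `len` samples long, separated by `gap` surface samples
make_square_depth <- function(depths, len = 20, gap = 30, offset = 0) {
  z <- numeric(0)
  for (d in depths) z <- c(z, rep(0, gap), rep(d, len))
  z <- c(z, rep(0, gap))
  data.frame(time = t_utc(seq_along(z)), depth_m = z + offset)
}

# independent nested-ANOVA method-of-moments oracle (balanced designs):
# a individuals x b trips x n observations per trip
nested_anova_mom <- function(y, individual, trip) {
  a <- length(unique(individual))
  b <- length(unique(trip)) / a
  n <- length(y) / (a * b)
  ybar <- mean(y)
  yi <- tapply(y, individual, mean)
  yij <- tapply(y, trip, mean)
  ind_of <- tapply(individual, trip, `[`, 1)[names(yij)]
  SSA <- b * n * sum((yi - ybar)^2)
  SSB <- n * sum((yij - yi[ind_of])^2)
  SSE <- sum((y - yij[trip])^2)
  MSA <- SSA / (a - 1)
  MSB <- SSB / (a * (b - 1))
  MSE <- SSE / (a * b * (n - 1))
  c(individual = (MSA - MSB) / (b * n),
    trip = (MSB - MSE) / n,
    residual = MSE)
}

# independent brute-force Ward agglomeration: at each step evaluate every
# pair merge by recomputing within-cluster sum of squares from scratch
brute_force_ward <- function(x) {
  x <- as.matrix(x)
  clusters <- as.list(seq_len(nrow(x)))
  wss <- function(idx) {
    if (length(idx) == 1) return(0)
    sum(scale(x[idx, , drop = FALSE], scale = FALSE)^2)
  }
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d_ss <- wss(c(clusters[[i]], clusters[[j]])) -
          wss(clusters[[i]]) - wss(clusters[[j]])
        if (is.null(best) || d_ss < best$d_ss) {
          best <- list(i = i, j = j, d_ss = d_ss)
        }
      }
    }
    merges[[length(merges) + 1L]] <- list(
      members = sort(c(clusters[[best$i]], clusters[[best$j]])),
      delta_ss = best$d_ss)
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  merges
}

# members of each cluster formed at every hclust merge step
hclust_merge_members <- function(hc) {
  out <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    mem <- integer(0)
    for (side in hc$merge[k, ]) {
      mem <- c(mem, if (side < 0) -side else out[[side]])
    }
    out[[k]] <- sort(mem)
  }
  out
}
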