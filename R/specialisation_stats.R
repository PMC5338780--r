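# Nested variance components and the proportion-of-variance specialisation
# statistic. The two-level model y = mu + a_ind + b_trip(ind) + e is fitted
# by REML with the residual scale profiled out and the two variance ratios
# optimised on the log scale; boundary solutions (either component zero) are
# evaluated explicitly and the best REML criterion kept, so estimates can
# never go negative. The proportion of total variance at the individual
# level is the repeatability / specialisation index.

# Per-individual sufficient quantities for W = I + gb*Zb Zb' + ga*11',
# computed in closed form from per-trip sizes and sums (Woodbury applied to
# the nested structure, so each evaluation is O(number of trips)). A block
# is list(nj = trip sizes, sj = trip response sums, sumsq = sum of squared
# responses). Returns logdet(W), 1'W^-1 1, 1'W^-1 y, y'W^-1 y accumulated
# over blocks.
reml_block_quantities <- function(blocks, ga, gb) {
  logdet <- 0; S1 <- 0; Sy <- 0; Syy <- 0
  for (bl in blocks) {
    d <- 1 + gb * bl$nj
    m <- sum(bl$nj / d)
    t1 <- sum(bl$sj / d)
    q <- bl$sumsq - gb * sum(bl$sj^2 / d)
    denom <- 1 + ga * m
    logdet <- logdet + sum(log(d)) + log(denom)
    S1 <- S1 + m / denom
    Sy <- Sy + t1 / denom
    Syy <- Syy + q - ga * t1^2 / denom
  }
  list(logdet = logdet, S1 = S1, Sy = Sy, Syy = Syy)
}

# Profiled REML log-likelihood (up to an additive constant) at variance
# ratios ga = s2_ind/s2_e, gb = s2_trip/s2_e.
reml_loglik_ratios <- function(blocks, n, ga, gb) {
  q <- reml_block_quantities(blocks, ga, gb)
  quad <- q$Syy - q$Sy^2 / q$S1
  if (quad <= 0) return(-Inf)
  s2e <- quad / (n - 1)
  -0.5 * (q$logdet + log(q$S1) + (n - 1) * log(s2e) + (n - 1))
}

#' Nested variance-components decomposition
#'
#' REML fit of the two-level random-effects model
#' `y = mu + a_individual + b_trip(individual) + e`, returning the variance,
#' standard deviation and percentage of total variance at the individual,
#' trip-within-individual and residual levels. The individual percentage is
#' the estimate of individual specialisation (behavioural repeatability).
#'
#' Trips with a single observation each leave the trip and residual
#' components unidentified jointly; when the within-trip variance is exactly
#' zero the decomposition is carried out on trip means (residual 0), and
#' when additionally each individual holds one trip all variance is
#' attributed to the individual level.
#'
#' @param y Numeric response (e.g. maximum dive depth per dive).
#' @param individual Individual labels, one per observation.
#' @param trip Trip labels nested in individual (a trip label may not recur
#'   under two individuals).
#' @return Object of class `variance_decomposition`: a data.frame with
#'   columns `level`, `sigma2`, `sigma`, `pct` and attributes `loglik_reml`,
#'   `truncated`, `degenerate`.
#' @export
fit_variance_components <- function(y, individual, trip) {
  stopifnot(length(y) == length(individual), length(y) == length(trip))
  individual <- as.character(individual); trip <- as.character(trip)
  if (length(unique(individual)) < 2) {
    stop("fit_variance_components: need at least 2 individuals")
  }
  n_ind_per_trip <- tapply(individual, trip, function(v) length(unique(v)))
  if (any(n_ind_per_trip > 1)) {
    stop("fit_variance_components: trip label(s) appear under more than one ",
         "individual; trips must be nested (use unique labels per individual)")
  }
  n <- length(y)
  out <- function(s2, loglik = NA_real_, truncated = FALSE, degenerate = FALSE) {
    tot <- sum(s2)
    res <- data.frame(level = c("individual", "trip", "residual"),
                      sigma2 = s2, sigma = sqrt(s2),
                      pct = if (tot > 0) 100 * s2 / tot else rep(NA_real_, 3))
    attr(res, "loglik_reml") <- loglik
    attr(res, "truncated") <- truncated
    attr(res, "degenerate") <- degenerate
    class(res) <- c("variance_decomposition", "data.frame")
    res
  }
  if (stats::var(y) == 0) {
    return(out(c(0, 0, 0), degenerate = TRUE))
  }
  trip_key <- paste(individual, trip, sep = "\r")
  within_ss <- sum(tapply(y, trip_key, function(v) sum((v - mean(v))^2)))
  if (within_ss <= .Machine$double.eps * sum(y^2)) {
    # residual variance zero: decompose at the trip-mean level
    ym <- tapply(y, trip_key, mean)
    ind_of_trip <- tapply(individual, trip_key, `[`, 1)[names(ym)]
    trips_per_ind <- table(ind_of_trip)
    if (all(trips_per_ind == 1)) {
      # one trip per individual: all between-individual
      return(out(c(stats::var(as.numeric(ym)), 0, 0), truncated = TRUE))
    }
    sub <- fit_one_way_reml(as.numeric(ym), as.character(ind_of_trip))
    return(out(c(sub$s2_between, sub$s2_within, 0),
               loglik = sub$loglik, truncated = TRUE))
  }
  # per-individual blocks: per-trip sizes and sums plus the block sum of
  # squares are sufficient for the REML criterion
  blocks <- lapply(split(seq_len(n), individual), function(idx) {
    yy <- y[idx]
    tk <- trip_key[idx]
    list(nj = as.numeric(table(tk)),
         sj = as.numeric(tapply(yy, tk, sum)),
         sumsq = sum(yy^2))
  })
  # moment-based starting values
  s2e0 <- within_ss / max(1, n - length(unique(trip_key)))
  vy <- stats::var(y)
  s2b0 <- max(vy / 4, s2e0 / 4)
  s2a0 <- max(vy / 4, s2e0 / 4)
  fits <- list()
  nll2 <- function(p) -reml_loglik_ratios(blocks, n, exp(p[1]), exp(p[2]))
  opt1 <- function(which_free) {
    # 1-d profile over the free log-ratio with the other component at 0
    fn <- function(l) {
      ga <- if (which_free == "a") exp(l) else 0
      gb <- if (which_free == "b") exp(l) else 0
      -reml_loglik_ratios(blocks, n, ga, gb)
    }
    o <- stats::optimize(fn, lower = -30, upper = 30, tol = 1e-10)
    list(par = o$minimum, nll = o$objective)
  }
  # full model: Nelder-Mead then cyclic 1-d polish for precision
  p0 <- c(log(s2a0 / s2e0), log(s2b0 / s2e0))
  o <- stats::optim(p0, nll2, method = "Nelder-Mead",
                    control = list(reltol = 1e-14, maxit = 4000))
  p <- o$par
  for (it in 1:3) {
    oa <- stats::optimize(function(l) nll2(c(l, p[2])),
                          lower = p[1] - 2, upper = p[1] + 2, tol = 1e-12)
    p[1] <- oa$minimum
    ob <- stats::optimize(function(l) nll2(c(p[1], l)),
                          lower = p[2] - 2, upper = p[2] + 2, tol = 1e-12)
    p[2] <- ob$minimum
  }
  fits$full <- list(ga = exp(p[1]), gb = exp(p[2]), nll = nll2(p))
  o <- opt1(which_free = "a")
  fits$no_trip <- list(ga = exp(o$par), gb = 0, nll = o$nll)
  o <- opt1(which_free = "b")
  fits$no_ind <- list(ga = 0, gb = exp(o$par), nll = o$nll)
  fits$none <- list(ga = 0, gb = 0,
                    nll = -reml_loglik_ratios(blocks, n, 0, 0))
  best <- fits[[which.min(vapply(fits, `[[`, 1, "nll"))]]
  ga <- best$ga; gb <- best$gb
  truncated <- FALSE
  if (ga < 1e-8) { ga <- 0; truncated <- TRUE }
  if (gb < 1e-8) { gb <- 0; truncated <- TRUE }
  if (!identical(best, fits$full)) truncated <- TRUE
  q <- reml_block_quantities(blocks, ga, gb)
  s2e <- (q$Syy - q$Sy^2 / q$S1) / (n - 1)
  out(c(ga * s2e, gb * s2e, s2e), loglik = -best$nll, truncated = truncated)
}

# One-way REML (between/within groups), used for the zero-residual branch.
fit_one_way_reml <- function(y, group) {
  n <- length(y)
  blocks <- lapply(split(y, group), function(v)
    list(nj = rep(1, length(v)), sj = v, sumsq = sum(v^2)))
  fn <- function(la) -reml_loglik_ratios(blocks, n, exp(la), 0)
  o <- stats::optimize(fn, lower = -30, upper = 30, tol = 1e-12)
  cand <- list(list(ga = exp(o$minimum), nll = o$objective),
               list(ga = 0, nll = -reml_loglik_ratios(blocks, n, 0, 0)))
  best <- cand[[which.min(vapply(cand, `[[`, 1, "nll"))]]
  q <- reml_block_quantities(blocks, best$ga, 0)
  s2w <- (q$Syy - q$Sy^2 / q$S1) / (n - 1)
  list(s2_between = best$ga * s2w, s2_within = s2w, loglik = -best$nll)
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat("Nested variance decomposition (REML)\n")
  df <- as.data.frame(x)
  df$sigma2 <- signif(df$sigma2, 5)
  df$sigma <- signif(df$sigma, 5)
  df$pct <- round(df$pct, 2)
  print(df, row.names = FALSE)
  if (isTRUE(attr(x, "truncated"))) {
    cat("note: one or more components at the zero boundary\n")
  }
  if (isTRUE(attr(x, "degenerate"))) {
    cat("note: degenerate input (constant response)\n")
  }
  invisible(x)
}

#' Write a variance decomposition as CSV
#'
#' One row per hierarchical level with variance, SD and percentage columns.
#'
#' @param vc `variance_decomposition` object (or a named list of them).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_variance_components_csv <- function(vc, path) {
  if (inherits(vc, "variance_decomposition")) vc <- list(response = vc)
  rows <- do.call(rbind, lapply(names(vc), function(nm) {
    df <- as.data.frame(vc[[nm]])
    cbind(response = nm, df)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Random-intercept model for a covariate effect
#'
#' REML fit of `y = b0 + b1 x + a_group + e` via lme4, with Wald standard
#' errors and conservative between-group degrees of freedom (number of
#' groups minus number of fixed effects). A perfectly linear response is
#' returned as an OLS fit with zero variance components.
#'
#' @param y Response vector.
#' @param x Covariate (must vary).
#' @param group Grouping labels (>= 2 groups).
#' @return List: `fixed_effects` (data.frame term/estimate/se/t/df/p),
#'   `sigma2_group`, `sigma2_resid`, `loglik_reml`.
#' @export
fit_random_intercept <- function(y, x, group) {
  group <- as.character(group)
  if (length(unique(group)) < 2) stop("fit_random_intercept: need >= 2 groups")
  if (stats::var(x) == 0) stop("fit_random_intercept: covariate is constant")
  df_wald <- length(unique(group)) - 2
  ols <- stats::lm(y ~ x)
  if (suppressWarnings(summary(ols))$sigma < 1e-10) {
    co <- suppressWarnings(summary(ols))$coefficients
    fe <- data.frame(term = c("(Intercept)", "x"), estimate = co[, 1],
                     se = co[, 2], t = NA_real_, df = df_wald, p = NA_real_)
    return(list(fixed_effects = fe, sigma2_group = 0, sigma2_resid = 0,
                loglik_reml = as.numeric(stats::logLik(ols))))
  }
  fit <- lme4::lmer(y ~ x + (1 | group), REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  co <- summary(fit)$coefficients
  tval <- co[, 1] / co[, 2]
  fe <- data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
                   t = tval, df = df_wald,
                   p = 2 * stats::pt(-abs(tval), max(df_wald, 1)),
                   row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(fit))
  list(fixed_effects = fe,
       sigma2_group = vc$vcov[vc$grp == "group"],
       sigma2_resid = vc$vcov[vc$grp == "Residual"],
       loglik_reml = as.numeric(stats::logLik(fit)))
}

#' Consistency regression between repeated measurements
#'
#' Regression of a later measurement on an earlier one (e.g. chick-rearing
#' blood isotope values on incubation values, or feather on blood), with a
#' pair-level random intercept when pairs contribute repeated observations
#' and an OLS fall-back when each pair contributes one observation. A slope
#' near 1 with high r indicates individual consistency.
#'
#' @param y_late,y_early Paired numeric vectors.
#' @param pair Pair/individual labels (default: each observation its own
#'   pair, giving OLS).
#' @return List: `slope`, `se`, `r`, `p`, `n`, `method`.
#' @export
consistency_regression <- function(y_late, y_early,
                                   pair = seq_along(y_late)) {
  ok <- is.finite(y_late) & is.finite(y_early)
  y_late <- y_late[ok]; y_early <- y_early[ok]
  pair <- as.character(pair[ok])
  if (length(y_late) < 3) stop("consistency_regression: need n >= 3")
  r <- stats::cor(y_early, y_late)
  if (!any(duplicated(pair)) || stats::var(y_late) < 1e-12) {
    fit <- stats::lm(y_late ~ y_early)
    co <- suppressWarnings(summary(fit))$coefficients
    return(list(slope = co[2, 1], se = co[2, 2], r = r, p = co[2, 4],
                n = length(y_late), method = "ols"))
  }
  fit <- lme4::lmer(y_late ~ y_early + (1 | pair), REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  co <- summary(fit)$coefficients
  df <- length(unique(pair)) - 2
  tval <- co[2, 1] / co[2, 2]
  list(slope = co[2, 1], se = co[2, 2], r = r,
       p = 2 * stats::pt(-abs(tval), max(df, 1)),
       n = length(y_late), method = "random_intercept")
}
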