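test_that("REML equals the Searle nested-ANOVA oracle on a balanced interior design", {
  set.seed(42)
  d <- simulate_nested_responses(6, 4, 5, mu = 10, sigma2_ind = 4,
                                 sigma2_trip = 2, sigma2_resid = 1)
  mom <- nested_anova_mom(d$y, d$individual, d$trip)
  # interior solution: all method-of-moments components positive
  expect_true(all(mom > 0))
  vc <- fit_variance_components(d$y, d$individual, d$trip)
  expect_equal(vc$sigma2, unname(mom), tolerance = 1e-6)
  expect_equal(vc$sigma, sqrt(vc$sigma2))
  expect_equal(sum(vc$pct), 100, tolerance = 0.1)
})

test_that("REML agrees with lme4 as an independent cross-check", {
  skip_if_not_installed("lme4")
  set.seed(43)
  d <- simulate_nested_responses(8, 3, 4, mu = 5, sigma2_ind = 3,
                                 sigma2_trip = 1.5, sigma2_resid = 1)
  vc <- fit_variance_components(d$y, d$individual, d$trip)
  f <- lme4::lmer(y ~ 1 + (1 | individual) + (1 | trip), data = d, REML = TRUE)
  v <- as.data.frame(lme4::VarCorr(f))
  expect_equal(vc$sigma2[1], v$vcov[v$grp == "individual"], tolerance = 1e-3)
  expect_equal(vc$sigma2[2], v$vcov[v$grp == "trip"], tolerance = 1e-3)
  expect_equal(vc$sigma2[3], v$vcov[v$grp == "Residual"], tolerance = 1e-3)
})

test_that("degenerate inputs decompose as specified", {
  # zero within-group variance, one trip per individual: all individual
  vc <- fit_variance_components(c(0, 0, 2, 2), c("A", "A", "B", "B"),
                                c("a1", "a1", "b1", "b1"))
  expect_equal(vc$sigma2[3], 0)
  expect_equal(vc$pct[1], 100)
  # constant response: all components zero, percentages undefined
  vc2 <- fit_variance_components(rep(3, 8), rep(c("A", "B"), each = 4),
                                 rep(c("a1", "a2", "b1", "b2"), each = 2))
  expect_true(all(vc2$sigma2 == 0))
  expect_true(all(is.na(vc2$pct)))
  expect_true(attr(vc2, "degenerate"))
  # unnested trip labels rejected
  expect_error(fit_variance_components(1:4, c("A", "A", "B", "B"),
                                       c("t1", "t1", "t1", "t1")),
               "nested")
})

test_that("variance percentages are invariant to affine rescaling of the response", {
  set.seed(44)
  d <- simulate_nested_responses(6, 3, 4, sigma2_ind = 2, sigma2_trip = 1,
                                 sigma2_resid = 0.5)
  vc1 <- fit_variance_components(d$y, d$individual, d$trip)
  vc2 <- fit_variance_components(7 * d$y + 3, d$individual, d$trip)
  expect_equal(vc1$pct, vc2$pct, tolerance = 1e-4)
  expect_equal(vc2$sigma2, 49 * vc1$sigma2, tolerance = 1e-4)
})

test_that("random-intercept covariate fits recover exact and null effects", {
  # perfectly linear response
  x <- rep(1:5, 4)
  g <- rep(letters[1:4], each = 5)
  fit <- fit_random_intercept(2 * x, x, g)
  expect_equal(fit$fixed_effects$estimate[2], 2, tolerance = 1e-9)
  expect_equal(fit$sigma2_resid, 0)
  # group effects only: slope ~ 0 within 2 SE
  set.seed(45)
  ge <- rnorm(8, 0, 2)[match(rep(letters[1:8], each = 6), letters[1:8])]
  xn <- rnorm(48)
  yn <- 1 + ge + rnorm(48, 0, 0.5)
  fit2 <- fit_random_intercept(yn, xn, rep(letters[1:8], each = 6))
  expect_lt(abs(fit2$fixed_effects$estimate[2]),
            2 * fit2$fixed_effects$se[2] + 1e-9)
  expect_error(fit_random_intercept(yn, rep(1, 48), rep(letters[1:8], each = 6)),
               "constant")
})

test_that("random-intercept fit matches the closed-form GLS oracle on a balanced toy", {
  # two groups, known variance ratio: GLS with compound-symmetric blocks
  y <- c(1.2, 1.9, 3.1, 3.9, 2.1, 2.9, 4.2, 5.0)
  x <- c(1, 2, 3, 4, 1, 2, 3, 4)
  g <- rep(c("g1", "g2"), each = 4)
  fit <- fit_random_intercept(y, x, g)
  s2g <- fit$sigma2_group; s2e <- fit$sigma2_resid
  # GLS normal equations at the fitted variance components
  V <- diag(s2e, 8)
  for (gg in unique(g)) V[g == gg, g == gg] <- V[g == gg, g == gg] + s2g
  X <- cbind(1, x)
  beta <- solve(t(X) %*% solve(V) %*% X, t(X) %*% solve(V) %*% y)
  se <- sqrt(diag(solve(t(X) %*% solve(V) %*% X)))
  expect_equal(fit$fixed_effects$estimate, as.numeric(beta), tolerance = 1e-6)
  expect_equal(fit$fixed_effects$se, unname(se), tolerance = 1e-6)
})

test_that("consistency regression recovers identity, null and shrunk slopes", {
  y <- c(1, 2, 3, 4, 5)
  out <- consistency_regression(y, y)
  expect_equal(out$slope, 1)
  expect_equal(out$r, 1)
  # uncorrelated tissues: slope ~ 0 within 2 SE
  set.seed(46)
  e1 <- rnorm(40); e2 <- rnorm(40)
  out2 <- consistency_regression(e2, e1)
  expect_lt(abs(out2$slope), 2 * out2$se + 1e-9)
  # slope 0.9 recovered within its confidence interval
  early <- rnorm(60, 0, 1.5)
  late <- 0.9 * early + rnorm(60, 0, 0.2)
  out3 <- consistency_regression(late, early)
  expect_lt(abs(out3$slope - 0.9), 2.5 * out3$se)
  expect_gt(out3$r, 0.9)
  expect_error(consistency_regression(1:2, 1:2), "n >= 3")
})

test_that("variance shares are recovered without bias across simulated populations", {
  set.seed(47)
  est <- replicate(40, {
    d <- simulate_nested_responses(12, 5, 5, sigma2_ind = 4, sigma2_trip = 2,
                                   sigma2_resid = 1)
    fit_variance_components(d$y, d$individual, d$trip)$pct[1]
  })
  truth <- 100 * 4 / 7
  expect_lt(abs(mean(est) - truth), 5)
})
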