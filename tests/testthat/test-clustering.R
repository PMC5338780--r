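test_that("standardization yields unit-variance columns and drops constants", {
  x <- cbind(a = c(1, 3), b = c(10, 20))
  z <- standardize(x)
  expect_equal(as.numeric(z), c(-1, 1, -1, 1) / sqrt(2))
  # idempotent on already-standardized data
  set.seed(6)
  m <- matrix(rnorm(40), 10, 4)
  z1 <- standardize(m)
  expect_equal(unclass(standardize(z1)), unclass(z1), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(abs(colMeans(z1)) < 1e-9))
  expect_true(all(abs(apply(z1, 2, sd) - 1) < 1e-9))
  expect_warning(z2 <- standardize(cbind(a = c(1, 2, 3), b = c(5, 5, 5))),
                 "zero-variance")
  expect_equal(colnames(z2), "a")
})

test_that("Ward agglomeration matches the brute-force merge-order oracle", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  hc <- ward_cluster(x)
  oracle <- brute_force_ward(x)
  got <- hclust_merge_members(hc)
  for (k in seq_along(oracle)) {
    expect_equal(got[[k]], oracle[[k]]$members)
  }
  # ward.D2 heights are sqrt(2 * increase in within-cluster SS)
  expect_equal(hc$height, sqrt(2 * vapply(oracle, `[[`, 1.0, "delta_ss")),
               tolerance = 1e-9)
  # heights monotone non-decreasing
  expect_true(all(diff(hc$height) >= -1e-12))
  # total inertia conserved: sum of merge criteria = total within-SS
  expect_equal(sum(hc$height^2 / 2), sum(scale(x, scale = FALSE)^2),
               tolerance = 1e-9)
  # identical rows merge at height zero
  xx <- matrix(rep(c(1, 5), each = 3), ncol = 1)
  expect_equal(ward_cluster(xx)$height[1:4], rep(0, 4), tolerance = 1e-12)
})

test_that("height-gap criterion selects the planted cluster count", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  expect_equal(choose_k(ward_cluster(x)), 2)
  # three well-separated blobs
  set.seed(7)
  y <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 20), 10, 2),
             matrix(rnorm(20, 40), 10, 2))
  expect_equal(choose_k(ward_cluster(y)), 3)
  # equally spaced points: any valid k in range
  z <- matrix(seq(0, 10, 1), ncol = 1)
  k <- choose_k(ward_cluster(z))
  expect_gte(k, 2)
  expect_lte(k, 8)
})

test_that("two separated Gaussian blobs are recovered exactly at the 2-cluster cut", {
  set.seed(8)
  lab <- rep(1:2, each = 15)
  x <- matrix(rnorm(60), 30, 2) + 10 * (lab - 1)
  hc <- ward_cluster(x)
  cut <- stats::cutree(hc, 2)
  expect_equal(adjusted_rand_index(cut, lab), 1)
  # cluster labels invariant to row permutation (up to renaming)
  perm <- sample(30)
  cut_p <- stats::cutree(ward_cluster(x[perm, ]), 2)
  expect_equal(adjusted_rand_index(cut_p, lab[perm]), 1)
})

test_that("adjusted Rand index matches the mclust implementation", {
  skip_if_not_installed("mclust")
  set.seed(9)
  for (i in 1:5) {
    a <- sample(1:4, 25, replace = TRUE)
    b <- sample(1:3, 25, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjusted_rand_index(1:5, c(2, 3, 4, 5, 1)), 1)
})

test_that("cluster comparison reduces to F = t^2 on a balanced two-group toy", {
  y <- c(1.1, 2.0, 1.5, 1.8, 3.2, 3.9, 3.5, 3.1)
  lab <- rep(1:2, each = 4)
  out <- compare_clusters(lab, y)
  tt <- t.test(y[lab == 1], y[lab == 2], var.equal = TRUE)
  expect_equal(out$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(out$p_value, tt$p.value, tolerance = 1e-9)
  # identical response across clusters: no evidence
  out2 <- compare_clusters(rep(1:2, each = 4), rep(2, 8))
  expect_true(is.na(out2$p_value) || out2$p_value > 0.99)
  # strongly shifted cluster means on the mixed-model route
  set.seed(10)
  ind <- rep(sprintf("i%d", 1:8), each = 2)
  cl <- rep(rep(1:2, each = 4), 2)
  resp <- 10 * (cl - 1) + rnorm(16, 0, 1)
  out3 <- compare_clusters(cl, resp, individual = ind)
  expect_lt(out3$p_value, 0.001)
  expect_match(out3$method, "LRT")
})

test_that("singleton clusters are excluded from pairwise comparisons with a warning", {
  y <- c(rnorm(4), rnorm(4, 5), 99)
  lab <- c(rep(1, 4), rep(2, 4), 3)
  expect_warning(out <- compare_clusters(lab, y), "singleton")
  expect_equal(nrow(out$pairwise), 1)
})

test_that("feature matrix encodes heading circularly and drops incomplete rows", {
  prof <- data.frame(
    individual_id = c("a", "b", "c", "d"), stage = "chick_rearing",
    mean_total_distance_km = c(10, 20, 30, 40),
    mean_max_distance_km = c(5, 9, 14, 18),
    mean_duration_h = c(2, 3, 4, 5),
    mean_heading_deg = c(359, 1, 180, 90),
    cv_total_distance = c(0.1, 0.2, 0.3, NA),
    sd_heading = c(0.1, 0.2, 0.3, 0.4),
    consistency_index = c(0.9, 0.5, 0.4, 0.3))
  expect_warning(x <- build_feature_matrix(prof), "missing")
  expect_equal(nrow(x), 3)
  expect_true(all(c("heading_cos", "heading_sin") %in% colnames(x)))
  # raw circular encoding keeps 359 and 1 degrees adjacent
  th <- prof$mean_heading_deg[1:2] * pi / 180
  expect_lt(abs(cos(th[1]) - cos(th[2])), 1e-3)
})
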