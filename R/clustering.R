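# Ward agglomeration of individual x stage behavioural profiles into
# foraging strategies, with automatic cluster-count selection by the
# largest gap in merge heights and mixed-model comparisons across clusters.

#' Standardize a feature matrix
#'
#' Per-column z-scores (n-1 SD). Zero-variance columns are dropped with a
#' warning since they carry no clustering information.
#'
#' @param features Numeric matrix or data.frame.
#' @return Standardized numeric matrix.
#' @export
standardize <- function(features) {
  x <- as.matrix(features)
  if (nrow(x) < 2) stop("standardize: need at least 2 rows")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("standardize: dropping zero-variance column(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  scale(x, center = TRUE, scale = sds)
}

#' Build the clustering feature matrix from profiles
#'
#' Selects the spatial means and CVs used to define foraging strategies,
#' encodes the circular mean heading as a (cos, sin) pair so that 359 and 1
#' degree headings are neighbours, drops rows with missing features (single-
#' trip profiles) with a warning, and standardizes.
#'
#' @param profiles Profiles data.frame from [build_profiles()].
#' @param features Character vector of profile columns; `mean_heading_deg`
#'   is expanded to `heading_cos` + `heading_sin`.
#' @return Standardized matrix with rownames `individual_id|stage`.
#' @export
build_feature_matrix <- function(profiles,
                                 features = c("mean_total_distance_km",
                                              "mean_max_distance_km",
                                              "mean_duration_h",
                                              "mean_heading_deg",
                                              "cv_total_distance",
                                              "sd_heading",
                                              "consistency_index")) {
  x <- profiles[, setdiff(features, "mean_heading_deg"), drop = FALSE]
  if ("mean_heading_deg" %in% features) {
    th <- profiles$mean_heading_deg * pi / 180
    x$heading_cos <- cos(th)
    x$heading_sin <- sin(th)
  }
  x <- as.matrix(x)
  rownames(x) <- paste(profiles$individual_id, profiles$stage, sep = "|")
  ok <- apply(x, 1, function(r) all(is.finite(r)))
  if (!all(ok)) {
    warning("build_feature_matrix: dropping row(s) with missing features: ",
            paste(rownames(x)[!ok], collapse = ", "))
    x <- x[ok, , drop = FALSE]
  }
  standardize(x)
}

#' Ward hierarchical clustering
#'
#' Agglomeration on Euclidean distance with the Ward.D2 criterion
#' (Lance-Williams update; merge heights are the square root of twice the
#' increase in within-cluster sum of squares).
#'
#' @param x Standardized feature matrix (>= 3 rows).
#' @return An `hclust` object.
#' @export
ward_cluster <- function(x) {
  if (nrow(x) < 3) stop("ward_cluster: need at least 3 rows")
  stats::hclust(stats::dist(x), method = "ward.D2")
}

#' Choose the number of clusters from a dendrogram
#'
#' Picks the partition preceding the largest gap between successive merge
#' heights, searched over 2..min(k_max, rows - 1): a large jump in the Ward
#' criterion means the next merge would fuse well-separated groups.
#'
#' @param hc `hclust` object from [ward_cluster()].
#' @param k_max Largest cluster count considered.
#' @return Integer k.
#' @export
choose_k <- function(hc, k_max = 8) {
  m <- length(hc$height)
  ks <- 2:min(k_max, m)
  gaps <- vapply(ks, function(k) {
    upper <- hc$height[m - k + 2]
    lower <- hc$height[m - k + 1]
    upper - lower
  }, 1.0)
  ks[which.max(gaps)]
}

#' Cluster behavioural profiles into foraging strategies
#'
#' Feature construction, Ward clustering and automatic k selection in one
#' step.
#'
#' @param profiles Profiles data.frame from [build_profiles()].
#' @param k Cluster count; `NULL` (default) selects it via [choose_k()].
#' @param k_max Passed to [choose_k()].
#' @param features Passed to [build_feature_matrix()].
#' @return List: `assignments` (data.frame individual_id, stage, cluster),
#'   `hclust`, `k`, `features` (the standardized matrix).
#' @export
cluster_profiles <- function(profiles, k = NULL, k_max = 8,
                             features = NULL) {
  x <- if (is.null(features)) build_feature_matrix(profiles) else
    build_feature_matrix(profiles, features)
  hc <- ward_cluster(x)
  if (is.null(k)) k <- choose_k(hc, k_max)
  labels <- stats::cutree(hc, k = k)
  ids <- do.call(rbind, strsplit(rownames(x), "|", fixed = TRUE))
  list(assignments = data.frame(individual_id = ids[, 1], stage = ids[, 2],
                                cluster = as.integer(labels),
                                stringsAsFactors = FALSE),
       hclust = hc, k = k, features = x)
}

#' Compare a response across clusters
#'
#' With repeated individuals, a likelihood-ratio comparison (ML) of
#' random-intercept models with and without the cluster factor; otherwise a
#' one-way ANOVA F test. Pairwise Welch t-tests between clusters with at
#' least two rows are reported descriptively; singleton clusters are
#' excluded from the pairwise table with a warning.
#'
#' @param labels Cluster labels, one per row.
#' @param response Numeric response per row (e.g. body mass, blood d15N).
#' @param individual Optional individual ids (repeats trigger the
#'   mixed-model route).
#' @param stage Optional stage labels; individuals are nested in stages in
#'   the random part.
#' @return List: `statistic`, `df`, `p_value`, `method`, `pairwise`.
#' @export
compare_clusters <- function(labels, response, individual = NULL,
                             stage = NULL) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("compare_clusters: need >= 2 clusters")
  if (stats::var(response) == 0) {
    # identical response everywhere: no evidence of cluster differences
    return(list(statistic = 0, df = nlevels(labels) - 1, p_value = 1,
                method = "degenerate (constant response)", pairwise = NULL))
  }
  mixed <- !is.null(individual) && any(duplicated(individual))
  if (mixed) {
    dat <- data.frame(y = response, cl = labels,
                      ind = as.character(individual))
    ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
    if (!is.null(stage)) {
      dat$stg <- as.character(stage)
      null_fit <- lme4::lmer(y ~ 1 + (1 | stg / ind), data = dat,
                             REML = FALSE, control = ctrl)
      full_fit <- lme4::lmer(y ~ cl + (1 | stg / ind), data = dat,
                             REML = FALSE, control = ctrl)
    } else {
      null_fit <- lme4::lmer(y ~ 1 + (1 | ind), data = dat, REML = FALSE,
                             control = ctrl)
      full_fit <- lme4::lmer(y ~ cl + (1 | ind), data = dat, REML = FALSE,
                             control = ctrl)
    }
    aa <- stats::anova(null_fit, full_fit)
    statistic <- aa$Chisq[2]; dfree <- aa$Df[2]; p <- aa$`Pr(>Chisq)`[2]
    method <- "LRT random-intercept"
  } else {
    aa <- stats::anova(stats::lm(response ~ labels))
    statistic <- aa$`F value`[1]; dfree <- aa$Df[1]; p <- aa$`Pr(>F)`[1]
    method <- "one-way ANOVA F"
  }
  sizes <- table(labels)
  big <- names(sizes)[sizes >= 2]
  if (length(big) < length(sizes)) {
    warning("compare_clusters: singleton cluster(s) excluded from pairwise ",
            "tests: ", paste(setdiff(names(sizes), big), collapse = ", "))
  }
  pw <- NULL
  if (length(big) >= 2) {
    combs <- utils::combn(big, 2)
    pw <- do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
      a <- combs[1, i]; b <- combs[2, i]
      tt <- tryCatch(stats::t.test(response[labels == a],
                                   response[labels == b]),
                     error = function(e) NULL)
      if (is.null(tt)) {
        # essentially constant data: no evidence of a difference
        return(data.frame(cluster_a = a, cluster_b = b,
                          diff = mean(response[labels == a]) -
                            mean(response[labels == b]),
                          t = NA_real_, df = NA_real_, p = NA_real_,
                          stringsAsFactors = FALSE))
      }
      data.frame(cluster_a = a, cluster_b = b,
                 diff = unname(diff(rev(tt$estimate))),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, stringsAsFactors = FALSE)
    }))
  }
  list(statistic = statistic, df = dfree, p_value = p, method = method,
       pairwise = pw)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same rows;
#' 1 for identical partitions (up to label renaming), ~0 for independent
#' ones. Used to score recovery of planted strategies in simulations.
#'
#' @param a,b Label vectors of equal length.
#' @return Numeric ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n2 <- ch2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

#' Export a dendrogram in Newick-like nested format
#'
#' @param hc `hclust` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  build <- function(node) {
    if (node < 0) return(hc$labels[-node])
    h <- hc$height[node]
    left <- build(hc$merge[node, 1])
    right <- build(hc$merge[node, 2])
    sprintf("(%s,%s):%.6g", left, right, h)
  }
  writeLines(paste0(build(length(hc$height)), ";"), path)
  invisible(path)
}
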