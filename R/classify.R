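#' Classify sites into climate groups by k-means
#'
#' Clusters sites on standardized climate covariates (coolest-quarter
#' precipitation, mean minimum temperature, altitude by default), keeping
#' the best of `restarts` k-means solutions by total within-cluster sum of
#' squares. Deterministic under a fixed seed.
#'
#' @param climate data.frame with site_id and the covariate columns.
#' @param k number of clusters (default 2: high/low rainfall).
#' @param restarts random restarts (default 25).
#' @param seed integer seed (required; k-means is initialization-sensitive).
#' @param covariates covariate columns to use.
#' @return list of class `env_assignment`: assignments (data.frame site_id,
#'   cluster), centers (original units), centers_scaled, tot_withinss,
#'   restarts, dropped covariates.
#' @export
classify_sites <- function(climate, k = 2, restarts = 25, seed,
                           covariates = c("precip_coolest_quarter_mm",
                                          "tmin_mean_coolest_C",
                                          "altitude_m")) {
  if (missing(seed)) stop("classify_sites requires an explicit seed")
  stopifnot("site_id" %in% names(climate))
  covariates <- intersect(covariates, names(climate))
  if (length(covariates) == 0) stop("no usable climate covariates found")
  if (nrow(climate) < k)
    stop("fewer sites (", nrow(climate), ") than clusters (", k, ")")
  X <- as.matrix(climate[, covariates, drop = FALSE])
  sds <- apply(X, 2, stats::sd)
  dropped <- covariates[sds == 0 | is.na(sds)]
  if (length(dropped)) {
    warning("dropping constant covariate(s): ", paste(dropped, collapse = ", "))
    covariates <- setdiff(covariates, dropped)
  }
  if (length(covariates) == 0 ||
      nrow(unique(climate[, covariates, drop = FALSE])) < k)
    stop("cannot form ", k, " distinct clusters: sites are not separable ",
         "on the available covariates")
  X <- as.matrix(climate[, covariates, drop = FALSE])
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  Z <- scale(X, center = mu, scale = sd_)
  set.seed(seed)
  if (nrow(Z) == k) {
    ## exact solution: every site is its own cluster (zero within-SS)
    km <- list(cluster = seq_len(k), centers = Z,
               tot.withinss = 0)
  } else {
    km <- stats::kmeans(Z, centers = k, nstart = restarts, iter.max = 100)
  }
  centers <- sweep(sweep(km$centers, 2, sd_, "*"), 2, mu, "+")
  out <- list(assignments = data.frame(site_id = climate$site_id,
                                       cluster = km$cluster,
                                       stringsAsFactors = FALSE),
              centers = centers,
              centers_scaled = km$centers,
              covariates = covariates,
              dropped = dropped,
              tot_withinss = km$tot.withinss,
              restarts = restarts,
              k = k)
  class(out) <- "env_assignment"
  out
}

#' Attach semantic high-/low-rainfall labels to a clustering
#'
#' The cluster with the higher mean coolest-quarter precipitation is
#' labeled `high_rainfall`, the other `low_rainfall` (ties broken by
#' altitude: the lower-altitude cluster becomes low_rainfall, with a
#' warning). Each site is also checked against the 150 mm precipitation
#' rule; sites whose label disagrees with their own precipitation are
#' flagged threshold-inconsistent. Idempotent.
#'
#' @param assignment an `env_assignment` from [classify_sites()].
#' @param climate the climate data.frame used for clustering.
#' @param precip_threshold mm separating high from low rainfall (150).
#' @return the assignment with `assignments$label` and
#'   `assignments$threshold_consistent` filled in.
#' @export
label_clusters <- function(assignment, climate, precip_threshold = 150) {
  stopifnot(inherits(assignment, "env_assignment"))
  if (assignment$k != 2)
    stop("semantic labeling requires k = 2 clusters")
  a <- assignment$assignments
  pr <- climate$precip_coolest_quarter_mm[match(a$site_id, climate$site_id)]
  mp <- tapply(pr, a$cluster, mean)
  if (length(unique(mp)) == 1) {
    alt <- climate$altitude_m[match(a$site_id, climate$site_id)]
    ma <- tapply(alt, a$cluster, mean)
    warning("clusters have equal mean precipitation; ",
            "labeling the lower-altitude cluster low_rainfall")
    low_cl <- as.integer(names(ma)[which.min(ma)])
  } else {
    low_cl <- as.integer(names(mp)[which.min(mp)])
  }
  a$label <- ifelse(a$cluster == low_cl, "low_rainfall", "high_rainfall")
  a$threshold_consistent <-
    (a$label == "high_rainfall") == (pr > precip_threshold)
  assignment$assignments <- a
  assignment$precip_threshold <- precip_threshold
  assignment
}
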