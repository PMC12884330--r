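#' Functional active-zone geometry from release-event positions
#'
#' The functional AZ is the convex hull of all detected release events
#' at a bouton; its area (shoelace formula) and area-weighted polygon
#' centroid define the AZ size and center. Fewer than 3 distinct points,
#' or collinear points, give a degenerate hull with zero area and the
#' centroid at the mean of the points.
#'
#' @param points_nm matrix or data.frame of event x/y coordinates, nm.
#' @return an object of class `az_geometry`: list with `hull_vertices`
#'   (counter-clockwise ordered), `area_nm2`, `centroid_nm`, `n_events`,
#'   `degenerate`.
#' @export
compute_az <- function(points_nm) {
  pts <- as.matrix(points_nm)
  stopifnot(ncol(pts) == 2, nrow(pts) >= 1)
  storage.mode(pts) <- "double"
  hull_idx <- grDevices::chull(pts[, 1], pts[, 2])
  hv <- pts[hull_idx, , drop = FALSE]
  n <- nrow(hv)
  degenerate <- n < 3L
  area <- 0
  centroid <- colMeans(pts)
  if (!degenerate) {
    i2 <- c(2:n, 1)
    cross <- hv[, 1] * hv[i2, 2] - hv[i2, 1] * hv[, 2]
    a2 <- sum(cross)            # chull() returns clockwise; sign handled
    area <- abs(a2) / 2
    if (area <= 1e-9) {
      degenerate <- TRUE        # collinear
      area <- 0
    } else {
      centroid <- c(sum((hv[, 1] + hv[i2, 1]) * cross),
                    sum((hv[, 2] + hv[i2, 2]) * cross)) / (3 * a2)
    }
  }
  structure(list(hull_vertices = hv, area_nm2 = area,
                 centroid_nm = unname(centroid),
                 n_events = nrow(pts), degenerate = degenerate),
            class = "az_geometry")
}

#' @export
print.az_geometry <- function(x, ...) {
  cat(sprintf("az_geometry: %d events, area %.0f nm^2, centroid (%.1f, %.1f)%s\n",
              x$n_events, x$area_nm2, x$centroid_nm[1], x$centroid_nm[2],
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Distances from each event to the AZ center
#'
#' @param points_nm event coordinates, nm.
#' @param centroid_nm length-2 AZ center (from [compute_az()]).
#' @return list: `distances_nm`, `mean_nm`, `median_nm`.
#' @export
event_center_distances <- function(points_nm, centroid_nm) {
  pts <- as.matrix(points_nm)
  stopifnot(length(centroid_nm) == 2)
  d <- sqrt((pts[, 1] - centroid_nm[1])^2 + (pts[, 2] - centroid_nm[2])^2)
  list(distances_nm = d, mean_nm = mean(d), median_nm = stats::median(d))
}

#' All pairwise distances between events of one AZ
#'
#' @param points_nm event coordinates, nm (>= 2 rows for a non-empty
#'   result).
#' @return list: `distances_nm` (condensed vector of n(n-1)/2 values),
#'   `mean_nm`, `median_nm`, `empty` flag.
#' @export
pairwise_distances <- function(points_nm) {
  pts <- as.matrix(points_nm)
  if (nrow(pts) < 2L)
    return(list(distances_nm = numeric(0), mean_nm = NA_real_,
                median_nm = NA_real_, empty = TRUE))
  d <- as.vector(stats::dist(pts))
  list(distances_nm = d, mean_nm = mean(d),
       median_nm = stats::median(d), empty = FALSE)
}

#' Release-site clustering at a fixed cluster diameter
#'
#' Agglomerative hierarchical clustering with complete linkage, cut at
#' `diameter_nm`. Complete linkage is the one standard linkage whose cut
#' height bounds the cluster diameter: every pair of events within a
#' cluster is at most `diameter_nm` apart.
#'
#' @param points_nm event coordinates, nm.
#' @param diameter_nm maximum intra-cluster pairwise distance (default
#'   50 nm).
#' @return an object of class `site_clustering`: list with `labels`
#'   (cluster id per event), `n_sites`, `events_per_site`,
#'   `site_centroids_nm` (one row per site), `diameter_nm`.
#' @export
cluster_release_sites <- function(points_nm, diameter_nm = 50) {
  pts <- as.matrix(points_nm)
  stopifnot(nrow(pts) >= 1, diameter_nm > 0)
  if (nrow(pts) == 1L) {
    labels <- 1L
  } else {
    hc <- stats::hclust(stats::dist(pts), method = "complete")
    labels <- stats::cutree(hc, h = diameter_nm)
  }
  k <- max(labels)
  centroids <- t(vapply(seq_len(k), function(cl)
    colMeans(pts[labels == cl, , drop = FALSE]), numeric(2)))
  structure(list(labels = labels, n_sites = k,
                 events_per_site = as.integer(table(labels)),
                 site_centroids_nm = centroids,
                 diameter_nm = diameter_nm),
            class = "site_clustering")
}

#' @export
print.site_clustering <- function(x, ...) {
  cat(sprintf("site_clustering: %d sites over %d events (diameter %.0f nm)\n",
              x$n_sites, length(x$labels), x$diameter_nm))
  invisible(x)
}

#' Full spatial summary for one synapse
#'
#' @param points_nm event coordinates, nm.
#' @param diameter_nm clustering diameter for release sites.
#' @return list: `az` (an `az_geometry`), `sites` (a `site_clustering`),
#'   `center_distances`, `pair_distances`.
#' @export
spatial_summary <- function(points_nm, diameter_nm = 50) {
  az <- compute_az(points_nm)
  list(az = az,
       sites = cluster_release_sites(points_nm, diameter_nm),
       center_distances = event_center_distances(points_nm,
                                                 az$centroid_nm),
       pair_distances = pairwise_distances(points_nm))
}
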