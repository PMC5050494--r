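#' Polygon-based cluster morphology
#'
#' Describes each cluster of a [dbscan()]/[extract_dbscan()] partition by its
#' convex hull: area, perimeter, circularity \eqn{4\pi A / P^2} (1 for a
#' disc), centroid (mean of member coordinates), maximum diameter (largest
#' hull vertex distance) and the number of member localizations (the "copy
#' number" proxy at the localization level). Clusters whose points are fewer
#' than 3 or collinear are flagged degenerate: their area is 0 and
#' circularity is reported as `NA`.
#'
#' @param table the [loc_table()] (or n x 2 matrix) that was clustered.
#' @param result the matching `cluster_result` (labels aligned with rows).
#' @return A data frame of class `cluster_shapes`, one row per non-noise
#'   cluster, with columns `cluster_id`, `n_localizations`, `area`,
#'   `perimeter`, `circularity`, `centroid_x`, `centroid_y`, `max_diameter`,
#'   `degenerate`; the hull vertex polygons are in `attr(, "hulls")` (list of
#'   matrices, in cluster order).
#' @examples
#' m <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' res <- dbscan(m, eps = 2, min_pts = 2)
#' cluster_morphology(m, res)
#' @export
cluster_morphology <- function(table, result) {
  xy <- if (is_loc_table(table)) as_xy_matrix(table) else coerce_points(table)
  stopifnot(inherits(result, "cluster_result"),
            length(result$labels) == nrow(xy))
  ids <- sort(unique(result$labels[result$labels >= 0L]))
  rows <- vector("list", length(ids))
  hulls <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    idx <- which(result$labels == ids[k])
    pts <- xy[idx, , drop = FALSE]
    hull_idx <- grDevices::chull(pts[, 1], pts[, 2])
    hull <- pts[hull_idx, , drop = FALSE]
    ar <- polygon_area(hull)
    degenerate <- nrow(hull) < 3L || ar <= 0
    per <- if (degenerate) 0 else polygon_perimeter(hull)
    rows[[k]] <- data.frame(
      cluster_id = ids[k],
      n_localizations = length(idx),
      area = if (degenerate) 0 else ar,
      perimeter = per,
      circularity = if (degenerate) NA_real_ else 4 * pi * ar / per^2,
      centroid_x = mean(pts[, 1]),
      centroid_y = mean(pts[, 2]),
      max_diameter = if (nrow(pts) < 2L) 0 else max(stats::dist(hull)),
      degenerate = degenerate)
    hulls[[k]] <- hull
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = integer(0), n_localizations = integer(0),
               area = numeric(0), perimeter = numeric(0),
               circularity = numeric(0), centroid_x = numeric(0),
               centroid_y = numeric(0), max_diameter = numeric(0),
               degenerate = logical(0))
  rownames(out) <- NULL
  structure(out, hulls = hulls, class = c("cluster_shapes", "data.frame"))
}

# Shoelace formula; vertices in order, not necessarily closed.
polygon_area <- function(v) {
  k <- nrow(v)
  if (k < 3L) return(0)
  j <- c(2:k, 1L)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

polygon_perimeter <- function(v) {
  k <- nrow(v)
  if (k < 2L) return(0)
  j <- c(2:k, 1L)
  sum(sqrt((v[j, 1] - v[, 1])^2 + (v[j, 2] - v[, 2])^2))
}
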