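#' Filter a localization table
#'
#' Selects the subset of localizations satisfying all of the given
#' predicates, preserving row order. Rectangular regions of interest use the
#' half-open convention `[x0, x1) x [y0, y1)` so that a tiling of ROIs
#' partitions the localizations uniquely; polygon ROIs use standard
#' point-in-polygon containment.
#'
#' @param table a [loc_table()].
#' @param roi `NULL`, a numeric length-4 rectangle `c(x0, y0, x1, y1)` in nm,
#'   or a two-column matrix of polygon vertices (nm, simple polygon).
#' @param frame_range `NULL` or `c(lo, hi)` (inclusive, 0-based frames).
#' @param min_photons `NULL` or minimum photon count (requires a `photons`
#'   column).
#' @return A [loc_table()] with the selected rows; when `roi` is given the
#'   region is updated to the ROI bounding box.
#' @examples
#' tab <- loc_table(data.frame(x = c(100, 110, 500), y = c(100, 110, 500),
#'                             frame = c(0, 0, 1)))
#' nrow(filter_localizations(tab, roi = c(0, 0, 300, 300)))
#' @export
filter_localizations <- function(table, roi = NULL, frame_range = NULL,
                                 min_photons = NULL) {
  stopifnot(is_loc_table(table))
  keep <- rep(TRUE, nrow(table))
  region <- loc_region(table)
  if (!is.null(roi)) {
    if (is.matrix(roi) || (is.data.frame(roi) && ncol(roi) == 2L)) {
      poly <- as.matrix(roi)
      stopifnot(ncol(poly) == 2L, nrow(poly) >= 3L)
      if (polygon_self_intersects(poly)) {
        stop("roi polygon must be simple (non-self-intersecting)")
      }
      keep <- keep & mgcv::in.out(poly, as_xy_matrix(table))
      region <- c(min(poly[, 1]), min(poly[, 2]),
                  max(poly[, 1]), max(poly[, 2]))
    } else {
      roi <- as.numeric(roi)
      stopifnot(length(roi) == 4L)
      if (roi[3] <= roi[1] || roi[4] <= roi[2]) {
        stop("roi rectangle must have positive width and height")
      }
      keep <- keep & table$x >= roi[1] & table$x < roi[3] &
        table$y >= roi[2] & table$y < roi[4]
      region <- roi
    }
  }
  if (!is.null(frame_range)) {
    stopifnot(length(frame_range) == 2L)
    if (frame_range[2] < frame_range[1]) {
      stop("inverted frame_range: lo must be <= hi")
    }
    keep <- keep & table$frame >= frame_range[1] & table$frame <= frame_range[2]
  }
  if (!is.null(min_photons)) {
    if (is.null(table$photons)) stop("table has no photons column")
    keep <- keep & !is.na(table$photons) & table$photons >= min_photons
  }
  subset_loc_table(table, which(keep), region = region)
}

# Segment-intersection test over all non-adjacent edge pairs (polygons here
# have few vertices, O(k^2) is fine).
polygon_self_intersects <- function(poly) {
  k <- nrow(poly)
  if (k < 4L) return(FALSE)
  edges <- cbind(seq_len(k), c(seq_len(k)[-1], 1L))
  cross2 <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  seg_int <- function(p1, p2, q1, q2) {
    d1 <- cross2(q1, q2, p1); d2 <- cross2(q1, q2, p2)
    d3 <- cross2(p1, p2, q1); d4 <- cross2(p1, p2, q2)
    ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
  }
  for (i in seq_len(k - 2L)) {
    for (j in seq.int(i + 2L, k)) {
      if (i == 1L && j == k) next  # adjacent through the closing edge
      if (seg_int(poly[edges[i, 1], ], poly[edges[i, 2], ],
                  poly[edges[j, 1], ], poly[edges[j, 2], ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Identify fiducial markers by frame persistence
#'
#' Fiducial beads are bright emitters visible in (nearly) every frame. This
#' helper clusters bright localizations spatially and keeps groups that
#' appear in at least `persistent_frac` of all frames, returning the mean
#' position of each marker.
#'
#' @param table a [loc_table()].
#' @param min_photons photon threshold pre-selecting bright localizations
#'   (ignored when the table has no `photons` column).
#' @param persistent_frac minimum fraction of the acquisition's frames in
#'   which a candidate marker must appear (default 0.9).
#' @param eps spatial grouping radius in nm.
#' @return A matrix with columns `x`, `y` (one row per fiducial marker).
#' @export
find_fiducials <- function(table, min_photons = NULL, persistent_frac = 0.9,
                           eps = 100) {
  stopifnot(is_loc_table(table))
  bright <- if (!is.null(min_photons) && !is.null(table$photons)) {
    filter_localizations(table, min_photons = min_photons)
  } else {
    table
  }
  if (nrow(bright) == 0L) return(matrix(numeric(0), ncol = 2,
                                        dimnames = list(NULL, c("x", "y"))))
  n_frames <- max(table$frame) + 1L
  cl <- dbscan(bright, eps = eps, min_pts = 2L)
  keep <- which(cl$labels >= 0L)
  if (length(keep) == 0L) return(matrix(numeric(0), ncol = 2,
                                        dimnames = list(NULL, c("x", "y"))))
  labs <- cl$labels[keep]
  centers <- lapply(split(keep, labs), function(idx) {
    frac <- length(unique(bright$frame[idx])) / n_frames
    if (frac < persistent_frac) return(NULL)
    c(x = mean(bright$x[idx]), y = mean(bright$y[idx]))
  })
  centers <- centers[!vapply(centers, is.null, logical(1))]
  if (length(centers) == 0L) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  }
  do.call(rbind, centers)
}
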