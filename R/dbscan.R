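#' Density-based clustering (DBSCAN)
#'
#' Standard DBSCAN semantics: a point is a *core* point when its
#' eps-neighbourhood contains at least `min_pts` points, counting the point
#' itself; clusters are the connected components of the core points under
#' the "within eps" relation; a non-core point within eps of at least one
#' core point (a *border* point) is assigned to the cluster of its nearest
#' core point (ties broken by lowest row index, making the result fully
#' deterministic and independent of scan order); remaining points are noise
#' (label -1).
#'
#' @param table a [loc_table()] or n x 2 coordinate matrix.
#' @param eps neighbourhood radius in nm (> 0).
#' @param min_pts minimum neighbourhood size for a core point, counting the
#'   point itself (>= 1).
#' @return A list of class `cluster_result`: `labels` (integer per
#'   localization; clusters 0..k-1, noise -1), `n_clusters`, `is_core`
#'   (logical), `params`.
#' @examples
#' m <- cbind(c(0, 1, 2, 10), c(0, 0, 0, 0))
#' dbscan(m, eps = 1.5, min_pts = 2)$labels
#' @export
dbscan <- function(table, eps, min_pts) {
  xy <- if (is_loc_table(table)) as_xy_matrix(table) else coerce_points(table)
  stopifnot(eps > 0, min_pts >= 1)
  n <- nrow(xy)
  labels <- integer(0)
  is_core <- logical(0)
  if (n > 0L) {
    nb <- grid_neighbors(xy, eps)
    is_core <- lengths(nb) >= min_pts
    labels <- rep.int(-1L, n)
    next_label <- 0L
    for (i in seq_len(n)) {
      if (!is_core[i] || labels[i] >= 0L) next
      # BFS over core points of this component
      labels[i] <- next_label
      queue <- i
      while (length(queue) > 0L) {
        p <- queue[1L]
        queue <- queue[-1L]
        cores <- nb[[p]][is_core[nb[[p]]]]
        fresh <- cores[labels[cores] < 0L]
        labels[fresh] <- next_label
        queue <- c(queue, fresh)
      }
      next_label <- next_label + 1L
    }
    # border points: nearest core neighbour within eps
    border <- which(!is_core)
    for (i in border) {
      cores <- nb[[i]][is_core[nb[[i]]]]
      if (length(cores) == 0L) next
      dd <- sqrt((xy[cores, 1] - xy[i, 1])^2 + (xy[cores, 2] - xy[i, 2])^2)
      labels[i] <- labels[cores[which.min(dd)]]
    }
  }
  structure(list(labels = labels,
                 n_clusters = if (n > 0L) max(labels) + 1L else 0L,
                 is_core = is_core,
                 params = list(eps = eps, min_pts = min_pts)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d clusters, %d localizations (%d noise)\n",
              x$n_clusters, length(x$labels), sum(x$labels < 0L)))
  invisible(x)
}

# Fixed-radius neighbour lists (including self) via cell-grid binning.
# Returns a list of integer vectors of indices within eps of each point.
grid_neighbors <- function(xy, eps) {
  n <- nrow(xy)
  cx <- as.integer(floor(xy[, 1] / eps))
  cy <- as.integer(floor(xy[, 2] / eps))
  key <- paste(cx, cy)
  cells <- split(seq_len(n), key)
  cell_of <- match(key, names(cells))
  # candidate pool per cell: the 3x3 block of cells around it
  pool <- vector("list", length(cells))
  ux <- vapply(strsplit(names(cells), " ", fixed = TRUE),
               function(s) as.integer(s[1]), integer(1))
  uy <- vapply(strsplit(names(cells), " ", fixed = TRUE),
               function(s) as.integer(s[2]), integer(1))
  for (ci in seq_along(cells)) {
    nbr_keys <- as.vector(outer(ux[ci] + (-1:1), uy[ci] + (-1:1), paste))
    hit <- match(nbr_keys, names(cells))
    pool[[ci]] <- sort(unlist(cells[hit[!is.na(hit)]], use.names = FALSE))
  }
  eps2 <- eps * eps
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- pool[[cell_of[i]]]
    d2 <- (xy[cand, 1] - xy[i, 1])^2 + (xy[cand, 2] - xy[i, 2])^2
    out[[i]] <- cand[d2 <= eps2]
  }
  out
}

#' OPTICS ordering and reachability analysis
#'
#' Computes the OPTICS cluster ordering with core and reachability distances.
#' The core distance of a point is the distance to its `min_pts`-th nearest
#' neighbour (counting the point itself, consistent with [dbscan()]); the
#' reachability distance recorded for each point is the smallest
#' `max(core_dist(q), d(q, p))` over already-processed points `q`, `Inf` for
#' points that start a new component. Use [extract_dbscan()] to cut the
#' ordering at a radius `eps' <= max_eps`.
#'
#' @param table a [loc_table()] or n x 2 coordinate matrix.
#' @param min_pts neighbourhood size defining core distances (>= 2).
#' @param max_eps maximum neighbourhood radius considered (default `Inf`).
#' @return A list of class `optics_result`: `order` (processing order, row
#'   indices), `reachability` and `core_dist` (in row order, nm), `xy`,
#'   `params`.
#' @export
optics <- function(table, min_pts, max_eps = Inf) {
  xy <- if (is_loc_table(table)) as_xy_matrix(table) else coerce_points(table)
  stopifnot(min_pts >= 2)
  n <- nrow(xy)
  if (n == 0L) {
    return(structure(list(order = integer(0), reachability = numeric(0),
                          core_dist = numeric(0), xy = xy,
                          params = list(min_pts = min_pts, max_eps = max_eps)),
                     class = "optics_result"))
  }
  reach <- rep.int(Inf, n)
  core_dist <- rep.int(Inf, n)
  processed <- rep.int(FALSE, n)
  ordering <- integer(n)
  pos <- 0L
  pending <- rep.int(Inf, n)  # current queue priority (Inf = not queued)
  for (start in seq_len(n)) {
    if (processed[start]) next
    pending[start] <- 0
    while (TRUE) {
      cand <- which(!processed & is.finite(pending))
      if (length(cand) == 0L) break
      p <- cand[which.min(pending[cand])]
      processed[p] <- TRUE
      pos <- pos + 1L
      ordering[pos] <- p
      d <- sqrt((xy[, 1] - xy[p, 1])^2 + (xy[, 2] - xy[p, 2])^2)
      within <- d <= max_eps
      k <- sum(within)
      if (k >= min_pts) {
        core_dist[p] <- sort(d[within], partial = min_pts)[min_pts]
        targets <- which(within & !processed)
        newreach <- pmax(core_dist[p], d[targets])
        upd <- newreach < reach[targets]
        reach[targets[upd]] <- newreach[upd]
        pending[targets] <- pmin(pending[targets], reach[targets])
      }
    }
    pending[] <- Inf
  }
  # the seed of each component keeps reachability Inf
  structure(list(order = ordering, reachability = reach,
                 core_dist = core_dist, xy = xy,
                 params = list(min_pts = min_pts, max_eps = max_eps)),
            class = "optics_result")
}

#' @export
print.optics_result <- function(x, ...) {
  cat(sprintf("<optics_result> %d points, min_pts = %d, max_eps = %g\n",
              length(x$order), x$params$min_pts, x$params$max_eps))
  invisible(x)
}

#' Extract a DBSCAN partition from an OPTICS ordering
#'
#' Cuts the reachability profile at radius `eps_prime`: walking the ordering,
#' a point with reachability larger than `eps_prime` starts a new cluster if
#' it is core at `eps_prime`, otherwise it is provisionally noise; other
#' points join the current cluster. Non-core points are then re-assigned to
#' the cluster of their nearest core point within `eps_prime` (the same
#' border rule as [dbscan()]), so the result equals
#' `dbscan(table, eps_prime, min_pts)` exactly.
#'
#' @param x an [optics()] result.
#' @param eps_prime cut radius, must be `<= max_eps` used for the ordering.
#' @return A `cluster_result` (see [dbscan()]).
#' @export
extract_dbscan <- function(x, eps_prime) {
  stopifnot(inherits(x, "optics_result"), eps_prime > 0,
            eps_prime <= x$params$max_eps)
  n <- length(x$order)
  labels <- rep.int(-1L, n)
  core <- x$core_dist <= eps_prime
  current <- -1L
  next_label <- 0L
  for (p in x$order) {
    if (x$reachability[p] > eps_prime) {
      if (core[p]) {
        current <- next_label
        next_label <- next_label + 1L
        labels[p] <- current
      } else {
        current <- -1L
      }
    } else if (core[p]) {
      labels[p] <- current
    }
  }
  # border / early-noise fix-up: nearest core within eps_prime
  xy <- x$xy
  noncore <- which(!core)
  core_idx <- which(core)
  for (i in noncore) {
    if (length(core_idx) == 0L) break
    dd <- sqrt((xy[core_idx, 1] - xy[i, 1])^2 +
               (xy[core_idx, 2] - xy[i, 2])^2)
    j <- which(dd <= eps_prime)
    if (length(j) == 0L) next
    labels[i] <- labels[core_idx[j[which.min(dd[j])]]]
  }
  structure(list(labels = labels,
                 n_clusters = if (n > 0L) max(labels, -1L) + 1L else 0L,
                 is_core = core,
                 params = list(eps = eps_prime,
                               min_pts = x$params$min_pts)),
            class = "cluster_result")
}
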