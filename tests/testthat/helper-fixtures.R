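# Shared fixtures and independent oracles for the test suite.

# Minimal 3-row table used across the I/O tests.
three_row_table <- function() {
  loc_table(data.frame(x = c(100, 110, 500), y = c(200, 210, 500),
                       frame = c(0L, 0L, 1L)))
}

# A randomized table with optional columns, for round-trip tests.
random_table <- function(n = 50L, seed = 1L, photons = TRUE) {
  withr::with_seed(seed, {
    df <- data.frame(x = runif(n, 0, 20000), y = runif(n, 0, 20000),
                     frame = sample(0:99, n, replace = TRUE))
    if (photons) df$photons <- rlnorm(n, log(1000), 0.5)
    loc_table(df)
  })
}

# --- independent DBSCAN oracle -------------------------------------------
# Connected components of the eps-graph restricted to core points (igraph),
# plus the nearest-core border rule. Structurally independent of the
# package's grid-index BFS implementation.
oracle_dbscan <- function(xy, eps, min_pts) {
  n <- nrow(xy)
  d <- as.matrix(stats::dist(xy))
  nbhd <- d <= eps                      # includes self (d = 0)
  is_core <- rowSums(nbhd) >= min_pts
  labels <- rep.int(-1L, n)
  cores <- which(is_core)
  if (length(cores) > 0L) {
    sub <- nbhd[cores, cores, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    # relabel components by order of first appearance (row order)
    first <- order(vapply(seq_len(max(comp)),
                          function(k) min(which(comp == k)), integer(1)))
    relab <- match(seq_len(max(comp)), first)
    labels[cores] <- relab[comp] - 1L
    for (i in which(!is_core)) {
      cand <- cores[nbhd[i, cores]]
      if (length(cand) == 0L) next
      labels[i] <- labels[cand[which.min(d[i, cand])]]
    }
  }
  labels
}

# TRUE when two label vectors describe the same partition (same noise set,
# clusters equal up to relabeling).
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!all((a < 0L) == (b < 0L))) return(FALSE)
  keep <- a >= 0L
  if (!any(keep)) return(TRUE)
  pa <- a[keep]
  pb <- b[keep]
  length(unique(paste(pa, pb))) == length(unique(pa)) &&
    length(unique(paste(pa, pb))) == length(unique(pb))
}

# --- brute-force convex hull oracle (O(n^3)) ------------------------------
# A directed segment (i, j) is a hull edge iff every other point lies
# strictly to its left or on it; walking the edges gives area and perimeter.
oracle_hull_metrics <- function(pts) {
  n <- nrow(pts)
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  edges <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ok <- TRUE
      for (k in seq_len(n)) {
        if (k == i || k == j) next
        if (cross(pts[i, ], pts[j, ], pts[k, ]) < -1e-9) {
          ok <- FALSE
          break
        }
      }
      if (ok) edges[[length(edges) + 1L]] <- c(i, j)
    }
  }
  if (length(edges) == 0L) return(list(area = 0, perimeter = 0))
  em <- do.call(rbind, edges)
  # walk the cycle
  start <- em[1, 1]
  verts <- start
  cur <- em[1, 2]
  while (cur != start && length(verts) <= n) {
    verts <- c(verts, cur)
    nxt <- em[em[, 1] == cur, 2]
    # pick the next vertex that is not where we came from
    nxt <- nxt[!nxt %in% verts | nxt == start][1]
    if (is.na(nxt)) break
    cur <- nxt
  }
  v <- pts[verts, , drop = FALSE]
  k <- nrow(v)
  jn <- c(2:k, 1L)
  list(area = abs(sum(v[, 1] * v[jn, 2] - v[jn, 1] * v[, 2])) / 2,
       perimeter = sum(sqrt((v[jn, 1] - v[, 1])^2 + (v[jn, 2] - v[, 2])^2)))
}

# --- brute-force mutual nearest neighbour oracle --------------------------
oracle_mutual_nn <- function(a, b, max_dist) {
  pairs <- list()
  for (i in seq_len(nrow(a))) {
    di <- sqrt((b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2)
    j <- which.min(di)
    dj <- sqrt((a[, 1] - b[j, 1])^2 + (a[, 2] - b[j, 2])^2)
    if (which.min(dj) == i && di[j] <= max_dist) {
      pairs[[length(pairs) + 1L]] <- c(i, j)
    }
  }
  if (length(pairs) == 0L) return(matrix(integer(0), ncol = 2))
  do.call(rbind, pairs)
}

# Simulate blink counts of n m-mers directly (independent geometric blink
# counts per labelled subunit; complexes with zero labels unobserved).
simulate_mmers <- function(n, m, q, p_label = 1) {
  k <- stats::rbinom(n, m, p_label)
  k <- k[k > 0]
  vapply(k, function(kk) sum(stats::rgeom(kk, prob = 1 - q)), numeric(1))
}
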