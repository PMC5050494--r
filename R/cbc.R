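#' Coordinate-based colocalization (CBC)
#'
#' For every localization \eqn{A_i} of channel A, neighbour counts of both
#' channels are collected on a radius grid \eqn{r_j = j\, r_{max}/n_{steps}}
#' (j = 1..n_steps) and converted to distance-scaled density ratios
#' \deqn{D_{A_i,X}(r_j) = \frac{N_{A_i,X}(r_j)}{N_{A_i,X}(r_{max})}
#'       \cdot \frac{r_{max}^2}{r_j^2}}
#' (the localization itself is excluded from its own channel's counts). The
#' Spearman rank correlation \eqn{S_{A_i}} of the two density curves,
#' weighted by the nearest-neighbour distance \eqn{E_{A_i,B}} to channel B,
#' gives the per-localization colocalization value
#' \deqn{C_{A_i} = S_{A_i} \cdot \exp(-E_{A_i,B} / r_{max}) \in [-1, 1].}
#' \eqn{C_{A_i}} is reported as `NA` (undefined) when either channel has no
#' neighbour within `r_max`, or when either density curve is constant so
#' that its rank correlation does not exist. Values near +1 indicate
#' colocalization, near 0 independence, negative values segregation.
#'
#' @param table_a,table_b [loc_table()]s (or n x 2 matrices) of the two
#'   channels; `C` is computed for every localization of `table_a`.
#' @param r_max largest correlation radius in nm.
#' @param n_steps number of radius steps (>= 3; default 10).
#' @param self set to `TRUE` when `table_b` is the same physical record list
#'   as `table_a`: each record is then excluded from its own neighbourhood
#'   in channel B as well.
#' @return A list of class `cbc_result`: `C` (per-A-localization value, `NA`
#'   when undefined), `S` (rank correlations), `E` (nearest-B distances,
#'   nm), `n_undefined`, `params`.
#' @export
cbc <- function(table_a, table_b, r_max, n_steps = 10L, self = FALSE) {
  a <- if (is_loc_table(table_a)) as_xy_matrix(table_a) else
    coerce_points(table_a)
  b <- if (is_loc_table(table_b)) as_xy_matrix(table_b) else
    coerce_points(table_b)
  if (nrow(a) == 0L || nrow(b) == 0L) stop("both channels must be non-empty")
  stopifnot(r_max > 0, n_steps >= 3L)
  radii <- seq_len(n_steps) * r_max / n_steps
  n <- nrow(a)
  daa <- cross_dist(a, a)
  diag(daa) <- Inf                       # exclude self in own channel
  dab <- cross_dist(a, b)
  if (self) {
    if (nrow(b) != n) stop("self mode requires equally sized channels")
    diag(dab) <- Inf
  }
  E <- apply(dab, 1, min)
  # zero-distance (coincident) records contribute nothing to the shape of
  # the neighbour-count curve; dropping them makes identical channels
  # perfectly colocalized (C = 1) instead of self-biased
  dab_counts <- dab
  dab_counts[dab_counts == 0] <- Inf
  scale <- r_max^2 / radii^2
  C <- rep.int(NA_real_, n)
  S <- rep.int(NA_real_, n)
  for (i in seq_len(n)) {
    ca <- count_within(daa[i, ], radii)
    cb <- count_within(dab_counts[i, ], radii)
    if (ca[n_steps] == 0L || cb[n_steps] == 0L) next
    DA <- ca / ca[n_steps] * scale
    DB <- cb / cb[n_steps] * scale
    if (stats::sd(DA) == 0 || stats::sd(DB) == 0) next
    S[i] <- stats::cor(DA, DB, method = "spearman")
    C[i] <- S[i] * exp(-E[i] / r_max)
  }
  structure(list(C = C, S = S, E = E,
                 n_undefined = sum(is.na(C)),
                 params = list(r_max = r_max, n_steps = n_steps,
                               self = self)),
            class = "cbc_result")
}

count_within <- function(d, radii) {
  findInterval(radii, sort(d[is.finite(d)]))
}

#' @export
print.cbc_result <- function(x, ...) {
  cat(sprintf(
    "<cbc_result> %d localizations, %d undefined; mean C = %.3f\n",
    length(x$C), x$n_undefined, mean(x$C, na.rm = TRUE)))
  invisible(x)
}

#' Interaction domains from CBC and DBSCAN
#'
#' Clusters of the subset of channel-A localizations whose colocalization
#' value is at least `c_threshold` mark candidate domains of molecular
#' interaction. Labels are reported for the full table (`-1` for
#' localizations below the threshold or undefined).
#'
#' @param table_a the channel-A [loc_table()] the CBC result refers to.
#' @param cbc_result a [cbc()] result aligned with `table_a`.
#' @param c_threshold minimum colocalization value (dimensionless).
#' @param eps,min_pts DBSCAN parameters (see [dbscan()]).
#' @return A `cluster_result` whose `labels` align with `table_a` rows; an
#'   empty selection yields 0 clusters.
#' @export
interaction_domains <- function(table_a, cbc_result, c_threshold, eps,
                                min_pts) {
  stopifnot(inherits(cbc_result, "cbc_result"))
  xy <- if (is_loc_table(table_a)) as_xy_matrix(table_a) else
    coerce_points(table_a)
  stopifnot(length(cbc_result$C) == nrow(xy))
  sel <- which(!is.na(cbc_result$C) & cbc_result$C >= c_threshold)
  labels <- rep.int(-1L, nrow(xy))
  n_clusters <- 0L
  is_core <- rep.int(FALSE, nrow(xy))
  if (length(sel) > 0L) {
    sub <- dbscan(xy[sel, , drop = FALSE], eps = eps, min_pts = min_pts)
    labels[sel] <- sub$labels
    is_core[sel] <- sub$is_core
    n_clusters <- sub$n_clusters
  }
  structure(list(labels = labels, n_clusters = n_clusters, is_core = is_core,
                 params = list(eps = eps, min_pts = min_pts,
                               c_threshold = c_threshold)),
            class = "cluster_result")
}
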