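#' Blinking-event count model for molecular counting
#'
#' Under a Markov-chain photoswitching model with an absorbing bleached
#' state, the number of re-activations (blinking events) `N` of a single
#' fluorophore is geometric with blinking probability `q`; for a complex of
#' `m` independent fluorophores it is negative-binomial:
#' \deqn{P(N \mid m, q) = \binom{N + m - 1}{N} q^N (1 - q)^m.}
#'
#' @param N number of blinking events (non-negative integer, vectorised).
#' @param m number of active fluorophores (subunits), integer >= 1.
#' @param q blinking probability, in `[0, 1)`.
#' @return Probability mass at `N`.
#' @examples
#' blink_pmf(0:5, m = 2, q = 0.4)
#' @export
blink_pmf <- function(N, m, q) {
  if (m < 1 || m != round(m)) stop("m must be an integer >= 1")
  if (q < 0 || q >= 1) stop("q must be in [0, 1)")
  N <- as.numeric(N)
  if (any(N < 0 | N != round(N))) stop("N must be non-negative integers")
  if (q == 0) return(as.numeric(N == 0))
  exp(lchoose(N + m - 1, N) + N * log(q) + m * log1p(-q))
}

#' Extract per-molecule blinking-event counts
#'
#' Groups localizations spatially with [dbscan()]; each group is a candidate
#' molecule (or complex). Within a group, the sorted frame indices are merged
#' into *on-events*: detections separated by at most `dark_tolerance` dark
#' frames belong to the same event. The blinking-event count of the group is
#' `N = number of on-events - 1` (re-activations after the first event).
#'
#' @param table a [loc_table()] with frame information.
#' @param eps,min_pts spatial grouping parameters (see [dbscan()]).
#' @param dark_tolerance maximum number of dark frames bridged within one
#'   on-event (default 1).
#' @return A list of class `blink_counts`: `N` (per-group event counts),
#'   `histogram` (named table over N), `n_molecules`, `params`.
#' @examples
#' tab <- loc_table(data.frame(x = 0, y = 0, frame = c(3, 4, 5, 20, 21, 40)))
#' extract_blink_counts(tab, eps = 10, min_pts = 1)$N  # 3 events -> N = 2
#' @export
extract_blink_counts <- function(table, eps, min_pts, dark_tolerance = 1L) {
  stopifnot(is_loc_table(table), dark_tolerance >= 0)
  cl <- dbscan(table, eps = eps, min_pts = min_pts)
  groups <- split(seq_len(nrow(table)), cl$labels)
  groups <- groups[names(groups) != "-1"]
  if (length(groups) == 0L) {
    stop("extraction error: no spatial groups found")
  }
  N <- vapply(groups, function(idx) {
    f <- sort(unique(table$frame[idx]))
    dark <- diff(f) - 1L
    n_events <- 1L + sum(dark > dark_tolerance)
    n_events - 1L
  }, integer(1))
  N <- unname(N)
  structure(list(N = N,
                 histogram = table_counts(N),
                 n_molecules = length(N),
                 params = list(eps = eps, min_pts = min_pts,
                               dark_tolerance = dark_tolerance)),
            class = "blink_counts")
}

table_counts <- function(N) {
  tab <- tabulate(N + 1L, nbins = max(N) + 1L)
  names(tab) <- 0:max(N)
  tab
}

#' Construct a blink-count distribution directly from counts
#'
#' Wraps pre-computed per-molecule blinking-event counts (e.g. from a
#' simulation) in the container returned by [extract_blink_counts()].
#'
#' @param N integer vector of blinking-event counts (>= 0).
#' @return A `blink_counts` object.
#' @export
blink_counts <- function(N) {
  N <- as.integer(N)
  if (length(N) == 0L) stop("empty count vector")
  if (any(N < 0L)) stop("counts must be >= 0")
  structure(list(N = N, histogram = table_counts(N), n_molecules = length(N),
                 params = list()),
            class = "blink_counts")
}

#' Calibrate the blinking probability on a monomeric standard
#'
#' Maximum-likelihood estimate of the blinking probability `q` under the
#' geometric model (`m = 1`): `q_hat = mean(N) / (1 + mean(N))`.
#'
#' @param counts a `blink_counts` object from a known-monomer sample.
#' @return The estimate `q_hat`.
#' @export
calibrate_q <- function(counts) {
  stopifnot(inherits(counts, "blink_counts"))
  if (counts$n_molecules == 0L) stop("empty blink-count distribution")
  nbar <- mean(counts$N)
  nbar / (1 + nbar)
}

#' Fit the oligomeric state from blinking-event counts
#'
#' For each candidate subunit number `m`, evaluates the log-likelihood of
#' the observed blinking-event counts under the labelling-efficiency
#' mixture
#' \deqn{P(N \mid m, q, p) = \sum_{k=1}^{m} w_k\, P_{NB}(N \mid k, q),
#'       \qquad w_k \propto \binom{m}{k} p^k (1-p)^{m-k},}
#' where the binomial weights over the number `k` of active labels are
#' renormalised over `k >= 1` because complexes with zero active labels are
#' never observed. The fitted oligomeric state is the `m` with the highest
#' (profile) likelihood; when `q` is free it is profiled out per `m` by 1-D
#' likelihood maximisation.
#'
#' @param counts a `blink_counts` object.
#' @param q blinking probability: a fixed value in `[0, 1)` (e.g. from
#'   [calibrate_q()]) or `NULL` to profile it per candidate `m`.
#' @param p_label labelling/detection efficiency in `(0, 1]`.
#' @param m_candidates integer candidate subunit numbers (default `1:8`).
#' @return A list of class `oligomer_fit`: `m_hat`, `q_hat` (per the best
#'   `m`), `p_label`, `log_likelihood`, `model_table` (data frame `m`,
#'   `q_hat`, `log_likelihood`).
#' @export
fit_oligomer <- function(counts, q = NULL, p_label = 1,
                         m_candidates = 1:8) {
  stopifnot(inherits(counts, "blink_counts"), length(m_candidates) >= 1L,
            p_label > 0, p_label <= 1)
  m_candidates <- sort(unique(as.integer(m_candidates)))
  if (any(m_candidates < 1L)) stop("m candidates must be >= 1")
  N <- counts$N
  single_bin <- length(unique(N)) == 1L
  loglik <- function(m, qv) {
    p <- mixture_pmf(N, m, qv, p_label)
    if (any(p <= 0)) return(-Inf)
    sum(log(p))
  }
  rows <- lapply(m_candidates, function(m) {
    if (!is.null(q)) {
      data.frame(m = m, q_hat = q, log_likelihood = loglik(m, q))
    } else {
      opt <- stats::optimize(function(qv) loglik(m, qv),
                             interval = c(1e-6, 1 - 1e-6), maximum = TRUE)
      data.frame(m = m, q_hat = opt$maximum, log_likelihood = opt$objective)
    }
  })
  tab <- do.call(rbind, rows)
  if (single_bin && is.null(q)) {
    warning("degenerate blink-count histogram (single value); ",
            "q estimate at or near the boundary")
  }
  best <- which.max(tab$log_likelihood)
  structure(list(m_hat = tab$m[best], q_hat = tab$q_hat[best],
                 p_label = p_label,
                 log_likelihood = tab$log_likelihood[best],
                 model_table = tab),
            class = "oligomer_fit")
}

# P(N | m, q, p_label): mixture over the number of active labels.
mixture_pmf <- function(N, m, q, p_label) {
  if (p_label == 1) return(blink_pmf(N, m, q))
  w <- stats::dbinom(1:m, m, p_label)
  w <- w / sum(w)
  out <- numeric(length(N))
  for (k in 1:m) out <- out + w[k] * blink_pmf(N, k, q)
  out
}

#' @export
print.oligomer_fit <- function(x, ...) {
  cat(sprintf(
    "<oligomer_fit> m_hat = %d (q_hat = %.3f, p_label = %.2f, logL = %.2f)\n",
    x$m_hat, x$q_hat, x$p_label, x$log_likelihood))
  invisible(x)
}
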