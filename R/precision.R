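#' Theoretical localization precision from photon statistics
#'
#' Closed-form estimates of the lateral localization precision of a fitted
#' single-molecule emitter from its photon count `N`, the fitted PSF standard
#' deviation `s` (nm), the camera pixel size `a` (nm) and the background
#' noise `b` (std. dev. in photons/pixel).
#'
#' `precision_thompson()` implements the least-squares error estimate
#' \deqn{\sigma^2 = \frac{s^2}{N} + \frac{a^2}{12 N}
#'       + \frac{8 \pi s^4 b^2}{a^2 N^2}}
#' and `precision_mortensen()` the maximum-likelihood variant
#' \deqn{\sigma^2 = \frac{s^2 + a^2/12}{N}\left(\frac{16}{9}
#'       + \frac{8 \pi (s^2 + a^2/12)\, b^2}{N a^2}\right).}
#' Both are vectorised over their arguments.
#'
#' @param N photon count (> 0).
#' @param s fitted PSF standard deviation in nm (> 0).
#' @param a pixel size in nm (> 0).
#' @param b background noise standard deviation in photons/pixel (>= 0).
#' @return Localization precision in nm.
#' @examples
#' precision_thompson(N = 100, s = 150, a = 100, b = 0)
#' precision_mortensen(N = 100, s = 150, a = 100, b = 0)
#' @export
precision_thompson <- function(N, s, a, b = 0) {
  check_photon_model(N, s, a, b)
  sqrt(s^2 / N + a^2 / (12 * N) + 8 * pi * s^4 * b^2 / (a^2 * N^2))
}

#' @rdname precision_thompson
#' @export
precision_mortensen <- function(N, s, a, b = 0) {
  check_photon_model(N, s, a, b)
  sa2 <- s^2 + a^2 / 12
  sqrt(sa2 / N * (16 / 9 + 8 * pi * sa2 * b^2 / (N * a^2)))
}

check_photon_model <- function(N, s, a, b) {
  if (any(N <= 0) || any(s <= 0) || any(a <= 0)) {
    stop("N, s and a must be > 0")
  }
  if (any(b < 0)) stop("b must be >= 0")
  invisible(TRUE)
}

#' Experimental localization precision from nearest-neighbour distances
#' (NeNA)
#'
#' A molecule that stays on over consecutive frames is localized repeatedly;
#' the distance between its re-localizations in frames `f` and `f + 1`
#' reflects the localization error directly. For isotropic Gaussian errors
#' with per-axis standard deviation `sigma` in each of the two frames, these
#' distances follow a Rayleigh-type density
#' \deqn{p(d) = \frac{d}{2\sigma^2} \exp\!\left(-\frac{d^2}{4\sigma^2}\right)}
#' (scale \eqn{\sqrt{2}\sigma}, because two independent localizations
#' contribute). `nena()` collects, for every localization in frame `f`, the
#' nearest-neighbour distance to frame `f + 1` (capped at `max_dist`), bins
#' the distances, and fits the density
#' `A * d/(2 sigma^2) * exp(-d^2/(4 sigma^2)) + c * d` by nonlinear least
#' squares; the linear term absorbs unrelated random neighbours at short
#' range. The fitted `sigma` is the experimental localization precision.
#'
#' @param table a [loc_table()] spanning at least 2 frames.
#' @param max_dist maximum nearest-neighbour distance considered, nm.
#' @param bin_width histogram bin width, nm.
#' @param min_pairs minimum number of usable consecutive-frame pairs below
#'   which estimation is refused.
#' @return A list of class `nena_result`: `sigma_loc` (nm), `fit`
#'   (coefficients `A`, `sigma`, `c`), `histogram` (data frame `center`,
#'   `density`), `n_pairs`.
#' @export
nena <- function(table, max_dist = 500, bin_width = 5, min_pairs = 100L) {
  stopifnot(is_loc_table(table), max_dist > 0, bin_width > 0,
            bin_width < max_dist)
  if (nrow(table) < 2L || length(unique(table$frame)) < 2L) {
    stop("estimation error: NeNA needs localizations in at least 2 frames")
  }
  d <- consecutive_frame_nn(table, max_dist)
  if (length(d) < min_pairs) {
    stop("estimation error: only ", length(d),
         " consecutive-frame pairs within max_dist (need >= ", min_pairs, ")")
  }
  breaks <- seq(0, max_dist, by = bin_width)
  if (breaks[length(breaks)] < max_dist) breaks <- c(breaks, max_dist)
  hist <- graphics::hist(d, breaks = breaks, plot = FALSE)
  df <- data.frame(center = hist$mids, density = hist$density)
  sigma0 <- max(df$center[which.max(df$density)], bin_width) / sqrt(2)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      density ~ A * center / (2 * sigma^2) * exp(-center^2 / (4 * sigma^2)) +
        c * center,
      data = df,
      start = list(A = 1, sigma = sigma0, c = 0),
      lower = c(A = 0, sigma = 1e-6, c = 0),
      upper = c(A = Inf, sigma = max_dist / 2, c = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("fit error: NeNA fit did not converge (",
                             conditionMessage(e), ")"))
  co <- stats::coef(fit)
  structure(list(sigma_loc = unname(co[["sigma"]]),
                 fit = as.list(co),
                 histogram = df,
                 n_pairs = length(d)),
            class = "nena_result")
}

#' @export
print.nena_result <- function(x, ...) {
  cat(sprintf("<nena_result> sigma_loc = %.2f nm from %d pairs\n",
              x$sigma_loc, x$n_pairs))
  invisible(x)
}

# Nearest-neighbour distance from every localization in frame f to frame
# f + 1, keeping distances <= max_dist.
consecutive_frame_nn <- function(table, max_dist) {
  xy <- as_xy_matrix(table)
  by_frame <- split(seq_len(nrow(table)), table$frame)
  frames <- as.integer(names(by_frame))
  out <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    nxt <- match(frames[k] + 1L, frames)
    if (is.na(nxt)) next
    a <- xy[by_frame[[k]], , drop = FALSE]
    b <- xy[by_frame[[nxt]], , drop = FALSE]
    d <- cross_dist(a, b)
    nn <- apply(d, 1, min)
    out[[k]] <- nn[nn <= max_dist]
  }
  unlist(out, use.names = FALSE)
}
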