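#' Render a localization table as a 2D count histogram
#'
#' Bins localization coordinates over the table's region into a pixel image
#' (row = y, column = x). The sum of all pixels equals the number of
#' localizations; points on the right/bottom region edge fall into the last
#' pixel.
#'
#' @param table a [loc_table()].
#' @param pixel_size_img rendering pixel size in nm (> 0).
#' @return An integer matrix of counts with attribute `pixel_size_img`.
#' @export
render_histogram <- function(table, pixel_size_img) {
  stopifnot(is_loc_table(table), pixel_size_img > 0)
  r <- loc_region(table)
  nx <- max(1L, ceiling((r[3] - r[1]) / pixel_size_img))
  ny <- max(1L, ceiling((r[4] - r[2]) / pixel_size_img))
  img <- matrix(0L, nrow = ny, ncol = nx)
  if (nrow(table) > 0L) {
    ix <- pmin(nx, 1L + floor((table$x - r[1]) / pixel_size_img))
    iy <- pmin(ny, 1L + floor((table$y - r[2]) / pixel_size_img))
    idx <- (ix - 1L) * ny + iy
    img <- matrix(tabulate(idx, nbins = nx * ny), nrow = ny, ncol = nx)
  }
  attr(img, "pixel_size_img") <- pixel_size_img
  img
}

#' Fourier ring correlation between two images
#'
#' Correlates the Fourier transforms of two equally sized images over rings
#' of constant spatial frequency:
#' \deqn{FRC(q) = \frac{\mathrm{Re} \sum_{ring}
#'       F_1 \overline{F_2}}{\sqrt{\sum_{ring} |F_1|^2
#'       \sum_{ring} |F_2|^2}}.}
#' Images are zero-padded to the next power-of-two square. The raw curve is
#' returned together with a moving-average smoothed version (window 3
#' rings).
#'
#' @param img1,img2 numeric matrices of identical size.
#' @param pixel_size_img pixel size of the images in nm.
#' @return A data frame of class `frc_curve` with columns `q` (spatial
#'   frequency, 1/nm), `frc` (smoothed), `frc_raw`, plus attributes
#'   `n_rings` and `pixel_size_img`.
#' @export
frc_from_images <- function(img1, img2, pixel_size_img) {
  stopifnot(all(dim(img1) == dim(img2)), pixel_size_img > 0)
  n <- 2^ceiling(log2(max(dim(img1), 2)))
  pad <- function(m) {
    out <- matrix(0, n, n)
    out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    out
  }
  f1 <- stats::fft(pad(img1))
  f2 <- stats::fft(pad(img2))
  # integer ring index from the centred frequency grid
  k <- c(0:(n / 2), (n / 2 - 1):1)
  kx <- matrix(k, n, n, byrow = TRUE)
  ky <- matrix(k, n, n)
  ring <- pmin(round(sqrt(kx^2 + ky^2)), n %/% 2)
  num <- Re(f1 * Conj(f2))
  p1 <- Mod(f1)^2
  p2 <- Mod(f2)^2
  rs <- function(v) as.numeric(rowsum(as.vector(v), as.vector(ring)))
  s_num <- rs(num)
  s1 <- rs(p1)
  s2 <- rs(p2)
  denom <- sqrt(s1 * s2)
  raw <- ifelse(denom > 0, s_num / denom, NA_real_)
  q <- (0:(n %/% 2)) / (n * pixel_size_img)
  sm <- smooth_ma3(raw)
  out <- data.frame(q = q, frc = sm, frc_raw = raw)
  structure(out, n_rings = length(q), pixel_size_img = pixel_size_img,
            class = c("frc_curve", "data.frame"))
}

smooth_ma3 <- function(v) {
  n <- length(v)
  out <- v
  for (i in seq_len(n)) {
    w <- max(1, i - 1):min(n, i + 1)
    out[i] <- mean(v[w], na.rm = TRUE)
  }
  out
}

#' Fourier ring correlation resolution of a localization table
#'
#' Splits the localizations into two statistically independent halves,
#' renders each half as a count image and computes the Fourier ring
#' correlation between the two images ([frc_from_images()]). The resolution
#' is `1 / q*` where `q*` is the first crossing of the smoothed curve below
#' the fixed threshold 1/7 (linear interpolation between rings); it is `NA`
#' when the curve never crosses.
#'
#' Splitting modes: `"random_halves"` assigns every localization
#' independently with probability 1/2 (seeded); `"odd_even_blocks"` assigns
#' blocks of `block_size` consecutive frames alternately to the two halves —
#' preferable when repeated blinking of the same fluorophore would correlate
#' randomly split halves.
#'
#' @param table a [loc_table()] with at least 2 localizations.
#' @param pixel_size_img rendering pixel size in nm.
#' @param split_mode `"random_halves"` or `"odd_even_blocks"`.
#' @param seed integer seed for the random split.
#' @param threshold resolution threshold on the FRC curve (default 1/7).
#' @param block_size frame block length for `"odd_even_blocks"`.
#' @return A list of class `frc_result`: `curve` ([frc_from_images()]
#'   output), `resolution` (nm or `NA`), `threshold`, `split_mode`, `seed`,
#'   `n_half` (localizations per half).
#' @export
frc_curve <- function(table, pixel_size_img,
                      split_mode = c("random_halves", "odd_even_blocks"),
                      seed = 1L, threshold = 1 / 7, block_size = 50L) {
  split_mode <- match.arg(split_mode)
  stopifnot(is_loc_table(table))
  if (nrow(table) < 2L) stop("FRC needs at least 2 localizations")
  if (split_mode == "random_halves") {
    half1 <- withr::with_seed(as.integer(seed),
                              stats::runif(nrow(table)) < 0.5)
  } else {
    half1 <- (table$frame %/% as.integer(block_size)) %% 2L == 0L
  }
  t1 <- subset_loc_table(table, which(half1))
  t2 <- subset_loc_table(table, which(!half1))
  img1 <- render_histogram(t1, pixel_size_img)
  img2 <- render_histogram(t2, pixel_size_img)
  dims <- pmax(dim(img1), dim(img2))
  grow <- function(m) {
    out <- matrix(0, dims[1], dims[2])
    out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    out
  }
  curve <- frc_from_images(grow(img1), grow(img2), pixel_size_img)
  structure(list(curve = curve,
                 resolution = frc_resolution(curve, threshold),
                 threshold = threshold, split_mode = split_mode,
                 seed = as.integer(seed),
                 n_half = c(nrow(t1), nrow(t2))),
            class = "frc_result")
}

# First downward crossing of the smoothed curve below the threshold,
# linearly interpolated in q; NA when it never crosses.
frc_resolution <- function(curve, threshold = 1 / 7) {
  q <- curve$q
  v <- curve$frc
  below <- which(v < threshold & q > 0)
  below <- below[below > 1L]
  if (length(below) == 0L) return(NA_real_)
  i <- below[1L]
  q_lo <- q[i - 1L]; v_lo <- v[i - 1L]
  q_hi <- q[i]; v_hi <- v[i]
  qs <- if (is.finite(v_lo) && v_lo != v_hi) {
    q_lo + (v_lo - threshold) / (v_lo - v_hi) * (q_hi - q_lo)
  } else {
    q_hi
  }
  1 / qs
}

#' @export
print.frc_result <- function(x, ...) {
  cat(sprintf("<frc_result> split = %s, resolution = %s\n", x$split_mode,
              if (is.na(x$resolution)) "undefined" else
                sprintf("%.1f nm (threshold %.3f)", x$resolution,
                        x$threshold)))
  invisible(x)
}
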