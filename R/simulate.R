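#' Simulate ground-truth molecule positions
#'
#' Generates molecule positions with known ground truth for validating the
#' analysis modules. Patterns:
#' \describe{
#'   \item{`csr`}{complete spatial randomness: exactly `n` points uniform on
#'     the region (fixed-`n` binomial process, so counts are exact).}
#'   \item{`gaussian_clusters`}{`n_clusters` cluster centres uniform on the
#'     region; members isotropic Gaussian with standard deviation `sigma_c`
#'     around their centre (resampled until inside the region).}
#'   \item{`segregated_halves`}{two channels: channel 1 uniform on the left
#'     half of the region, channel 2 on the right half (`n` points each).}
#'   \item{`filament`}{points spread uniformly along a straight filament
#'     spanning the region diagonal, with transverse Gaussian jitter
#'     `sigma_c`.}
#' }
#' All generators are bit-exact reproducible for a fixed `seed`.
#'
#' @param n number of molecules (per channel for `segregated_halves`).
#' @param region field of view `c(xmin, ymin, xmax, ymax)` in nm.
#' @param pattern one of `"csr"`, `"gaussian_clusters"`,
#'   `"segregated_halves"`, `"filament"`.
#' @param n_clusters,sigma_c cluster number and spread (nm) for the
#'   clustered/filament patterns.
#' @param seed integer seed (mandatory).
#' @return A data frame with columns `x`, `y`, `cluster` (ground-truth
#'   cluster id or `NA`) and `channel` (for `segregated_halves`), with the
#'   region as attribute `region`.
#' @export
simulate_points <- function(n, region = c(0, 0, 2000, 2000),
                            pattern = c("csr", "gaussian_clusters",
                                        "segregated_halves", "filament"),
                            n_clusters = 5L, sigma_c = 50, seed) {
  pattern <- match.arg(pattern)
  stopifnot(n >= 1, length(region) == 4L, !missing(seed))
  region <- as.numeric(region)
  out <- withr::with_seed(as.integer(seed), {
    switch(pattern,
      csr = data.frame(x = stats::runif(n, region[1], region[3]),
                       y = stats::runif(n, region[2], region[4]),
                       cluster = NA_integer_),
      gaussian_clusters = {
        centers <- cbind(stats::runif(n_clusters, region[1], region[3]),
                         stats::runif(n_clusters, region[2], region[4]))
        assign <- sample.int(n_clusters, n, replace = TRUE)
        xy <- matrix(NA_real_, n, 2)
        todo <- seq_len(n)
        while (length(todo) > 0L) {
          prop <- centers[assign[todo], , drop = FALSE] +
            matrix(stats::rnorm(2 * length(todo), sd = sigma_c), ncol = 2)
          ok <- prop[, 1] >= region[1] & prop[, 1] <= region[3] &
            prop[, 2] >= region[2] & prop[, 2] <= region[4]
          xy[todo[ok], ] <- prop[ok, , drop = FALSE]
          todo <- todo[!ok]
        }
        data.frame(x = xy[, 1], y = xy[, 2], cluster = assign)
      },
      segregated_halves = {
        xmid <- (region[1] + region[3]) / 2
        data.frame(
          x = c(stats::runif(n, region[1], xmid),
                stats::runif(n, xmid, region[3])),
          y = stats::runif(2 * n, region[2], region[4]),
          cluster = NA_integer_,
          channel = rep(1:2, each = n))
      },
      filament = {
        t <- stats::runif(n)
        ortho <- stats::rnorm(n, sd = sigma_c)
        p0 <- region[c(1, 2)]
        p1 <- region[c(3, 4)]
        dirv <- (p1 - p0) / sqrt(sum((p1 - p0)^2))
        nrm <- c(-dirv[2], dirv[1])
        x <- p0[1] + t * (p1[1] - p0[1]) + ortho * nrm[1]
        y <- p0[2] + t * (p1[2] - p0[2]) + ortho * nrm[2]
        x <- pmin(pmax(x, region[1]), region[3])
        y <- pmin(pmax(y, region[2]), region[4])
        data.frame(x = x, y = y, cluster = NA_integer_)
      })
  })
  attr(out, "region") <- region
  out
}

#' Simulate a localization table from ground-truth positions
#'
#' Emulates the observable output of SMLM photoswitching: each molecule is
#' retained with labelling probability `p_label`; a retained molecule
#' produces `1 + Geometric(q)` on-events (so `q` is the blinking
#' probability: the count of re-activations is geometric); each event starts
#' at a uniformly drawn frame and spans `frames_per_event` consecutive
#' frames; every frame of every event yields one localization with isotropic
#' Gaussian coordinate noise `sigma_loc` per axis and a log-normal photon
#' count. Setting `q = 0` and `frames_per_event = n_frames` re-localizes
#' every molecule in every frame (the NeNA fixture); `q = 0`,
#' `sigma_loc = 0`, `frames_per_event = 1` reproduces the ground truth
#' exactly.
#'
#' @param truth positions from [simulate_points()] (or any data frame with
#'   `x`, `y`).
#' @param sigma_loc per-axis localization noise in nm.
#' @param n_frames number of camera frames.
#' @param q blinking probability in `[0, 1)`.
#' @param p_label labelling efficiency in `(0, 1]`.
#' @param frames_per_event frames spanned by each on-event (clipped at the
#'   end of the acquisition).
#' @param photons_meanlog,photons_sdlog log-normal photon-count parameters.
#' @param seed integer seed (mandatory).
#' @return A [loc_table()] with columns `x`, `y`, `frame`, `photons`,
#'   `molecule` (ground-truth molecule index) and, when the truth has one, a
#'   `channel` column.
#' @export
simulate_localizations <- function(truth, sigma_loc = 10, n_frames = 100L,
                                   q = 0.2, p_label = 1,
                                   frames_per_event = 1L,
                                   photons_meanlog = log(1000),
                                   photons_sdlog = 0.5, seed) {
  stopifnot(!missing(seed), q >= 0, q < 1, p_label > 0, p_label <= 1,
            sigma_loc >= 0, n_frames >= 1, frames_per_event >= 1)
  n <- nrow(truth)
  rows <- withr::with_seed(as.integer(seed), {
    kept <- which(stats::runif(n) <= p_label)
    recs <- lapply(kept, function(i) {
      if (frames_per_event >= n_frames) {
        frames <- seq.int(0L, n_frames - 1L)   # re-localized in every frame
      } else {
        n_events <- 1L + if (q > 0) stats::rgeom(1L, prob = 1 - q) else 0L
        starts <- sample.int(n_frames, n_events, replace = TRUE) - 1L
        frames <- unique(unlist(lapply(starts, function(s) {
          seq.int(s, min(s + frames_per_event - 1L, n_frames - 1L))
        })))
      }
      k <- length(frames)
      df <- data.frame(
        x = truth$x[i] + stats::rnorm(k, sd = sigma_loc),
        y = truth$y[i] + stats::rnorm(k, sd = sigma_loc),
        frame = frames,
        photons = stats::rlnorm(k, photons_meanlog, photons_sdlog),
        molecule = i)
      if ("channel" %in% names(truth)) df$channel <- truth$channel[i]
      df
    })
    do.call(rbind, recs)
  })
  if (is.null(rows)) rows <- data.frame(x = numeric(0), y = numeric(0),
                                        frame = integer(0),
                                        photons = numeric(0),
                                        molecule = integer(0))
  rows <- rows[order(rows$frame, rows$molecule), , drop = FALSE]
  loc_table(rows)
}

#' Simulate a two-colour SMLM experiment with fiducial markers
#'
#' Builds paired channel tables for testing registration and colocalization:
#' channel A molecules are CSR on the region; a fraction
#' `colocalized_fraction` of channel B molecules sit at channel A positions
#' (within Gaussian `jitter`), the rest are independent CSR. All channel B
#' coordinates are then mapped through the true channel transform
#' `transform_b` (an [affine2d()]; identity by default), emulating chromatic
#' offset between cameras. `n_fiducials` bright markers are visible in both
#' channels in a fraction `fiducial_presence` of all frames. Both channels
#' receive isotropic localization noise `sigma_loc`; regular molecules are
#' localized once each at a random frame.
#'
#' @param n_a,n_b molecules per channel.
#' @param region field of view `c(xmin, ymin, xmax, ymax)` nm.
#' @param colocalized_fraction fraction of B molecules placed at A positions.
#' @param jitter standard deviation (nm) of the true A-B molecular offset
#'   for colocalized molecules.
#' @param transform_b true transform mapping sample coordinates into channel
#'   B's frame; registration of B onto A should recover its inverse.
#' @param n_fiducials number of fiducial markers.
#' @param n_frames number of frames.
#' @param sigma_loc localization noise per axis, nm.
#' @param fiducial_photons mean photon count of fiducial localizations
#'   (molecules get ~1000).
#' @param fiducial_presence per-frame detection probability of a fiducial.
#' @param seed integer seed (mandatory).
#' @return A list: `a`, `b` ([loc_table()]s with `photons` and `fiducial`
#'   columns), `truth` (list with molecule positions per channel, the index
#'   pairing of colocalized molecules, fiducial positions in both frames and
#'   `transform_b`).
#' @export
simulate_two_color <- function(n_a = 500L, n_b = 500L,
                               region = c(0, 0, 2000, 2000),
                               colocalized_fraction = 0.5, jitter = 10,
                               transform_b = affine2d(),
                               n_fiducials = 4L, n_frames = 100L,
                               sigma_loc = 10, fiducial_photons = 5000,
                               fiducial_presence = 0.95, seed) {
  stopifnot(!missing(seed), colocalized_fraction >= 0,
            colocalized_fraction <= 1, inherits(transform_b, "affine2d"))
  region <- as.numeric(region)
  res <- withr::with_seed(as.integer(seed), {
    pos_a <- cbind(x = stats::runif(n_a, region[1], region[3]),
                   y = stats::runif(n_a, region[2], region[4]))
    n_col <- round(colocalized_fraction * n_b)
    partner <- if (n_col > 0) sample.int(n_a, n_col, replace = n_col > n_a)
               else integer(0)
    pos_b <- rbind(
      pos_a[partner, , drop = FALSE] +
        matrix(stats::rnorm(2 * n_col, sd = jitter), ncol = 2),
      cbind(stats::runif(n_b - n_col, region[1], region[3]),
            stats::runif(n_b - n_col, region[2], region[4])))
    # fiducials away from the region edge so noise keeps them inside
    mar <- 0.05 * c(region[3] - region[1], region[4] - region[2])
    fid <- cbind(stats::runif(n_fiducials, region[1] + mar[1],
                              region[3] - mar[1]),
                 stats::runif(n_fiducials, region[2] + mar[2],
                              region[4] - mar[2]))
    make_channel <- function(pos, fid_pos, transform) {
      mol_frames <- sample.int(n_frames, nrow(pos), replace = TRUE) - 1L
      mol <- data.frame(x = pos[, 1], y = pos[, 2], frame = mol_frames,
                        photons = stats::rlnorm(nrow(pos), log(1000), 0.5),
                        fiducial = FALSE)
      fid_rows <- lapply(seq_len(nrow(fid_pos)), function(i) {
        present <- which(stats::runif(n_frames) <= fiducial_presence) - 1L
        data.frame(x = fid_pos[i, 1], y = fid_pos[i, 2], frame = present,
                   photons = stats::rlnorm(length(present),
                                           log(fiducial_photons), 0.1),
                   fiducial = TRUE)
      })
      df <- rbind(mol, do.call(rbind, fid_rows))
      df$x <- df$x + stats::rnorm(nrow(df), sd = sigma_loc)
      df$y <- df$y + stats::rnorm(nrow(df), sd = sigma_loc)
      xy <- transform_points(transform, cbind(df$x, df$y))
      df$x <- xy[, 1]
      df$y <- xy[, 2]
      df[order(df$frame), , drop = FALSE]
    }
    ident <- affine2d()
    list(a = make_channel(pos_a, fid, ident),
         b = make_channel(pos_b, fid, transform_b),
         truth = list(pos_a = pos_a, pos_b = pos_b,
                      pairing = data.frame(b = seq_len(n_col), a = partner),
                      fiducials = fid,
                      fiducials_b = transform_points(transform_b, fid),
                      transform_b = transform_b))
  })
  list(a = loc_table(res$a), b = loc_table(res$b), truth = res$truth)
}
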