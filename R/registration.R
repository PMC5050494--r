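#' 2D affine transforms for channel registration
#'
#' An `affine2d` maps a coordinate `p` to `matrix %*% p + offset` (nm). Three
#' models are supported: `translation` (identity matrix), `similarity`
#' (rotation + isotropic scale + translation) and full `affine`.
#'
#' @param matrix 2x2 real matrix (invertible).
#' @param offset numeric length-2 translation in nm.
#' @param model one of `"translation"`, `"similarity"`, `"affine"`.
#' @return An object of class `affine2d`.
#' @export
affine2d <- function(matrix = diag(2), offset = c(0, 0),
                     model = c("affine", "translation", "similarity")) {
  model <- match.arg(model)
  matrix <- base::matrix(as.numeric(matrix), 2, 2)
  offset <- as.numeric(offset)
  stopifnot(length(offset) == 2L)
  if (abs(det(matrix)) <= 1e-12) stop("transform matrix is singular")
  if (model == "translation" && any(abs(matrix - diag(2)) > 1e-12)) {
    stop("translation model requires an identity matrix")
  }
  structure(list(matrix = matrix, offset = offset, model = model),
            class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat(sprintf("<affine2d: %s>\n", x$model))
  cat(sprintf("  matrix: [%.6g %.6g; %.6g %.6g]\n",
              x$matrix[1, 1], x$matrix[1, 2], x$matrix[2, 1], x$matrix[2, 2]))
  cat(sprintf("  offset: (%.6g, %.6g) nm\n", x$offset[1], x$offset[2]))
  invisible(x)
}

#' @rdname affine2d
#' @param t an `affine2d`.
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "affine2d"))
  inv <- solve(t$matrix)
  affine2d(inv, -as.vector(inv %*% t$offset), model = t$model)
}

#' @rdname affine2d
#' @param points n x 2 matrix of coordinates (nm).
#' @export
transform_points <- function(t, points) {
  stopifnot(inherits(t, "affine2d"))
  points <- base::matrix(as.numeric(points), ncol = 2)
  sweep(points %*% t(t$matrix), 2, t$offset, "+")
}

#' Match fiducial markers between two channels
#'
#' Pairs points of two channels by mutual nearest neighbours: `a[i]` and
#' `b[j]` form a pair when each is the other's nearest neighbour and their
#' distance is at most `max_dist`. Each point is used at most once.
#'
#' @param a,b fiducial coordinates: n x 2 matrices or [loc_table()]s
#'   (`a` = moving channel, `b` = fixed channel).
#' @param max_dist maximum pairing distance in nm.
#' @return A list of class `fiducial_pairs` with `moving` and `fixed`
#'   coordinate matrices (equal row counts) and the pair distances `dist`.
#' @export
match_fiducials <- function(a, b, max_dist) {
  pa <- coerce_points(a)
  pb <- coerce_points(b)
  if (nrow(pa) == 0L || nrow(pb) == 0L) stop("both point sets must be non-empty")
  d <- cross_dist(pa, pb)
  nn_ab <- apply(d, 1, which.min)
  nn_ba <- apply(d, 2, which.min)
  mutual <- which(nn_ba[nn_ab] == seq_len(nrow(pa)))
  dd <- d[cbind(mutual, nn_ab[mutual])]
  ok <- dd <= max_dist
  if (!any(ok)) stop("matching error: no mutual-nearest-neighbor pairs within max_dist")
  structure(list(moving = pa[mutual[ok], , drop = FALSE],
                 fixed = pb[nn_ab[mutual[ok]], , drop = FALSE],
                 dist = dd[ok]),
            class = "fiducial_pairs")
}

coerce_points <- function(x) {
  if (is_loc_table(x)) return(as_xy_matrix(x))
  m <- base::matrix(as.numeric(as.matrix(x)), ncol = 2)
  colnames(m) <- c("x", "y")
  m
}

cross_dist <- function(a, b) {
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(dx * dx + dy * dy)
}

#' Estimate a channel-registration transform from fiducial pairs
#'
#' Least-squares estimation of the transform mapping the moving points onto
#' the fixed points. The translation model is the mean displacement; the
#' similarity model (rotation, isotropic scale, translation) is solved in
#' closed form by the SVD-based Procrustes method; the affine model by linear
#' least squares. The fiducial registration error (FRE) is the
#' root-mean-square residual distance of the fiducials after applying the
#' transform.
#'
#' @param pairs a [match_fiducials()] result, or a list with `moving` and
#'   `fixed` n x 2 matrices.
#' @param model `"similarity"` (default), `"translation"` or `"affine"`.
#' @return A list of class `registration_fit`: `transform` ([affine2d()]),
#'   `fre` (nm), `n_pairs`.
#' @export
estimate_transform <- function(pairs, model = c("similarity", "translation",
                                                "affine")) {
  model <- match.arg(model)
  mov <- coerce_points(pairs$moving)
  fix <- coerce_points(pairs$fixed)
  stopifnot(nrow(mov) == nrow(fix))
  n <- nrow(mov)
  need <- c(translation = 1L, similarity = 2L, affine = 3L)[[model]]
  if (n < need) stop("need at least ", need, " pairs for the ", model, " model")
  if (model == "translation") {
    tr <- affine2d(diag(2), colMeans(fix) - colMeans(mov), "translation")
  } else if (model == "similarity") {
    mu_m <- colMeans(mov); mu_f <- colMeans(fix)
    mc <- sweep(mov, 2, mu_m); fc <- sweep(fix, 2, mu_f)
    S <- crossprod(fc, mc) / n              # covariance fixed ~ moving
    sv <- svd(S)
    D <- diag(2)
    if (det(sv$u %*% t(sv$v)) < 0) D[2, 2] <- -1
    R <- sv$u %*% D %*% t(sv$v)
    var_m <- sum(mc^2) / n
    if (var_m <= 0) stop("degenerate geometry: moving points are coincident")
    s <- sum(diag(D) * sv$d) / var_m
    A <- s * R
    tr <- affine2d(A, mu_f - as.vector(A %*% mu_m), "similarity")
  } else {
    X <- cbind(1, mov)
    if (qr(X)$rank < 3L) {
      stop("degenerate geometry: fiducials are collinear, cannot fit affine")
    }
    beta <- qr.solve(X, fix)                # 3 x 2: offset row + matrix rows
    tr <- affine2d(t(beta[2:3, , drop = FALSE]), beta[1, ], "affine")
  }
  res <- transform_points(tr, mov) - fix
  structure(list(transform = tr,
                 fre = sqrt(mean(rowSums(res^2))),
                 n_pairs = n),
            class = "registration_fit")
}

#' @export
print.registration_fit <- function(x, ...) {
  print(x$transform)
  cat(sprintf("  FRE: %.3f nm over %d fiducial pairs\n", x$fre, x$n_pairs))
  invisible(x)
}

#' Apply a transform to a localization table
#'
#' Maps the `x`, `y` coordinates of every localization through an
#' [affine2d()]; all other columns are untouched. The region becomes the
#' bounding box of the transformed region corners.
#'
#' @param table a [loc_table()].
#' @param t an [affine2d()].
#' @return The transformed [loc_table()].
#' @export
apply_transform <- function(table, t) {
  stopifnot(is_loc_table(table), inherits(t, "affine2d"))
  r <- loc_region(table)
  corners <- rbind(c(r[1], r[2]), c(r[3], r[2]), c(r[1], r[4]), c(r[3], r[4]))
  tc <- transform_points(t, corners)
  region <- c(min(tc[, 1]), min(tc[, 2]), max(tc[, 1]), max(tc[, 2]))
  df <- as.data.frame(table)
  if (nrow(df) > 0L) {
    xy <- transform_points(t, as_xy_matrix(table))
    df$x <- xy[, 1]
    df$y <- xy[, 2]
  }
  loc_table(df, region = region,
            pixel_size = attr(table, "pixel_size", exact = TRUE),
            source_format = attr(table, "source_format", exact = TRUE))
}
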