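#' Localization tables
#'
#' A `loc_table` is the universal container every analysis in this package
#' consumes: a data frame of single-molecule localizations with mandatory
#' columns `x`, `y` (nanometres) and `frame` (0-based integer), optional
#' columns `photons`, `psf_sigma`, `background`, `precision`, `channel`, and
#' any number of extra columns that are carried through untouched. The table
#' carries a rectangular `region` attribute (the field of view, in nm) used
#' for edge corrections and histogram rendering.
#'
#' Internal conventions: coordinates are always nanometres with the origin at
#' the top-left of the field, x rightward and y downward; frames are 0-based
#' regardless of the source software.
#'
#' @param data data frame with at least columns `x`, `y`, `frame`.
#' @param region numeric length-4 vector `c(xmin, ymin, xmax, ymax)` in nm,
#'   or `NULL` to derive the tight bounding box of the data.
#' @param pixel_size camera pixel size in nm/pixel (metadata; `NA` if unknown).
#' @param source_format one of `"rapidstorm"`, `"thunderstorm"`,
#'   `"internal"` (provenance metadata).
#' @return An object of class `loc_table` (a data frame with attributes
#'   `region`, `pixel_size`, `source_format`).
#' @examples
#' tab <- loc_table(data.frame(x = c(0, 100), y = c(0, 50), frame = c(0, 1)))
#' loc_region(tab)
#' @export
loc_table <- function(data, region = NULL, pixel_size = NA_real_,
                      source_format = "internal") {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(c("x", "y", "frame"), names(data))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  data <- as.data.frame(data)
  rownames(data) <- NULL
  if (nrow(data) > 0L) {
    if (!all(is.finite(data$x)) || !all(is.finite(data$y))) {
      stop("x and y must be finite")
    }
    if (any(data$frame < 0L)) stop("frame indices must be >= 0")
    if (!is.null(data$photons) && any(data$photons < 0, na.rm = TRUE)) {
      stop("photons must be >= 0")
    }
    if (!is.null(data$psf_sigma) && any(data$psf_sigma <= 0, na.rm = TRUE)) {
      stop("psf_sigma must be > 0")
    }
  }
  data$frame <- as.integer(data$frame)
  if (is.null(region)) {
    region <- derive_region(data)
  } else {
    region <- as.numeric(region)
    stopifnot(length(region) == 4L)
    if (region[3] <= region[1] || region[4] <= region[2]) {
      stop("region must have strictly positive width and height")
    }
    if (nrow(data) > 0L) {
      tol <- 1e-9 * max(1, abs(region))
      if (min(data$x) < region[1] - tol || max(data$x) > region[3] + tol ||
          min(data$y) < region[2] - tol || max(data$y) > region[4] + tol) {
        stop("records fall outside the supplied region")
      }
    }
  }
  structure(data,
    region = region,
    pixel_size = as.numeric(pixel_size),
    source_format = match.arg(source_format,
      c("internal", "rapidstorm", "thunderstorm")),
    class = c("loc_table", "data.frame"))
}

# Tight bounding box; degenerate (empty or single-point) tables get a unit box
# so downstream area computations stay finite.
derive_region <- function(data) {
  if (nrow(data) == 0L) return(c(0, 0, 1, 1))
  r <- c(min(data$x), min(data$y), max(data$x), max(data$y))
  if (r[3] - r[1] <= 0) r[3] <- r[1] + 1
  if (r[4] - r[2] <= 0) r[4] <- r[2] + 1
  r
}

#' @rdname loc_table
#' @param x a `loc_table`.
#' @export
loc_region <- function(x) attr(x, "region", exact = TRUE)

#' @rdname loc_table
#' @export
is_loc_table <- function(x) inherits(x, "loc_table")

#' @export
print.loc_table <- function(x, ...) {
  r <- loc_region(x)
  cat(sprintf("<loc_table> %d localizations, %d frame(s)\n",
              nrow(x), length(unique(x$frame))))
  cat(sprintf("  region: [%.1f, %.1f] x [%.1f, %.1f] nm\n",
              r[1], r[3], r[2], r[4]))
  opt <- intersect(c("photons", "psf_sigma", "background", "precision",
                     "channel"), names(x))
  if (length(opt)) cat("  optional columns:", paste(opt, collapse = ", "), "\n")
  if (nrow(x) > 0L) print.data.frame(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

# Rebuild a loc_table from a row subset, keeping metadata. Internal.
subset_loc_table <- function(x, idx, region = loc_region(x)) {
  loc_table(as.data.frame(x)[idx, , drop = FALSE],
            region = region,
            pixel_size = attr(x, "pixel_size", exact = TRUE),
            source_format = attr(x, "source_format", exact = TRUE))
}

as_xy_matrix <- function(x) cbind(x = x$x, y = x$y)
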