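#' Pixel classification parameters
#'
#' Bundles every threshold used by the two per-pixel decision rules:
#' background detection (bright and chromatically uniform pixels) and
#' DAB-stain detection (dark pixels that are not blue-dominant).
#'
#' @param bg_min Minimum channel intensity for a background pixel. Slide
#'   background is near-white; scanned backgrounds typically exceed 230.
#' @param bg_uniformity Maximum allowed spread (max - min) across the three
#'   channels for a background pixel. Chromatic (tissue) pixels have a large
#'   spread even when bright.
#' @param dark_threshold A sample pixel can only be called stained when at
#'   least one channel falls strictly below this intensity.
#' @param alpha Scale applied to the red channel in the blue-dominance test.
#' @param beta Scale applied to the green channel in the blue-dominance test.
#'   A pixel is blue-dominant (hematoxylin, unstained) when
#'   \code{b >= alpha * r} and \code{b >= beta * g}.
#'
#' @return An object of class \code{pixel_class_params}.
#' @examples
#' p <- pixel_class_params()
#' p$dark_threshold
#' @export
pixel_class_params <- function(bg_min = 230, bg_uniformity = 25,
                               dark_threshold = 125,
                               alpha = 1.00, beta = 1.25) {
  stopifnot(
    is.numeric(bg_min), length(bg_min) == 1, bg_min > 0, bg_min <= 255,
    is.numeric(bg_uniformity), length(bg_uniformity) == 1, bg_uniformity >= 0,
    is.numeric(dark_threshold), length(dark_threshold) == 1,
    dark_threshold > 0, dark_threshold < 255,
    is.numeric(alpha), length(alpha) == 1, alpha > 0,
    is.numeric(beta), length(beta) == 1, beta > 0
  )
  structure(
    list(bg_min = bg_min, bg_uniformity = bg_uniformity,
         dark_threshold = dark_threshold, alpha = alpha, beta = beta),
    class = "pixel_class_params"
  )
}

#' @export
print.pixel_class_params <- function(x, ...) {
  cat("Pixel classification parameters\n")
  cat(sprintf("  background: min channel >= %g, channel spread <= %g\n",
              x$bg_min, x$bg_uniformity))
  cat(sprintf("  stain: min channel < %g and not (B >= %g*R and B >= %g*G)\n",
              x$dark_threshold, x$alpha, x$beta))
  invisible(x)
}

#' Tiling configuration for whole-block processing
#'
#' Large whole-block scans are processed one tile at a time so that only a
#' small part of the raster needs classifying at once. The default 4 x 4
#' grid yields sixteen tiles.
#'
#' @param grid_rows,grid_cols Number of tile rows and columns (>= 1).
#' @return An object of class \code{tile_config}.
#' @export
tile_config <- function(grid_rows = 4, grid_cols = 4) {
  stopifnot(
    is.numeric(grid_rows), length(grid_rows) == 1, grid_rows >= 1,
    grid_rows == as.integer(grid_rows),
    is.numeric(grid_cols), length(grid_cols) == 1, grid_cols >= 1,
    grid_cols == as.integer(grid_cols)
  )
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols)),
            class = "tile_config")
}

#' TMA de-arraying parameters
#'
#' Controls core detection on the thumbnail (morphology and object-area
#' filtering) and grid assignment (tolerances of the row/column walk).
#'
#' @param grid_rows,grid_cols TMA design grid size (user-declared; the grid
#'   is a property of how the array was constructed, not inferred).
#' @param min_area,max_area Object area bounds in thumbnail pixels squared.
#'   Components smaller than \code{min_area} (debris) or larger than
#'   \code{max_area} (merged cores) are discarded. When \code{NULL} the
#'   bounds are derived from the estimated core spacing: with expected core
#'   radius r = 0.4 * spacing, \code{min_area = 0.2 * pi * r^2} and
#'   \code{max_area = 2.5 * pi * r^2}, which keeps the defaults
#'   resolution-independent.
#' @param struct_radius Radius in pixels of the disc structuring element used
#'   by the morphological closing that merges fragmented cores.
#' @param col_tolerance Maximum perpendicular offset, as a fraction of the
#'   estimated spacing, for a centroid to count as "in line" with the
#'   row/column being walked.
#' @param spacing_window Two numbers (low, high): a candidate k grid steps
#'   away must lie within \code{c(low, high) * k * spacing} along the walk
#'   direction.
#' @param max_gap Largest number of consecutive missing cores the walk
#'   searches past. \code{NULL} means walk to the end of the line
#'   (grid dimension - 1).
#' @param baseline_min_fraction Minimum fraction of the expected column
#'   length that the first-column walk must recover for the column to serve
#'   as the baseline; otherwise the first row is used instead.
#' @param invert_labels Flip row and column labels (first becomes last).
#'   TMA scans are commonly oriented opposite to the pathologist's numbering
#'   convention, so this defaults to \code{TRUE}.
#' @return An object of class \code{dearray_params}.
#' @export
dearray_params <- function(grid_rows, grid_cols,
                           min_area = NULL, max_area = NULL,
                           struct_radius = 5,
                           col_tolerance = 0.35,
                           spacing_window = c(0.5, 1.5),
                           max_gap = NULL,
                           baseline_min_fraction = 0.5,
                           invert_labels = TRUE) {
  stopifnot(
    is.numeric(grid_rows), grid_rows >= 1, grid_rows == as.integer(grid_rows),
    is.numeric(grid_cols), grid_cols >= 1, grid_cols == as.integer(grid_cols),
    is.null(min_area) || (is.numeric(min_area) && min_area > 0),
    is.null(max_area) || (is.numeric(max_area) && max_area > 0),
    is.numeric(struct_radius), struct_radius >= 1,
    is.numeric(col_tolerance), col_tolerance > 0, col_tolerance < 1,
    is.numeric(spacing_window), length(spacing_window) == 2,
    spacing_window[1] < spacing_window[2],
    is.null(max_gap) || (is.numeric(max_gap) && max_gap >= 1),
    is.numeric(baseline_min_fraction),
    baseline_min_fraction > 0, baseline_min_fraction <= 1,
    is.logical(invert_labels), length(invert_labels) == 1
  )
  structure(
    list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
         min_area = min_area, max_area = max_area,
         struct_radius = struct_radius,
         col_tolerance = col_tolerance,
         spacing_window = spacing_window,
         max_gap = if (is.null(max_gap)) NULL else as.integer(max_gap),
         baseline_min_fraction = baseline_min_fraction,
         invert_labels = invert_labels),
    class = "dearray_params"
  )
}
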