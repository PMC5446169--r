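# ROI and whole-block quantification built on the per-pixel rules.

#' Quantify the stained area of a region-of-interest image
#'
#' Classifies every pixel and returns the tallies as a [stain_quant].
#' Optionally also returns the two binary composite masks that the tallies
#' are counted from: the sample mask (tissue vs background) and the stain
#' mask (DAB-positive pixels).
#'
#' @param img An H x W x 3 array of 8-bit intensities.
#' @param params A [pixel_class_params()] object.
#' @param return_masks If \code{TRUE}, attach logical matrices
#'   \code{sample_mask} and \code{stain_mask} to the result.
#' @return A [stain_quant] object; with \code{return_masks = TRUE}, a list
#'   \code{list(quant, sample_mask, stain_mask)}.
#' @examples
#' fx <- gen_tissue_image(width = 40, height = 40, stain_fraction = 0.25,
#'                        tissue_fraction = 0.5, seed = 1)
#' quantify_roi(fx$img)
#' @export
quantify_roi <- function(img, params = pixel_class_params(),
                         return_masks = FALSE) {
  res <- classify_image(img, params)
  if (!return_masks) return(res$quant)
  list(quant = res$quant,
       sample_mask = res$labels != 0L,
       stain_mask = res$labels == 2L)
}

#' Partition an image into a grid of tiles
#'
#' Splits the image extent into \code{grid_rows x grid_cols} rectangles that
#' are pairwise disjoint and together cover every pixel. When a dimension is
#' not divisible by the grid size, interior tiles take the floor size and
#' the last row/column of tiles absorbs the remainder, so cumulative tallies
#' over tiles stay exact.
#'
#' @param shape Integer vector \code{c(height, width)} of the image.
#' @param cfg A [tile_config()] object.
#' @return A data.frame with one row per tile: \code{tile}, \code{tile_row},
#'   \code{tile_col}, and 1-based inclusive pixel bounds \code{y0}, \code{y1},
#'   \code{x0}, \code{x1}, in row-major order.
#' @examples
#' tile_image(c(1024, 1024))          # sixteen 256 x 256 tiles
#' tile_image(c(10, 16), tile_config(1, 4))
#' @export
tile_image <- function(shape, cfg = tile_config()) {
  stopifnot(length(shape) == 2, all(shape >= 1))
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  if (h < cfg$grid_rows || w < cfg$grid_cols)
    stop(sprintf("image (%d x %d) is smaller than the %d x %d tile grid",
                 h, w, cfg$grid_rows, cfg$grid_cols))
  th <- h %/% cfg$grid_rows
  tw <- w %/% cfg$grid_cols
  out <- expand.grid(tile_col = seq_len(cfg$grid_cols),
                     tile_row = seq_len(cfg$grid_rows))
  out <- out[, c("tile_row", "tile_col")]
  out$y0 <- (out$tile_row - 1L) * th + 1L
  out$y1 <- ifelse(out$tile_row == cfg$grid_rows, h, out$tile_row * th)
  out$x0 <- (out$tile_col - 1L) * tw + 1L
  out$x1 <- ifelse(out$tile_col == cfg$grid_cols, w, out$tile_col * tw)
  out <- cbind(tile = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Quantify a whole-block image tile by tile
#'
#' Processes a large scan as a sequence of tiles (default 4 x 4, sixteen
#' segments), classifying one tile at a time and adding its tallies to the
#' cumulative totals. The result is identical, tally for tally, to a single
#' pass over the whole raster; tiling only bounds how much of the image is
#' classified at once.
#'
#' @param img An H x W x 3 array, or a path to a PNG/TIFF file which is read
#'   with [read_image()].
#' @param params A [pixel_class_params()] object.
#' @param cfg A [tile_config()] object.
#' @return A [stain_quant] object for the whole image.
#' @export
quantify_whole_block <- function(img, params = pixel_class_params(),
                                 cfg = tile_config()) {
  if (is.character(img)) img <- read_image(img)
  .check_rgb_image(img)
  tiles <- tile_image(dim(img)[1:2], cfg)
  n_bg <- 0; n_st <- 0; n_un <- 0
  for (i in seq_len(nrow(tiles))) {
    t <- tiles[i, ]
    q <- classify_image(img[t$y0:t$y1, t$x0:t$x1, , drop = FALSE],
                        params)$quant
    n_bg <- n_bg + q$background_pixels
    n_st <- n_st + q$stained_pixels
    n_un <- n_un + q$unstained_pixels
  }
  stain_quant(background = n_bg, stained = n_st, unstained = n_un)
}

#' Normalize stain fractions by the maximum sample
#'
#' Rescales a set of per-sample stain measurements so that the sample with
#' the highest value equals 1. Used when comparing relative stain levels
#' between measurement methods whose absolute scales differ.
#'
#' @param values Numeric vector of stain fractions (or any non-negative
#'   measurements), at least one of them positive.
#' @return Numeric vector of the same length with maximum 1.
#' @examples
#' normalize_by_max(c(2, 4, 8))
#' @export
normalize_by_max <- function(values) {
  if (length(values) == 0) stop("cannot normalize an empty vector")
  if (any(is.na(values))) stop("cannot normalize undefined (NA) values")
  m <- max(values)
  if (m <= 0) stop("cannot normalize: maximum value is not positive")
  values / m
}
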