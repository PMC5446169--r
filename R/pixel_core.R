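# Per-pixel decision rules. Every other module reduces to these two tests.

PIXEL_LEVELS <- c("background", "unstained", "stained")

.as_rgb_matrix <- function(p) {
  if (is.matrix(p)) {
    if (ncol(p) != 3) stop("pixel matrix must have 3 columns (R, G, B)")
    return(p)
  }
  if (length(p) != 3) stop("a pixel is a length-3 numeric (R, G, B)")
  matrix(as.numeric(p), nrow = 1)
}

#' Background test for RGB pixels
#'
#' A pixel is background when it is bright (every channel at or above
#' \code{bg_min}) and chromatically uniform (channel spread at most
#' \code{bg_uniformity}). Slide background is near-white; tissue is darker
#' and/or strongly colored, so it fails one of the two conditions.
#'
#' @param p A length-3 numeric \code{c(r, g, b)} with 8-bit intensities in
#'   [0, 255], or an n x 3 matrix of such pixels.
#' @param params A [pixel_class_params()] object.
#' @return Logical vector, one element per pixel.
#' @examples
#' is_background(c(255, 255, 255))   # perfect white
#' is_background(c(175, 175, 125))   # tissue pixel
#' @export
is_background <- function(p, params = pixel_class_params()) {
  m <- .as_rgb_matrix(p)
  mn <- pmin(m[, 1], m[, 2], m[, 3])
  mx <- pmax(m[, 1], m[, 2], m[, 3])
  mn >= params$bg_min & (mx - mn) <= params$bg_uniformity
}

#' DAB-stain test for sample (non-background) pixels
#'
#' A sample pixel is called stained (DAB-positive, brown) when at least one
#' channel is strictly below \code{dark_threshold} and the pixel is not
#' blue-dominant. Blue dominance means \code{b >= alpha * r} and
#' \code{b >= beta * g}; such pixels are hematoxylin-counterstained tissue.
#' Comparing B against scaled R and G, rather than raw channel magnitudes,
#' makes the call robust to overall darkness: a dark stained region can have
#' a lower absolute blue value than a light unstained one.
#'
#' The test is only meaningful for pixels that already failed
#' [is_background()]; [classify_pixel()] applies the rules in that order.
#'
#' @inheritParams is_background
#' @return Logical vector, one element per pixel.
#' @examples
#' is_stained(c(75, 175, 100))    # red-dominant: stained
#' is_stained(c(175, 175, 125))   # no channel below 125: unstained
#' @export
is_stained <- function(p, params = pixel_class_params()) {
  m <- .as_rgb_matrix(p)
  r <- m[, 1]; g <- m[, 2]; b <- m[, 3]
  mn <- pmin(r, g, b)
  blue_dominant <- (b >= params$alpha * r) & (b >= params$beta * g)
  (mn < params$dark_threshold) & !blue_dominant
}

#' Classify a pixel as background, unstained sample, or stained sample
#'
#' Background is tested first; remaining (sample) pixels are split into
#' stained and unstained by [is_stained()]. The three labels are mutually
#' exclusive and exhaustive.
#'
#' @inheritParams is_background
#' @return A factor with levels \code{background}, \code{unstained},
#'   \code{stained}; one element per pixel.
#' @examples
#' classify_pixel(c(75, 175, 100))
#' classify_pixel(rbind(c(255, 255, 255), c(175, 175, 125)))
#' @export
classify_pixel <- function(p, params = pixel_class_params()) {
  m <- .as_rgb_matrix(p)
  bg <- is_background(m, params)
  st <- is_stained(m, params)
  lab <- ifelse(bg, 1L, ifelse(st, 3L, 2L))
  factor(PIXEL_LEVELS[lab], levels = PIXEL_LEVELS)
}

.check_rgb_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3)
    stop("image must be an H x W x 3 array of 8-bit intensities")
  if (dim(img)[3] != 3)
    stop("image must have exactly 3 channels (R, G, B); ",
         "use read_image() to drop an alpha channel")
  if (dim(img)[1] < 1 || dim(img)[2] < 1)
    stop("degenerate input: image has no pixels")
  invisible(img)
}

#' Label every pixel of an image and tally the classes
#'
#' Applies [classify_pixel()] to the whole raster in one vectorized pass and
#' returns the label raster together with the pixel tallies as a
#' [stain_quant] object. Background and sample counts always sum to the
#' total pixel count, and stained plus unstained pixels sum to the sample
#' count.
#'
#' @param img An H x W x 3 array of 8-bit intensities in [0, 255]
#'   (\code{img[y, x, channel]}).
#' @param params A [pixel_class_params()] object.
#' @return A list with components \code{labels} (H x W integer matrix:
#'   0 = background, 1 = unstained sample, 2 = stained sample) and
#'   \code{quant} (a [stain_quant] object).
#' @examples
#' img <- array(255L, dim = c(2, 2, 3))
#' img[2, 1, ] <- c(75, 175, 100)
#' classify_image(img)$quant
#' @export
classify_image <- function(img, params = pixel_class_params()) {
  .check_rgb_image(img)
  r <- img[, , 1, drop = TRUE]
  g <- img[, , 2, drop = TRUE]
  b <- img[, , 3, drop = TRUE]
  mn <- pmin(r, g, b)
  mx <- pmax(r, g, b)
  bg <- mn >= params$bg_min & (mx - mn) <= params$bg_uniformity
  blue_dom <- (b >= params$alpha * r) & (b >= params$beta * g)
  st <- !bg & (mn < params$dark_threshold) & !blue_dom

  labels <- matrix(1L, nrow = dim(img)[1], ncol = dim(img)[2])
  labels[bg] <- 0L
  labels[st] <- 2L

  n_bg <- sum(bg)
  n_st <- sum(st)
  total <- length(labels)
  list(labels = labels,
       quant = stain_quant(background = n_bg,
                           stained = n_st,
                           unstained = total - n_bg - n_st))
}

#' Stain quantification tallies for one region
#'
#' Holds the pixel tallies produced by classifying a region and the derived
#' stain fraction. The fraction is stained / sample; it is \code{NA}
#' (undefined) when the region contains no sample pixels, never silently 0,
#' so that downstream ratios fail loudly.
#'
#' @param background,stained,unstained Non-negative integer pixel counts.
#' @return An object of class \code{stain_quant} with fields
#'   \code{total_pixels}, \code{background_pixels}, \code{sample_pixels},
#'   \code{stained_pixels}, \code{unstained_pixels}, \code{stain_fraction}.
#' @export
stain_quant <- function(background = 0, stained = 0, unstained = 0) {
  stopifnot(background >= 0, stained >= 0, unstained >= 0)
  background <- as.numeric(background)
  stained <- as.numeric(stained)
  unstained <- as.numeric(unstained)
  sample_px <- stained + unstained
  structure(
    list(total_pixels = background + sample_px,
         background_pixels = background,
         sample_pixels = sample_px,
         stained_pixels = stained,
         unstained_pixels = unstained,
         stain_fraction = if (sample_px > 0) stained / sample_px else NA_real_),
    class = "stain_quant"
  )
}

#' @export
print.stain_quant <- function(x, ...) {
  cat(sprintf("Stain quantification over %.0f pixels\n", x$total_pixels))
  cat(sprintf("  background: %.0f   sample: %.0f\n",
              x$background_pixels, x$sample_pixels))
  cat(sprintf("  stained: %.0f   unstained: %.0f\n",
              x$stained_pixels, x$unstained_pixels))
  if (is.na(x$stain_fraction)) {
    cat("  stain fraction: undefined (no sample pixels)\n")
  } else {
    cat(sprintf("  stain fraction: %.4f\n", x$stain_fraction))
  }
  invisible(x)
}
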