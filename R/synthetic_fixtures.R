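# Rule-consistent synthetic IHC fixtures with exact ground truth.
#
# Colors are drawn from simple models of the three pixel populations
# (near-white background, hematoxylin-blue tissue, DAB-brown stain) and then
# verified against the classifier by rejection sampling, so generator labels
# and classifier labels agree exactly by construction. Target fractions are
# realized by placing exact pixel counts, not by per-pixel coin flips.

.resample_until <- function(n, draw, accept, what, max_iter = 50) {
  m <- draw(n)
  ok <- accept(m)
  iter <- 0
  while (!all(ok)) {
    iter <- iter + 1
    if (iter > max_iter || mean(ok) < 0.01)
      stop("color model incompatible with classifier rules for ", what,
           " pixels (rejection rate too high)")
    bad <- which(!ok)
    m[bad, ] <- draw(length(bad))
    ok <- accept(m)
  }
  m
}

.draw_background <- function(n, params) {
  draw <- function(k) {
    base <- sample(240:245, k, replace = TRUE)
    mm <- cbind(base + sample(0:10, k, replace = TRUE),
                base + sample(0:10, k, replace = TRUE),
                base + sample(0:10, k, replace = TRUE))
    mm[mm > 255] <- 255
    mm
  }
  .resample_until(n, draw,
                  function(mm) classify_pixel(mm, params) == "background",
                  "background")
}

.draw_unstained <- function(n, params) {
  draw <- function(k) {
    b <- sample(135:205, k, replace = TRUE)
    g <- floor(b / params$beta) - sample(0:25, k, replace = TRUE)
    r <- b - sample(0:60, k, replace = TRUE)
    cbind(pmax(r, 0), pmax(g, 0), b)
  }
  .resample_until(n, draw,
                  function(mm) classify_pixel(mm, params) == "unstained",
                  "unstained tissue")
}

.draw_stained <- function(n, params) {
  draw <- function(k) {
    r <- sample(105:185, k, replace = TRUE)
    g <- round(r * runif(k, 0.50, 0.85))
    b <- pmin(round(r * runif(k, 0.40, 0.80)),
              ceiling(params$dark_threshold) - 1, r - 1)
    cbind(r, g, pmax(b, 0))
  }
  .resample_until(n, draw,
                  function(mm) classify_pixel(mm, params) == "stained",
                  "stained tissue")
}

.fill_pixels <- function(img, idx, colors) {
  # idx: linear indices into the H x W plane
  npix <- dim(img)[1] * dim(img)[2]
  img[idx] <- colors[, 1]
  img[idx + npix] <- colors[, 2]
  img[idx + 2 * npix] <- colors[, 3]
  img
}

#' Generate a synthetic tissue image with exact stain ground truth
#'
#' Produces an RGB raster whose pixels are background, unstained tissue, or
#' DAB-stained tissue in exactly known counts: \code{round(tissue_fraction *
#' N)} tissue pixels of which \code{round(stain_fraction * n_tissue)} are
#' stained, at positions shuffled uniformly. Every emitted color is checked
#' against [classify_pixel()], so classifying the image recovers the ground
#' truth exactly.
#'
#' @param width,height Image size in pixels.
#' @param stain_fraction Target fraction of tissue pixels that are stained,
#'   in [0, 1].
#' @param tissue_fraction Target fraction of all pixels that are tissue
#'   (non-background), in [0, 1].
#' @param seed RNG seed; identical specs and seeds give identical images.
#' @param params Classifier parameters the colors must be consistent with.
#' @return A list: \code{img} (H x W x 3 integer array), \code{labels}
#'   (ground-truth matrix, 0/1/2 as in [classify_image()]), and the exact
#'   counts \code{n_tissue} and \code{n_stained}.
#' @examples
#' fx <- gen_tissue_image(100, 100, stain_fraction = 0.2,
#'                        tissue_fraction = 0.5, seed = 1)
#' fx$n_stained
#' @export
gen_tissue_image <- function(width, height, stain_fraction,
                             tissue_fraction, seed = NULL,
                             params = pixel_class_params()) {
  stopifnot(width >= 1, height >= 1,
            stain_fraction >= 0, stain_fraction <= 1,
            tissue_fraction >= 0, tissue_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  npix <- as.integer(width) * as.integer(height)
  n_tissue <- round(tissue_fraction * npix)
  n_stained <- round(stain_fraction * n_tissue)

  idx_tissue <- sample.int(npix, n_tissue)
  idx_stained <- if (n_stained > 0) idx_tissue[seq_len(n_stained)] else integer(0)
  idx_unstained <- setdiff(idx_tissue, idx_stained)
  idx_bg <- setdiff(seq_len(npix), idx_tissue)

  img <- array(0L, dim = c(height, width, 3))
  if (length(idx_bg) > 0)
    img <- .fill_pixels(img, idx_bg, .draw_background(length(idx_bg), params))
  if (length(idx_unstained) > 0)
    img <- .fill_pixels(img, idx_unstained,
                        .draw_unstained(length(idx_unstained), params))
  if (length(idx_stained) > 0)
    img <- .fill_pixels(img, idx_stained,
                        .draw_stained(length(idx_stained), params))

  labels <- matrix(0L, nrow = height, ncol = width)
  labels[idx_unstained] <- 1L
  labels[idx_stained] <- 2L

  list(img = img, labels = labels,
       n_tissue = n_tissue, n_stained = n_stained)
}

.disk_pixels <- function(cx, cy, radius, height, width) {
  x0 <- max(1L, floor(cx - radius)); x1 <- min(width, ceiling(cx + radius))
  y0 <- max(1L, floor(cy - radius)); y1 <- min(height, ceiling(cy + radius))
  g <- expand.grid(y = y0:y1, x = x0:x1)
  keep <- (g$x - cx)^2 + (g$y - cy)^2 <= radius^2
  g[keep, , drop = FALSE]
}

#' Generate a synthetic TMA scene at two resolutions
#'
#' Renders a regular grid of circular tissue cores on a near-white
#' background, with optional centroid jitter, randomly missing cores, cores
#' fragmented into two half-disks separated by a 3-pixel gap, and small
#' debris specks. The full-resolution image is an exact integer upscale of
#' the thumbnail scene (each thumbnail pixel replicated \code{scale} times
#' along both axes), so per-core stain fractions are identical at both
#' resolutions.
#'
#' @param grid_rows,grid_cols TMA design grid size.
#' @param spacing Center-to-center core spacing in thumbnail pixels.
#' @param core_radius Core radius in thumbnail pixels (must leave room for
#'   the jitter: \code{core_radius + jitter_fraction * spacing < spacing / 2}).
#' @param jitter_fraction Uniform centroid jitter amplitude, as a fraction
#'   of \code{spacing}, applied independently per axis.
#' @param missing_prob Probability that a core is absent.
#' @param fragment_prob Probability that a present core is rendered as two
#'   half-disks with a 3-pixel vertical gap between them.
#' @param debris_count Number of small (sub-core) debris specks placed away
#'   from the cores.
#' @param core_stain_fraction Fraction of each core's pixels that are
#'   stained; a single value or one per grid cell (row-major). Realized as
#'   exact pixel counts per core.
#' @param scale Integer upscale factor from thumbnail to full resolution.
#' @param seed RNG seed.
#' @param params Classifier parameters the colors must be consistent with.
#' @return A list: \code{thumb} and \code{full} (RGB arrays), and
#'   \code{truth}, a data.frame with one row per grid cell: \code{row},
#'   \code{col}, \code{present}, \code{fragmented}, thumbnail centroid
#'   \code{cx}, \code{cy}, full-resolution centroid \code{cx_full},
#'   \code{cy_full}, \code{n_core_px}, and realized \code{stain_fraction}.
#' @examples
#' tma <- gen_tma_image(3, 3, spacing = 40, core_radius = 12, seed = 1)
#' dim(tma$thumb); sum(tma$truth$present)
#' @export
gen_tma_image <- function(grid_rows, grid_cols, spacing, core_radius,
                          jitter_fraction = 0, missing_prob = 0,
                          fragment_prob = 0, debris_count = 0,
                          core_stain_fraction = 0.3, scale = 4,
                          seed = NULL, params = pixel_class_params()) {
  stopifnot(grid_rows >= 1, grid_cols >= 1, spacing > 0, core_radius > 0,
            jitter_fraction >= 0, missing_prob >= 0, missing_prob <= 1,
            fragment_prob >= 0, fragment_prob <= 1, debris_count >= 0,
            scale >= 1, scale == as.integer(scale))
  if (core_radius + jitter_fraction * spacing >= spacing / 2)
    stop("cores would overlap: need core_radius + jitter < spacing / 2")
  if (!is.null(seed)) set.seed(seed)

  n_cells <- grid_rows * grid_cols
  stain_target <- rep_len(core_stain_fraction, n_cells)
  margin <- ceiling(0.75 * spacing)
  height <- as.integer(2 * margin + (grid_rows - 1) * spacing)
  width <- as.integer(2 * margin + (grid_cols - 1) * spacing)

  img <- array(0L, dim = c(height, width, 3))
  img <- .fill_pixels(img, seq_len(height * width),
                      .draw_background(height * width, params))

  truth <- expand.grid(col = seq_len(grid_cols), row = seq_len(grid_rows))
  truth <- truth[, c("row", "col")]
  truth$present <- runif(n_cells) >= missing_prob
  truth$fragmented <- truth$present & (runif(n_cells) < fragment_prob)
  jx <- runif(n_cells, -1, 1) * jitter_fraction * spacing
  jy <- runif(n_cells, -1, 1) * jitter_fraction * spacing
  truth$cx <- margin + (truth$col - 1) * spacing + jx
  truth$cy <- margin + (truth$row - 1) * spacing + jy
  truth$n_core_px <- 0L
  truth$stain_fraction <- NA_real_

  npix_plane <- height * width
  for (i in seq_len(n_cells)) {
    if (!truth$present[i]) {
      truth$cx[i] <- NA_real_; truth$cy[i] <- NA_real_
      next
    }
    px <- .disk_pixels(truth$cx[i], truth$cy[i], core_radius, height, width)
    if (truth$fragmented[i]) {
      # two half-disks with a 3-px vertical gap centred on the core
      px <- px[abs(px$x - truth$cx[i]) > 1.5, , drop = FALSE]
    }
    idx <- (px$x - 1L) * height + px$y
    n_px <- length(idx)
    n_st <- round(stain_target[i] * n_px)
    idx <- sample(idx)
    idx_st <- idx[seq_len(n_st)]
    idx_un <- if (n_st < n_px) idx[(n_st + 1):n_px] else integer(0)
    if (length(idx_un) > 0)
      img <- .fill_pixels(img, idx_un, .draw_unstained(length(idx_un), params))
    if (n_st > 0)
      img <- .fill_pixels(img, idx_st, .draw_stained(n_st, params))
    truth$n_core_px[i] <- n_px
    truth$stain_fraction[i] <- if (n_px > 0) n_st / n_px else NA_real_
  }

  # debris: specks well below core area, kept clear of every core
  if (debris_count > 0) {
    present <- truth[truth$present, , drop = FALSE]
    placed <- 0; tries <- 0
    while (placed < debris_count && tries < 200 * debris_count) {
      tries <- tries + 1
      dx <- runif(1, 3, width - 3); dy <- runif(1, 3, height - 3)
      if (nrow(present) > 0) {
        d2 <- (present$cx - dx)^2 + (present$cy - dy)^2
        if (min(d2) < (core_radius + spacing / 4)^2) next
      }
      px <- .disk_pixels(dx, dy, runif(1, 1, 2), height, width)
      if (nrow(px) == 0) next
      idx <- (px$x - 1L) * height + px$y
      img <- .fill_pixels(img, idx, .draw_unstained(length(idx), params))
      placed <- placed + 1
    }
  }

  full <- img[rep(seq_len(height), each = scale),
              rep(seq_len(width), each = scale), , drop = FALSE]
  truth$cx_full <- (truth$cx - 0.5) * scale + 0.5
  truth$cy_full <- (truth$cy - 0.5) * scale + 0.5

  list(thumb = img, full = full, truth = truth, scale = scale,
       spacing = spacing)
}

#' Generate paired Ki-67/CD31 marker measurements for two grade groups
#'
#' Simulates per-sample stain fractions for a proliferation marker (Ki-67)
#' and a vascular marker (CD31) under low- and high-grade categories. CD31
#' fractions are drawn from a fixed positive uniform distribution; each
#' sample's proliferative vascular index (PVI = Ki-67 / CD31) equals the
#' group mean times mean-one lognormal noise, and Ki-67 is derived as
#' PVI * CD31. With \code{noise_sd = 0} every sample's PVI equals its group
#' mean exactly.
#'
#' @param n_low,n_high Samples per category (>= 2).
#' @param pvi_low_mean,pvi_high_mean Mean PVI in each category (> 0).
#' @param noise_sd Lognormal sdlog of the multiplicative PVI noise.
#' @param seed RNG seed.
#' @return A data.frame with columns \code{sample_id}, \code{ki67_fraction},
#'   \code{cd31_fraction}, \code{gleason} (6/7 for low, 8/9 for high), and
#'   \code{category}.
#' @examples
#' gen_marker_pairs(3, 3, pvi_low_mean = 0.5, pvi_high_mean = 1,
#'                  noise_sd = 0, seed = 1)
#' @export
gen_marker_pairs <- function(n_low, n_high, pvi_low_mean, pvi_high_mean,
                             noise_sd = 0.2, seed = NULL) {
  stopifnot(n_low >= 2, n_high >= 2,
            pvi_low_mean > 0, pvi_high_mean > 0, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- n_low + n_high
  category <- rep(c("low", "high"), c(n_low, n_high))
  pvi_mean <- rep(c(pvi_low_mean, pvi_high_mean), c(n_low, n_high))
  cd31 <- runif(n, 0.02, 0.08)
  noise <- if (noise_sd > 0)
    stats::rlnorm(n, meanlog = -noise_sd^2 / 2, sdlog = noise_sd)
  else rep(1, n)
  pvi <- pvi_mean * noise
  ki67 <- pvi * cd31
  if (any(ki67 > 1)) {
    warning("some Ki-67 fractions exceeded 1 and were clipped")
    ki67 <- pmin(ki67, 1)
  }
  gleason <- ifelse(category == "low",
                    sample(c(6L, 7L), n, replace = TRUE),
                    sample(c(8L, 9L), n, replace = TRUE))
  data.frame(sample_id = sprintf("S%03d", seq_len(n)),
             ki67_fraction = ki67,
             cd31_fraction = cd31,
             gleason = gleason,
             category = category,
             stringsAsFactors = FALSE)
}
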