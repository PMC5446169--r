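# Independent oracles and small fixture builders used across the suite.

# Scalar per-pixel reference classifier: a plain double loop applying the
# two decision rules directly, independent of the vectorized implementation.
naive_classify <- function(img, params = pixel_class_params()) {
  h <- dim(img)[1]; w <- dim(img)[2]
  out <- matrix(0L, h, w)
  for (y in seq_len(h)) {
    for (x in seq_len(w)) {
      r <- img[y, x, 1]; g <- img[y, x, 2]; b <- img[y, x, 3]
      lo <- min(r, g, b); hi <- max(r, g, b)
      if (lo >= params$bg_min && (hi - lo) <= params$bg_uniformity) {
        out[y, x] <- 0L
      } else if (lo < params$dark_threshold &&
                 !(b >= params$alpha * r && b >= params$beta * g)) {
        out[y, x] <- 2L
      } else {
        out[y, x] <- 1L
      }
    }
  }
  out
}

random_rgb_image <- function(h, w) {
  array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
}

# Perfect centroid lattice as a centroid table, optionally with cells
# removed: cells is a data.frame(row, col) of cores to KEEP (default all).
lattice_table <- function(rows, cols, spacing = 100, origin = 50,
                          drop = NULL) {
  g <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  if (!is.null(drop)) {
    keep <- !(paste(g$row, g$col) %in% paste(drop$row, drop$col))
    g <- g[keep, , drop = FALSE]
  }
  tab <- data.frame(centroid_x = origin + (g$col - 1) * spacing,
                    centroid_y = origin + (g$row - 1) * spacing,
                    true_row = g$row, true_col = g$col)
  centroid_table(tab)
}
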