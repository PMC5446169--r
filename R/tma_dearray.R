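# TMA de-arraying: detect cores on a thumbnail, assign each to its design
# grid cell, score each core at full resolution, join pathologist
# annotations, and export a results table.

#' Detect TMA cores on a thumbnail image
#'
#' Builds a foreground mask (every pixel that is not background according to
#' the pixel rules), merges fragmented cores by morphological closing with a
#' disc structuring element, solidifies each core by filling holes, labels
#' connected components, and discards components whose area falls outside
#' \code{[min_area, max_area]} (debris and merged core pairs). When the area
#' bounds are not supplied they are derived from the estimated inter-core
#' spacing (see [dearray_params()]).
#'
#' @param thumb An H x W x 3 RGB array small enough for in-memory
#'   morphology.
#' @param params A [pixel_class_params()] object.
#' @param dp A [dearray_params()] object.
#' @return A data.frame with one row per detected core: \code{centroid_x},
#'   \code{centroid_y} (thumbnail pixel coordinates, 1-based), \code{area}.
#' @export
detect_cores <- function(thumb, params = pixel_class_params(), dp) {
  .check_rgb_image(thumb)
  labels <- classify_image(thumb, params)$labels
  mask <- labels != 0L

  # EBImage works in (x, y) order: transpose so dim 1 is x (image column)
  m <- t(mask) * 1
  brush_size <- 2L * as.integer(dp$struct_radius) + 1L
  m <- EBImage::closing(m, EBImage::makeBrush(brush_size, shape = "disc"))
  m <- EBImage::fillHull(m)
  lab <- EBImage::bwlabel(m)

  n_obj <- max(lab)
  if (n_obj == 0)
    stop("no foreground objects detected on the thumbnail")
  areas <- tabulate(lab[lab > 0], nbins = n_obj)
  mom <- EBImage::computeFeatures.moment(lab)
  blobs <- data.frame(centroid_x = mom[, "m.cx"],
                      centroid_y = mom[, "m.cy"],
                      area = areas)

  min_area <- dp$min_area
  max_area <- dp$max_area
  if (is.null(min_area) || is.null(max_area)) {
    spacing <- .estimate_spacing(blobs$centroid_x, blobs$centroid_y)
    if (is.na(spacing))
      stop("cannot derive area bounds from a single object; ",
           "supply min_area and max_area explicitly")
    r_exp <- 0.4 * spacing
    if (is.null(min_area)) min_area <- 0.2 * pi * r_exp^2
    if (is.null(max_area)) max_area <- 2.5 * pi * r_exp^2
  }

  keep <- blobs$area >= min_area & blobs$area <= max_area
  if (!any(keep))
    stop(sprintf(
      paste0("no objects survived area filtering [%g, %g]; ",
             "component areas were: %s"),
      min_area, max_area, paste(sort(blobs$area), collapse = ", ")))
  out <- blobs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the centroid table used for grid assignment
#'
#' Adds the coordinate sum column (\code{centroid_x + centroid_y}) whose
#' minimum identifies the core nearest the image origin (top-left corner).
#'
#' @param blobs A data.frame from [detect_cores()].
#' @return The same data.frame with a \code{coord_sum} column.
#' @export
centroid_table <- function(blobs) {
  stopifnot(is.data.frame(blobs),
            all(c("centroid_x", "centroid_y") %in% names(blobs)))
  blobs$coord_sum <- blobs$centroid_x + blobs$centroid_y
  blobs
}

#' Find the core nearest the image origin
#'
#' Returns the index of the centroid with the smallest coordinate sum
#' (x + y); ties are broken by the smaller y, then the smaller x.
#'
#' @param table A [centroid_table()] data.frame.
#' @return Integer row index of the origin core.
#' @examples
#' tab <- centroid_table(data.frame(centroid_x = c(10, 10, 50),
#'                                  centroid_y = c(10, 50, 10)))
#' find_origin_core(tab)
#' @export
find_origin_core <- function(table) {
  if (nrow(table) == 0) stop("empty centroid table")
  order(table$coord_sum, table$centroid_y, table$centroid_x)[1]
}

.estimate_spacing <- function(x, y) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf
  s <- stats::median(apply(d, 1, min))
  # The nearest-neighbour median is biased low under centroid jitter (a
  # minimum statistic). Refine with axis-aligned pair gaps, whose per-step
  # distances are symmetric around the true spacing: assign each gap its
  # step count and iterate the median unit distance to a fixed point.
  dx <- abs(outer(x, x, "-")); dy <- abs(outer(y, y, "-"))
  ut <- upper.tri(dx)
  rowish <- ut & dy <= 0.35 * s & dx >= 0.6 * s
  colish <- ut & dx <= 0.35 * s & dy >= 0.6 * s
  g <- c(dx[rowish], dy[colish])
  if (length(g) < 3) return(s)
  for (i in 1:3) {
    k <- pmax(1, round(g / s))
    s <- stats::median(g / k)
  }
  s
}

# Search for the next core k grid steps from (px, py) along `axis`
# ("y" walks a column, "x" walks a row) in direction `dir` (+1/-1).
# Returns the index of the nearest admissible unused centroid, or NA.
.find_next <- function(table, used, px, py, axis, dir, k, spacing, dp) {
  if (axis == "y") {
    along <- dir * (table$centroid_y - py)
    perp <- table$centroid_x - px
    pred_x <- px; pred_y <- py + dir * k * spacing
  } else {
    along <- dir * (table$centroid_x - px)
    perp <- table$centroid_y - py
    pred_x <- px + dir * k * spacing; pred_y <- py
  }
  # clip the search band to (k -/+ 0.5) spacings so that consecutive gap
  # sizes claim disjoint distance ranges; for k = 1 this leaves the
  # configured window unchanged
  lo <- max(dp$spacing_window[1] * k, k - 0.5) * spacing
  hi <- min(dp$spacing_window[2] * k, k + 0.5) * spacing
  cand <- which(!used & abs(perp) <= dp$col_tolerance * spacing &
                  along >= lo & along <= hi)
  if (length(cand) == 0) return(NA_integer_)
  d2 <- (table$centroid_x[cand] - pred_x)^2 +
    (table$centroid_y[cand] - pred_y)^2
  cand[which.min(d2)]
}

# Walk up to `max_steps` grid steps from a (possibly virtual) position,
# expanding the step size k past missing cores. Returns the indices of the
# cores found and the (positive) step offsets from the start.
.walk_line <- function(table, used, px, py, axis, dir, max_steps,
                       spacing, dp) {
  pos <- 0L
  out_idx <- integer(0); out_pos <- integer(0)
  while (pos < max_steps) {
    remaining <- max_steps - pos
    max_gap <- if (is.null(dp$max_gap)) remaining
    else min(dp$max_gap, remaining)
    hit <- NA_integer_; step <- NA_integer_
    for (k in seq_len(max_gap)) {
      hit <- .find_next(table, used, px, py, axis, dir, k, spacing, dp)
      if (!is.na(hit)) { step <- k; break }
    }
    if (is.na(hit)) break
    pos <- pos + step
    used[hit] <- TRUE
    out_idx <- c(out_idx, hit); out_pos <- c(out_pos, pos)
    px <- table$centroid_x[hit]; py <- table$centroid_y[hit]
  }
  list(idx = out_idx, pos = out_pos, used = used)
}

#' Assign detected cores to their TMA grid cells
#'
#' Estimates the inter-core spacing as the median nearest-neighbour centroid
#' distance, starts at the core nearest the image origin, and walks the
#' first column: at each step it accepts the nearest unused centroid whose
#' horizontal offset is within \code{col_tolerance * spacing} and whose
#' vertical offset lies within \code{spacing_window * (k * spacing)},
#' expanding the step k past missing cores up to \code{max_gap}. If the
#' first column recovers fewer than \code{baseline_min_fraction * grid_rows}
#' cores, the first row is used as the baseline instead. Each remaining line
#' is then filled from its baseline core by the same search; lines whose
#' baseline cell is empty are walked from a position predicted by a linear
#' fit of the baseline centroids.
#'
#' Grid labels are anchored to the array's bounding lattice: the origin
#' core's absolute row and column are estimated from its offset to the
#' minimal centroid coordinates, so a missing top-left corner core does not
#' shift every label. Every core is assigned to at most one cell and every
#' cell holds at most one core.
#'
#' @param table A [centroid_table()] data.frame.
#' @param dp A [dearray_params()] object declaring the grid size.
#' @return An object of class \code{tma_grid}: a list with \code{centroids}
#'   (the table plus \code{assigned_row}, \code{assigned_col}),
#'   \code{matrix} (grid of table row indices, NA for empty cells),
#'   \code{grid_rows}, \code{grid_cols}, \code{spacing}, \code{inverted}.
#' @export
assemble_grid <- function(table, dp) {
  n <- nrow(table)
  if (n == 0) stop("empty centroid table")
  R <- dp$grid_rows; C <- dp$grid_cols
  spacing <- .estimate_spacing(table$centroid_x, table$centroid_y)

  if (n == 1 || R * C == 1) {
    table$assigned_row <- 1L; table$assigned_col <- 1L
    return(.new_tma_grid(table, R, C, spacing))
  }

  origin <- find_origin_core(table)
  ox <- table$centroid_x[origin]; oy <- table$centroid_y[origin]

  # anchor the origin core to its absolute cell in the array's bounding
  # lattice, so a missing top-left corner core does not shift every label
  row0 <- 1L + as.integer(
    min(R - 1, max(0, round((oy - min(table$centroid_y)) / spacing))))
  col0 <- 1L + as.integer(
    min(C - 1, max(0, round((ox - min(table$centroid_x)) / spacing))))

  # walk a baseline line through the origin in both directions; `axis` is
  # the direction of the walk, `start` the origin's position along it
  baseline_walk <- function(axis, start, L) {
    used <- rep(FALSE, n); used[origin] <- TRUE
    fwd <- .walk_line(table, used, ox, oy, axis, +1L, L - start,
                      spacing, dp)
    bwd <- .walk_line(table, fwd$used, ox, oy, axis, -1L, start - 1L,
                      spacing, dp)
    list(idx = c(origin, fwd$idx, bwd$idx),
         pos = c(start, start + fwd$pos, start - bwd$pos),
         used = bwd$used)
  }

  col_walk <- baseline_walk("y", row0, R)
  if (length(col_walk$idx) >= dp$baseline_min_fraction * R) {
    baseline <- col_walk; b_axis <- "y"
    b_len <- R; f_len <- C; f_axis <- "x"; f_start <- col0
  } else {
    row_walk <- baseline_walk("x", col0, C)
    if (length(row_walk$idx) < dp$baseline_min_fraction * C)
      stop(sprintf(
        paste0("gridding failed: neither the first column (%d/%d cores) ",
               "nor the first row (%d/%d cores) yields a valid baseline"),
        length(col_walk$idx), R, length(row_walk$idx), C))
    baseline <- row_walk; b_axis <- "x"
    b_len <- C; f_len <- R; f_axis <- "y"; f_start <- row0
  }

  used <- baseline$used
  rel_row <- rel_col <- rep(NA_integer_, n)
  set_cell <- function(i, line, pos) {
    # `line` indexes along the baseline axis, `pos` along the fill axis
    if (b_axis == "y") { rel_row[i] <<- line; rel_col[i] <<- pos }
    else { rel_row[i] <<- pos; rel_col[i] <<- line }
  }
  for (j in seq_along(baseline$idx))
    set_cell(baseline$idx[j], baseline$pos[j], f_start)

  # predicted baseline positions for lines with no baseline core
  b_along <- if (b_axis == "y") table$centroid_y else table$centroid_x
  b_perp <- if (b_axis == "y") table$centroid_x else table$centroid_y
  bp <- baseline$pos; bi <- baseline$idx
  slope <- if (length(bi) >= 2)
    unname(stats::coef(stats::lm(b_along[bi] ~ bp))[2]) else spacing
  icept <- stats::median(b_along[bi] - slope * bp)
  perp0 <- stats::median(b_perp[bi])

  for (line in seq_len(b_len)) {
    j <- match(line, baseline$pos)
    if (!is.na(j)) {
      i <- baseline$idx[j]
      px <- table$centroid_x[i]; py <- table$centroid_y[i]
    } else {
      along_pred <- icept + slope * line
      if (b_axis == "y") { px <- perp0; py <- along_pred }
      else { px <- along_pred; py <- perp0 }
      # a core may sit at the virtual baseline cell itself
      d2 <- (table$centroid_x - px)^2 + (table$centroid_y - py)^2
      near <- which(!used & d2 <= (dp$col_tolerance * spacing)^2)
      if (length(near) > 0) {
        i <- near[which.min(d2[near])]
        used[i] <- TRUE
        set_cell(i, line, f_start)
        px <- table$centroid_x[i]; py <- table$centroid_y[i]
      }
    }
    fwd <- .walk_line(table, used, px, py, f_axis, +1L, f_len - f_start,
                      spacing, dp)
    bwd <- .walk_line(table, fwd$used, px, py, f_axis, -1L, f_start - 1L,
                      spacing, dp)
    used <- bwd$used
    for (j2 in seq_along(fwd$idx))
      set_cell(fwd$idx[j2], line, f_start + fwd$pos[j2])
    for (j2 in seq_along(bwd$idx))
      set_cell(bwd$idx[j2], line, f_start - bwd$pos[j2])
  }

  # rescue pass: cores the line walks missed (e.g. lines entered from an
  # extrapolated virtual start) are matched to the lattice fitted through
  # everything assigned so far, under the same perpendicular tolerance
  unass <- which(is.na(rel_row))
  assigned <- which(!is.na(rel_row))
  if (length(unass) > 0 &&
      length(unique(rel_row[assigned])) >= 2 &&
      length(unique(rel_col[assigned])) >= 2) {
    fy <- stats::lm(table$centroid_y[assigned] ~ rel_row[assigned])
    fx <- stats::lm(table$centroid_x[assigned] ~ rel_col[assigned])
    ay <- stats::coef(fy)[1]; by <- stats::coef(fy)[2]
    ax <- stats::coef(fx)[1]; bx <- stats::coef(fx)[2]
    taken <- paste(rel_row[assigned], rel_col[assigned])
    for (i in unass) {
      r_hat <- as.integer(round((table$centroid_y[i] - ay) / by))
      c_hat <- as.integer(round((table$centroid_x[i] - ax) / bx))
      if (r_hat < 1 || r_hat > R || c_hat < 1 || c_hat > C) next
      if (paste(r_hat, c_hat) %in% taken) next
      tol <- dp$col_tolerance * spacing
      if (abs(table$centroid_y[i] - (ay + by * r_hat)) > tol ||
          abs(table$centroid_x[i] - (ax + bx * c_hat)) > tol) next
      rel_row[i] <- r_hat; rel_col[i] <- c_hat
      taken <- c(taken, paste(r_hat, c_hat))
    }
  }
  if (anyNA(rel_row))
    warning(sum(is.na(rel_row)),
            " detected core(s) could not be assigned to a grid cell")

  table$assigned_row <- rel_row
  table$assigned_col <- rel_col
  .new_tma_grid(table, R, C, spacing)
}

.new_tma_grid <- function(table, R, C, spacing, inverted = FALSE) {
  m <- matrix(NA_integer_, nrow = R, ncol = C)
  ok <- which(!is.na(table$assigned_row))
  for (i in ok) {
    r <- table$assigned_row[i]; c <- table$assigned_col[i]
    if (!is.na(m[r, c]))
      stop(sprintf("two cores assigned to grid cell (%d, %d)", r, c))
    m[r, c] <- i
  }
  structure(list(centroids = table, matrix = m,
                 grid_rows = R, grid_cols = C,
                 spacing = spacing, inverted = inverted),
            class = "tma_grid")
}

#' @export
print.tma_grid <- function(x, ...) {
  n_assigned <- sum(!is.na(x$centroids$assigned_row))
  cat(sprintf("TMA grid %d x %d: %d detected core(s), %d assigned%s\n",
              x$grid_rows, x$grid_cols, nrow(x$centroids), n_assigned,
              if (x$inverted) " (labels inverted)" else ""))
  invisible(x)
}

#' Invert TMA grid labels
#'
#' Relabels row r as \code{grid_rows + 1 - r} and column c as
#' \code{grid_cols + 1 - c}, for arrays scanned in the orientation opposite
#' to the pathologist's numbering convention. Applying the inversion twice
#' restores the original labels.
#'
#' @param grid A \code{tma_grid} from [assemble_grid()].
#' @return The relabeled \code{tma_grid}.
#' @export
invert_grid_labels <- function(grid) {
  stopifnot(inherits(grid, "tma_grid"))
  tab <- grid$centroids
  tab$assigned_row <- grid$grid_rows + 1L - tab$assigned_row
  tab$assigned_col <- grid$grid_cols + 1L - tab$assigned_col
  .new_tma_grid(tab, grid$grid_rows, grid$grid_cols, grid$spacing,
                inverted = !grid$inverted)
}

#' Scale thumbnail centroids to full-resolution coordinates
#'
#' Multiplies each centroid by the per-axis ratio of the full image size to
#' the thumbnail size and rounds to the nearest pixel (round-half-even). The
#' two rasters must be the same scene: their aspect ratios must agree within
#' 1 percent.
#'
#' @param table A data.frame with \code{centroid_x}, \code{centroid_y}.
#' @param thumb_shape,full_shape Integer \code{c(height, width)} of the two
#'   rasters.
#' @return The table with added \code{centroid_full_x},
#'   \code{centroid_full_y} columns.
#' @examples
#' tab <- data.frame(centroid_x = 100, centroid_y = 200)
#' scale_centroids(tab, c(800, 1000), c(3200, 4000))
#' @export
scale_centroids <- function(table, thumb_shape, full_shape) {
  stopifnot(length(thumb_shape) == 2, length(full_shape) == 2,
            all(thumb_shape >= 1), all(full_shape >= 1))
  fy <- full_shape[1] / thumb_shape[1]
  fx <- full_shape[2] / thumb_shape[2]
  if (abs(fy / fx - 1) > 0.01)
    stop(sprintf(
      paste0("aspect-ratio mismatch: vertical scale %.4f vs horizontal ",
             "%.4f; the rasters are not the same scene"), fy, fx))
  table$centroid_full_x <- round(table$centroid_x * fx)
  table$centroid_full_y <- round(table$centroid_y * fy)
  table
}

#' Score one TMA core on the full-resolution image
#'
#' Quantifies the square window of side \code{window_side} centred on the
#' core's full-resolution centroid, clipped to the image bounds. The default
#' window side in the [dearray_tma()] pipeline is the estimated inter-core
#' spacing scaled to full resolution, so neighbouring windows abut without
#' overlapping.
#'
#' @param full An H x W x 3 RGB array at full resolution.
#' @param cx,cy Full-resolution centroid of the core.
#' @param window_side Window side length in pixels.
#' @param params A [pixel_class_params()] object.
#' @return A [stain_quant] for the window. If the window contains no sample
#'   pixels the stain fraction is NA and a warning is raised.
#' @export
score_core <- function(full, cx, cy, window_side,
                       params = pixel_class_params()) {
  .check_rgb_image(full)
  h <- dim(full)[1]; w <- dim(full)[2]
  half <- floor(window_side / 2)
  x0 <- max(1L, as.integer(round(cx)) - half)
  x1 <- min(w, as.integer(round(cx)) + half)
  y0 <- max(1L, as.integer(round(cy)) - half)
  y1 <- min(h, as.integer(round(cy)) + half)
  q <- classify_image(full[y0:y1, x0:x1, , drop = FALSE], params)$quant
  if (q$sample_pixels == 0)
    warning(sprintf("window at (%g, %g) contains no sample pixels", cx, cy))
  q
}

#' Join pathologist annotations onto scored cores
#'
#' Matches each core record to the annotation table on (row, col). Records
#' with no matching annotation keep a missing Gleason score (with a
#' warning); annotation rows matching no detected core are reported.
#'
#' @param records A data.frame of core records with \code{row}, \code{col}.
#' @param annot A data.frame with columns \code{row}, \code{col},
#'   \code{gleason}; (row, col) pairs must be unique.
#' @return \code{records} with a \code{gleason} column.
#' @export
join_annotations <- function(records, annot) {
  stopifnot(all(c("row", "col") %in% names(records)),
            all(c("row", "col", "gleason") %in% names(annot)))
  if (anyDuplicated(annot[, c("row", "col")]))
    stop("duplicate (row, col) pairs in the annotation table")
  key_rec <- paste(records$row, records$col, sep = ":")
  key_ann <- paste(annot$row, annot$col, sep = ":")
  records$gleason <- annot$gleason[match(key_rec, key_ann)]
  n_unmatched <- sum(is.na(records$gleason))
  if (n_unmatched > 0)
    warning(n_unmatched, " core(s) have no annotation; Gleason left missing")
  orphan <- setdiff(key_ann, key_rec)
  if (length(orphan) > 0)
    message("annotation rows with no detected core: ",
            paste(orphan, collapse = ", "))
  records
}

#' Export scored core records to CSV
#'
#' Writes one row per core in row-major grid order with columns
#' \code{centroid_x}, \code{centroid_y}, \code{row}, \code{col},
#' \code{gleason}, \code{percent_stained} (100 times the stain fraction).
#' An undefined stain fraction is written as an empty cell, never as 0.
#'
#' @param records A data.frame of scored core records.
#' @param path Output CSV path.
#' @return The exported data.frame, invisibly.
#' @export
export_results <- function(records, path) {
  cols <- c("centroid_x", "centroid_y", "row", "col", "gleason",
            "percent_stained")
  if (!"gleason" %in% names(records)) records$gleason <- NA_integer_
  if (!"percent_stained" %in% names(records))
    records$percent_stained <- 100 * records$stain_fraction
  out <- records[order(records$row, records$col), cols, drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(out)
}

#' Run the full TMA de-arraying and scoring pipeline
#'
#' Detects cores on the thumbnail, assigns them to the declared design grid,
#' optionally inverts the labels, scales centroids to the full-resolution
#' image, scores every assigned core, and joins annotations when provided.
#'
#' @param thumb,full RGB arrays of the same scene at thumbnail and full
#'   resolution (or file paths readable by [read_image()]).
#' @param dp A [dearray_params()] object.
#' @param params A [pixel_class_params()] object.
#' @param annotations Optional annotation data.frame (or CSV path) with
#'   columns \code{row}, \code{col}, \code{gleason}.
#' @param window_side Scoring window side at full resolution; default is
#'   the estimated spacing scaled to full resolution.
#' @return A data.frame of core records: thumbnail and full-resolution
#'   centroids, \code{row}, \code{col}, tallies, \code{stain_fraction},
#'   \code{percent_stained}, and \code{gleason} when annotated.
#' @export
dearray_tma <- function(thumb, full, dp, params = pixel_class_params(),
                        annotations = NULL, window_side = NULL) {
  if (is.character(thumb)) thumb <- read_image(thumb)
  if (is.character(full)) full <- read_image(full)
  blobs <- detect_cores(thumb, params, dp)
  grid <- assemble_grid(centroid_table(blobs), dp)
  if (dp$invert_labels) grid <- invert_grid_labels(grid)

  tab <- grid$centroids
  tab <- scale_centroids(tab, dim(thumb)[1:2], dim(full)[1:2])
  fx <- dim(full)[2] / dim(thumb)[2]
  if (is.null(window_side))
    window_side <- max(3L, as.integer(round(grid$spacing * fx)))

  tab <- tab[!is.na(tab$assigned_row), , drop = FALSE]
  if (nrow(tab) == 0) stop("no cores were assigned to the grid")

  recs <- lapply(seq_len(nrow(tab)), function(i) {
    q <- score_core(full, tab$centroid_full_x[i], tab$centroid_full_y[i],
                    window_side, params)
    data.frame(centroid_x = tab$centroid_x[i],
               centroid_y = tab$centroid_y[i],
               centroid_full_x = tab$centroid_full_x[i],
               centroid_full_y = tab$centroid_full_y[i],
               row = tab$assigned_row[i], col = tab$assigned_col[i],
               total_pixels = q$total_pixels,
               sample_pixels = q$sample_pixels,
               stained_pixels = q$stained_pixels,
               stain_fraction = q$stain_fraction,
               percent_stained = 100 * q$stain_fraction)
  })
  records <- do.call(rbind, recs)
  records <- records[order(records$row, records$col), , drop = FALSE]
  rownames(records) <- NULL
  if (!is.null(annotations)) {
    if (is.character(annotations))
      annotations <- utils::read.csv(annotations)
    records <- join_annotations(records, annotations)
  }
  records
}
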