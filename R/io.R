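# Raster and table I/O plus batch orchestration.

#' Read an RGB image as an 8-bit array
#'
#' Reads PNG or TIFF rasters into the H x W x 3 integer array used
#' throughout the package. Grayscale images are promoted to three identical
#' channels and an alpha channel is dropped, each with a warning; inputs
#' with more than 8 bits per channel are rescaled to 0..255 with a warning.
#'
#' @param path Path to a \code{.png}, \code{.tif} or \code{.tiff} file.
#' @return An H x W x 3 integer array with values in [0, 255]. The image
#'   dimensions are attached as attribute \code{shape}.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext,
         "': supported formats are PNG and TIFF")
  )
  if (length(dim(raw)) == 2) {
    warning("grayscale image promoted to 3 identical channels: ", path)
    raw <- array(rep(raw, 3), dim = c(dim(raw), 3))
  }
  if (dim(raw)[3] == 2) {
    warning("gray+alpha image: alpha dropped, gray promoted: ", path)
    raw <- array(rep(raw[, , 1], 3), dim = c(dim(raw)[1:2], 3))
  }
  if (dim(raw)[3] == 4) {
    warning("alpha channel dropped: ", path)
    raw <- raw[, , 1:3, drop = FALSE]
  }
  # readPNG/readTIFF return intensities in [0, 1] regardless of bit depth
  img <- array(as.integer(round(raw * 255)), dim = dim(raw))
  attr(img, "shape") <- dim(img)[1:2]
  img
}

#' Write an RGB array to a PNG or TIFF file
#'
#' @param img An H x W x 3 array with values in [0, 255].
#' @param path Output path ending in \code{.png}, \code{.tif} or
#'   \code{.tiff}.
#' @return \code{path}, invisibly.
#' @export
write_image <- function(img, path) {
  .check_rgb_image(img)
  ext <- tolower(tools::file_ext(path))
  scaled <- img / 255
  switch(ext,
    png = png::writePNG(scaled, path),
    tif = ,
    tiff = tiff::writeTIFF(scaled, path),
    stop("unsupported image format '.", ext, "'")
  )
  invisible(path)
}

#' Quantify every image in a directory
#'
#' Runs [quantify_whole_block()] (which equals a single-pass [quantify_roi()]
#' tally for tally) on each PNG/TIFF image found and returns one row per
#' image, sorted by file name so that directory listing order cannot change
#' the result.
#'
#' @param dir Directory containing the images, or a character vector of
#'   image paths.
#' @param params A [pixel_class_params()] object.
#' @param cfg A [tile_config()] object.
#' @param csv Optional path; when given, the table is also written as CSV.
#' @return A data.frame with columns \code{image_id}, \code{total_pixels},
#'   \code{sample_pixels}, \code{stained_pixels}, \code{stain_fraction}.
#' @export
quantify_batch <- function(dir, params = pixel_class_params(),
                           cfg = tile_config(), csv = NULL) {
  paths <- if (length(dir) == 1 && dir.exists(dir))
    list.files(dir, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
               full.names = TRUE)
  else dir
  if (length(paths) == 0) stop("no PNG/TIFF images found in ", dir)
  paths <- paths[order(basename(paths))]
  rows <- lapply(paths, function(p) {
    q <- quantify_whole_block(read_image(p), params, cfg)
    data.frame(image_id = basename(p),
               total_pixels = q$total_pixels,
               sample_pixels = q$sample_pixels,
               stained_pixels = q$stained_pixels,
               stain_fraction = q$stain_fraction)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE, na = "")
  out
}

#' Join two per-sample stain tables into marker pairs
#'
#' Joins the Ki-67 and CD31 quantification tables of the same samples on
#' \code{sample_id}, producing the input expected by [marker_summary()] and
#' [compare_markers()]. Samples present in only one table are dropped with
#' a warning; samples with an undefined or zero CD31 fraction are excluded
#' with a message, since their PVI is undefined.
#'
#' @param ki67,cd31 Data.frames with columns \code{sample_id} and
#'   \code{stain_fraction}.
#' @param gleason Optional data.frame with columns \code{sample_id},
#'   \code{gleason} to annotate the pairs.
#' @return A data.frame with columns \code{sample_id}, \code{ki67_fraction},
#'   \code{cd31_fraction} and, when annotated, \code{gleason}.
#' @export
join_marker_tables <- function(ki67, cd31, gleason = NULL) {
  stopifnot(all(c("sample_id", "stain_fraction") %in% names(ki67)),
            all(c("sample_id", "stain_fraction") %in% names(cd31)))
  common <- intersect(ki67$sample_id, cd31$sample_id)
  dropped <- length(unique(c(ki67$sample_id, cd31$sample_id))) -
    length(common)
  if (dropped > 0)
    warning(dropped, " sample(s) present in only one marker table dropped")
  out <- data.frame(
    sample_id = common,
    ki67_fraction = ki67$stain_fraction[match(common, ki67$sample_id)],
    cd31_fraction = cd31$stain_fraction[match(common, cd31$sample_id)],
    stringsAsFactors = FALSE)
  bad <- is.na(out$cd31_fraction) | out$cd31_fraction == 0 |
    is.na(out$ki67_fraction)
  if (any(bad)) {
    message(sum(bad), " sample(s) excluded: undefined fraction or zero ",
            "CD31 denominator (", paste(out$sample_id[bad], collapse = ", "),
            ")")
    out <- out[!bad, , drop = FALSE]
  }
  if (!is.null(gleason)) {
    stopifnot(all(c("sample_id", "gleason") %in% names(gleason)))
    out$gleason <- gleason$gleason[match(out$sample_id, gleason$sample_id)]
  }
  rownames(out) <- NULL
  out
}
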