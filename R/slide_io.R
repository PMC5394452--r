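#' Slide, mask and heatmap containers and raster IO
#'
#' A slide is an 8-bit RGB raster plus its physical resolution in microns
#' per pixel (mpp); the mpp travels in a JSON sidecar next to the raster so
#' every later stage (tiling at a fixed physical size, evaluation at a fixed
#' analysis resolution) can reason in physical units. At 40x magnification
#' Aperio scanners deliver 0.25 um/pixel and Ventana 0.23 um/pixel; the
#' analysis resolution used throughout this package is 4 um/pixel.
#'
#' @name slide_io
NULL

#' Construct a slide image object
#'
#' @param pixels numeric array `height x width x 3`, values in `[0, 255]`.
#' @param mpp physical resolution in microns per pixel (> 0).
#' @param slide_id identifier string.
#' @return An object of class `slide_image` with fields `pixels`, `mpp`,
#'   `slide_id`.
#' @export
slide_image <- function(pixels, mpp, slide_id = "slide") {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop_wsi("pixels must be a height x width x 3 array", class = "format_error")
  if (!is.numeric(mpp) || length(mpp) != 1L || !is.finite(mpp) || mpp <= 0)
    stop_wsi("mpp must be a single positive number", class = "metadata_error")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop_wsi("pixel values must lie in [0, 255]", class = "format_error")
  structure(list(slide_id = as.character(slide_id),
                 pixels = pixels, mpp = as.numeric(mpp)),
            class = "slide_image")
}

#' @export
print.slide_image <- function(x, ...) {
  cat(sprintf("<slide_image '%s'> %d x %d px @ %.3g um/pixel (%.2f x %.2f mm)\n",
              x$slide_id, slide_width(x), slide_height(x), x$mpp,
              slide_width(x) * x$mpp / 1000, slide_height(x) * x$mpp / 1000))
  invisible(x)
}

#' @export
dim.slide_image <- function(x) dim(x$pixels)[1:2]

#' Slide pixel dimensions
#' @param slide a `slide_image`.
#' @return Width / height in pixels.
#' @export
slide_width <- function(slide) dim(slide$pixels)[2]

#' @rdname slide_width
#' @export
slide_height <- function(slide) dim(slide$pixels)[1]

#' Construct a binary annotation mask
#'
#' Masks are binary rasters aligned to a slide at a stated resolution:
#' 1 marks invasive tumor (or tissue, for tissue masks), 0 everything else.
#'
#' @param pixels numeric or logical matrix; any nonzero value maps to 1.
#' @param mpp resolution of the mask grid in microns per pixel.
#' @param slide_id identifier string.
#' @return An object of class `annotation_mask`.
#' @export
annotation_mask <- function(pixels, mpp, slide_id = "slide") {
  if (is.null(dim(pixels)) || length(dim(pixels)) != 2L)
    stop_wsi("mask pixels must be a matrix", class = "format_error")
  if (!is.numeric(mpp) || mpp <= 0)
    stop_wsi("mpp must be positive", class = "metadata_error")
  m <- matrix(as.integer(pixels != 0), nrow = nrow(pixels))
  structure(list(slide_id = as.character(slide_id), pixels = m,
                 mpp = as.numeric(mpp)),
            class = "annotation_mask")
}

#' @export
print.annotation_mask <- function(x, ...) {
  cat(sprintf("<annotation_mask '%s'> %d x %d px @ %.3g um/pixel, %d positive (%.1f%%)\n",
              x$slide_id, ncol(x$pixels), nrow(x$pixels), x$mpp,
              sum(x$pixels), 100 * mean(x$pixels)))
  invisible(x)
}

#' @export
dim.annotation_mask <- function(x) dim(x$pixels)

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read a slide raster with its metadata sidecar
#'
#' @param path PNG or TIFF file with 8-bit RGB pixels.
#' @param metadata_path JSON sidecar holding `slide_id` and `mpp`; defaults
#'   to the raster path with a `.json` extension.
#' @return A [slide_image()].
#' @export
read_slide <- function(path, metadata_path = sidecar_path(path)) {
  if (!file.exists(path))
    stop_wsi("slide raster not found: ", path, class = "format_error")
  if (!file.exists(metadata_path))
    stop_wsi("metadata sidecar not found: ", metadata_path, class = "metadata_error")
  meta <- jsonlite::read_json(metadata_path)
  if (is.null(meta$mpp) || !is.numeric(meta$mpp) || meta$mpp <= 0)
    stop_wsi("sidecar must declare a positive numeric 'mpp'", class = "metadata_error")
  px <- read_raster(path)
  if (length(dim(px)) == 2L) px <- array(px, c(dim(px), 3L))  # grayscale promoted
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]        # drop alpha
  slide_image(round(px * 255), mpp = meta$mpp,
              slide_id = meta$slide_id %||% tools::file_path_sans_ext(basename(path)))
}

read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_wsi("unsupported raster format: .", ext, class = "format_error"))
  px
}

#' Write a slide raster and its metadata sidecar
#'
#' @param slide a [slide_image()].
#' @param path output PNG path.
#' @param metadata_path JSON sidecar path.
#' @return `path`, invisibly.
#' @export
write_slide <- function(slide, path, metadata_path = sidecar_path(path)) {
  stopifnot(inherits(slide, "slide_image"))
  png::writePNG(slide$pixels / 255, target = path)
  jsonlite::write_json(list(slide_id = slide$slide_id, mpp = slide$mpp),
                       metadata_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a binary mask raster
#'
#' Any nonzero pixel becomes 1. When `expected_dims` is given the mask
#' dimensions are checked against it so misaligned ground truth fails fast.
#'
#' @param path PNG mask file.
#' @param expected_dims optional `c(height, width)` in pixels.
#' @param mpp resolution of the mask grid (microns per pixel).
#' @param slide_id identifier; defaults to the file stem.
#' @return An [annotation_mask()].
#' @export
read_mask <- function(path, expected_dims = NULL, mpp = 4,
                      slide_id = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path))
    stop_wsi("mask raster not found: ", path, class = "format_error")
  px <- read_raster(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  if (!is.null(expected_dims) && !identical(dim(px), as.integer(expected_dims)))
    stop_wsi(sprintf("mask dims %d x %d do not match expected %d x %d",
                     nrow(px), ncol(px), expected_dims[1], expected_dims[2]),
             class = "alignment_error")
  annotation_mask(px != 0, mpp = mpp, slide_id = slide_id)
}

#' @rdname read_mask
#' @param mask an [annotation_mask()] to persist (8-bit grayscale PNG, 0/255).
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "annotation_mask"))
  png::writePNG(mask$pixels * 1.0, target = path)
  invisible(path)
}

#' Persist a probability map as a 16-bit grayscale raster
#'
#' 16-bit depth keeps the quantization step (1/65535) far below any
#' operating threshold of interest, so thresholding a written-then-read
#' map gives the same binary mask as thresholding the original.
#'
#' @param map a [probability_map()] with values in `[0, 1]`.
#' @param path output TIFF path (16-bit grayscale).
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(map, path) {
  stopifnot(inherits(map, "probability_map"))
  v <- map$values
  if (anyNA(v) || min(v) < 0 || max(v) > 1)
    stop_wsi("probability values must lie in [0, 1]", class = "validation_error")
  tiff::writeTIFF(v, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_heatmap
#' @param mpp resolution to attach on read-back.
#' @param slide_id identifier for the read-back map.
#' @export
read_heatmap <- function(path, mpp = 4,
                         slide_id = tools::file_path_sans_ext(basename(path))) {
  v <- tiff::readTIFF(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  probability_map(v, mpp = mpp, slide_id = slide_id)
}
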