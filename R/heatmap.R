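#' Probability maps: stitching and thresholding
#'
#' Tile probabilities are stitched into a slide-level probability map at
#' the evaluation resolution (4 um/pixel by default): every pixel inside a
#' tile footprint takes that tile's invasive probability, and pixels
#' outside any tile (glass background, rejected or edge-dropped tiles)
#' take probability 0 — the prior that there is no tumor outside tissue.
#' Thresholding the map (inclusive, default 0.5) yields the binary
#' invasive-region prediction used by the pixel-wise evaluation.
#'
#' @name heatmap
NULL

#' Construct a probability map
#'
#' @param values numeric matrix with entries in `[0, 1]`.
#' @param mpp resolution of the map grid in microns per pixel.
#' @param slide_id identifier string.
#' @return An object of class `probability_map`.
#' @export
probability_map <- function(values, mpp, slide_id = "slide") {
  if (is.null(dim(values)) || length(dim(values)) != 2L)
    stop_wsi("values must be a matrix", class = "format_error")
  if (anyNA(values) || min(values) < 0 || max(values) > 1)
    stop_wsi("probabilities must lie in [0, 1]", class = "validation_error")
  structure(list(slide_id = as.character(slide_id),
                 values = values, mpp = as.numeric(mpp)),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map '%s'> %d x %d px @ %.3g um/pixel, range [%.3f, %.3f]\n",
              x$slide_id, ncol(x$values), nrow(x$values), x$mpp,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.probability_map <- function(x) dim(x$values)

#' Stitch per-tile probabilities into a slide probability map
#'
#' @param tile_probs numeric vector, one invasive probability per tile of
#'   `tiles`, each in `[0, 1]`.
#' @param tiles a `tile_set` (non-overlapping by construction).
#' @param slide_dims optional `c(height, width)`; defaults to the slide
#'   dimensions recorded on the tile set.
#' @return A [probability_map()] at the tile set's resolution.
#' @export
stitch_probability_map <- function(tile_probs, tiles,
                                   slide_dims = attr(tiles, "slide_dims")) {
  stopifnot(inherits(tiles, "tile_set"))
  if (length(tile_probs) != nrow(tiles))
    stop_wsi("need exactly one probability per tile", class = "validation_error")
  if (length(tile_probs) && (anyNA(tile_probs) ||
      min(tile_probs) < 0 || max(tile_probs) > 1))
    stop_wsi("tile probabilities must lie in [0, 1]", class = "validation_error")
  v <- matrix(0, nrow = slide_dims[1], ncol = slide_dims[2])
  side <- if (nrow(tiles)) tiles$side_px[1] else 0L
  for (i in seq_len(nrow(tiles)))
    v[tiles$y[i] + seq_len(side), tiles$x[i] + seq_len(side)] <- tile_probs[i]
  probability_map(v, mpp = attr(tiles, "mpp"), slide_id = attr(tiles, "slide_id"))
}

#' Threshold a probability map into a binary prediction
#'
#' A pixel is called positive when its probability is greater than or
#' equal to `threshold` (inclusive rule, so `binarize_map` at 0.5 agrees
#' with the per-tile argmax of the two-class output).
#'
#' @param map a [probability_map()].
#' @param threshold operating threshold in `[0, 1]`, default 0.5.
#' @return An [annotation_mask()] aligned to the map.
#' @export
binarize_map <- function(map, threshold = 0.5) {
  stopifnot(inherits(map, "probability_map"))
  if (threshold < 0 || threshold > 1)
    stop_wsi("threshold must lie in [0, 1]", class = "validation_error")
  annotation_mask(map$values >= threshold, mpp = map$mpp, slide_id = map$slide_id)
}
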