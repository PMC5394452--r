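#' Physical-scale tile sampling
#'
#' Tiles are square tissue regions of fixed physical size (200 x 200 um by
#' default) sampled on a rectangular, non-overlapping grid. Tiles whose
#' footprint holds too little tissue are rejected, and partial tiles at the
#' slide edge are dropped so every tile presents the classifier with the
#' same geometry. Ground-truth labels follow the 80%-overlap rule: a tile is
#' a positive (invasive) example only when at least 80% of its pixels fall
#' inside the annotated invasive region.
#'
#' @name tiling
NULL

#' Segment tissue from slide background
#'
#' Glass background on an H&E slide is near-white; tissue is stained. A
#' pixel is called tissue when its HSV saturation exceeds `sat_min` or its
#' brightness falls below `val_max` (catching darkly stained but
#' low-saturation pixels such as dense hematoxylin).
#'
#' @param slide a [slide_image()].
#' @param sat_min saturation threshold (default 0.05).
#' @param val_max brightness threshold (default 0.85).
#' @return An [annotation_mask()] with 1 = tissue, aligned to the slide.
#' @export
segment_tissue <- function(slide, sat_min = 0.05, val_max = 0.85) {
  stopifnot(inherits(slide, "slide_image"))
  d <- dim(slide$pixels)
  rgb <- matrix(aperm(slide$pixels, c(3, 1, 2)), nrow = 3)
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  tissue <- hsv[2, ] > sat_min | hsv[3, ] < val_max
  annotation_mask(matrix(tissue, nrow = d[1], ncol = d[2]),
                  mpp = slide$mpp, slide_id = slide$slide_id)
}

new_tile_set <- function(df, slide_id, tile_side_um, mpp, slide_dims) {
  structure(df, class = c("tile_set", "data.frame"),
            slide_id = slide_id, tile_side_um = tile_side_um,
            mpp = mpp, slide_dims = slide_dims)
}

#' Compute the rectangular tile grid of a slide
#'
#' The tile side in pixels is `round(tile_side_um / mpp)` (half-up); the
#' grid stride equals the side, so tiles never overlap. Coordinates are
#' 0-based with origin at the top-left; `x` runs along columns, `y` along
#' rows. Tiles with tissue fraction below `min_tissue_frac` are removed;
#' partial edge tiles are dropped rather than padded.
#'
#' @param slide a [slide_image()].
#' @param tile_side_um physical tile side, default 200 um.
#' @param tissue tissue [annotation_mask()] from [segment_tissue()]; `NULL`
#'   treats the whole slide as tissue.
#' @param min_tissue_frac minimum tissue fraction to keep a tile (default 0.5).
#' @return A `tile_set`: a data frame with one row per kept tile
#'   (`slide_id, row, col, x, y, side_px, label, tissue_frac`), row-major
#'   order, plus grid metadata in attributes.
#' @export
compute_tile_grid <- function(slide, tile_side_um = 200, tissue = NULL,
                              min_tissue_frac = 0.5) {
  stopifnot(inherits(slide, "slide_image"))
  if (min_tissue_frac < 0 || min_tissue_frac > 1)
    stop_wsi("min_tissue_frac must lie in [0, 1]", class = "configuration_error")
  side <- as.integer(round_half_up(tile_side_um / slide$mpp))
  if (side < 1L)
    stop_wsi("tile side is below one pixel at this resolution",
             class = "configuration_error")
  h <- slide_height(slide); w <- slide_width(slide)
  n_rows <- h %/% side; n_cols <- w %/% side
  if (n_rows < 1L || n_cols < 1L) {
    df <- data.frame(slide_id = character(), row = integer(), col = integer(),
                     x = integer(), y = integer(), side_px = integer(),
                     label = character(), tissue_frac = numeric())
    return(new_tile_set(df, slide$slide_id, tile_side_um, slide$mpp, c(h, w)))
  }
  grid <- expand.grid(col = seq_len(n_cols) - 1L, row = seq_len(n_rows) - 1L)
  grid <- grid[order(grid$row, grid$col), ]  # row-major
  x <- grid$col * side; y <- grid$row * side
  if (is.null(tissue)) {
    frac <- rep(1, nrow(grid))
  } else {
    if (!isTRUE(all.equal(tissue$mpp, slide$mpp)) ||
        !identical(dim(tissue$pixels), c(h, w)))
      stop_wsi("tissue mask is not aligned to the slide", class = "alignment_error")
    frac <- window_fractions(tissue$pixels, y, x, side)
  }
  keep <- frac >= min_tissue_frac
  df <- data.frame(slide_id = rep(slide$slide_id, nrow(grid)),
                   row = grid$row, col = grid$col,
                   x = x, y = y, side_px = rep(side, nrow(grid)),
                   label = rep("unlabeled", nrow(grid)), tissue_frac = frac,
                   stringsAsFactors = FALSE)[keep, ]
  rownames(df) <- NULL
  new_tile_set(df, slide$slide_id, tile_side_um, slide$mpp, c(h, w))
}

# Mean of a binary matrix over square windows, via a summed-area table.
window_fractions <- function(mask, y, x, side) {
  sat <- rbind(0, cbind(0, apply(apply(mask, 2, cumsum), 1, cumsum)))
  # sat is transposed by the second apply: sat[j, i] = sum of mask[1:i-1, 1:j-1]
  y0 <- y + 1L; x0 <- x + 1L; y1 <- y + side + 1L; x1 <- x + side + 1L
  s <- sat[cbind(x1, y1)] - sat[cbind(x0, y1)] -
       sat[cbind(x1, y0)] + sat[cbind(x0, y0)]
  s / (side * side)
}

#' @export
`[.tile_set` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out))
    out <- new_tile_set(out, attr(x, "slide_id"), attr(x, "tile_side_um"),
                        attr(x, "mpp"), attr(x, "slide_dims"))
  out
}

#' @export
print.tile_set <- function(x, ...) {
  cat(sprintf("<tile_set '%s'> %d tiles of %g um (%d px) at %.3g um/pixel; labels: %s\n",
              attr(x, "slide_id"), nrow(x), attr(x, "tile_side_um"),
              if (nrow(x)) x$side_px[1] else NA_integer_, attr(x, "mpp"),
              paste(names(table(x$label)), table(x$label),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Label tiles by overlap with ground-truth annotations
#'
#' A tile is labeled positive when the fraction of its pixels lying inside
#' the annotated invasive region is at least `overlap_threshold`
#' (inclusive, default 0.8); otherwise negative. Only the `label` column is
#' modified.
#'
#' For assembling a training set, `negative_threshold` restricts negative
#' examples to tiles from genuinely non-invasive tissue regions: tiles
#' whose overlap lies strictly between `negative_threshold` and
#' `overlap_threshold` (mixed boundary tiles, neither an invasive nor a
#' non-invasive region) are marked `"unlabeled"` and excluded from
#' training pools.
#'
#' @param tiles a `tile_set` from [compute_tile_grid()].
#' @param gt ground-truth [annotation_mask()] aligned to the tile frame
#'   (same mpp and slide dimensions).
#' @param overlap_threshold minimum positive-pixel fraction, default 0.8.
#' @param negative_threshold maximum overlap for a negative example;
#'   `NULL` (default) labels every non-positive tile negative.
#' @return The tile set with `label` set to `"positive"`/`"negative"`
#'   (and possibly `"unlabeled"`).
#' @export
label_tiles <- function(tiles, gt, overlap_threshold = 0.8,
                        negative_threshold = NULL) {
  stopifnot(inherits(tiles, "tile_set"), inherits(gt, "annotation_mask"))
  dims <- attr(tiles, "slide_dims")
  if (!isTRUE(all.equal(gt$mpp, attr(tiles, "mpp"))) ||
      !identical(dim(gt$pixels), as.integer(dims)))
    stop_wsi("ground-truth mask is not aligned to the tile grid",
             class = "alignment_error")
  if (nrow(tiles) == 0L) return(tiles)
  frac <- window_fractions(gt$pixels, tiles$y, tiles$x, tiles$side_px[1])
  if (is.null(negative_threshold)) {
    tiles$label <- ifelse(frac >= overlap_threshold, "positive", "negative")
  } else {
    tiles$label <- ifelse(frac >= overlap_threshold, "positive",
                          ifelse(frac <= negative_threshold, "negative",
                                 "unlabeled"))
  }
  tiles
}

#' Read or write a tile set as CSV
#'
#' @param tiles a `tile_set`.
#' @param path CSV path.
#' @export
write_tile_set <- function(tiles, path) {
  write.csv(as.data.frame(tiles), path, row.names = FALSE)
  invisible(path)
}
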