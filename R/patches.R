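#' Patch extraction and positive-class augmentation
#'
#' A patch is the pixel content of one tile, resampled to the network input
#' size (50 x 50 px: a 200 um tile at the 4 um/pixel analysis resolution).
#' Patches are stored column-wise in a `D x n` matrix with
#' `D = side * side * 3` (row index fastest, then column, then channel),
#' the layout the C-level network code expects.
#'
#' @name patches
NULL

#' Extract tile patches from a slide
#'
#' Crops every tile of `tiles` out of `slide` and resamples it to
#' `out_side` pixels per side (bilinear) when the tile side differs.
#'
#' @param slide a [slide_image()].
#' @param tiles a `tile_set` aligned to the slide.
#' @param out_side network input side in pixels (default 50).
#' @return A `patch_set`: list with `x` (`D x n` matrix, RGB 0-255),
#'   `labels` (character vector), `side`, `tiles` (the tile data frame).
#' @export
extract_patches <- function(slide, tiles, out_side = 50L) {
  stopifnot(inherits(slide, "slide_image"), inherits(tiles, "tile_set"))
  n <- nrow(tiles)
  d <- as.integer(out_side)^2 * 3L
  x <- matrix(0, nrow = d, ncol = n)
  if (n > 0L) {
    side <- tiles$side_px[1]
    for (i in seq_len(n)) {
      p <- slide$pixels[tiles$y[i] + seq_len(side), tiles$x[i] + seq_len(side), ,
                        drop = FALSE]
      if (side != out_side)
        p <- EBImage::resize(p, w = out_side, h = out_side)
      x[, i] <- as.vector(p)
    }
  }
  structure(list(x = x, labels = tiles$label, side = as.integer(out_side),
                 tiles = as.data.frame(tiles)),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches of %d x %d px (%s)\n",
              ncol(x$x), x$side, x$side,
              paste(names(table(x$labels)), table(x$labels),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

# The 8 orientations of the dihedral group of the square, applied to a
# side x side x 3 array: 4 right-angle rotations and their mirror images.
orient_patch <- function(a, k) {
  if (k > 4L) { a <- a[, rev(seq_len(dim(a)[2])), , drop = FALSE]; k <- k - 4L }
  for (i in seq_len(k - 1L))  # rotate 90 degrees clockwise (k-1) times
    a <- aperm(a, c(2, 1, 3))[, rev(seq_len(dim(a)[1])), , drop = FALSE]
  a
}

#' Augment the positive class by rotations and mirroring
#'
#' Every positive patch is replicated under the first `factor` orientations
#' of the dihedral group of the square (4 right-angle rotations plus their
#' mirror images; identity first), multiplying the positive count exactly
#' by `factor`. Negative and unlabeled patches pass through unchanged, in
#' their original order, followed by the augmented positives.
#'
#' @param patches a `patch_set`.
#' @param factor number of orientations per positive patch, 1-8 (default 8).
#' @return A `patch_set` with `factor` times as many positives.
#' @export
augment_positive_class <- function(patches, factor = 8L) {
  stopifnot(inherits(patches, "patch_set"))
  factor <- as.integer(factor)
  if (factor < 1L || factor > 8L)
    stop_wsi("augmentation factor must be between 1 and 8", class = "configuration_error")
  pos <- which(patches$labels == "positive")
  if (length(pos) == 0L || factor == 1L) return(patches)
  s <- patches$side
  neg <- setdiff(seq_along(patches$labels), pos)
  aug <- matrix(0, nrow = nrow(patches$x), ncol = length(pos) * factor)
  j <- 0L
  for (i in pos) {
    a <- array(patches$x[, i], c(s, s, 3L))
    for (k in seq_len(factor)) {
      j <- j + 1L
      aug[, j] <- as.vector(orient_patch(a, k))
    }
  }
  structure(list(x = cbind(patches$x[, neg, drop = FALSE], aug),
                 labels = c(patches$labels[neg], rep("positive", ncol(aug))),
                 side = s, tiles = NULL),
            class = "patch_set")
}

#' Convert a patch set to normalized YUV network input
#'
#' RGB patches are converted to YUV and standardized with frozen training
#' statistics; the result feeds [predict.convnet()] or [train_convnet()].
#'
#' @param patches a `patch_set` (RGB, 0-255).
#' @param stats a frozen [fit_normalization()] object.
#' @return The patch set with `x` replaced by normalized YUV values and a
#'   `normalized = TRUE` flag.
#' @export
normalize_patches <- function(patches, stats) {
  stopifnot(inherits(patches, "patch_set"))
  d <- nrow(patches$x)
  yuv <- patch_matrix_to_yuv(patches$x)
  hw <- d / 3L
  for (c in 1:3) {
    idx <- (c - 1L) * hw + seq_len(hw)
    yuv[idx, ] <- (yuv[idx, ] - stats$mean[c]) / stats$sd[c]
  }
  patches$x <- yuv
  patches$normalized <- TRUE
  patches
}

# D x n patch matrix (channel slowest) -> YUV in the same layout.
patch_matrix_to_yuv <- function(x) {
  hw <- nrow(x) / 3L
  r <- x[seq_len(hw), , drop = FALSE]
  g <- x[hw + seq_len(hw), , drop = FALSE]
  b <- x[2L * hw + seq_len(hw), , drop = FALSE]
  m <- .yuv_fwd
  rbind(m[1, 1] * r + m[1, 2] * g + m[1, 3] * b,
        m[2, 1] * r + m[2, 2] * g + m[2, 3] * b,
        m[3, 1] * r + m[3, 2] * g + m[3, 3] * b)
}

# Pool YUV pixels of a patch matrix into an n_pixels x 3 matrix for fitting.
patch_matrix_pixels <- function(x) {
  hw <- nrow(x) / 3L
  cbind(as.vector(x[seq_len(hw), ]),
        as.vector(x[hw + seq_len(hw), ]),
        as.vector(x[2L * hw + seq_len(hw), ]))
}
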