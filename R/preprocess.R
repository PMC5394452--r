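#' YUV conversion and channel standardization
#'
#' Tiles are converted from RGB to YUV before classification: luma (Y)
#' carries overall stain intensity while the two chroma channels (U, V)
#' separate the blue-purple hematoxylin axis from the pink eosin axis, so
#' the channels are far less correlated than R, G, B. Each channel is then
#' standardized to zero mean and unit variance with statistics fitted once
#' on the training tiles and frozen; tiles from new slides at inference
#' time are standardized with those same frozen statistics, never refit.
#'
#' @name preprocess
NULL

# BT.601 RGB -> YUV: Y = 0.299 R + 0.587 G + 0.114 B on the 0-255 scale,
# U = 0.492 (B - Y), V = 0.877 (R - Y). The difference form keeps the
# chroma rows exactly zero-sum, so achromatic pixels have U = V = 0.
.yuv_fwd <- local({
  y <- c(0.299, 0.587, 0.114)
  rbind(Y = y, U = 0.492 * (c(0, 0, 1) - y), V = 0.877 * (c(1, 0, 0) - y))
})
.yuv_inv <- solve(.yuv_fwd)

#' Convert between RGB and YUV color spaces
#'
#' Linear BT.601 transform: `Y = 0.299 R + 0.587 G + 0.114 B`, with U and V
#' the zero-centered blue- and red-difference chroma channels. The
#' transform is exactly invertible; [yuv_to_rgb()] applies the matrix
#' inverse (no clamping or rounding).
#'
#' @param x numeric array whose last dimension has length 3 (RGB triplets,
#'   0-255), or an `n x 3` matrix.
#' @return Array of the same shape in YUV (or RGB for the inverse).
#' @export
rgb_to_yuv <- function(x) apply_color_matrix(x, .yuv_fwd)

#' @rdname rgb_to_yuv
#' @export
yuv_to_rgb <- function(x) apply_color_matrix(x, .yuv_inv)

apply_color_matrix <- function(x, m) {
  d <- dim(x) %||% c(length(x) / 3, 3)
  nd <- length(d)
  if (d[nd] != 3L) stop_wsi("last dimension must have length 3", class = "format_error")
  flat <- matrix(x, ncol = 3L)  # column-major: channel is the slowest index
  out <- flat %*% t(m)
  array(out, dim = d)
}

#' Fit channel normalization statistics on training tiles
#'
#' Computes the per-channel mean and population standard deviation over all
#' pixels of all supplied YUV tiles. Standard deviations are clamped below
#' at `eps` so constant channels cannot produce division by zero. The
#' returned object is frozen: inference code applies it but never updates
#' it, which is the guard against train/test leakage.
#'
#' @param tiles a list of YUV arrays (`h x w x 3`), or a single such array,
#'   or an `n x 3`-column pixel matrix.
#' @param eps lower clamp for the standard deviations (default 1e-8).
#' @return An object of class `norm_stats`: `mean` and `sd` (length-3, named
#'   Y/U/V), `n_pixels`, and `frozen = TRUE`.
#' @export
fit_normalization <- function(tiles, eps = 1e-8) {
  if (is.list(tiles)) {
    if (length(tiles) == 0L) stop_wsi("no tiles to fit on", class = "fit_error")
    flat <- do.call(rbind, lapply(tiles, function(t) matrix(t, ncol = 3L)))
  } else if (!is.null(dim(tiles))) {
    flat <- matrix(tiles, ncol = 3L)
  } else {
    stop_wsi("no tiles to fit on", class = "fit_error")
  }
  if (nrow(flat) == 0L) stop_wsi("no pixels to fit on", class = "fit_error")
  mu <- colMeans(flat)
  # population (1/n) standard deviation: pixel counts are huge
  sdv <- sqrt(colMeans(sweep(flat, 2, mu)^2))
  sdv <- pmax(sdv, eps)
  structure(list(mean = setNames(mu, c("Y", "U", "V")),
                 sd = setNames(sdv, c("Y", "U", "V")),
                 n_pixels = nrow(flat), frozen = TRUE),
            class = "norm_stats")
}

#' @export
print.norm_stats <- function(x, ...) {
  cat(sprintf("<norm_stats> fitted on %d pixels (frozen)\n", x$n_pixels))
  print(rbind(mean = x$mean, sd = x$sd))
  invisible(x)
}

#' Standardize a YUV tile with frozen statistics
#'
#' Applies `(value - mean) / sd` per channel. Stateless and deterministic:
#' applying the same frozen statistics twice standardizes twice (there is
#' no silent idempotence), and the statistics object is never modified.
#'
#' @param tile YUV array (`h x w x 3`) or `n x 3` matrix.
#' @param stats a fitted [fit_normalization()] object.
#' @return Tile of the same shape, standardized per channel.
#' @export
apply_normalization <- function(tile, stats) {
  if (!inherits(stats, "norm_stats") || !isTRUE(stats$frozen))
    stop_wsi("stats must be a fitted, frozen norm_stats object", class = "usage_error")
  d <- dim(tile)
  flat <- matrix(tile, ncol = 3L)
  out <- sweep(sweep(flat, 2, stats$mean), 2, stats$sd, "/")
  array(out, dim = d)
}

#' Serialize normalization statistics to JSON
#'
#' @param stats a `norm_stats` object.
#' @param path JSON file path.
#' @export
write_norm_stats <- function(stats, path) {
  jsonlite::write_json(list(mean = stats$mean, sd = stats$sd,
                            n_pixels = stats$n_pixels),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_norm_stats
#' @export
read_norm_stats <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = setNames(as.numeric(j$mean), c("Y", "U", "V")),
                 sd = setNames(as.numeric(j$sd), c("Y", "U", "V")),
                 n_pixels = j$n_pixels, frozen = TRUE),
            class = "norm_stats")
}
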