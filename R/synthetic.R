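#' Synthetic H&E-like slides with known ground truth
#'
#' Generates seeded desk-scale stand-ins for scanned H&E slides: a white
#' glass background, a smooth random tissue region of pink stroma, and
#' invasive subregions rendered as dense clusters of dark-purple elliptical
#' "nuclei" over the stroma — the two texture classes a tile classifier
#' must separate. The invasive region is returned as an exact ground-truth
#' mask, so the whole pipeline (tiling, training, stitching, pixel-wise
#' evaluation) can be exercised without any real cohort. Optional artifacts
#' emulate two batch effects seen across scanners and labs: an eosin-heavy
#' stain shift and a dark air-bubble discoloration.
#'
#' @name synthetic
NULL

#' Parameters of the synthetic slide generator
#'
#' Defaults describe a 1000 x 800 px slide at the 4 um/pixel analysis
#' resolution (4 x 3.2 mm of tissue; 320 candidate 50 px tiles), with about
#' 55% of the slide covered by tissue and 30% of that tissue invasive.
#' Invasive texture uses at least 3x the stromal nuclear density and a
#' darker hematoxylin hue, which is the separation signal the classifier
#' learns.
#'
#' @param width_px,height_px slide dimensions in pixels.
#' @param mpp resolution in microns per pixel.
#' @param tissue_fraction target fraction of the slide that is tissue.
#' @param invasive_fraction target fraction of the tissue that is invasive.
#' @param nuclear_density_invasive,nuclear_density_stroma expected nucleus
#'   stamps per pixel in each texture class.
#' @param nuclear_radius_px range of nucleus semi-axes in pixels.
#' @param stroma_rgb,nucleus_stroma_rgb,nucleus_invasive_rgb stain colors.
#' @param invasive_base_rgb base tint of invasive stroma (extra
#'   hematoxylin uptake between nuclei).
#' @param noise_sd per-channel Gaussian texture noise, in 0-255 units.
#' @param eosin_shift,dark_bubble artifact flags.
#' @param seed integer; fully determines the slide.
#' @return A `synthetic_params` list.
#' @export
synthetic_params <- function(width_px = 1000L, height_px = 800L, mpp = 4,
                             tissue_fraction = 0.55, invasive_fraction = 0.3,
                             nuclear_density_invasive = 0.020,
                             nuclear_density_stroma = 0.005,
                             nuclear_radius_px = c(1.5, 3),
                             stroma_rgb = c(231, 172, 196),
                             nucleus_stroma_rgb = c(150, 110, 170),
                             nucleus_invasive_rgb = c(90, 58, 138),
                             invasive_base_rgb = c(200, 150, 190),
                             noise_sd = 6,
                             eosin_shift = FALSE, dark_bubble = FALSE,
                             seed = 1L) {
  if (tissue_fraction < 0 || tissue_fraction > 1 ||
      invasive_fraction < 0 || invasive_fraction > 1)
    stop_wsi("fractions must lie in [0, 1]", class = "parameter_error")
  structure(list(width_px = as.integer(width_px), height_px = as.integer(height_px),
                 mpp = mpp, tissue_fraction = tissue_fraction,
                 invasive_fraction = invasive_fraction,
                 nuclear_density_invasive = nuclear_density_invasive,
                 nuclear_density_stroma = nuclear_density_stroma,
                 nuclear_radius_px = nuclear_radius_px,
                 stroma_rgb = stroma_rgb,
                 nucleus_stroma_rgb = nucleus_stroma_rgb,
                 nucleus_invasive_rgb = nucleus_invasive_rgb,
                 invasive_base_rgb = invasive_base_rgb,
                 noise_sd = noise_sd,
                 eosin_shift = isTRUE(eosin_shift),
                 dark_bubble = isTRUE(dark_bubble),
                 seed = as.integer(seed)),
            class = "synthetic_params")
}

# Smooth random field: coarse Gaussian grid upsampled bilinearly, blurred
# at quarter resolution for speed; thresholding at a quantile of its values
# carves out blobs covering exactly the requested area fraction.
smooth_field <- function(h, w, coarse = c(4L, 5L), blur_sigma = 12) {
  g <- matrix(rnorm(coarse[1] * coarse[2]), coarse[1], coarse[2])
  hq <- max(ceiling(h / 4), coarse[1]); wq <- max(ceiling(w / 4), coarse[2])
  f <- EBImage::resize(g, w = hq, h = wq)  # EBImage: w is first dim (rows)
  # the Gaussian brush (2*ceil(3*sigma)+1 wide) must fit inside the field
  sigma <- min(blur_sigma / 4, (min(hq, wq) - 3) / 6.2)
  if (sigma > 0.3) f <- as.matrix(EBImage::gblur(f, sigma = sigma))
  EBImage::resize(f, w = h, h = w)
}

# Separable 3-tap Gaussian-ish blur (kernel 1/4, 1/2, 1/4 per axis) with
# replicated edges; a cheap stand-in for slight optical defocus.
blur3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  up <- m[c(1, seq_len(h - 1)), , drop = FALSE]
  dn <- m[c(seq_len(h - 1) + 1, h), , drop = FALSE]
  m <- 0.25 * up + 0.5 * m + 0.25 * dn
  lf <- m[, c(1, seq_len(w - 1)), drop = FALSE]
  rt <- m[, c(seq_len(w - 1) + 1, w), drop = FALSE]
  0.25 * lf + 0.5 * m + 0.25 * rt
}

# Stamp elliptical nuclei into a logical canvas at the given pixel indices.
stamp_nuclei <- function(canvas, centers_ij, radii, aspect, theta) {
  h <- nrow(canvas); w <- ncol(canvas)
  for (k in seq_len(nrow(centers_ij))) {
    r <- radii[k]
    rx <- r; ry <- r * aspect[k]
    ci <- centers_ij[k, 1]; cj <- centers_ij[k, 2]
    rr <- ceiling(max(rx, ry))
    is <- max(1, ci - rr):min(h, ci + rr)
    js <- max(1, cj - rr):min(w, cj + rr)
    di <- is - ci
    dj <- js - cj
    co <- cos(theta[k]); si <- sin(theta[k])
    u <- outer(di, dj, function(a, b) (a * co + b * si) / rx)
    v <- outer(di, dj, function(a, b) (-a * si + b * co) / ry)
    canvas[is, js] <- canvas[is, js] | (u * u + v * v <= 1)
  }
  canvas
}

#' Generate one synthetic slide with ground truth
#'
#' @param params a [synthetic_params()] object.
#' @param slide_id identifier for the generated slide.
#' @return A list: `slide` ([slide_image()]), `gt` (invasive
#'   [annotation_mask()]), `tissue` (tissue [annotation_mask()]). The
#'   invasive region is always a subset of the tissue region.
#' @export
generate_slide <- function(params = synthetic_params(), slide_id = "synthetic") {
  h <- params$height_px; w <- params$width_px
  side <- round_half_up(200 / params$mpp)
  if (h < side || w < side)
    stop_wsi("slide too small to host one 200 um tile", class = "parameter_error")
  with_seed(params$seed, {
    # tissue region: threshold a smooth field at the matching quantile
    tis <- matrix(FALSE, h, w)
    if (params$tissue_fraction > 0) {
      f <- smooth_field(h, w, coarse = c(4L, 5L), blur_sigma = 15)
      tis <- f >= quantile(f, 1 - params$tissue_fraction)
    }
    # invasive region: second smooth field, thresholded within tissue only
    gt <- matrix(FALSE, h, w)
    if (params$invasive_fraction > 0 && any(tis)) {
      g <- smooth_field(h, w, coarse = c(3L, 4L), blur_sigma = 25)
      gt[tis] <- g[tis] >= quantile(g[tis], 1 - params$invasive_fraction)
    }

    px <- array(255, c(h, w, 3))
    n_tis <- sum(tis & !gt); n_inv <- sum(gt)
    for (c in 1:3) {
      ch <- px[, , c]
      ch[tis & !gt] <- params$stroma_rgb[c]
      ch[gt] <- params$invasive_base_rgb[c]
      px[, , c] <- ch
    }

    # nuclei: sparse light-purple in stroma, dense dark-purple in invasive
    paint_class <- function(region, density, color) {
      n <- round(density * sum(region))
      if (n < 1L) return(NULL)
      idx <- which(region)
      pick <- idx[sample.int(length(idx), n, replace = TRUE)]
      centers <- cbind((pick - 1L) %% h + 1L, (pick - 1L) %/% h + 1L)
      radii <- runif(n, params$nuclear_radius_px[1], params$nuclear_radius_px[2])
      mask <- stamp_nuclei(matrix(FALSE, h, w), centers, radii,
                           aspect = runif(n, 0.6, 1), theta = runif(n, 0, pi))
      mask <- mask & region
      for (c in 1:3) {
        ch <- px[, , c]
        ch[mask] <- color[c]
        px[, , c] <<- ch
      }
      NULL
    }
    paint_class(tis & !gt, params$nuclear_density_stroma, params$nucleus_stroma_rgb)
    paint_class(gt, params$nuclear_density_invasive, params$nucleus_invasive_rgb)

    # texture noise on tissue, then a light blur for optical softness
    noise <- array(rnorm(h * w * 3, sd = params$noise_sd), c(h, w, 3))
    noise[!array(tis, c(h, w, 3))] <- 0
    px <- px + noise
    for (c in 1:3) px[, , c] <- blur3(px[, , c])

    if (params$eosin_shift) {
      gain <- c(1.08, 0.96, 0.88)  # more eosin, less hematoxylin
      for (c in 1:3) {
        ch <- px[, , c]
        ch[tis] <- ch[tis] * gain[c]
        px[, , c] <- ch
      }
    }
    if (params$dark_bubble) {
      ci <- runif(1, 0.2 * h, 0.8 * h); cj <- runif(1, 0.2 * w, 0.8 * w)
      r <- runif(1, 0.08, 0.15) * min(h, w)
      d <- sqrt(outer((seq_len(h) - ci)^2, (seq_len(w) - cj)^2, "+"))
      shade <- 0.35 + 0.65 / (1 + exp(-(d - r) / (0.1 * r)))  # soft-edged disc
      px <- px * array(shade, c(h, w, 3))
    }
    px <- pmin(pmax(round(px), 0), 255)

    list(slide = slide_image(px, mpp = params$mpp, slide_id = slide_id),
         gt = annotation_mask(gt, mpp = params$mpp, slide_id = slide_id),
         tissue = annotation_mask(tis, mpp = params$mpp, slide_id = slide_id))
  })
}

#' Generate a cohort of synthetic slides on disk
#'
#' Writes `n` slides (PNG + JSON sidecar) and their ground-truth masks,
#' with seeds `base_seed, base_seed + 1, ...`, and returns the manifest.
#'
#' @param n number of slides (>= 1).
#' @param params a [synthetic_params()] template; its `seed` is replaced
#'   per slide.
#' @param base_seed first slide seed.
#' @param dir output directory (created if missing).
#' @param prefix slide id prefix.
#' @return Manifest data frame: `slide_id`, `slide_path`, `mask_path`,
#'   `seed`, `invasive_frac` (realized invasive / tissue area). Also
#'   written to `manifest.csv` in `dir`.
#' @export
generate_cohort <- function(n, params = synthetic_params(), base_seed = 1L,
                            dir = tempfile("cohort"), prefix = "slide") {
  stopifnot(n >= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- params
    p$seed <- as.integer(base_seed + i - 1L)
    id <- sprintf("%s_%03d", prefix, i)
    gen <- generate_slide(p, slide_id = id)
    slide_path <- file.path(dir, paste0(id, ".png"))
    mask_path <- file.path(dir, paste0(id, "_gt.png"))
    write_slide(gen$slide, slide_path)
    write_mask(gen$gt, mask_path)
    tissue_area <- sum(gen$tissue$pixels)
    rows[[i]] <- data.frame(
      slide_id = id, slide_path = slide_path, mask_path = mask_path,
      seed = p$seed,
      invasive_frac = if (tissue_area) sum(gen$gt$pixels) / tissue_area else 0)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}
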