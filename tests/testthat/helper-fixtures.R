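# Fixtures are built in code at test time; nothing is read from disk.

# Uniform-color slide.
flat_slide <- function(h, w, rgb = c(128, 128, 128), mpp = 4, id = "flat") {
  px <- array(0, c(h, w, 3))
  for (c in 1:3) px[, , c] <- rgb[c]
  slide_image(px, mpp = mpp, slide_id = id)
}

# Random patch set with the layout train/predict expect.
random_patch_set <- function(n, side = 50L, seed = 1, labels = NULL,
                             normalized = TRUE) {
  set.seed(seed)
  d <- side * side * 3L
  x <- matrix(rnorm(n * d), d, n)
  if (is.null(labels)) labels <- rep(c("negative", "positive"), length.out = n)
  structure(list(x = x, labels = labels, side = as.integer(side),
                 normalized = normalized),
            class = "patch_set")
}

# Linearly separable patch set: positives shifted by `gap` in every value.
separable_patch_set <- function(n, side = 16L, gap = 1, seed = 1) {
  ps <- random_patch_set(n, side = side, seed = seed)
  ps$x[, ps$labels == "positive"] <- ps$x[, ps$labels == "positive"] + gap
  ps
}

# Random binary mask pair for metric oracle checks.
random_mask_pair <- function(h, w, p1 = 0.4, p2 = 0.4, mpp = 4) {
  a <- annotation_mask(matrix(runif(h * w) < p1, h, w), mpp = mpp)
  b <- annotation_mask(matrix(runif(h * w) < p2, h, w), mpp = mpp)
  list(a, b)
}

# Independent metric oracle: recount from an explicit 2x2 table.
oracle_metrics <- function(pred, gt) {
  tab <- table(factor(as.vector(pred$pixels), levels = 0:1),
               factor(as.vector(gt$pixels), levels = 0:1))
  tp <- tab["1", "1"]; fp <- tab["1", "0"]
  fn <- tab["0", "1"]; tn <- tab["0", "0"]
  div <- function(n, d) if (d == 0) NA_real_ else n / d
  c(dice = div(2 * tp, 2 * tp + fp + fn), ppv = div(tp, tp + fp),
    npv = div(tn, tn + fn), tpr = div(tp, tp + fn), tnr = div(tn, tn + fp),
    fpr = div(fp, fp + tn), fnr = div(fn, fn + tp))
}

oracle_kappa <- function(a, b) {
  x <- as.vector(a$pixels); y <- as.vector(b$pixels)
  n <- length(x)
  po <- mean(x == y)
  pe <- mean(x) * mean(y) + mean(1 - x) * mean(1 - y)
  if (pe == 1) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

# Brute-force AUC by counting positive-negative pairs.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  if (!length(pos) || !length(neg)) return(NA_real_)
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Mask with exactly the requested confusion counts against its ground truth.
masks_with_counts <- function(tp, fp, tn, fn, mpp = 4) {
  n <- tp + fp + tn + fn
  pred <- c(rep(1, tp), rep(1, fp), rep(0, tn), rep(0, fn))
  gt <- c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn))
  list(pred = annotation_mask(matrix(pred, 1, n), mpp = mpp),
       gt = annotation_mask(matrix(gt, 1, n), mpp = mpp))
}

# Small synthetic slides for property tests (fast to render).
small_params <- function(seed, ...) {
  synthetic_params(width_px = 250L, height_px = 200L, seed = seed, ...)
}
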