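test_that("tissue segmentation separates stain from glass", {
  white <- flat_slide(60, 60, c(255, 255, 255))
  expect_equal(sum(segment_tissue(white)$pixels), 0)

  pink <- flat_slide(60, 60, c(231, 172, 196))
  expect_equal(mean(segment_tissue(pink)$pixels), 1)

  # generator ground truth: at least 90% of true tissue must be recovered
  gen <- generate_slide(small_params(seed = 5))
  seg <- segment_tissue(gen$slide)
  recall <- sum(seg$pixels & gen$tissue$pixels) / sum(gen$tissue$pixels)
  expect_gte(recall, 0.9)
})

test_that("tile grid follows floor-division arithmetic at physical scale", {
  s <- flat_slide(400, 1000, mpp = 4)  # 200 um -> 50 px
  ts <- compute_tile_grid(s, 200, tissue = NULL, min_tissue_frac = 0)
  expect_equal(nrow(ts), (400 %/% 50) * (1000 %/% 50))  # 8 x 20
  expect_equal(ts$side_px[1], 50)
  # row-major ordering, 0-based origin
  expect_equal(ts$row[1:21], c(rep(0, 20), 1))
  expect_equal(ts$x[1:3], c(0, 50, 100))

  s40 <- flat_slide(800, 800, mpp = 0.25)  # 200 um -> 800 px
  ts40 <- compute_tile_grid(s40, 200, tissue = NULL, min_tissue_frac = 0)
  expect_equal(nrow(ts40), 1)
  expect_equal(ts40$side_px[1], 800)
  expect_equal(c(ts40$x, ts40$y), c(0, 0))

  # tile larger than the slide: empty tile set, not an error
  tiny <- flat_slide(40, 40, mpp = 4)
  expect_equal(nrow(compute_tile_grid(tiny, 200)), 0)

  # all-background mask with a tissue requirement removes everything
  bg <- annotation_mask(matrix(0, 400, 1000), mpp = 4)
  expect_equal(nrow(compute_tile_grid(s, 200, bg, min_tissue_frac = 0.5)), 0)
})

test_that("80%-overlap labeling is inclusive at the threshold", {
  s <- flat_slide(100, 100, mpp = 4)  # 2 x 2 grid of 50 px tiles
  ts <- compute_tile_grid(s, 200, tissue = NULL, min_tissue_frac = 0)
  gt <- matrix(0, 100, 100)
  gt[1:50, 1:50] <- 1              # tile (0,0): overlap 1
  gt[1:25, 51:100] <- 1            # tile (0,1): overlap 0.50
  gt[51:100, 1:40] <- 1            # tile (1,0): overlap 0.80 exactly
  labeled <- label_tiles(ts, annotation_mask(gt, mpp = 4))
  lab <- setNames(labeled$label, paste(labeled$row, labeled$col))
  expect_equal(lab[["0 0"]], "positive")   # full overlap
  expect_equal(lab[["0 1"]], "negative")   # 0.50 < 0.80
  expect_equal(lab[["1 0"]], "positive")   # exactly 0.80, inclusive
  expect_equal(lab[["1 1"]], "negative")
  # labels are the only mutated field
  expect_identical(as.data.frame(labeled)[names(labeled) != "label"],
                   as.data.frame(ts)[names(ts) != "label"])

  misaligned <- annotation_mask(matrix(0, 50, 50), mpp = 4)
  expect_error(label_tiles(ts, misaligned), class = "alignment_error")
})

test_that("tile footprints are disjoint, inside the slide, and bounded", {
  for (seed in 1:5) {
    gen <- generate_slide(small_params(seed = seed))
    tis <- segment_tissue(gen$slide)
    ts <- compute_tile_grid(gen$slide, 200, tis, min_tissue_frac = 0.25)
    side <- 200 / gen$slide$mpp
    expect_lte(nrow(ts), floor(slide_height(gen$slide) / side) *
                 floor(slide_width(gen$slide) / side))
    expect_true(all(ts$x + ts$side_px <= slide_width(gen$slide)))
    expect_true(all(ts$y + ts$side_px <= slide_height(gen$slide)))
    expect_false(any(duplicated(ts[c("x", "y")])))
    # coverage counter: each pixel covered at most once
    cov <- matrix(0L, slide_height(gen$slide), slide_width(gen$slide))
    for (i in seq_len(nrow(ts)))
      cov[ts$y[i] + 1:ts$side_px[i], ts$x[i] + 1:ts$side_px[i]] <-
        cov[ts$y[i] + 1:ts$side_px[i], ts$x[i] + 1:ts$side_px[i]] + 1L
    expect_lte(max(cov), 1L)
  }
})

test_that("tissue and overlap thresholds act monotonically", {
  for (seed in 1:8) {
    gen <- generate_slide(small_params(seed = seed))
    tis <- segment_tissue(gen$slide)
    counts <- sapply(c(0, 0.25, 0.5, 0.75, 1),
                     function(f) nrow(compute_tile_grid(gen$slide, 200, tis, f)))
    expect_true(all(diff(counts) <= 0))
    ts <- compute_tile_grid(gen$slide, 200, tis, 0)
    pos <- sapply(c(0.2, 0.5, 0.8, 1),
                  function(t) sum(label_tiles(ts, gen$gt, t)$label == "positive"))
    expect_true(all(diff(pos) <= 0))
  }
})
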