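test_that("generation is fully determined by the seed", {
  g1 <- generate_slide(small_params(seed = 71))
  g2 <- generate_slide(small_params(seed = 71))
  expect_identical(g1$slide$pixels, g2$slide$pixels)
  expect_identical(g1$gt$pixels, g2$gt$pixels)
  expect_identical(g1$tissue$pixels, g2$tissue$pixels)

  g3 <- generate_slide(small_params(seed = 72))
  expect_false(identical(g1$slide$pixels, g3$slide$pixels))
})

test_that("ground truth is controlled by invasive_fraction and lies in tissue", {
  none <- generate_slide(small_params(seed = 73, invasive_fraction = 0))
  expect_equal(sum(none$gt$pixels), 0)

  fr <- sapply(74:81, function(s) {
    g <- generate_slide(small_params(seed = s, invasive_fraction = 0.3))
    expect_true(all(g$gt$pixels <= g$tissue$pixels))  # gt subset of tissue
    sum(g$gt$pixels) / sum(g$tissue$pixels)
  })
  expect_true(all(abs(fr - 0.3) < 0.05))

  expect_error(generate_slide(synthetic_params(width_px = 30, height_px = 30)),
               class = "parameter_error")
  expect_error(synthetic_params(invasive_fraction = 1.2),
               class = "parameter_error")
})

test_that("cohort generation writes readable triples with distinct seeds", {
  dir <- withr::local_tempdir()
  man <- generate_cohort(5, small_params(seed = 1), base_seed = 90, dir = dir)
  expect_equal(nrow(man), 5)
  expect_equal(man$seed, 90:94)
  expect_true(all(file.exists(man$slide_path)))
  expect_true(all(file.exists(man$mask_path)))
  expect_true(file.exists(file.path(dir, "manifest.csv")))

  s <- read_slide(man$slide_path[1])
  m <- read_mask(man$mask_path[1], expected_dims = dim(s), mpp = s$mpp)
  expect_equal(dim(m), dim(s))

  nc <- generate_cohort(3, small_params(seed = 1, invasive_fraction = 0),
                        base_seed = 90, dir = withr::local_tempdir())
  expect_true(all(nc$invasive_frac == 0))
})

test_that("stain knobs shift cohort-level channel means (batch effect)", {
  a <- generate_slide(small_params(seed = 95))
  b <- generate_slide(small_params(seed = 95, eosin_shift = TRUE))
  mean_rgb <- function(g) {
    tis <- g$tissue$pixels == 1
    sapply(1:3, function(c) mean(g$slide$pixels[, , c][tis]))
  }
  ma <- mean_rgb(a); mb <- mean_rgb(b)
  expect_gt(mb[1] - mb[3], ma[1] - ma[3])  # shifted toward eosin (red over blue)

  d <- generate_slide(small_params(seed = 95, dark_bubble = TRUE))
  expect_lt(mean(d$slide$pixels), mean(a$slide$pixels))  # darkened by bubble
})

test_that("the two texture classes differ in nuclear-pixel density", {
  g <- generate_slide(small_params(seed = 96))
  # dark (nucleus) pixels: low luma
  luma <- 0.299 * g$slide$pixels[, , 1] + 0.587 * g$slide$pixels[, , 2] +
    0.114 * g$slide$pixels[, , 3]
  dark <- luma < 160
  inv <- g$gt$pixels == 1
  str <- g$tissue$pixels == 1 & !inv
  expect_gt(mean(dark[inv]), 3 * mean(dark[str]))
})
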