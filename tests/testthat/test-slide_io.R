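test_that("slide write/read round trip preserves pixels and metadata", {
  set.seed(11)
  px <- array(sample(0:255, 100 * 80 * 3, replace = TRUE), c(80, 100, 3))
  s <- slide_image(px, mpp = 4.0, slide_id = "rt")
  path <- withr::local_tempfile(fileext = ".png")
  write_slide(s, path)
  s2 <- read_slide(path)
  expect_identical(s2$pixels, s$pixels + 0)  # byte-identical values
  expect_equal(s2$mpp, 4.0)
  expect_equal(s2$slide_id, "rt")
  expect_equal(slide_width(s2), 100)
  expect_equal(slide_height(s2), 80)
  # physical size is representation-invariant
  expect_equal(slide_width(s2) * s2$mpp, slide_width(s) * s$mpp)
})

test_that("missing or invalid mpp metadata is a metadata error", {
  s <- flat_slide(10, 10)
  path <- withr::local_tempfile(fileext = ".png")
  write_slide(s, path)
  jsonlite::write_json(list(slide_id = "x"), sidecar <- sub("png$", "json", path),
                       auto_unbox = TRUE)
  expect_error(read_slide(path), class = "metadata_error")
  expect_error(read_slide(path, metadata_path = tempfile()),
               class = "metadata_error")
  expect_error(slide_image(array(0, c(4, 4, 3)), mpp = -1),
               class = "metadata_error")
})

test_that("mask IO binarizes saved values and checks alignment", {
  m <- annotation_mask(matrix(c(0, 1, 1, 0, 1, 0), 2, 3), mpp = 4)
  path <- withr::local_tempfile(fileext = ".png")
  write_mask(m, path)  # persisted as {0, 255}
  m2 <- read_mask(path, expected_dims = c(2, 3), mpp = 4)
  expect_setequal(unique(as.vector(m2$pixels)), c(0L, 1L))
  expect_identical(m2$pixels, m$pixels)

  zero <- annotation_mask(matrix(0, 5, 5), mpp = 4)
  write_mask(zero, path)
  expect_equal(sum(read_mask(path, c(5, 5))$pixels), 0)

  expect_error(read_mask(path, expected_dims = c(6, 6)),
               class = "alignment_error")
})

test_that("heatmaps persist at 16-bit depth within one quantization step", {
  set.seed(12)
  vals <- matrix(runif(40 * 30), 30, 40)
  pm <- probability_map(vals, mpp = 4, slide_id = "hm")
  path <- withr::local_tempfile(fileext = ".tif")
  write_heatmap(pm, path)
  back <- read_heatmap(path, mpp = 4)
  expect_lt(max(abs(back$values - vals)), 1 / 65535 + 1e-12)

  u <- probability_map(matrix(0.5, 4, 4), mpp = 4)
  write_heatmap(u, path)
  expect_lt(max(abs(read_heatmap(path)$values - 0.5)), 1 / 65535)

  z <- probability_map(matrix(0, 4, 4), mpp = 4)
  write_heatmap(z, path)
  expect_true(all(read_heatmap(path)$values == 0))

  expect_error(probability_map(matrix(1.3, 2, 2), mpp = 4),
               class = "validation_error")
})
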