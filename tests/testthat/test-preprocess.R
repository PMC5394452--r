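test_that("BT.601 YUV transform has zero chroma on gray and is invertible", {
  gray <- rgb_to_yuv(matrix(c(128, 128, 128), 1))
  expect_equal(gray[1], 128)
  expect_lt(max(abs(gray[2:3])), 1e-9)

  red <- rgb_to_yuv(matrix(c(255, 0, 0), 1))
  expect_equal(red[1], 0.299 * 255)  # 76.245

  set.seed(21)
  x <- array(runif(20 * 20 * 3, 0, 255), c(20, 20, 3))
  expect_lt(max(abs(yuv_to_rgb(rgb_to_yuv(x)) - x)), 1e-6)
})

test_that("normalization fitting uses population statistics with clamping", {
  const <- array(7, c(4, 4, 3))
  st <- fit_normalization(list(const))
  expect_equal(unname(st$mean), c(7, 7, 7))
  expect_equal(unname(st$sd), rep(1e-8, 3))  # clamped at eps

  two <- matrix(c(0, 2), nrow = 2, ncol = 3)  # values {0,2} per channel
  st2 <- fit_normalization(two)
  expect_equal(unname(st2$mean), c(1, 1, 1))
  expect_equal(unname(st2$sd), c(1, 1, 1))   # population std of {0,2}

  expect_error(fit_normalization(list()), class = "fit_error")
})

test_that("standardizing the fitting pool gives mean 0 variance 1", {
  set.seed(22)
  tiles <- lapply(1:5, function(i) array(rnorm(12 * 12 * 3, i, i), c(12, 12, 3)))
  st <- fit_normalization(tiles)
  pooled <- do.call(rbind, lapply(tiles, function(t)
    matrix(apply_normalization(t, st), ncol = 3)))
  expect_lt(max(abs(colMeans(pooled))), 1e-6)
  expect_lt(max(abs(colMeans(pooled^2) - colMeans(pooled)^2 - 1)), 1e-6)
})

test_that("apply_normalization is the stated affine map with frozen stats", {
  st <- structure(list(mean = c(Y = 3, U = 3, V = 3), sd = c(Y = 2, U = 2, V = 2),
                       n_pixels = 1, frozen = TRUE), class = "norm_stats")
  expect_equal(as.vector(apply_normalization(matrix(5, 1, 3), st)), rep(1, 3))

  ident <- structure(list(mean = c(Y = 0, U = 0, V = 0), sd = c(Y = 1, U = 1, V = 1),
                          n_pixels = 1, frozen = TRUE), class = "norm_stats")
  x <- matrix(rnorm(30), 10, 3)
  expect_equal(apply_normalization(x, ident), array(x, dim(x)))

  # no silent idempotence: applying twice standardizes twice
  once <- apply_normalization(x, st)
  twice <- apply_normalization(once, st)
  expect_false(isTRUE(all.equal(once, twice)))
  expect_equal(twice, (once - 3) / 2)

  # leakage guard: applying never refits the frozen stats
  before <- unclass(st)
  invisible(apply_normalization(x, st))
  expect_identical(unclass(st), before)
  unfitted <- structure(list(mean = 0, sd = 1, frozen = FALSE), class = "norm_stats")
  expect_error(apply_normalization(x, unfitted), class = "usage_error")
})

test_that("normalization statistics survive a JSON round trip", {
  set.seed(23)
  st <- fit_normalization(list(array(runif(100 * 3, 0, 255), c(10, 10, 3))))
  path <- withr::local_tempfile(fileext = ".json")
  write_norm_stats(st, path)
  st2 <- read_norm_stats(path)
  expect_equal(st2$mean, st$mean)
  expect_equal(st2$sd, st$sd)
  expect_true(st2$frozen)
})
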