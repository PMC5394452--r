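test_that("architecture specs match the three candidate networks", {
  three <- build_convnet("three_layer", 50)
  expect_equal(three$conv_maps, 256L)
  expect_equal(three$fc_units, 256L)
  expect_equal(vapply(three$layers, `[[`, "", "kind"),
               c("conv+pool", "fully_connected", "softmax_output"))
  expect_equal(three$layers[[length(three$layers)]]$units, 2L)

  four <- build_convnet("four_layer", 50)
  expect_equal(four$conv_maps, c(16L, 32L))
  expect_equal(four$fc_units, 128L)

  six <- build_convnet("six_layer", 50)
  expect_equal(six$conv_maps, rep(16L, 4))
  expect_equal(six$fc_units, 128L)
  expect_equal(length(six$layers), 6L)
  expect_equal(six$layers[[6]]$units, 2L)

  expect_error(build_convnet("vgg"), class = "configuration_error")
  expect_error(build_convnet("three_layer", 8), class = "configuration_error")
})

test_that("training is reproducible and honors the zero step size", {
  ps <- separable_patch_set(60, side = 16, seed = 41)
  spec <- build_convnet("four_layer", 16)
  cfg <- train_config(epochs = 3, seed = 7)
  m1 <- train_convnet(spec, ps, cfg)
  m2 <- train_convnet(spec, ps, cfg)
  expect_identical(m1$history$loss, m2$history$loss)
  expect_identical(m1$weights$fc_W, m2$weights$fc_W)

  m0 <- train_convnet(spec, ps, train_config(epochs = 3, learning_rate = 0,
                                             seed = 7))
  expect_lt(max(abs(diff(m0$history$loss))), 1e-12)
  init <- train_convnet(spec, ps, train_config(epochs = 1, learning_rate = 0,
                                               seed = 7))
  expect_identical(m0$weights$out_W, init$weights$out_W)  # never updated
})

test_that("training rejects degenerate inputs", {
  ps <- random_patch_set(10, side = 16, seed = 42,
                         labels = rep("positive", 10))
  spec <- build_convnet("four_layer", 16)
  expect_error(train_convnet(spec, ps, train_config(epochs = 1)),
               class = "training_error")
  mixed <- separable_patch_set(10, side = 16, seed = 42)
  spec50 <- build_convnet("four_layer", 50)
  expect_error(train_convnet(spec50, mixed, train_config(epochs = 1)),
               class = "shape_error")
  raw <- mixed; raw$normalized <- NULL
  expect_error(train_convnet(spec, raw, train_config(epochs = 1)),
               class = "usage_error")
})

test_that("a separable patch set is learned to high training accuracy", {
  ps <- separable_patch_set(120, side = 16, gap = 1, seed = 43)
  spec <- build_convnet("four_layer", 16)
  m <- train_convnet(spec, ps, train_config(epochs = 10, seed = 7))
  expect_gte(m$history$accuracy[nrow(m$history)], 0.95)
  expect_lt(m$history$loss[nrow(m$history)], m$history$loss[1])
})

test_that("predicted probabilities are valid, deterministic and paired", {
  ps <- separable_patch_set(40, side = 16, seed = 44)
  spec <- build_convnet("six_layer", 16)
  m <- train_convnet(spec, ps, train_config(epochs = 2, seed = 9))
  p <- predict(m, ps)
  expect_true(all(p >= 0 & p <= 1))
  expect_lt(max(abs(rowSums(p) - 1)), 1e-6)

  # duplicate patches in one batch get identical probabilities
  dup <- ps
  dup$x <- ps$x[, c(1, 1, 2, 2)]
  dup$labels <- ps$labels[c(1, 1, 2, 2)]
  pd <- predict(m, dup)
  expect_equal(pd[1, ], pd[2, ])
  expect_equal(pd[3, ], pd[4, ])

  # batch composition does not change the output
  sub <- ps; sub$x <- ps$x[, 1, drop = FALSE]; sub$labels <- ps$labels[1]
  expect_equal(unname(predict(m, sub)[1, ]), unname(p[1, ]), tolerance = 1e-6)

  # zeroed output layer gives symmetric logits
  m0 <- m
  m0$weights$out_W[] <- 0
  m0$weights$out_b[] <- 0
  p0 <- predict(m0, ps)
  expect_equal(unname(p0), matrix(0.5, nrow(p0), 2), tolerance = 1e-7)
})
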