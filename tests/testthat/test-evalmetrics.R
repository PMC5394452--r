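test_that("pixel metrics match the closed-form worked example", {
  mm <- masks_with_counts(tp = 6, fp = 2, tn = 10, fn = 2)
  out <- pixel_metrics(mm$pred, mm$gt)
  expect_equal(unname(out$counts), c(6, 2, 10, 2))  # TP FP TN FN
  expect_equal(out$metrics[["dice"]], 0.75)
  expect_equal(out$metrics[["ppv"]], 0.75)
  expect_equal(out$metrics[["npv"]], 10 / 12)
  expect_equal(out$metrics[["tpr"]], 0.75)
  expect_equal(out$metrics[["tnr"]], 10 / 12)
  expect_equal(out$metrics[["fpr"]], 2 / 12)
  expect_equal(out$metrics[["fnr"]], 0.25)
})

test_that("perfect predictions and normal-control slides behave as defined", {
  set.seed(61)
  gt <- annotation_mask(matrix(runif(400) < 0.3, 20, 20), mpp = 4)
  perfect <- pixel_metrics(gt, gt)$metrics
  expect_equal(unname(perfect[c("dice", "ppv", "npv", "tpr", "tnr")]),
               rep(1, 5))
  expect_equal(unname(perfect[c("fpr", "fnr")]), c(0, 0))

  # normal control: no positive ground truth, all-negative prediction
  empty <- annotation_mask(matrix(0, 20, 20), mpp = 4)
  nc <- pixel_metrics(empty, empty)$metrics
  expect_equal(nc[["npv"]], 1)
  expect_equal(nc[["tnr"]], 1)
  expect_equal(nc[["fpr"]], 0)
  expect_true(all(is.na(nc[c("dice", "ppv", "tpr", "fnr")])))

  # FN = 0 with TN > 0 forces NPV = 1 exactly, whatever the FP count
  some_fp <- annotation_mask(matrix(c(1, rep(0, 399)), 20, 20), mpp = 4)
  expect_equal(pixel_metrics(some_fp, empty)$metrics[["npv"]], 1)

  misaligned <- annotation_mask(matrix(0, 10, 10), mpp = 4)
  expect_error(pixel_metrics(gt, misaligned), class = "alignment_error")
})

test_that("metrics equal an independent recount on random mask pairs", {
  set.seed(62)
  for (rep in 1:60) {
    h <- sample(1:64, 1); w <- sample(1:64, 1)
    mm <- random_mask_pair(h, w, runif(1), runif(1))
    got <- pixel_metrics(mm[[1]], mm[[2]])$metrics
    want <- oracle_metrics(mm[[1]], mm[[2]])
    expect_equal(got, want, tolerance = 1e-12)
    if (!is.na(got["tpr"])) expect_equal(got[["tpr"]] + got[["fnr"]], 1)
    if (!is.na(got["tnr"])) expect_equal(got[["tnr"]] + got[["fpr"]], 1)
    # Dice symmetry
    expect_equal(got[["dice"]],
                 pixel_metrics(mm[[2]], mm[[1]])$metrics[["dice"]])
  }
})

test_that("tissue-only evaluation restricts the pixel domain", {
  set.seed(63)
  mm <- random_mask_pair(30, 30, 0.4, 0.4)
  tissue <- annotation_mask(matrix(rep(c(1, 0), each = 450), 30, 30), mpp = 4)
  full <- pixel_metrics(mm[[1]], mm[[2]])
  sub <- pixel_metrics(mm[[1]], mm[[2]], tissue = tissue)
  expect_equal(sum(sub$counts), 450)
  expect_equal(sum(full$counts), 900)
})

test_that("Cohen's kappa matches hand computation and is symmetric", {
  set.seed(64)
  a <- annotation_mask(matrix(runif(900) < 0.4, 30, 30), mpp = 4)
  expect_equal(cohens_kappa(a, a), 1)

  # both-pos 40, both-neg 40, 10 + 10 disagreements -> po 0.8, pe 0.5
  x <- c(rep(1, 40), rep(0, 40), rep(1, 10), rep(0, 10))
  y <- c(rep(1, 40), rep(0, 40), rep(0, 10), rep(1, 10))
  ka <- cohens_kappa(annotation_mask(matrix(x, 10, 10), mpp = 4),
                     annotation_mask(matrix(y, 10, 10), mpp = 4))
  expect_equal(ka, 0.6)

  # degenerate rater: all-negative vs mixed gives kappa 0
  allneg <- annotation_mask(matrix(0, 30, 30), mpp = 4)
  expect_equal(cohens_kappa(allneg, a), 0)

  b <- annotation_mask(matrix(runif(900) < 0.5, 30, 30), mpp = 4)
  expect_equal(cohens_kappa(a, b), cohens_kappa(b, a))
  expect_lt(abs(cohens_kappa(a, b) - oracle_kappa(a, b)), 1e-12)
})

test_that("tile AUC is the tie-corrected Mann-Whitney statistic", {
  expect_equal(tile_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  expect_equal(tile_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(tile_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_true(is.na(tile_auc(runif(5), rep(1, 5))))

  set.seed(65)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    scores <- round(runif(n), 1)  # coarse grid forces ties
    labels <- runif(n) < 0.5
    if (length(unique(labels)) < 2) next
    expect_equal(tile_auc(scores, labels), oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("tile AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(66)
  scores <- round(runif(200), 2)
  labels <- runif(200) < 0.4
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(tile_auc(scores, labels), ref, tolerance = 1e-12)
})

test_that("metric correlation handles pairing, NAs and degeneracy", {
  x <- c(0.2, 0.5, 0.9)
  expect_equal(metric_correlation(x, x), 1)
  expect_equal(metric_correlation(x, 1 - x), -1)

  # hand Pearson on (1,2,3) vs (1,2,4)
  xs <- c(1, 2, 3); ys <- c(1, 2, 4)
  hand <- sum((xs - mean(xs)) * (ys - mean(ys))) /
    sqrt(sum((xs - mean(xs))^2) * sum((ys - mean(ys))^2))
  expect_equal(metric_correlation(xs, ys), hand)
  expect_equal(round(hand, 4), 0.982)

  expect_equal(metric_correlation(c(1, 2, 3, NA), c(1, 2, 4, 0)), hand)
  expect_true(is.na(metric_correlation(c(1, 1, 1), c(1, 2, 3))))
  expect_true(is.na(metric_correlation(c(1, NA), c(1, 2))))
  expect_error(metric_correlation(1:3, 1:4), class = "usage_error")
})

test_that("cohort summaries aggregate defined values with sample std", {
  one <- data.frame(dice = 0.8, ppv = NA, npv = 1, tpr = NA, tnr = 1,
                    fpr = 0, fnr = NA)
  s1 <- cohort_summary(one, "single")
  expect_equal(s1$mean[s1$metric == "dice"], 0.8)
  expect_equal(s1$sd[s1$metric == "dice"], 0)
  expect_equal(s1$n_defined[s1$metric == "ppv"], 0)

  two <- data.frame(dice = c(0.6, 0.8), ppv = c(0.7, NA), npv = c(1, 1),
                    tpr = c(0.5, 0.6), tnr = c(1, 1), fpr = c(0, 0),
                    fnr = c(0.5, 0.4))
  s2 <- cohort_summary(two, "pair")
  expect_equal(s2$mean[s2$metric == "dice"], 0.7)
  expect_equal(s2$sd[s2$metric == "dice"], sd(c(0.6, 0.8)))  # n-1 convention
  expect_equal(round(s2$sd[s2$metric == "dice"], 4), 0.1414)
  expect_equal(s2$mean[s2$metric == "ppv"], 0.7)
  expect_equal(s2$n_defined[s2$metric == "ppv"], 1)

  expect_error(cohort_summary(data.frame()), class = "usage_error")
})
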