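#' Pixel-wise evaluation, agreement, and model comparison
#'
#' Predictions are scored pixel by pixel against ground truth at the
#' evaluation resolution. Seven per-slide measures are reported — Dice,
#' PPV, NPV, TPR, TNR, FPR, FNR — each defined from the confusion counts
#' and reported as `NA` (not coerced to 0) whenever its denominator is
#' zero; on a normal-control slide with no annotated cancer this yields
#' defined NPV/TNR/FPR and undefined Dice/PPV/TPR/FNR. Cohort aggregation
#' averages defined values only. Inter-rater (or inter-model) agreement
#' uses Cohen's kappa; tile-level ranking quality uses the rank-based
#' (Mann-Whitney) AUC with ties counted one half; cross-classifier
#' agreement uses the Pearson correlation of per-slide measures.
#'
#' @name evalmetrics
NULL

check_aligned <- function(a, b) {
  if (!identical(dim(a$pixels), dim(b$pixels)) ||
      !isTRUE(all.equal(a$mpp, b$mpp)))
    stop_wsi("masks are not aligned (dims or mpp differ)", class = "alignment_error")
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Pixel-wise confusion counts and the seven slide measures
#'
#' Counts are taken over every pixel of the masks (background glass counts
#' as negative) unless `tissue` is supplied, in which case only tissue
#' pixels are evaluated.
#'
#' @param pred predicted [annotation_mask()].
#' @param gt ground-truth [annotation_mask()], aligned to `pred`.
#' @param tissue optional tissue mask restricting the evaluation domain.
#' @return A list with `counts` (`TP`, `FP`, `TN`, `FN`) and `metrics`
#'   (named numeric vector `dice, ppv, npv, tpr, tnr, fpr, fnr`, `NA`
#'   where undefined).
#' @export
pixel_metrics <- function(pred, gt, tissue = NULL) {
  stopifnot(inherits(pred, "annotation_mask"), inherits(gt, "annotation_mask"))
  check_aligned(pred, gt)
  p <- pred$pixels == 1L
  g <- gt$pixels == 1L
  if (!is.null(tissue)) {
    check_aligned(pred, tissue)
    keep <- tissue$pixels == 1L
    p <- p[keep]; g <- g[keep]
  }
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g); tn <- sum(!p & !g)
  metrics <- c(dice = safe_ratio(2 * tp, 2 * tp + fp + fn),
               ppv  = safe_ratio(tp, tp + fp),
               npv  = safe_ratio(tn, tn + fn),
               tpr  = safe_ratio(tp, tp + fn),
               tnr  = safe_ratio(tn, tn + fp),
               fpr  = safe_ratio(fp, fp + tn),
               fnr  = safe_ratio(fn, fn + tp))
  list(counts = c(TP = tp, FP = fp, TN = tn, FN = fn), metrics = metrics)
}

metric_names <- c("dice", "ppv", "npv", "tpr", "tnr", "fpr", "fnr")

#' Aggregate per-slide measures into a cohort summary
#'
#' Mean and sample (n-1) standard deviation per measure, over defined
#' (non-`NA`) values only; `n_defined` records how many slides contributed.
#'
#' @param metrics a data frame with one row per slide and the seven metric
#'   columns (as from [run_experiment()]'s `slide_metrics`), or a list of
#'   `metrics` vectors from [pixel_metrics()].
#' @param cohort_id label for the cohort.
#' @return A `cohort_summary` data frame: one row per measure with `mean`,
#'   `sd`, `n_defined`, plus attributes `cohort_id` and `n_slides`.
#' @export
cohort_summary <- function(metrics, cohort_id = "cohort") {
  if (is.list(metrics) && !is.data.frame(metrics))
    metrics <- as.data.frame(do.call(rbind, metrics))
  if (!is.data.frame(metrics) || nrow(metrics) == 0L)
    stop_wsi("need at least one slide's metrics", class = "usage_error")
  rows <- lapply(metric_names, function(m) {
    v <- metrics[[m]]
    v <- v[!is.na(v)]
    data.frame(metric = m,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1L) sd(v) else if (length(v)) 0 else NA_real_,
               n_defined = length(v))
  })
  out <- do.call(rbind, rows)
  structure(out, cohort_id = cohort_id, n_slides = nrow(metrics),
            class = c("cohort_summary", "data.frame"))
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort '%s' (%d slides):\n", attr(x, "cohort_id"),
              attr(x, "n_slides")))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-4s %s (n = %d)\n", toupper(x$metric[i]),
                if (is.na(x$mean[i])) "N/A"
                else sprintf("%.4f ± %.4f", x$mean[i], x$sd[i]),
                x$n_defined[i]))
  invisible(x)
}

#' Cohen's kappa between two binary masks
#'
#' Chance-corrected pixel agreement: `kappa = (p_o - p_e) / (1 - p_e)` with
#' `p_o` the observed agreement and `p_e` the agreement expected from the
#' two raters' marginal positive rates. When both raters agree perfectly
#' and chance agreement is also perfect (`p_e = 1`), kappa is 1.
#'
#' @param a,b aligned [annotation_mask()] objects.
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(a, b) {
  stopifnot(inherits(a, "annotation_mask"), inherits(b, "annotation_mask"))
  check_aligned(a, b)
  x <- a$pixels == 1L; y <- b$pixels == 1L
  n <- length(x)
  po <- sum(x == y) / n
  pe <- mean(x) * mean(y) + (1 - mean(x)) * (1 - mean(y))
  if (pe == 1) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Tile-level area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' tile scores above a random negative one, with ties counted one half.
#' Undefined (`NA`) when only one class is present.
#'
#' @param scores per-tile invasive probabilities.
#' @param labels per-tile truth: `"positive"`/`"negative"`, logical, or 0/1.
#' @return AUC in `[0, 1]`, or `NA`.
#' @export
tile_auc <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels)) labels <- labels == "positive"
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Pearson correlation between paired per-slide measures
#'
#' Pairs where either value is `NA` are dropped; the result is `NA` when
#' fewer than two pairs remain or either side has zero variance.
#'
#' @param xs,ys paired per-slide values of one measure from two models.
#' @return Pearson r in `[-1, 1]`, or `NA`.
#' @export
metric_correlation <- function(xs, ys) {
  if (length(xs) != length(ys))
    stop_wsi("xs and ys must be paired", class = "usage_error")
  keep <- !is.na(xs) & !is.na(ys)
  xs <- xs[keep]; ys <- ys[keep]
  if (length(xs) < 2L || sd(xs) == 0 || sd(ys) == 0) return(NA_real_)
  cor(xs, ys)
}
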