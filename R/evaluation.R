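## Counting metrics (RMSE / Bias / R^2), mask IoU, greedy detection
## matching, COCO-style average precision and density-level stratification.

#' Counting metrics: RMSE, Bias, R-squared
#'
#' `RMSE = sqrt(mean((y - yhat)^2))`, `Bias = mean(y - yhat)` (so a
#' positive Bias means the prediction is low on average), and
#' `R2 = 1 - SS_res / SS_tot`.
#'
#' @param y true counts (integer >= 0), or a data.frame with columns
#'   `y` and `y_hat`.
#' @param y_hat predicted counts.
#' @return list of class "counting_metrics" with `rmse`, `bias`, `r2`, `n`.
#' @export
counting_metrics <- function(y, y_hat = NULL) {
  if (is.data.frame(y)) { y_hat <- y$y_hat; y <- y$y }
  n <- length(y)
  if (n == 0) stop("no count pairs")
  stopifnot(length(y_hat) == n, all(y >= 0))
  err <- y - y_hat
  rmse <- sqrt(mean(err^2))
  bias <- mean(err)
  r2 <- NA_real_
  if (n >= 2) {
    ss_tot <- sum((y - mean(y))^2)
    if (ss_tot > 0) r2 <- 1 - sum(err^2) / ss_tot
    else warning("constant true counts: R^2 is undefined")
  }
  structure(list(rmse = rmse, bias = bias, r2 = r2, n = n),
            class = "counting_metrics")
}

#' @export
print.counting_metrics <- function(x, ...) {
  cat(sprintf("RMSE %.4f  Bias %.4f  R2 %.4f  (n = %d)\n",
              x$rmse, x$bias, x$r2, x$n))
  invisible(x)
}

#' Intersection-over-union of two binary masks
#'
#' @param mask_a,mask_b logical/0-1 matrices of identical shape.
#' @return IoU in [0, 1]; two empty masks give 0 with a warning.
#' @export
mask_iou <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b))) stop("mask shapes differ")
  a <- mask_a > 0; b <- mask_b > 0
  un <- sum(a | b)
  if (un == 0) {
    warning("both masks are empty; IoU defined as 0")
    return(0)
  }
  sum(a & b) / un
}

#' Greedily match detections to ground truth on one image
#'
#' Detections are processed in descending score order; each claims its
#' best-IoU still-unmatched ground-truth instance if that IoU reaches the
#' threshold (TP), otherwise it is a false positive.  Unmatched ground
#' truths are false negatives.
#'
#' @param detections list of `list(mask, score)` (or full detection
#'   records).
#' @param gt_masks list of ground-truth binary masks.
#' @param iou_threshold matching threshold.
#' @return list with `tp` (logical per detection, score-sorted), `scores`
#'   (sorted), `fn` count, `n_gt` and `iou_threshold`.
#' @export
match_detections <- function(detections, gt_masks, iou_threshold = 0.5) {
  scores <- vapply(detections, `[[`, numeric(1), "score")
  ord <- order(scores, decreasing = TRUE)
  matched <- logical(length(gt_masks))
  tp <- logical(length(detections))
  for (i in ord) {
    best <- 0; best_j <- 0L
    for (j in seq_along(gt_masks)) {
      if (matched[j]) next
      iou <- suppressWarnings(mask_iou(detections[[i]]$mask, gt_masks[[j]]))
      if (iou > best) { best <- iou; best_j <- j }
    }
    if (best_j > 0L && best >= iou_threshold) {
      tp[i] <- TRUE
      matched[best_j] <- TRUE
    }
  }
  list(tp = tp[ord], scores = scores[ord], fn = sum(!matched),
       n_gt = length(gt_masks), iou_threshold = iou_threshold)
}

#' Average precision from pooled match results
#'
#' Area under the precision-recall curve of the score-ranked pooled
#' detections.  `"coco101"` samples the precision envelope at recalls 0,
#' 0.01, ..., 1.00 (COCO convention); `"all"` integrates the envelope at
#' every recall change (the hand-checkable variant).
#'
#' @param scores detection scores (pooled over images).
#' @param tp logical TP flag per detection.
#' @param n_gt total number of ground-truth instances pooled (>= 1).
#' @param interpolation `"coco101"` or `"all"`.
#' @return list of class "ap_result" with `ap`, `precision`, `recall`,
#'   `interpolation`.
#' @export
average_precision <- function(scores, tp, n_gt,
                              interpolation = c("coco101", "all")) {
  interpolation <- match.arg(interpolation)
  if (n_gt < 1) stop("average precision needs at least one ground-truth instance")
  ord <- order(scores, decreasing = TRUE)
  tp <- tp[ord]
  ctp <- cumsum(tp); cfp <- cumsum(!tp)
  precision <- ctp / (ctp + cfp)
  recall <- ctp / n_gt
  ## precision envelope: best precision at recall >= r
  env <- rev(cummax(rev(precision)))
  ap <- if (length(tp) == 0) 0
  else if (interpolation == "coco101") {
    rs <- seq(0, 1, by = 0.01)
    mean(vapply(rs, function(r) {
      ok <- recall >= r
      if (any(ok)) env[which(ok)[1]] else 0
    }, numeric(1)))
  } else {
    r_prev <- c(0, head(recall, -1))
    sum((recall - r_prev) * env)
  }
  structure(list(ap = ap, precision = precision, recall = recall,
                 interpolation = interpolation), class = "ap_result")
}

pool_matches <- function(detections_by_image, gts_by_image, iou_threshold) {
  scores <- numeric(0); tp <- logical(0); n_gt <- 0L
  for (i in seq_along(gts_by_image)) {
    mr <- match_detections(detections_by_image[[i]] %||% list(),
                           gts_by_image[[i]], iou_threshold)
    scores <- c(scores, mr$scores)
    tp <- c(tp, mr$tp)
    n_gt <- n_gt + mr$n_gt
  }
  list(scores = scores, tp = tp, n_gt = n_gt)
}

#' Mask mAP suite
#'
#' Mask-based average precision averaged over IoU thresholds 0.50, 0.55,
#' ..., 0.95 (mAP) plus the fixed-threshold values mAP50 and mAP75, as
#' percentages.  With the single "ear" class, the class mean is the class
#' value itself.
#'
#' @param detections_by_image list (per image) of detection lists, each
#'   detection carrying `mask` and `score`.
#' @param gts_by_image list (per image) of lists of ground-truth masks.
#' @return list with `map`, `map50`, `map75` (percent, 0-100).
#' @export
map_suite <- function(detections_by_image, gts_by_image) {
  thr <- seq(0.5, 0.95, by = 0.05)
  aps <- vapply(thr, function(t) {
    pm <- pool_matches(detections_by_image, gts_by_image, t)
    average_precision(pm$scores, pm$tp, pm$n_gt)$ap
  }, numeric(1))
  list(map = 100 * mean(aps), map50 = 100 * aps[thr == 0.5],
       map75 = 100 * aps[thr == 0.75], ap_by_threshold = stats::setNames(aps, thr))
}

#' Stratify images into density levels
#'
#' Bins images into `n_levels` groups (Level 1 = sparsest) by quartiles (in
#' general, quantiles) of their ground-truth instance counts.
#'
#' @param counts per-image ground-truth counts.
#' @param n_levels number of levels (default 4).
#' @return list with `level` (integer per image), `edges` (inner bin
#'   edges).
#' @export
stratify_by_density <- function(counts, n_levels = 4) {
  edges <- quantile(counts, probs = seq_len(n_levels - 1) / n_levels,
                    names = FALSE)
  if (length(unique(counts)) < n_levels)
    warning("fewer distinct counts than levels; bins are degenerate")
  level <- findInterval(counts, unique(edges), left.open = TRUE) + 1L
  ## map back onto 1..n_levels when edges collapsed
  list(level = level, edges = edges)
}
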