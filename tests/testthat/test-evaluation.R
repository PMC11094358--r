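test_that("counting metrics match hand evaluation", {
  cm <- counting_metrics(c(10, 20, 30), c(12, 18, 30))
  expect_equal(cm$rmse, sqrt(8 / 3), tolerance = 1e-12)
  expect_equal(cm$bias, 0)
  expect_equal(cm$r2, 1 - 8 / 200, tolerance = 1e-12)
  perfect <- counting_metrics(c(4, 9, 2), c(4, 9, 2))
  expect_equal(c(perfect$rmse, perfect$bias, perfect$r2), c(0, 0, 1))
  ## mean predictor scores R2 = 0
  y <- c(3, 7, 11, 19)
  expect_equal(counting_metrics(y, rep(mean(y), 4))$r2, 0)
  expect_warning(counting_metrics(c(5, 5, 5), c(4, 5, 6)), "undefined")
  expect_error(counting_metrics(numeric(0), numeric(0)), "no count")
})

test_that("counting metrics match a naive loop oracle and RMSE >= |Bias|", {
  set.seed(21)
  for (r in 1:10) {
    y <- sample(0:50, 12, TRUE)
    yh <- pmax(0, y + rnorm(12, 0, 3))
    cm <- counting_metrics(y, yh)
    s2 <- 0; s1 <- 0
    for (i in seq_along(y)) { s2 <- s2 + (y[i] - yh[i])^2; s1 <- s1 + (y[i] - yh[i]) }
    expect_equal(cm$rmse, sqrt(s2 / 12), tolerance = 1e-10)
    expect_equal(cm$bias, s1 / 12, tolerance = 1e-10)
    expect_gte(cm$rmse, abs(cm$bias) - 1e-12)
  }
})

test_that("mask IoU counts cells", {
  a <- matrix(FALSE, 5, 6); a[2:3, 2:4] <- TRUE   # 2 x 3
  b <- matrix(FALSE, 5, 6); b[2:3, 3:5] <- TRUE   # 2 x 3, 2x2 overlap
  expect_equal(mask_iou(a, b), 4 / 8)
  expect_equal(mask_iou(a, a), 1)
  d <- matrix(FALSE, 5, 6); d[5, 6] <- TRUE
  expect_equal(mask_iou(a, d), 0)
  expect_warning(v <- mask_iou(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), "empty")
  expect_equal(v, 0)
  expect_error(mask_iou(a, matrix(FALSE, 2, 2)), "differ")
})

test_that("greedy matching assigns TPs by score order", {
  gt <- list(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  hit <- list(mask = gt[[1]], score = 0.9)
  mr <- match_detections(list(hit), gt, 0.5)
  expect_equal(sum(mr$tp), 1)
  expect_equal(mr$fn, 0)
  ## two overlapping detections on one gt: higher score TP, lower FP
  lo <- list(mask = gt[[1]], score = 0.3)
  mr2 <- match_detections(list(lo, hit), gt, 0.5)
  expect_equal(mr2$tp, c(TRUE, FALSE))       # sorted by descending score
  expect_equal(mr2$scores, c(0.9, 0.3))
  ## no detections: all gts are FN
  mr3 <- match_detections(list(), list(gt[[1]], gt[[1]], gt[[1]]), 0.5)
  expect_equal(mr3$fn, 3)
})

test_that("average precision reproduces the hand-enumerated PR envelope", {
  ## 2 gts, ranked outcomes [TP, FP, TP]
  scores <- c(0.9, 0.8, 0.7)
  tp <- c(TRUE, FALSE, TRUE)
  all_pt <- average_precision(scores, tp, n_gt = 2, interpolation = "all")
  expect_equal(all_pt$ap, 0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-12)
  ## independent 101-point envelope oracle
  prec <- cumsum(tp) / seq_along(tp)
  rec <- cumsum(tp) / 2
  oracle <- mean(sapply(seq(0, 1, 0.01), function(r) {
    ok <- rec >= r
    if (any(ok)) max(prec[which(ok)[1]:length(prec)]) else 0
  }))
  c101 <- average_precision(scores, tp, n_gt = 2)
  expect_equal(c101$ap, oracle, tolerance = 1e-12)
  ## degenerate cases
  expect_equal(average_precision(c(0.9, 0.8), c(TRUE, TRUE), 2)$ap, 1)
  expect_equal(average_precision(c(0.9, 0.8), c(FALSE, FALSE), 2)$ap, 0)
  expect_error(average_precision(numeric(0), logical(0), 0), "ground-truth")
})

test_that("AP is invariant to rank-preserving score transforms", {
  set.seed(31)
  scores <- runif(20)
  tp <- runif(20) > 0.5
  a1 <- average_precision(scores, tp, n_gt = 12)$ap
  a2 <- average_precision(10 + 3 * scores, tp, n_gt = 12)$ap
  expect_equal(a1, a2)
  ## removing a FP never lowers AP; removing a TP never raises it
  fp_i <- which(!tp)[1]; tp_i <- which(tp)[1]
  expect_gte(average_precision(scores[-fp_i], tp[-fp_i], 12)$ap, a1)
  expect_lte(average_precision(scores[-tp_i], tp[-tp_i], 12)$ap, a1)
})

test_that("the mAP suite behaves across IoU thresholds", {
  blob <- function(r0, r1, c0, c1) {
    m <- matrix(FALSE, 12, 12); m[r0:r1, c0:c1] <- TRUE; m
  }
  gts <- list(list(blob(1, 4, 1, 4), blob(7, 10, 7, 10)))
  perfect <- list(list(list(mask = blob(1, 4, 1, 4), score = 0.9),
                       list(mask = blob(7, 10, 7, 10), score = 0.8)))
  ms <- map_suite(perfect, gts)
  expect_equal(ms$map, 100)
  expect_equal(ms$map50, 100)
  expect_equal(ms$map75, 100)
  ## detector whose masks have IoU = 0.6 exactly: mAP50 100, mAP75 0
  ## 4x4 gt vs 4x4 detection shifted by 1 column: inter 12, union 20 -> 0.6
  shifted <- list(list(list(mask = blob(1, 4, 2, 5), score = 0.9),
                       list(mask = blob(7, 10, 8, 11), score = 0.8)))
  ms2 <- map_suite(shifted, gts)
  expect_equal(ms2$map50, 100)
  expect_equal(ms2$map75, 0)
  expect_lte(ms2$map, ms2$map50)
})

test_that("density stratification bins by count quantiles", {
  st <- stratify_by_density(1:100)
  expect_equal(as.integer(table(st$level)), rep(25L, 4))
  ## level means strictly increase for non-degenerate data
  set.seed(41)
  counts <- sample(1:120, 60, TRUE)
  st2 <- stratify_by_density(counts)
  mns <- tapply(counts, st2$level, mean)
  expect_true(all(diff(mns) > 0))
  expect_warning(st3 <- stratify_by_density(rep(7, 10)), "degenerate")
  expect_true(all(st3$level == 1))
})
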