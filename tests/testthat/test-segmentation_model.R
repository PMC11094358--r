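test_that("model building is seed-deterministic and shape-consistent", {
  cfg <- tiny64_config()
  m1 <- build_model(cfg, seed = 7)
  m2 <- build_model(cfg, seed = 7)
  expect_identical(names(m1$params), names(m2$params))
  for (nm in names(m1$params))
    expect_identical(m1$params[[nm]]$value, m2$params[[nm]]$value)
  m3 <- build_model(cfg, seed = 8)
  expect_false(identical(m1$params[["bb.stem.w"]]$value,
                         m3$params[["bb.stem.w"]]$value))
})

test_that("forward pass produces shape-consistent head outputs", {
  cfg <- tiny64_config()
  m <- build_model(cfg, seed = 0)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  out <- model_forward(m, img, grad = FALSE)
  A <- length(cfg$aspect_ratios)
  sizes <- 64 %/% cfg$fpn_strides
  expect_length(out$levels, length(sizes))
  for (i in seq_along(sizes)) {
    S <- sizes[i]
    lv <- out$levels[[i]]
    expect_equal(dim(earcount:::ad_value(lv$obj)), c(S * S * A, 1))
    expect_equal(dim(earcount:::ad_value(lv$cls)), c(S * S * A, cfg$num_classes))
    expect_equal(dim(earcount:::ad_value(lv$box)), c(S * S * A, 4))
    expect_equal(dim(earcount:::ad_value(lv$coef)), c(S * S * A, cfg$num_prototypes))
    expect_equal(dim(earcount:::ad_value(out$density[[i]])), c(S, S))
    expect_true(all(earcount:::ad_value(out$density[[i]]) >= 0))
  }
  expect_equal(dim(earcount:::ad_value(out$protos)),
               c(16, 16, cfg$num_prototypes))
  expect_equal(nrow(m$priors$priors), sum(sizes^2 * A))
  ## disabling the density branch removes its outputs and parameters
  m0 <- build_model(tiny64_config(density_branch = FALSE), seed = 0)
  out0 <- model_forward(m0, img, grad = FALSE)
  expect_null(out0$density)
  expect_false(any(startsWith(names(m0$params), "dens.")))
  expect_error(model_forward(m, array(0, c(32, 32, 3))), "expected")
})

test_that("prior matching follows the positive/negative/ignore rule", {
  priors <- rbind(c(0.3, 0.3, 0.2, 0.2),
                  c(0.7, 0.7, 0.2, 0.2),
                  c(0.5, 0.1, 0.1, 0.1))
  ## gt exactly equal to prior 1 (corner form)
  gt <- rbind(c(0.2, 0.2, 0.2, 0.2))
  asg <- match_priors(priors, gt)
  expect_equal(asg$label, c(1L, 0L, 0L))
  ## no ground truth: everything negative
  expect_equal(match_priors(priors, NULL)$label, c(0L, 0L, 0L))
  ## low-IoU gt still receives its best prior
  far <- rbind(c(0.05, 0.85, 0.1, 0.1))
  asg2 <- match_priors(priors, far)
  expect_equal(sum(asg2$label > 0), 1)
  ## the ignore band labels -1
  part <- rbind(c(0.23, 0.25, 0.2, 0.2))  # IoU with prior 1 between 0.4 and 0.5
  iou <- earcount:::box_iou_matrix(
    earcount:::boxes_cxcywh_to_corners(priors),
    earcount:::boxes_xywh_to_corners(part))
  expect_true(any(iou > 0.4 & iou < 0.5))
})

test_that("detection and classification losses match closed forms", {
  out <- toy_outputs(n_priors = 8, seed = 10)
  ## well-separated fixed priors so exactly one matches the gt
  out$priors$priors <- cbind(cx = rep(c(0.15, 0.4, 0.65, 0.9), 2),
                             cy = rep(c(0.25, 0.75), each = 4),
                             w = 0.15, h = 0.15)
  priors <- out$priors$priors
  gt <- matrix(c(priors[3, 1] - priors[3, 3] / 2, priors[3, 2] - priors[3, 4] / 2,
                 priors[3, 3], priors[3, 4]), 1)
  asg <- match_priors(priors, gt)
  expect_equal(asg$label[3], 1L)
  ## craft perfect predictions: large logits on the positive, negative elsewhere
  out$levels[[1]]$obj$value <- matrix(ifelse(asg$label > 0, 20, -20), ncol = 1)
  out$levels[[1]]$box$value <- matrix(0, 8, 4)  # exact offsets (gt == prior)
  det <- detection_loss(out, asg, gt)
  expect_lt(earcount:::ad_value(det$l_obj), 1e-6)
  expect_equal(earcount:::ad_value(det$l_box), 0)
  ## offset differing by 0.5 in one coordinate: smooth-L1 contribution 0.125
  out$levels[[1]]$box$value[3, 1] <- 0.5
  det2 <- detection_loss(out, asg, gt)
  expect_equal(earcount:::ad_value(det2$l_box), 0.125, tolerance = 1e-10)
  ## objectness 0.5 everywhere: BCE = ln 2 per counted prior
  out$levels[[1]]$obj$value <- matrix(0, 8, 1)
  det3 <- detection_loss(out, asg, gt)
  expect_equal(earcount:::ad_value(det3$l_obj), log(2), tolerance = 1e-10)
  ## uniform class scores over C = 2: cross-entropy ln 2
  out$levels[[1]]$cls$value <- matrix(0, 8, 2)
  expect_equal(earcount:::ad_value(classification_loss(out, asg)), log(2),
               tolerance = 1e-10)
  ## confident correct classes: loss near 0
  lab <- ifelse(asg$label > 0, 2, 1)
  out$levels[[1]]$cls$value <- cbind(ifelse(lab == 1, 20, -20),
                                     ifelse(lab == 2, 20, -20))
  expect_lt(earcount:::ad_value(classification_loss(out, asg)), 1e-6)
})

test_that("loss components match naive scalar-loop oracles on toy instances", {
  for (seed in 1:3) {
    out <- toy_outputs(n_priors = 8, seed = seed)
    priors <- out$priors$priors
    set.seed(seed + 50)
    g <- sample(8, 2)
    gt <- cbind(priors[g, 1] - priors[g, 3] / 2, priors[g, 2] - priors[g, 4] / 2,
                priors[g, 3], priors[g, 4])
    asg <- match_priors(priors, gt)
    det <- detection_loss(out, asg, gt)
    ## oracle objectness: positives + hardest 3:1 negatives by BCE
    obj <- as.numeric(earcount:::ad_value(out$levels[[1]]$obj))
    pos <- which(asg$label > 0); neg <- which(asg$label == 0)
    nl <- sapply(neg, function(i) oracle_bce(obj[i], 0))
    nsel <- neg[order(nl, decreasing = TRUE)[seq_len(min(length(neg), 3 * length(pos)))]]
    o_obj <- (oracle_bce(obj[pos], rep(1, length(pos))) +
                oracle_bce(obj[nsel], rep(0, length(nsel)))) /
      (length(pos) + length(nsel))
    expect_equal(earcount:::ad_value(det$l_obj), o_obj, tolerance = 1e-8)
    ## oracle box loss
    enc <- earcount:::encode_boxes(priors[pos, , drop = FALSE],
                                   gt[asg$label[pos], , drop = FALSE])
    bx <- earcount:::ad_value(out$levels[[1]]$box)[pos, , drop = FALSE]
    expect_equal(earcount:::ad_value(det$l_box),
                 oracle_smooth_l1(as.numeric(bx), as.numeric(enc)) / length(pos),
                 tolerance = 1e-8)
    ## oracle classification
    cls <- earcount:::ad_value(out$levels[[1]]$cls)
    sel <- c(pos, nsel)
    lab <- c(rep(2L, length(pos)), rep(1L, length(nsel)))
    expect_equal(earcount:::ad_value(classification_loss(out, asg)),
                 oracle_softmax_ce(cls[sel, , drop = FALSE], lab),
                 tolerance = 1e-8)
  }
})

test_that("mask assembly matches the per-pixel brute-force oracle", {
  set.seed(11)
  protos <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  coef <- rnorm(3)
  expect_equal(assemble_masks(protos, coef), oracle_assemble(protos, coef),
               tolerance = 1e-6)
  ## zero coefficients: 0.5 inside the crop box, 0 outside
  m <- assemble_masks(protos, c(0, 0, 0), bbox = c(1, 2, 3, 2))
  expect_equal(sort(unique(as.vector(m))), c(0, 0.5))
  expect_equal(m[3, 2], 0.5)   # row 3 (y in [2,4)), col 2 (x in [1,4))
  expect_equal(m[1, 1], 0)
  ## saturation: large positive prototype with unit coefficient
  big <- array(50, c(4, 4, 1))
  expect_true(all(assemble_masks(big, 1, bbox = c(0, 0, 4, 4)) > 0.999))
  expect_error(assemble_masks(protos, c(1, 2)), "length")
  ## sign-flip invariance of the product (k = 1)
  p1 <- array(rnorm(16), c(4, 4, 1))
  expect_equal(assemble_masks(p1, 2), assemble_masks(-p1, -2), tolerance = 1e-12)
})

test_that("mask loss is ln 2 for uninformative masks and 0 with no positives", {
  out <- toy_outputs(n_priors = 8, k = 3, Hp = 8, seed = 12)
  priors <- out$priors$priors
  gt <- matrix(c(priors[2, 1] - priors[2, 3] / 2, priors[2, 2] - priors[2, 4] / 2,
                 priors[2, 3], priors[2, 4]), 1)
  asg <- match_priors(priors, gt)
  gt_masks <- list(matrix(sample(0:1, 64, TRUE), 8, 8))
  ## zero prototypes => assembled logits 0 => BCE ln 2 per in-box pixel
  out$protos$value <- array(0, c(8, 8, 3))
  expect_equal(earcount:::ad_value(mask_loss(out, asg, gt_masks, gt)), log(2),
               tolerance = 1e-10)
  none <- match_priors(priors, NULL)
  expect_equal(earcount:::ad_value(mask_loss(out, none, gt_masks, gt)), 0)
})

test_that("total loss composes with the published weights", {
  lb <- total_loss(1, 0.5, 0.5, 1, 1, w_density = 1)
  expect_equal(lb$total, 9.625, tolerance = 1e-12)
  expect_equal(unname(lb$weights), c(1, 1.5, 6.125, 1))
  expect_equal(total_loss(0, 0, 0, 0, 0)$total, 0)
  ## density weight 0 reproduces the plain objective
  expect_equal(total_loss(1, 0.5, 0.5, 1, 99, w_density = 0)$total,
               1 + 1.5 * 1 + 6.125)
  expect_error(total_loss(-1, 0, 0, 0, 0), "negative")
})

test_that("density branch loss averages per-level MSEs", {
  out <- toy_outputs(with_density = TRUE, S_density = 4, seed = 13)
  tgt <- list(earcount:::ad_value(out$density[[1]]))
  expect_equal(earcount:::ad_value(density_branch_loss(out, tgt)), 0)
  out$density <- c(out$density, out$density)
  t1 <- earcount:::ad_value(out$density[[1]]) + 0.1  # mse 0.01
  t2 <- earcount:::ad_value(out$density[[2]]) + 0.2  # mse 0.04
  expect_equal(earcount:::ad_value(density_branch_loss(out, list(t1, t2))),
               0.025, tolerance = 1e-10)
  expect_error(density_branch_loss(out, list(t1)), "per pyramid level")
})

test_that("greedy NMS keeps exactly the higher-scored duplicate", {
  boxes <- rbind(c(0.1, 0.1, 0.3, 0.3), c(0.1, 0.1, 0.3, 0.3),
                 c(0.6, 0.6, 0.9, 0.9))
  keep <- earcount:::nms_greedy(boxes, c(0.4, 0.9, 0.5), 0.5)
  expect_equal(sort(keep), c(2, 3))
})

test_that("prediction on an untrained model honours its contracts", {
  m <- build_model(tiny64_config(), seed = 1)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  pred <- predict(m, img, score_threshold = 0.05)
  expect_type(pred$detections, "list")
  for (d in pred$detections) {
    expect_true(d$score >= 0.05 && d$score <= 1)
    expect_equal(dim(d$mask), c(64, 64))
    expect_true(all(d$bbox[1:2] >= 0) && all(d$bbox[1:2] + d$bbox[3:4] <= 64 + 1e-9))
  }
  expect_s3_class(pred$density, "density_map")
  ## alpha = 0 disables density modulation: scores equal the plain product
  p0 <- predict(m, img, score_threshold = 0, alpha = 0, nms_iou = 1.01)
  expect_true(length(p0$detections) > 0)
  ## count readout
  expect_equal(count_instances(list()), 0L)
  dets <- list(list(score = 0.9), list(score = 0.4))
  expect_equal(count_instances(dets, 0.5), 1)
  expect_equal(count_instances(dets, 0), 2)
})

test_that("training is reproducible and a zero learning rate is inert", {
  scenes <- lapply(1:2, function(i) make_scene64(level = 1, seed = 20 + i))
  samples <- lapply(scenes, scene_to_sample)
  m <- build_model(tiny64_config(), seed = 2)
  before <- lapply(m$params, `[[`, "value")
  res0 <- train_model(m, samples, train_config(learning_rate = 0,
                                               batch_size = 2, iterations = 1,
                                               seed = 0))
  for (nm in names(before))
    expect_identical(m$params[[nm]]$value, before[[nm]])
  ## identical seeds give identical loss histories
  mA <- build_model(tiny64_config(), seed = 3)
  hA <- train_model(mA, samples, train_config(learning_rate = 0.01,
                                              batch_size = 2, iterations = 3,
                                              seed = 5))$history
  mB <- build_model(tiny64_config(), seed = 3)
  hB <- train_model(mB, samples, train_config(learning_rate = 0.01,
                                              batch_size = 2, iterations = 3,
                                              seed = 5))$history
  expect_identical(hA, hB)
  ## every logged step satisfies the loss-decomposition identity
  expect_true(all(abs(hA$total - (hA$l_cla + 1.5 * (hA$l_obj + hA$l_box) +
                                    6.125 * hA$l_seg + hA$l_density)) < 1e-10))
})

test_that("score-threshold calibration picks the training-RMSE minimizer", {
  m <- build_model(tiny64_config(), seed = 9)
  scenes <- lapply(1:3, function(i) make_scene64(level = 1, seed = 60 + i))
  mc <- calibrate_score_threshold(m, lapply(scenes, scene_to_sample),
                                  thresholds = c(0.1, 0.3, 0.5))
  tab <- attr(mc, "calibration")
  expect_equal(nrow(tab), 3)
  expect_equal(mc$config$score_threshold, tab$threshold[which.min(tab$rmse)])
  cnt <- count_ears(mc, scenes[[1]]$image)
  expect_true(is.numeric(cnt) && cnt >= 0)
})

test_that("checkpoints round-trip through disk", {
  m <- build_model(tiny64_config(), seed = 4)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  for (nm in names(m$params))
    expect_identical(m2$params[[nm]]$value, m$params[[nm]]$value)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  o1 <- model_forward(m, img, grad = FALSE)
  o2 <- model_forward(m2, img, grad = FALSE)
  expect_equal(earcount:::ad_value(o1$levels[[1]]$obj),
               earcount:::ad_value(o2$levels[[1]]$obj))
  unlink(path)
})

test_that("ablation toggles change exactly the intended parameter sets", {
  full <- build_model(tiny64_config(attention = "gem_cbam", density_branch = TRUE), 0)
  nodens <- build_model(tiny64_config(attention = "gem_cbam", density_branch = FALSE), 0)
  cbam <- build_model(tiny64_config(attention = "cbam", density_branch = FALSE), 0)
  plain <- build_model(tiny64_config(attention = "none", density_branch = FALSE), 0)
  n_full <- names(full$params); n_nd <- names(nodens$params)
  ## density toggle adds exactly the density-head parameters
  expect_setequal(setdiff(n_full, n_nd),
                  c("dens.c1.w", "dens.c1.b", "dens.c2.w", "dens.c2.b"))
  ## attention toggle: improved CBAM carries learnable exponents, original does not
  expect_true(any(grepl("p_channel", n_nd)))
  expect_false(any(grepl("p_channel", names(cbam$params))))
  expect_false(any(startsWith(names(plain$params), "att.")))
  ## spatial conv input: 1 channel (GeM descriptor) vs 2 (avg+max stack)
  expect_equal(nrow(nodens$params[["att.1.conv_w"]]$value), 49)
  expect_equal(nrow(cbam$params[["att.1.conv_w"]]$value), 98)
  ## original-CBAM forward works too
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  out <- model_forward(cbam, img, grad = FALSE)
  expect_length(out$levels, 2)
})
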