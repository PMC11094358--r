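## Inference (decode + density-modulated scores + greedy NMS + mask
## assembly) and SGD training.

nms_greedy <- function(boxes, scores, iou_thr) {
  ord <- order(scores, decreasing = TRUE)
  keep <- integer(0)
  while (length(ord) > 0) {
    i <- ord[1]
    keep <- c(keep, i)
    if (length(ord) == 1) break
    rest <- ord[-1]
    iou <- box_iou_matrix(boxes[i, , drop = FALSE], boxes[rest, , drop = FALSE])
    ord <- rest[iou[1, ] <= iou_thr]
  }
  keep
}

#' Run inference on an image
#'
#' Decodes boxes from the priors, forms per-prior scores as objectness times
#' class probability, modulates each score by the predicted local density
#' (`s' = s (1 + alpha min(d_local, 1)) / (1 + alpha)`, sampled at the box
#' center on the prior's own pyramid level), applies greedy NMS, and
#' assembles prototype/coefficient masks for the survivors (thresholded at
#' 0.5 and cropped to the detected box).
#'
#' @param object a trained (or freshly built) `ear_model`.
#' @param image (H, W, 3) input array.
#' @param score_threshold minimum fused score to keep a detection.
#' @param nms_iou greedy NMS IoU threshold.
#' @param alpha density modulation strength; 0 disables the fusion and
#'   reduces scores to the plain detection score.
#' @param mask_threshold probability cutoff for binarizing masks.
#' @param max_detections cap on detections entering NMS.
#' @param ... unused.
#' @return list with `detections` (each `list(bbox, score, category, mask,
#'   coefficients)`; bbox in pixels, mask a full-resolution logical matrix)
#'   and `density` (fused `density_map` at input/4 resolution).
#' @export
predict.ear_model <- function(object, image, score_threshold = NULL,
                              nms_iou = NULL, alpha = NULL,
                              mask_threshold = 0.5, max_detections = 300, ...) {
  cfg <- object$config
  score_threshold <- score_threshold %||% cfg$score_threshold
  nms_iou <- nms_iou %||% cfg$nms_iou
  alpha <- alpha %||% cfg$fusion_alpha
  out <- model_forward(object, image, grad = FALSE)
  pri <- object$priors
  n <- nrow(pri$priors)
  obj <- sigmoid(as.numeric(do.call(rbind, lapply(out$levels, function(l)
    ad_value(l$obj)))))
  cls <- do.call(rbind, lapply(out$levels, function(l) ad_value(l$cls)))
  box <- do.call(rbind, lapply(out$levels, function(l) ad_value(l$box)))
  coef <- do.call(rbind, lapply(out$levels, function(l) ad_value(l$coef)))
  ex <- exp(cls - apply(cls, 1, max))
  probs <- ex / rowSums(ex)
  p_ear <- if (ncol(probs) == 2) probs[, 2] else apply(probs[, -1, drop = FALSE], 1, max)
  score <- obj * p_ear

  if (!is.null(out$density) && alpha > 0) {
    dens <- lapply(out$density, ad_value)
    dloc <- numeric(n)
    for (lv in seq_along(dens)) {
      idx <- which(pri$level == lv)
      S <- pri$sizes[lv]
      pos <- ((idx - idx[1]) %% (S * S))
      h <- (pos %% S) + 1L
      w <- (pos %/% S) + 1L
      dloc[idx] <- dens[[lv]][cbind(h, w)]
    }
    ## bounded, scene-independent modulation: priors sitting on predicted
    ## density keep their score, priors in empty regions are damped by at
    ## most 1/(1 + alpha); a global normalizer would rescale every score by
    ## a scene-dependent factor and break absolute score thresholds
    score <- score * (1 + alpha * pmin(dloc, 1)) / (1 + alpha)
  }

  boxes <- decode_boxes(pri$priors, box)
  boxes[, 1] <- pmin(pmax(boxes[, 1], 0), 1)
  boxes[, 2] <- pmin(pmax(boxes[, 2], 0), 1)
  boxes[, 3] <- pmin(boxes[, 3], 1 - boxes[, 1])
  boxes[, 4] <- pmin(boxes[, 4], 1 - boxes[, 2])

  cand <- which(score >= score_threshold)
  cand <- cand[order(score[cand], decreasing = TRUE)]
  if (length(cand) > max_detections) cand <- cand[seq_len(max_detections)]
  detections <- list()
  if (length(cand) > 0) {
    corners <- boxes_xywh_to_corners(boxes[cand, , drop = FALSE])
    keep <- nms_greedy(corners, score[cand], nms_iou)
    protos <- ad_value(out$protos)
    dpp <- dim(protos)
    sz <- cfg$input_size
    for (i in keep) {
      r <- cand[i]
      bb_px <- boxes[r, ] * sz
      bb_proto <- boxes[r, ] * c(dpp[2], dpp[1], dpp[2], dpp[1])
      m <- assemble_masks(protos, coef[r, ], bbox = bb_proto)
      full <- resize_bilinear(m, sz, sz) >= mask_threshold
      detections[[length(detections) + 1L]] <- list(
        bbox = bb_px, score = score[r], category = "ear",
        mask = full, coefficients = coef[r, ])
    }
  }
  fused <- NULL
  if (!is.null(out$density)) {
    q <- cfg$input_size %/% 4L
    lv_maps <- lapply(out$density, function(d)
      rescale_density_map(new_density_map(pmax(ad_value(d), 0),
                                          scale = 1), c(q, q)))
    fused <- new_density_map(Reduce(`+`, lapply(lv_maps, `[[`, "values")) /
                               length(lv_maps), scale = 0.25)
  }
  list(detections = detections, density = fused)
}

#' Count detected instances
#'
#' @param detections detection list from [predict.ear_model()] (either the
#'   full result or its `detections` element).
#' @param score_threshold minimum score for a detection to count.
#' @return integer count.
#' @export
count_instances <- function(detections, score_threshold = 0.3) {
  if (!is.null(detections$detections)) detections <- detections$detections
  if (length(detections) == 0) return(0L)
  sum(vapply(detections, `[[`, numeric(1), "score") >= score_threshold)
}

#' Training configuration
#'
#' Defaults follow the reference full-scale protocol (SGD, momentum 0.9,
#' learning rate 0.001, batch size 8); desk-scale runs on the tiny backbone
#' typically raise the learning rate since they train from scratch.
#'
#' @param learning_rate SGD step size.
#' @param momentum momentum coefficient.
#' @param batch_size images per iteration.
#' @param iterations number of SGD steps.
#' @param seed RNG seed controlling batch sampling.
#' @param log_file optional path receiving one JSON loss record per line.
#' @return list of class "train_config".
#' @export
train_config <- function(learning_rate = 0.001, momentum = 0.9,
                         batch_size = 8, iterations = 100, seed = 0,
                         log_file = NULL) {
  stopifnot(learning_rate >= 0, momentum >= 0, momentum < 1,
            batch_size >= 1, iterations >= 1)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 iterations = as.integer(iterations),
                 seed = as.integer(seed), log_file = log_file),
            class = "train_config")
}

## Precompute per-sample training targets (boxes, proto-resolution masks,
## density maps per level).
prepare_sample <- function(model, sample) {
  cfg <- model$config
  sz <- cfg$input_size
  q <- sz %/% 4L
  anns <- sample$annotations %||% list()
  gt_boxes <- if (length(anns) > 0)
    do.call(rbind, lapply(anns, function(a) a$bbox / sz))
  else matrix(numeric(0), 0, 4)
  gt_masks <- lapply(anns, function(a)
    rasterize_polygon(a$vertices * (q / sz), q, q))
  centers <- sample$centers %||% if (length(anns) > 0)
    do.call(rbind, lapply(anns, instance_center)) else matrix(numeric(0), 0, 2)
  targets <- NULL
  if (cfg$density_branch) {
    shapes <- lapply(cfg$fpn_strides, function(s) c(sz %/% s, sz %/% s))
    targets <- multi_scale_targets(centers, c(sz, sz), shapes,
                                   density_config(sigma = cfg$density_sigma))
  }
  assignments <- match_priors(model$priors$priors, gt_boxes)
  list(image = sample$image, gt_boxes = gt_boxes, gt_masks = gt_masks,
       density_targets = targets, assignments = assignments)
}

image_loss <- function(model, prep) {
  out <- model_forward(model, prep$image, grad = TRUE)
  det <- detection_loss(out, prep$assignments, prep$gt_boxes)
  l_cla <- classification_loss(out, prep$assignments)
  l_seg <- mask_loss(out, prep$assignments, prep$gt_masks, prep$gt_boxes)
  l_den <- if (model$config$density_branch)
    density_branch_loss(out, prep$density_targets) else 0
  total_loss(l_cla, det$l_obj, det$l_box, l_seg, l_den,
             w_density = if (model$config$density_branch)
               model$config$density_weight else 0)
}

#' Train the model with SGD
#'
#' Momentum SGD on the composite loss.  Deterministic for a fixed seed on a
#' fixed dataset: the loss history is bitwise reproducible.  Training aborts
#' with a diagnostic naming the first non-finite loss component.
#'
#' The GeM exponents (when learnable) receive gradient clipping to [-1, 1]
#' and are floored at p = 1 after each step.
#'
#' @param model an `ear_model` (updated in place; parameter nodes are
#'   mutable environments).
#' @param dataset list of samples, each `list(image, annotations, centers)`.
#' @param config a [train_config()].
#' @return list with `model` and `history` (per-iteration loss breakdown
#'   data.frame).
#' @export
train_model <- function(model, dataset, config = train_config()) {
  stopifnot(length(dataset) >= 1)
  preps <- lapply(dataset, prepare_sample, model = model)
  velocity <- list()
  hist <- vector("list", config$iterations)
  log_con <- if (!is.null(config$log_file)) file(config$log_file, "w")
  if (!is.null(log_con)) on.exit(close(log_con))
  p_names <- grep("p_channel$|p_spatial$", names(model$params), value = TRUE)
  with_seed(config$seed, {
    for (it in seq_len(config$iterations)) {
      batch <- sample.int(length(preps), config$batch_size, replace = TRUE)
      for (nm in names(model$params)) model$params[[nm]]$grad <- NULL
      node <- NULL
      comp <- c(l_cla = 0, l_obj = 0, l_box = 0, l_seg = 0, l_density = 0, total = 0)
      for (b in batch) {
        lb <- image_loss(model, preps[[b]])
        for (f in names(comp)) comp[[f]] <- comp[[f]] + lb[[f]] / length(batch)
        contrib <- ad_scale(lb$node, 1 / length(batch))
        node <- if (is.null(node)) contrib else ad_add(node, contrib)
      }
      bad <- names(comp)[!is.finite(comp)]
      if (length(bad))
        stop(sprintf("non-finite loss component '%s' at iteration %d", bad[1], it))
      ad_backward(node)
      for (nm in names(model$params)) {
        p <- model$params[[nm]]
        g <- p$grad
        if (is.null(g)) next
        if (nm %in% p_names) g <- pmin(pmax(g, -1), 1)
        v <- velocity[[nm]] %||% 0
        v <- config$momentum * v - config$learning_rate * g
        velocity[[nm]] <- v
        p$value <- p$value + v
        if (nm %in% p_names) p$value <- max(p$value, 1)
        p$grad <- NULL
      }
      hist[[it]] <- comp
      if (!is.null(log_con))
        writeLines(jsonlite::toJSON(as.list(comp), auto_unbox = TRUE), log_con)
    }
  })
  history <- as.data.frame(do.call(rbind, hist))
  history$iteration <- seq_len(nrow(history))
  list(model = model, history = history)
}

#' Calibrate the counting operating point on training data
#'
#' The counting readout (number of detections above a score threshold) needs
#' an operating point; a fixed threshold assumes well-calibrated scores,
#' which a briefly trained model does not have.  This picks the threshold
#' minimizing counting RMSE on the supplied (training) scenes — never on
#' held-out data — and stores it in the model config so later
#' [predict.ear_model()] / [count_instances()] calls use it by default.
#'
#' @param model a trained `ear_model`.
#' @param samples list of training samples (`list(image, annotations)`).
#' @param thresholds candidate score thresholds.
#' @return the model with `config$score_threshold` set; the calibration
#'   table is attached as attribute "calibration".
#' @export
calibrate_score_threshold <- function(model, samples,
                                      thresholds = seq(0.05, 0.5, by = 0.05)) {
  y <- vapply(samples, function(s) length(s$annotations), numeric(1))
  preds <- lapply(samples, function(s)
    predict(model, s$image, score_threshold = min(thresholds)))
  rmse <- vapply(thresholds, function(th) {
    y_hat <- vapply(preds, count_instances, numeric(1), score_threshold = th)
    sqrt(mean((y - y_hat)^2))
  }, numeric(1))
  best <- thresholds[which.min(rmse)]
  model$config$score_threshold <- best
  attr(model, "calibration") <- data.frame(threshold = thresholds, rmse = rmse)
  model
}

#' Count the ears in an image
#'
#' Convenience readout: predict, then count detections at the model's
#' (possibly calibrated) score threshold.
#'
#' @param model an `ear_model`.
#' @param image (H, W, 3) input array.
#' @return integer count.
#' @export
count_ears <- function(model, image) {
  count_instances(predict(model, image),
                  score_threshold = model$config$score_threshold)
}

#' Save / load a model checkpoint
#'
#' Single-file archive of the configuration, initialization seed and all
#' parameter values.
#'
#' @param model an `ear_model`.
#' @param path file path.
#' @return `load_checkpoint` returns an `ear_model`.
#' @export
save_checkpoint <- function(model, path) {
  vals <- lapply(model$params, `[[`, "value")
  saveRDS(list(config = model$config, seed = model$seed, params = vals), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$config, seed = ck$seed)
  for (nm in names(ck$params)) model$params[[nm]]$value <- ck$params[[nm]]
  model
}
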