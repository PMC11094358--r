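## Training objective: weighted sum of classification, detection (objectness
## + box regression), assembled-mask and density terms, with weights
## 1 / 1.5 / 6.125 / w_density.

LOSS_WEIGHTS <- list(cla = 1, det = 1.5, seg = 6.125)

#' Match prior boxes to ground-truth boxes
#'
#' Priors with best IoU >= `iou_pos` are positive (assigned to their best
#' gt), with IoU < `iou_neg` negative, in between ignored.  Every gt is
#' additionally guaranteed its single best-IoU prior as a positive, even
#' below threshold.
#'
#' @param priors N x 4 matrix of normalized (cx, cy, w, h) prior boxes.
#' @param gt_boxes M x 4 matrix of normalized (x, y, w, h) boxes (may have
#'   zero rows).
#' @param iou_pos,iou_neg matching thresholds.
#' @return list with `label` (integer per prior: gt index > 0, 0 = negative,
#'   -1 = ignored) and the IoU matrix.
#' @export
match_priors <- function(priors, gt_boxes, iou_pos = 0.5, iou_neg = 0.4) {
  n <- nrow(priors)
  if (is.null(gt_boxes) || length(gt_boxes) == 0 || nrow(gt_boxes) == 0)
    return(list(label = integer(n), iou = matrix(0, n, 0)))
  iou <- box_iou_matrix(boxes_cxcywh_to_corners(priors),
                        boxes_xywh_to_corners(gt_boxes))
  best_gt <- max.col(iou, ties.method = "first")
  best_iou <- iou[cbind(seq_len(n), best_gt)]
  label <- integer(n)
  label[best_iou >= iou_pos] <- best_gt[best_iou >= iou_pos]
  label[best_iou >= iou_neg & best_iou < iou_pos] <- -1L
  ## best-prior guarantee, resolving conflicts in gt order
  for (m in seq_len(ncol(iou))) {
    label[which.max(iou[, m])] <- m
  }
  list(label = label, iou = iou)
}

## SSD-style box encoding with variances (0.1, 0.2)
encode_boxes <- function(priors, gt) {
  cxg <- gt[, 1] + gt[, 3] / 2; cyg <- gt[, 2] + gt[, 4] / 2
  cbind((cxg - priors[, 1]) / priors[, 3] / 0.1,
        (cyg - priors[, 2]) / priors[, 4] / 0.1,
        log(gt[, 3] / priors[, 3]) / 0.2,
        log(gt[, 4] / priors[, 4]) / 0.2)
}

decode_boxes <- function(priors, offsets) {
  cx <- priors[, 1] + offsets[, 1] * 0.1 * priors[, 3]
  cy <- priors[, 2] + offsets[, 2] * 0.1 * priors[, 4]
  w <- priors[, 3] * exp(offsets[, 3] * 0.2)
  h <- priors[, 4] * exp(offsets[, 4] * 0.2)
  cbind(cx - w / 2, cy - h / 2, w, h)
}

concat_heads <- function(outputs, field) {
  ad_rbind(lapply(outputs$levels, `[[`, field))
}

## Counted-prior set for the objectness/classification terms: all positives
## plus the hardest negatives at 3:1 (by current objectness BCE).
counted_set <- function(obj_logits, label) {
  pos <- which(label > 0)
  neg <- which(label == 0)
  n_sel <- min(length(neg), 3L * max(1L, length(pos)))
  if (n_sel > 0) {
    neg_loss <- stable_bce_logits(obj_logits[neg], 0)
    neg <- neg[order(neg_loss, decreasing = TRUE)[seq_len(n_sel)]]
  } else neg <- integer(0)
  list(pos = pos, neg = neg)
}

#' Objectness and box-regression losses
#'
#' Objectness is binary cross-entropy over positives plus 3:1
#' hard-negative-mined negatives, averaged over the counted priors; box
#' regression is smooth-L1 on encoded offsets over positive priors, averaged
#' by the positive count.  With no positives the box term is zero and the
#' objectness term runs over mined negatives only.
#'
#' @param outputs an `ear_outputs` (or compatible list with `levels`).
#' @param assignments result of [match_priors()].
#' @param gt_boxes M x 4 normalized (x, y, w, h) matrix.
#' @return list with `l_obj`, `l_box` (ad nodes; use `$value`), `npos`.
#' @export
detection_loss <- function(outputs, assignments, gt_boxes) {
  obj <- concat_heads(outputs, "obj")
  box <- concat_heads(outputs, "box")
  label <- assignments$label
  cs <- counted_set(as.numeric(ad_value(obj)), label)
  sel <- c(cs$pos, cs$neg)
  targets <- c(rep(1, length(cs$pos)), rep(0, length(cs$neg)))
  l_obj <- if (length(sel) > 0) ad_bce_logits(obj, targets, sel = sel)
           else ad_scale(ad_sum(obj), 0)
  if (length(cs$pos) > 0) {
    pri <- outputs$priors$priors[cs$pos, , drop = FALSE]
    enc <- encode_boxes(pri, gt_boxes[label[cs$pos], , drop = FALSE])
    l_box <- ad_smooth_l1(ad_row(box, cs$pos), enc, norm = length(cs$pos))
  } else {
    l_box <- ad_scale(ad_sum(box), 0)
  }
  list(l_obj = l_obj, l_box = l_box, npos = length(cs$pos), counted = sel)
}

#' Classification loss
#'
#' Softmax cross-entropy of the per-prior class scores against the assigned
#' labels (background for mined negatives), mean-reduced over the counted
#' priors.
#'
#' @inheritParams detection_loss
#' @return an ad node (use `$value`).
#' @export
classification_loss <- function(outputs, assignments, gt_labels = NULL) {
  cls <- concat_heads(outputs, "cls")
  label <- assignments$label
  cs <- counted_set(as.numeric(ad_value(concat_heads(outputs, "obj"))), label)
  sel <- c(cs$pos, cs$neg)
  if (length(sel) == 0) return(ad_scale(ad_sum(cls), 0))
  ## class ids: 1 = background; positives take their gt class (default 2 = ear)
  lab <- rep(1L, length(sel))
  if (length(cs$pos) > 0) {
    gl <- if (is.null(gt_labels)) rep(2L, max(label)) else gt_labels
    lab[seq_along(cs$pos)] <- gl[label[cs$pos]]
  }
  ad_softmax_ce(ad_row(cls, sel), lab)
}

#' Assemble an instance mask from prototypes and coefficients
#'
#' `sigmoid(sum_j coeff_j * prototype_j)`, optionally cropped (zeroed) to a
#' bounding box given in prototype-grid pixel coordinates.
#'
#' @param prototypes (Hp, Wp, k) array or node.
#' @param coefficients length-k vector or node.
#' @param bbox optional (x, y, w, h) crop box in prototype pixels.
#' @return Hp x Wp probability matrix (or node).
#' @export
assemble_masks <- function(prototypes, coefficients, bbox = NULL) {
  d <- dim(ad_value(prototypes))
  if (length(ad_value(coefficients)) != d[3])
    stop("coefficient length does not match the number of prototypes")
  pm <- ad_gather(as_ad(prototypes), seq_len(prod(d)), c(d[1] * d[2], d[3]))
  lin <- ad_matmul(pm, as_ad(coefficients))
  mask <- ad_sigmoid(ad_gather(lin, seq_len(d[1] * d[2]), c(d[1], d[2])))
  if (!is.null(bbox)) {
    crop <- bbox_crop_mask(bbox, d[1], d[2])
    mask <- ad_mul(mask, crop)
  }
  if (is_ad(prototypes) || is_ad(coefficients)) mask else mask$value
}

## binary crop indicator: pixel centers inside the half-open box
bbox_crop_mask <- function(bbox, h, w) {
  xc <- seq_len(w) - 0.5; yc <- seq_len(h) - 0.5
  outer(yc >= bbox[2] & yc < bbox[2] + bbox[4],
        xc >= bbox[1] & xc < bbox[1] + bbox[3], `&`) * 1
}

#' Mask loss
#'
#' For every positive prior the prototype/coefficient mask is assembled at
#' prototype resolution, cropped to its ground-truth box, and compared to
#' the rasterized ground-truth polygon mask by pixelwise binary
#' cross-entropy normalized by the crop area; the per-instance losses are
#' averaged.
#'
#' @inheritParams detection_loss
#' @param gt_masks list (one per gt instance) of Hp x Wp binary matrices.
#' @param gt_boxes M x 4 normalized (x, y, w, h) boxes, used for cropping.
#' @return an ad node (use `$value`).
#' @export
mask_loss <- function(outputs, assignments, gt_masks, gt_boxes) {
  label <- assignments$label
  pos <- which(label > 0)
  protos <- outputs$protos
  dp <- dim(ad_value(protos))
  if (length(pos) == 0) return(ad_scale(ad_sum(protos), 0))
  coef <- concat_heads(outputs, "coef")
  pm <- ad_gather(protos, seq_len(prod(dp)), c(dp[1] * dp[2], dp[3]))
  cm <- ad_row(coef, pos)                       # npos x k
  logits <- ad_matmul(pm, ad_make(t(ad_value(cm)), list(cm), function(g) list(t(g))))
  tgt <- matrix(0, dp[1] * dp[2], length(pos))
  msk <- matrix(0, dp[1] * dp[2], length(pos))
  for (j in seq_along(pos)) {
    g <- label[pos[j]]
    tgt[, j] <- as.numeric(gt_masks[[g]])
    bb <- gt_boxes[g, ] * c(dp[2], dp[1], dp[2], dp[1])
    msk[, j] <- as.numeric(bbox_crop_mask(bb, dp[1], dp[2]))
  }
  colnorm <- pmax(colSums(msk), 1)
  ad_masked_bce_logits(logits, tgt, msk, colnorm)
}

#' Density-branch loss
#'
#' Mean over pyramid levels of the density-map MSE between the predicted
#' and target maps at that level's resolution.
#'
#' @param outputs an `ear_outputs` with a density branch.
#' @param targets list of `density_map`s (one per level), e.g. from
#'   [multi_scale_targets()].
#' @return an ad node (use `$value`).
#' @export
density_branch_loss <- function(outputs, targets) {
  if (is.null(outputs$density)) stop("model has no density branch")
  if (length(outputs$density) != length(targets))
    stop("one density target per pyramid level is required")
  terms <- lapply(seq_along(targets), function(i)
    ad_mse_to(outputs$density[[i]], as_density_values(targets[[i]])))
  acc <- terms[[1]]
  if (length(terms) > 1) for (i in 2:length(terms)) acc <- ad_add(acc, terms[[i]])
  ad_scale(acc, 1 / length(terms))
}

#' Compose the total training loss
#'
#' `total = 1 * l_cla + 1.5 * (l_obj + l_box) + 6.125 * l_seg +
#' w_density * l_density`.  Components may be numbers or ad nodes; the
#' returned breakdown carries numeric values plus the composite node when
#' gradients are being tracked.
#'
#' @param l_cla,l_obj,l_box,l_seg,l_density loss components (>= 0).
#' @param w_density weight of the density term.
#' @return list of class "loss_breakdown" with the components, `weights`,
#'   `total`, and `node` (NULL for plain numeric inputs).
#' @export
total_loss <- function(l_cla, l_obj, l_box, l_seg, l_density = 0,
                       w_density = 1) {
  comp <- list(l_cla = l_cla, l_obj = l_obj, l_box = l_box,
               l_seg = l_seg, l_density = l_density)
  vals <- lapply(comp, function(x) as.numeric(ad_value(x)))
  bad <- names(vals)[vapply(vals, function(v) !is.finite(v) || v < 0, logical(1))]
  if (length(bad))
    stop("non-finite or negative loss component: ", paste(bad, collapse = ", "))
  any_node <- any(vapply(comp, is_ad, logical(1)))
  node <- NULL
  if (any_node) {
    node <- ad_add(ad_scale(as_ad(comp$l_cla), LOSS_WEIGHTS$cla),
                   ad_scale(ad_add(as_ad(comp$l_obj), as_ad(comp$l_box)),
                            LOSS_WEIGHTS$det))
    node <- ad_add(node, ad_scale(as_ad(comp$l_seg), LOSS_WEIGHTS$seg))
    if (w_density != 0 || is_ad(comp$l_density))
      node <- ad_add(node, ad_scale(as_ad(comp$l_density), w_density))
    total <- as.numeric(node$value)
  } else {
    total <- LOSS_WEIGHTS$cla * vals$l_cla +
      LOSS_WEIGHTS$det * (vals$l_obj + vals$l_box) +
      LOSS_WEIGHTS$seg * vals$l_seg + w_density * vals$l_density
  }
  structure(c(vals, list(weights = c(w_cla = LOSS_WEIGHTS$cla,
                                     w_det = LOSS_WEIGHTS$det,
                                     w_seg = LOSS_WEIGHTS$seg,
                                     w_density = w_density),
                         total = total, node = node)),
            class = "loss_breakdown")
}
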