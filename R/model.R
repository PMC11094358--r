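## YOLACT-style model: backbone + FPN + shared prediction heads + Protonet
## + auxiliary density branch, with GeM-CBAM (or original CBAM) attention on
## the backbone stages that feed the FPN.

#' Model configuration
#'
#' @param backbone `"tiny"` (a reduced-width few-stage CNN for desk-scale
#'   CPU experiments) or `"resnet101"` (bottleneck-residual stage layout of
#'   the full-scale model).
#' @param input_size square input side in pixels (128 for tiny, 1024 for
#'   resnet101).
#' @param num_prototypes number of prototype masks k.
#' @param num_classes number of classes C including background (2: background
#'   + "ear").
#' @param fpn_channels channel width of the pyramid.
#' @param aspect_ratios prior-box aspect ratios per position.
#' @param attention one of `"gem_cbam"` (GeM-pooled CBAM), `"cbam"`
#'   (original max+average pooled CBAM) or `"none"`.
#' @param attention_config optional [cbam_config()] overrides (list of
#'   arguments except `channels`).
#' @param density_branch enable the auxiliary density regression head.
#' @param density_sigma Gaussian sigma (pixels at `input_size`) for density
#'   targets; default scales the reference 8 px at 1024 to the input size.
#' @param density_weight weight of the density MSE term in the total loss.
#' @param score_threshold,nms_iou default prediction thresholds.
#' @param fusion_alpha strength of density modulation of detection scores.
#' @return list of class "ear_model_config".
#' @export
model_config <- function(backbone = c("tiny", "resnet101"),
                         input_size = NULL,
                         num_prototypes = NULL,
                         num_classes = 2L,
                         fpn_channels = NULL,
                         aspect_ratios = c(1, 0.5, 2),
                         attention = c("gem_cbam", "cbam", "none"),
                         attention_config = list(),
                         density_branch = TRUE,
                         density_sigma = NULL,
                         density_weight = 1,
                         score_threshold = 0.3,
                         nms_iou = 0.5,
                         fusion_alpha = 1) {
  backbone <- match.arg(backbone)
  attention <- match.arg(attention)
  tiny <- backbone == "tiny"
  input_size <- as.integer(input_size %||% if (tiny) 128L else 1024L)
  num_prototypes <- as.integer(num_prototypes %||% if (tiny) 8L else 32L)
  fpn_channels <- as.integer(fpn_channels %||% if (tiny) 32L else 256L)
  stopifnot(num_prototypes >= 1, num_classes >= 2)
  strides <- if (tiny) c(8L, 16L) else c(8L, 16L, 32L)
  ## one prior scale per level, in pixels at the input resolution
  scales <- strides * if (tiny) 2 else 4
  if (any(input_size %% (strides * 2) != 0))
    stop("input_size must be divisible by twice the largest stride")
  structure(list(
    backbone = backbone, input_size = input_size,
    num_prototypes = num_prototypes, num_classes = as.integer(num_classes),
    fpn_channels = fpn_channels, fpn_strides = strides,
    prior_scales = scales, aspect_ratios = aspect_ratios,
    attention = attention, attention_config = attention_config,
    density_branch = isTRUE(density_branch),
    density_sigma = density_sigma %||% max(1, 8 * input_size / 1024),
    density_weight = density_weight,
    score_threshold = score_threshold, nms_iou = nms_iou,
    fusion_alpha = fusion_alpha), class = "ear_model_config")
}

## Backbone stage widths; the last `n_fpn` stages feed the FPN.
backbone_spec <- function(config) {
  if (config$backbone == "tiny") {
    list(kind = "tiny", widths = c(16L, 32L, 48L, 64L), fpn_stages = 3:4)
  } else {
    list(kind = "resnet", blocks = c(3L, 4L, 23L, 3L),
         widths = c(256L, 512L, 1024L, 2048L), fpn_stages = 2:4)
  }
}

he_w <- function(k, cin, cout) {
  matrix(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))), k * k * cin, cout)
}

## Parameter initialisation; names are stable so checkpoints and ablation
## comparisons are well-defined.  Draws from the current RNG stream.
init_model_params <- function(config) {
  P <- list()
  conv <- function(name, k, cin, cout, bias = TRUE) {
    P[[paste0(name, ".w")]] <<- ad_param(he_w(k, cin, cout))
    if (bias) P[[paste0(name, ".b")]] <<- ad_param(numeric(cout))
    invisible()
  }
  bs <- backbone_spec(config)
  if (bs$kind == "tiny") {
    w <- bs$widths
    conv("bb.stem", 3, 3, w[1])
    for (s in 2:4) {
      conv(sprintf("bb.s%d.c1", s), 3, w[s - 1], w[s])
      conv(sprintf("bb.s%d.c2", s), 3, w[s], w[s])
    }
    fpn_in <- w[bs$fpn_stages]
  } else {
    conv("bb.stem", 7, 3, 64)
    cin <- 64L
    for (s in seq_along(bs$blocks)) {
      wout <- bs$widths[s]; mid <- wout %/% 4L
      for (b in seq_len(bs$blocks[s])) {
        pre <- sprintf("bb.s%d.b%d", s, b)
        conv(paste0(pre, ".c1"), 1, if (b == 1) cin else wout, mid)
        conv(paste0(pre, ".c2"), 3, mid, mid)
        conv(paste0(pre, ".c3"), 1, mid, wout)
        if (b == 1) conv(paste0(pre, ".proj"), 1, cin, wout)
      }
      cin <- wout
    }
    fpn_in <- bs$widths[bs$fpn_stages]
  }
  ## attention blocks on the FPN-feeding stages
  if (config$attention != "none") {
    for (i in seq_along(fpn_in)) {
      cc <- do.call(cbam_config, c(list(channels = fpn_in[i]),
                                   config$attention_config))
      if (config$attention == "gem_cbam") {
        wts <- init_cbam_weights(cc)
      } else {
        wts <- init_orig_cbam_weights(cc)
      }
      for (nm in names(wts))
        P[[sprintf("att.%d.%s", i, nm)]] <- wts[[nm]]
      attr(P, "cbam_configs") <- c(attr(P, "cbam_configs"), list(cc))
    }
  }
  d <- config$fpn_channels
  for (i in seq_along(fpn_in)) conv(sprintf("fpn.lat%d", i), 1, fpn_in[i], d)
  for (i in seq_along(fpn_in)) conv(sprintf("fpn.out%d", i), 3, d, d)
  ## shared prediction head
  A <- length(config$aspect_ratios)
  conv("head.tower", 3, d, d)
  conv("head.obj", 1, d, A)
  ## prior-probability initialization: start objectness near p = 0.1 so the
  ## dominant negatives do not produce a destabilizing early gradient spike
  P[["head.obj.b"]]$value[] <- -log((1 - 0.1) / 0.1)
  conv("head.cls", 1, d, A * config$num_classes)
  conv("head.box", 1, d, A * 4L)
  conv("head.coef", 1, d, A * config$num_prototypes)
  ## Protonet: operates on the finest level, upsampled to input/4
  conv("proto.c1", 3, d, d)
  conv("proto.c2", 3, d, d)
  conv("proto.out", 1, d, config$num_prototypes)
  ## density head (shared across levels)
  if (config$density_branch) {
    conv("dens.c1", 3, d, 16)
    conv("dens.c2", 3, 16, 1)
  }
  P
}

## Original CBAM weights: shared MLP applied to max- and average-pooled
## descriptors, spatial conv over the 2-channel [avg; max] stack.  No
## learnable pooling exponents.
init_orig_cbam_weights <- function(config) {
  C <- config$channels; Hd <- config$hidden; k <- config$spatial_kernel
  mk <- function(n, fan_in) ad_param(array(rnorm(prod(n), 0, sqrt(2 / fan_in)), dim = n))
  list(w1 = mk(c(Hd, C), C), b1 = ad_param(numeric(Hd)),
       w2 = mk(c(C, Hd), Hd), b2 = ad_param(numeric(C)),
       conv_w = mk(c(k * k * 2, 1), k * k * 2), conv_b = ad_param(0))
}

## max over spatial positions per channel, with subgradient backward
ad_max_spatial <- function(a) {
  a <- as_ad(a)
  d <- dim(a$value)
  m <- matrix(a$value, d[1] * d[2], d[3])
  wm <- max.col(t(m), ties.method = "first")
  v <- m[cbind(wm, seq_len(d[3]))]
  ad_make(v, list(a), function(g) {
    out <- array(0, d)
    flat <- wm + (seq_len(d[3]) - 1L) * d[1] * d[2]
    out[flat] <- as.numeric(g)
    list(out)
  })
}

ad_max_channels <- function(a) {
  a <- as_ad(a)
  d <- dim(a$value)
  m <- matrix(a$value, d[1] * d[2], d[3])
  wm <- max.col(m, ties.method = "first")
  v <- matrix(m[cbind(seq_len(d[1] * d[2]), wm)], d[1], d[2])
  ad_make(v, list(a), function(g) {
    out <- array(0, d)
    flat <- seq_len(d[1] * d[2]) + (wm - 1L) * d[1] * d[2]
    out[flat] <- as.numeric(g)
    list(out)
  })
}

orig_cbam <- function(x, config, wts) {
  mlp <- function(desc) ad_add(ad_matmul(wts$w2,
    ad_relu(ad_add(ad_matmul(wts$w1, desc), wts$b1))), wts$b2)
  cg <- ad_sigmoid(ad_add(mlp(ad_mean_spatial(x)), mlp(ad_max_spatial(x))))
  cg <- ad_gather(cg, seq_len(config$channels), NULL)
  x1 <- ad_mul(x, cg)
  d <- dim(ad_value(x1))[1:2]
  avg <- ad_mean_channels(x1); mx <- ad_max_channels(x1)
  stack <- ad_make(array(c(ad_value(avg), ad_value(mx)), c(d[1], d[2], 2)),
                   list(avg, mx), function(g)
                     list(array(g[, , 1], d), array(g[, , 2], d)))
  conv <- ad_conv2d(stack, wts$conv_w, wts$conv_b, k = config$spatial_kernel)
  sg <- ad_sigmoid(ad_gather(conv, seq_len(prod(d)), d))
  ad_mul(x1, sg)
}

## -- priors ------------------------------------------------------------------

## Prior grid for one level: rows ordered (h fastest, then w, then aspect),
## matching the column-major flattening of the head output arrays.
level_priors <- function(S, scale_norm, aspect_ratios) {
  g <- expand.grid(h = seq_len(S), w = seq_len(S), a = seq_along(aspect_ratios))
  ar <- aspect_ratios[g$a]
  cbind(cx = (g$w - 0.5) / S, cy = (g$h - 0.5) / S,
        w = pmin(1, scale_norm * sqrt(ar)), h = pmin(1, scale_norm / sqrt(ar)))
}

#' Build the prior-box grid for a model configuration
#' @param config an `ear_model_config`.
#' @return list with `priors` (N x 4 matrix of normalized (cx, cy, w, h)),
#'   `level` (level index per prior) and per-level sizes.
#' @export
build_priors <- function(config) {
  A <- length(config$aspect_ratios)
  pls <- list(); lev <- integer(0); sizes <- integer(0)
  for (i in seq_along(config$fpn_strides)) {
    S <- config$input_size %/% config$fpn_strides[i]
    p <- level_priors(S, config$prior_scales[i] / config$input_size,
                      config$aspect_ratios)
    pls[[i]] <- p
    lev <- c(lev, rep(i, nrow(p)))
    sizes <- c(sizes, S)
  }
  list(priors = do.call(rbind, pls), level = lev, sizes = sizes, A = A)
}

#' Build the segmentation/counting model
#'
#' Deterministic parameter initialization under `seed`; attention blocks are
#' inserted after each backbone stage that feeds the FPN, and (when enabled)
#' a density head with softplus output runs on every pyramid level.
#'
#' @param config a [model_config()].
#' @param seed integer seed for weight initialization.
#' @return object of class "ear_model".
#' @export
build_model <- function(config = model_config(), seed = 0) {
  params <- with_seed(seed, init_model_params(config))
  structure(list(config = config, params = params,
                 cbam_configs = attr(params, "cbam_configs"),
                 priors = build_priors(config), seed = as.integer(seed)),
            class = "ear_model")
}

#' @export
print.ear_model <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$value), numeric(1)))
  cat(sprintf("<ear_model backbone=%s input=%d attention=%s density=%s params=%s>\n",
              x$config$backbone, x$config$input_size, x$config$attention,
              x$config$density_branch, format(np, big.mark = ",")))
  invisible(x)
}

## cached head-extraction index: (S,S,A*d) array -> (S*S*A, d) matrix
head_gather_idx <- function(S, A, d) {
  key <- paste("hg", S, A, d, sep = "_")
  hit <- ad_env$im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  r <- expand.grid(h = seq_len(S), w = seq_len(S), a = seq_len(A))
  idx <- matrix(0L, S * S * A, d)
  for (j in seq_len(d))
    idx[, j] <- r$h + (r$w - 1L) * S + ((r$a - 1L) * d + j - 1L) * S * S
  res <- list(idx = idx, plan = scatter_plan(idx))
  ad_env$im2col_cache[[key]] <- res
  res
}

forward_backbone <- function(model, x) {
  P <- model$params
  cv <- function(nm, x, k, s = 1L)
    ad_conv2d(x, P[[paste0(nm, ".w")]], P[[paste0(nm, ".b")]], k = k, stride = s)
  bs <- backbone_spec(model$config)
  feats <- list()
  if (bs$kind == "tiny") {
    h <- ad_relu(cv("bb.stem", x, 3, 2L))
    stages <- list()
    for (s in 2:4) {
      h <- ad_relu(cv(sprintf("bb.s%d.c1", s), h, 3, 2L))
      h <- ad_relu(cv(sprintf("bb.s%d.c2", s), h, 3, 1L))
      stages[[s]] <- h
    }
    feats <- stages[bs$fpn_stages]
  } else {
    h <- ad_relu(cv("bb.stem", x, 7, 2L))
    stages <- list()
    for (s in seq_along(bs$blocks)) {
      for (b in seq_len(bs$blocks[s])) {
        pre <- sprintf("bb.s%d.b%d", s, b)
        stride <- if (b == 1 && s > 1) 2L else 1L
        idn <- if (b == 1) ad_conv2d(h, P[[paste0(pre, ".proj.w")]],
                                     P[[paste0(pre, ".proj.b")]], k = 1, stride = stride)
               else h
        y <- ad_relu(cv(paste0(pre, ".c1"), h, 1, stride))
        y <- ad_relu(cv(paste0(pre, ".c2"), y, 3, 1L))
        y <- cv(paste0(pre, ".c3"), y, 1, 1L)
        h <- ad_relu(ad_add(y, idn))
      }
      stages[[s]] <- h
    }
    feats <- stages[bs$fpn_stages]
  }
  ## attention on the FPN-feeding stages
  if (model$config$attention != "none") {
    for (i in seq_along(feats)) {
      wts <- list()
      pre <- sprintf("att.%d.", i)
      for (nm in names(P)[startsWith(names(P), pre)])
        wts[[substring(nm, nchar(pre) + 1)]] <- P[[nm]]
      cc <- model$cbam_configs[[i]]
      feats[[i]] <- if (model$config$attention == "gem_cbam")
        gem_cbam(feats[[i]], cc, wts)
      else orig_cbam(feats[[i]], cc, wts)
    }
  }
  feats
}

#' Forward pass
#'
#' Runs the network on one image and returns the raw head outputs: per-prior
#' objectness/class/box/mask-coefficient predictions per pyramid level, the
#' prototype masks, and (when enabled) the predicted density map per level.
#'
#' @param model an `ear_model`.
#' @param image (H, W, 3) array matching the configured input size.
#' @param grad build the gradient graph (TRUE during training)?
#' @return list of class "ear_outputs"; numeric values live in `$value`
#'   fields of the contained nodes.
#' @export
model_forward <- function(model, image, grad = TRUE) {
  cfg <- model$config
  d <- dim(image)
  if (is.null(d) || length(d) != 3 || d[1] != cfg$input_size || d[2] != cfg$input_size || d[3] != 3)
    stop(sprintf("expected a %d x %d x 3 image", cfg$input_size, cfg$input_size))
  P <- model$params
  cv <- function(nm, x, k, s = 1L)
    ad_conv2d(x, P[[paste0(nm, ".w")]], P[[paste0(nm, ".b")]], k = k, stride = s)
  old_grad <- ad_env$grad_enabled %||% TRUE
  ad_env$grad_enabled <- grad
  on.exit(ad_env$grad_enabled <- old_grad)

  feats <- forward_backbone(model, as_ad(image))
  ## FPN: lateral 1x1, top-down nearest upsample + add, 3x3 smoothing
  nl <- length(feats)
  lat <- lapply(seq_len(nl), function(i) cv(sprintf("fpn.lat%d", i), feats[[i]], 1))
  pyr <- vector("list", nl)
  pyr[[nl]] <- lat[[nl]]
  for (i in rev(seq_len(nl - 1)))
    pyr[[i]] <- ad_add(lat[[i]], ad_upsample2(pyr[[i + 1]]))
  pyr <- lapply(seq_len(nl), function(i) ad_relu(cv(sprintf("fpn.out%d", i), pyr[[i]], 3)))

  A <- length(cfg$aspect_ratios)
  k <- cfg$num_prototypes
  C <- cfg$num_classes
  levels <- lapply(seq_len(nl), function(i) {
    h <- ad_relu(cv("head.tower", pyr[[i]], 3))
    S <- dim(ad_value(h))[1]
    take <- function(node, dd) {
      hg <- head_gather_idx(S, A, dd)
      ad_gather(node, hg$idx, c(S * S * A, dd), plan = hg$plan)
    }
    list(obj = take(cv("head.obj", h, 1), 1L),
         cls = take(cv("head.cls", h, 1), C),
         box = take(cv("head.box", h, 1), 4L),
         coef = ad_tanh(take(cv("head.coef", h, 1), k)),
         shape = c(S, S))
  })

  pr <- ad_relu(cv("proto.c1", pyr[[1]], 3))
  pr <- ad_upsample2(pr)
  pr <- ad_relu(cv("proto.c2", pr, 3))
  protos <- ad_relu(cv("proto.out", pr, 1))

  density <- NULL
  if (cfg$density_branch) {
    density <- lapply(seq_len(nl), function(i) {
      hd <- ad_relu(cv("dens.c1", pyr[[i]], 3))
      dm <- ad_softplus(cv("dens.c2", hd, 3))
      S <- dim(ad_value(dm))[1]
      ad_gather(dm, seq_len(S * S), c(S, S))
    })
  }
  structure(list(levels = levels, protos = protos, density = density,
                 priors = model$priors, config = cfg),
            class = "ear_outputs")
}
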