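## Generalized-mean (GeM) pooling and the GeM-pooled CBAM attention block.
##
## Feature maps are (H, W, C) arrays.  Every operation accepts either a
## plain array (returning plain numerics) or an `ad_node` (returning a node
## through which gradients flow), so the same implementation serves both
## inference-style calls and training.

#' GeM pooling parameters
#'
#' @param p power-mean exponent, >= 1.  `p = 1` is average pooling; large
#'   `p` approaches max pooling.
#' @param epsilon positive clamp floor applied before exponentiation so
#'   fractional powers stay real on non-positive activations.
#' @return list of class "gem_params".
#' @export
gem_params <- function(p = 3, epsilon = 1e-6) {
  pv <- if (is_ad(p)) p$value else p
  stopifnot(pv >= 1, epsilon > 0)
  structure(list(p = p, epsilon = epsilon), class = "gem_params")
}

check_finite_map <- function(x) {
  if (!all(is.finite(ad_value(x)))) stop("feature map contains non-finite values")
  invisible(x)
}

## Core power-mean: given a node of positive values and a mean-reduction op,
## compute (mean(x^p))^(1/p) with p a scalar (node or numeric).
## For numerical stability at large p the group maximum M is factored out:
## GeM(x) = M * (mean((x/M)^p))^(1/p), an exact identity for any fixed
## M > 0, so treating M as a constant leaves the gradient exact.
gem_reduce <- function(x, p, epsilon, reducer) {
  xc <- ad_clamp_min(as_ad(x), epsilon)
  mx <- if (identical(reducer, ad_mean_spatial)) {
    d <- dim(xc$value)
    apply(xc$value, 3, max)
  } else {
    apply(xc$value, c(1, 2), max)
  }
  ratio <- ad_mul(xc, bc_inverse_const(mx))
  m <- reducer(ad_pow(ratio, p))
  root <- if (is_ad(p)) {
    ad_exp(ad_mul(ad_log(m), ad_recip(p)))
  } else {
    ad_pow(m, 1 / p)
  }
  ad_mul(root, ad_make(mx))
}

bc_inverse_const <- function(mx) ad_make(1 / mx)

#' GeM pooling over the spatial extent
#'
#' Per-channel generalized mean
#' `GeM(x)_c = ((1 / (H W)) * sum_ij x_{ijc}^p)^(1/p)`; `p = 1` reproduces
#' average pooling exactly and large `p` approaches the spatial maximum.
#'
#' @param map (H, W, C) feature map (array or `ad_node`).
#' @param params a [gem_params()].
#' @return length-C vector (or node) of pooled descriptors.
#' @export
gem_pool_spatial <- function(map, params = gem_params()) {
  check_finite_map(map)
  out <- gem_reduce(map, params$p, params$epsilon, ad_mean_spatial)
  if (is_ad(map) || is_ad(params$p)) out else out$value
}

#' GeM pooling across channels
#'
#' Each spatial position is reduced to the generalized mean of its C channel
#' values, producing the single-channel descriptor used by the spatial
#' attention branch.
#'
#' @inheritParams gem_pool_spatial
#' @return H x W matrix (or node).
#' @export
gem_pool_channelwise <- function(map, params = gem_params()) {
  check_finite_map(map)
  out <- gem_reduce(map, params$p, params$epsilon, ad_mean_channels)
  if (is_ad(map) || is_ad(params$p)) out else out$value
}

#' CBAM configuration with GeM pooling
#'
#' All pooling inside the block is generalized-mean pooling: the channel
#' branch pools one GeM descriptor over space (one exponent, initial value
#' 11) and the spatial branch pools one GeM descriptor over channels
#' (initial exponent 19), in place of the original max+average pooled pairs.
#'
#' @param channels number of feature channels C.
#' @param reduction_ratio bottleneck ratio of the shared channel MLP; the
#'   hidden width is clamped to at least 1.
#' @param p_channel_init,p_spatial_init initial GeM exponents for the
#'   channel and spatial branches.
#' @param spatial_kernel odd size of the spatial-attention convolution.
#' @param p_learnable should the exponents be trained (floored at 1)?
#' @return list of class "cbam_config".
#' @export
cbam_config <- function(channels, reduction_ratio = 16,
                        p_channel_init = 11, p_spatial_init = 19,
                        spatial_kernel = 7, p_learnable = TRUE) {
  stopifnot(channels >= 1, reduction_ratio >= 1,
            p_channel_init >= 1, p_spatial_init >= 1)
  if (spatial_kernel %% 2 == 0) stop("spatial_kernel must be odd")
  structure(list(channels = as.integer(channels),
                 reduction_ratio = as.integer(reduction_ratio),
                 hidden = max(1L, channels %/% as.integer(reduction_ratio)),
                 p_channel_init = p_channel_init,
                 p_spatial_init = p_spatial_init,
                 spatial_kernel = as.integer(spatial_kernel),
                 p_learnable = isTRUE(p_learnable)),
            class = "cbam_config")
}

#' Initialize GeM-CBAM weights
#'
#' He-normal MLP and convolution weights plus the two GeM exponents (as
#' parameter nodes when learnable).  Draws from the current RNG stream.
#'
#' @param config a [cbam_config()].
#' @return list of weight nodes: `w1`, `b1`, `w2`, `b2` (channel MLP),
#'   `conv_w`, `conv_b` (spatial conv), `p_channel`, `p_spatial`.
#' @export
init_cbam_weights <- function(config) {
  C <- config$channels; Hd <- config$hidden; k <- config$spatial_kernel
  mk <- function(n, fan_in) ad_param(array(rnorm(prod(n), 0, sqrt(2 / fan_in)), dim = n))
  pc <- config$p_channel_init; ps <- config$p_spatial_init
  list(
    w1 = mk(c(Hd, C), C), b1 = ad_param(numeric(Hd)),
    w2 = mk(c(C, Hd), Hd), b2 = ad_param(numeric(C)),
    conv_w = mk(c(k * k * 1, 1), k * k),
    conv_b = ad_param(0),
    p_channel = if (config$p_learnable) ad_param(pc) else pc,
    p_spatial = if (config$p_learnable) ad_param(ps) else ps)
}

#' Channel attention gate
#'
#' `sigmoid(MLP(GeM_spatial(map)))`: the GeM-pooled per-channel descriptor
#' passes through the shared bottleneck MLP (C -> C/r -> C) and a sigmoid,
#' giving one multiplicative gate per channel, strictly inside (0, 1).
#'
#' @param map (H, W, C) feature map (array or node).
#' @param config a [cbam_config()].
#' @param weights weights from [init_cbam_weights()].
#' @return length-C gate vector (or node).
#' @export
channel_attention <- function(map, config, weights) {
  d <- dim(ad_value(map))
  if (d[3] != config$channels) stop("channel count does not match config")
  desc <- gem_reduce(map, weights$p_channel, 1e-6, ad_mean_spatial)
  h <- ad_relu(ad_add(ad_matmul(weights$w1, desc), weights$b1))
  gate <- ad_sigmoid(ad_add(ad_matmul(weights$w2, h), weights$b2))
  gate <- ad_gather(gate, seq_len(config$channels), NULL)  # drop matrix shape
  if (is_ad(map)) gate else as.numeric(gate$value)
}

#' Spatial attention gate
#'
#' `sigmoid(conv_k(GeM_channelwise(map)))`: the channel-pooled single-map
#' descriptor is convolved with one k x k kernel (same padding) and passed
#' through a sigmoid, giving an H x W gate in (0, 1).
#'
#' @inheritParams channel_attention
#' @return H x W gate matrix (or node).
#' @export
spatial_attention <- function(map, config, weights) {
  pooled <- gem_reduce(map, weights$p_spatial, 1e-6, ad_mean_channels)
  d <- dim(ad_value(pooled))
  pooled3 <- ad_gather(pooled, seq_len(prod(d)), c(d[1], d[2], 1L))
  conv <- ad_conv2d(pooled3, weights$conv_w, weights$conv_b,
                    k = config$spatial_kernel, stride = 1L)
  gate <- ad_sigmoid(ad_gather(conv, seq_len(prod(d)), c(d[1], d[2])))
  if (is_ad(map)) gate else gate$value
}

#' GeM-CBAM attention block
#'
#' Sequential CBAM gating with every pooling operator replaced by GeM:
#' channels are gated first, then the channel-refined map is gated
#' spatially.  Because both gates lie in (0, 1) the output is elementwise
#' bounded by the input magnitude, and the output shape equals the input
#' shape.
#'
#' @inheritParams channel_attention
#' @return (H, W, C) feature map (array or node).
#' @export
gem_cbam <- function(map, config, weights) {
  x <- as_ad(map)
  cg <- channel_attention(x, config, weights)
  x1 <- ad_mul(x, cg)
  sg <- spatial_attention(x1, config, weights)
  out <- ad_mul(x1, sg)
  if (is_ad(map)) out else out$value
}
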