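## Minimal reverse-mode automatic differentiation over base-R arrays.
##
## A node is an environment with $value (numeric array/matrix/vector),
## $parents (list of nodes), $backfun (function(grad) -> list of gradients
## aligned with $parents), $requires_grad, $grad and a unique $id.
## Convolutions are im2col gathers followed by BLAS matrix products.
## Feature maps are (H, W, C) arrays; losses are length-1 nodes.

ad_env <- new.env(parent = emptyenv())
ad_env$counter <- 0L
ad_env$grad_enabled <- TRUE
ad_env$im2col_cache <- new.env(parent = emptyenv())
## gradient tape: nodes appended in creation order, which is a topological
## order by construction (a node's parents always exist before it)
ad_env$tape <- vector("list", 4096L)
ad_env$tape_n <- 0L

ad_make <- function(value, parents = list(), backfun = NULL) {
  rg <- FALSE
  if (ad_env$grad_enabled) {
    for (p in parents) if (p$requires_grad) { rg <- TRUE; break }
  }
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- if (rg) parents else list()
  e$backfun <- if (rg) backfun else NULL
  e$requires_grad <- rg
  e$grad <- NULL
  ad_env$counter <- ad_env$counter + 1L
  e$id <- ad_env$counter
  class(e) <- "ad_node"
  if (rg) {
    n <- ad_env$tape_n + 1L
    if (n > length(ad_env$tape)) length(ad_env$tape) <- 2L * n
    ad_env$tape[[n]] <- e
    ad_env$tape_n <- n
  }
  e
}

#' Wrap a value as an autodiff constant
#' @param x numeric value or an existing node.
#' @return an `ad_node`.
#' @keywords internal
as_ad <- function(x) {
  if (inherits(x, "ad_node")) return(x)
  ad_make(x)
}

is_ad <- function(x) inherits(x, "ad_node")

#' Create a trainable parameter node
#' @param value initial numeric value.
#' @return an `ad_node` with `requires_grad = TRUE`.
#' @keywords internal
ad_param <- function(value) {
  e <- ad_make(value)
  e$requires_grad <- TRUE
  e$is_param <- TRUE
  e
}

ad_value <- function(x) if (is_ad(x)) x$value else x

## Reverse pass from a scalar node; fills $grad on every reachable node
## that requires gradients.  Walks the creation-order tape backwards
## (nodes the gradient never reached are skipped), then clears the tape —
## each backward pass consumes the graphs built since the previous one.
ad_backward <- function(root) {
  stopifnot(length(root$value) == 1)
  n <- ad_env$tape_n
  tape <- ad_env$tape
  for (i in seq_len(n)) tape[[i]]$grad <- NULL
  root$grad <- 1
  for (i in rev(seq_len(n))) {
    node <- tape[[i]]
    if (is.null(node$backfun) || is.null(node$grad)) next
    gs <- node$backfun(node$grad)
    parents <- node$parents
    for (j in seq_along(parents)) {
      p <- parents[[j]]
      if (!p$requires_grad || is.null(gs[[j]])) next
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
  }
  for (i in seq_len(n)) ad_env$tape[i] <- list(NULL)
  ad_env$tape_n <- 0L
  invisible(root)
}

## -- broadcasting helpers ----------------------------------------------------
## Supported broadcast pairs for add/mul: equal shapes; scalar with anything;
## channel vector (length C) with (H,W,C); spatial matrix (H,W) with (H,W,C).

bc_expand <- function(x, ref) {
  dx <- dim(x) %||% length(x)
  dr <- dim(ref) %||% length(ref)
  if (identical(dx, dr)) return(x)
  no_dim <- is.null(dim(ref))
  if (length(x) == 1)
    return(if (no_dim) rep(as.numeric(x), length(ref)) else array(x, dim = dr))
  ## same total length, different layout (e.g. vector vs column matrix)
  if (length(x) == prod(dr))
    return(if (no_dim) as.numeric(x) else array(as.numeric(x), dim = dr))
  if (length(dr) == 3 && is.null(dim(x)) && length(x) == dr[3])
    return(aperm(array(x, dim = c(dr[3], dr[1], dr[2])), c(2, 3, 1)))
  if (length(dr) == 3 && length(dim(x)) == 2 && all(dim(x) == dr[1:2]))
    return(array(x, dim = dr))
  stop("unsupported broadcast")
}

bc_reduce <- function(grad, like) {
  dl <- dim(like) %||% length(like)
  dg <- dim(grad) %||% length(grad)
  if (identical(dg, dl)) return(grad)
  if (length(like) == 1) return(sum(grad))
  if (length(grad) == length(like)) {
    if (is.null(dim(like))) return(as.numeric(grad))
    return(array(as.numeric(grad), dim = dim(like)))
  }
  if (length(dg) == 3 && is.null(dim(like)) && length(like) == dg[3])
    return(as.numeric(colSums(matrix(grad, dg[1] * dg[2], dg[3]))))
  if (length(dg) == 3 && length(dim(like)) == 2 && all(dim(like) == dg[1:2]))
    return(array(rowSums(matrix(grad, dg[1] * dg[2], dg[3])), dim = dg[1:2]))
  stop("unsupported broadcast reduction")
}

## -- elementwise arithmetic --------------------------------------------------

ad_add <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ref <- if (length(a$value) >= length(b$value)) a$value else b$value
  val <- bc_expand(a$value, ref) + bc_expand(b$value, ref)
  ad_make(val, list(a, b), function(g)
    list(bc_reduce(g, a$value), bc_reduce(g, b$value)))
}

ad_sub <- function(a, b) ad_add(a, ad_scale(b, -1))

ad_scale <- function(a, k) {
  a <- as_ad(a)
  ad_make(a$value * k, list(a), function(g) list(g * k))
}

ad_mul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ref <- if (length(a$value) >= length(b$value)) a$value else b$value
  ae <- bc_expand(a$value, ref); be <- bc_expand(b$value, ref)
  ad_make(ae * be, list(a, b), function(g)
    list(bc_reduce(g * be, a$value), bc_reduce(g * ae, b$value)))
}

ad_recip <- function(a) {
  a <- as_ad(a)
  v <- 1 / a$value
  ad_make(v, list(a), function(g) list(-g * v * v))
}

## x^p with x > 0 everywhere; p may be a (scalar) node, giving d/dp.
ad_pow <- function(a, p) {
  a <- as_ad(a)
  if (!is_ad(p)) {
    pv <- p
    v <- a$value^pv
    return(ad_make(v, list(a), function(g) list(g * pv * a$value^(pv - 1))))
  }
  pv <- as.numeric(p$value)
  v <- a$value^pv
  ad_make(v, list(a, p), function(g)
    list(g * pv * a$value^(pv - 1), sum(g * v * log(a$value))))
}

ad_exp <- function(a) {
  a <- as_ad(a); v <- exp(a$value)
  ad_make(v, list(a), function(g) list(g * v))
}

ad_log <- function(a) {
  a <- as_ad(a)
  ad_make(log(a$value), list(a), function(g) list(g / a$value))
}

ad_clamp_min <- function(a, floor) {
  a <- as_ad(a)
  keep <- a$value >= floor
  v <- a$value; v[!keep] <- floor
  ad_make(v, list(a), function(g) { g[!keep] <- 0; list(g) })
}

## -- activations -------------------------------------------------------------

ad_relu <- function(a) {
  a <- as_ad(a)
  keep <- a$value > 0
  v <- a$value * keep
  ad_make(v, list(a), function(g) list(g * keep))
}

ad_sigmoid <- function(a) {
  a <- as_ad(a); v <- sigmoid(a$value)
  ad_make(v, list(a), function(g) list(g * v * (1 - v)))
}

ad_tanh <- function(a) {
  a <- as_ad(a); v <- tanh(a$value)
  ad_make(v, list(a), function(g) list(g * (1 - v * v)))
}

ad_softplus <- function(a) {
  a <- as_ad(a)
  ad_make(softplus(a$value), list(a), function(g) list(g * sigmoid(a$value)))
}

## -- reductions and reshapes -------------------------------------------------

ad_sum <- function(a) {
  a <- as_ad(a)
  ad_make(sum(a$value), list(a), function(g)
    list(array(as.numeric(g), dim = dim(a$value) %||% length(a$value))))
}

ad_mean <- function(a) ad_scale(ad_sum(a), 1 / length(ad_value(a)))

## (H, W, C) -> length-C vector of spatial means
ad_mean_spatial <- function(a) {
  a <- as_ad(a)
  d <- dim(a$value)
  v <- colMeans(matrix(a$value, d[1] * d[2], d[3]))
  ad_make(v, list(a), function(g)
    list(bc_expand(as.numeric(g) / (d[1] * d[2]), a$value)))
}

## (H, W, C) -> (H, W) matrix of channel means
ad_mean_channels <- function(a) {
  a <- as_ad(a)
  d <- dim(a$value)
  v <- matrix(rowMeans(matrix(a$value, d[1] * d[2], d[3])), d[1], d[2])
  ad_make(v, list(a), function(g) list(bc_expand(g / d[3], a$value)))
}

## Scatter-add `vals` into a length-n vector at (possibly repeated) `idx`
## positions, using a sort/cumsum plan that can be precomputed and cached.
scatter_plan <- function(idx) {
  idx <- as.integer(idx)
  perm <- order(idx)
  sorted <- idx[perm]
  ends <- which(c(sorted[-1L] != sorted[-length(sorted)], TRUE))
  list(perm = perm, ends = ends, uidx = sorted[ends])
}

scatter_add <- function(vals, n, plan) {
  cs <- cumsum(vals[plan$perm])
  s <- cs[plan$ends]
  out <- numeric(n)
  out[plan$uidx] <- s - c(0, s[-length(s)])
  out
}

## Rearrange/reshape through a flat index map: out_flat = x_flat[idx].
ad_gather <- function(a, idx, out_dim, plan = NULL) {
  a <- as_ad(a)
  v <- a$value[idx]
  if (!is.null(out_dim)) dim(v) <- out_dim
  n_in <- length(a$value)
  ad_make(v, list(a), function(g) {
    if (is.null(plan)) plan <<- scatter_plan(idx)
    out <- scatter_add(as.numeric(g), n_in, plan)
    dim(out) <- dim(a$value) %||% NULL
    list(out)
  })
}

ad_matmul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$value; bv <- b$value
  if (is.null(dim(av))) av <- matrix(av, nrow = 1)
  if (is.null(dim(bv))) bv <- matrix(bv, ncol = 1)
  v <- av %*% bv
  ad_make(v, list(a, b), function(g) {
    if (is.null(dim(g))) g <- matrix(g, nrow(av), ncol(bv))
    ga <- g %*% t(bv); gb <- crossprod(av, g)
    if (is.null(dim(a$value))) ga <- as.numeric(ga)
    if (is.null(dim(b$value))) gb <- as.numeric(gb)
    list(ga, gb)
  })
}

ad_rbind <- function(nodes) {
  nodes <- lapply(nodes, as_ad)
  rows <- vapply(nodes, function(n) nrow(n$value), integer(1))
  v <- do.call(rbind, lapply(nodes, `[[`, "value"))
  ends <- cumsum(rows)
  starts <- c(1L, head(ends, -1) + 1L)
  ad_make(v, nodes, function(g)
    lapply(seq_along(nodes), function(i) g[starts[i]:ends[i], , drop = FALSE]))
}

## Concatenate scalar nodes into a vector (used for loss bookkeeping).
ad_row <- function(a, i) {
  a <- as_ad(a)
  nr <- nrow(a$value)
  v <- a$value[i, , drop = FALSE]
  ad_make(v, list(a), function(g) {
    out <- matrix(0, nr, ncol(a$value))
    out[i, ] <- g
    list(out)
  })
}

## -- convolution -------------------------------------------------------------

## im2col index for a padded input; cached per geometry.  Returns list with
## idx ((Ho*Wo) x (kh*kw*Cin) indices into the padded flat array), pad and
## output dims.
im2col_index <- function(h, w, cin, k, stride) {
  key <- paste(h, w, cin, k, stride, sep = "_")
  hit <- ad_env$im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  p <- (k - 1L) %/% 2L
  hp <- h + 2L * p; wp <- w + 2L * p
  ho <- 1L + (h - 1L) %/% stride
  wo <- 1L + (w - 1L) %/% stride
  oy <- (seq_len(ho) - 1L) * stride    # top-left of window = position of
  ox <- (seq_len(wo) - 1L) * stride    # output pixel in padded coords
  ## rows ordered with output row fastest, matching column-major array()
  base_y <- rep(oy, times = wo)
  base_x <- rep(ox, each = ho)
  off <- expand.grid(ky = seq_len(k) - 1L, kx = seq_len(k) - 1L,
                     ci = seq_len(cin) - 1L)
  idx <- matrix(0L, ho * wo, k * k * cin)
  for (j in seq_len(nrow(off))) {
    yy <- base_y + off$ky[j]
    xx <- base_x + off$kx[j]
    idx[, j] <- 1L + yy + xx * hp + off$ci[j] * hp * wp
  }
  res <- list(idx = idx, pad = p, ho = ho, wo = wo, hp = hp, wp = wp,
              plan = scatter_plan(idx))
  ad_env$im2col_cache[[key]] <- res
  res
}

## 2-D convolution with same padding.  x: (H, W, Cin) node; w: (k*k*Cin,
## Cout) weight node (kernel offsets ordered ky, kx, ci to match
## im2col_index); b: length-Cout bias node or NULL.
ad_conv2d <- function(x, w, b = NULL, k, stride = 1L) {
  x <- as_ad(x); w <- as_ad(w)
  d <- dim(x$value)
  cin <- d[3]; cout <- ncol(w$value)
  ii <- im2col_index(d[1], d[2], cin, as.integer(k), as.integer(stride))
  xp <- array(0, c(ii$hp, ii$wp, cin))
  xp[ii$pad + seq_len(d[1]), ii$pad + seq_len(d[2]), ] <- x$value
  cols <- matrix(xp[ii$idx], nrow(ii$idx), ncol(ii$idx))
  out <- cols %*% w$value
  if (!is.null(b)) b <- as_ad(b)
  if (!is.null(b)) out <- sweep(out, 2, b$value, `+`)
  val <- array(out, c(ii$ho, ii$wo, cout))
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ad_make(val, parents, function(g) {
    gm <- matrix(g, ii$ho * ii$wo, cout)
    gw <- crossprod(cols, gm)
    gcols <- gm %*% t(w$value)
    gxp <- scatter_add(as.numeric(gcols), ii$hp * ii$wp * cin, ii$plan)
    dim(gxp) <- c(ii$hp, ii$wp, cin)
    gx <- gxp[ii$pad + seq_len(d[1]), ii$pad + seq_len(d[2]), , drop = FALSE]
    if (is.null(b)) list(gx, gw) else list(gx, gw, colSums(gm))
  })
}

## Nearest-neighbour x2 upsampling of an (H, W, C) node.
ad_upsample2 <- function(x) {
  x <- as_ad(x)
  d <- dim(x$value)
  key <- paste("up2", d[1], d[2], d[3], sep = "_")
  hit <- ad_env$im2col_cache[[key]]
  if (is.null(hit)) {
    ri <- rep(seq_len(d[1]), each = 2)
    ci <- rep(seq_len(d[2]), each = 2)
    idx <- array(seq_len(prod(d)), d)[ri, ci, , drop = FALSE]
    hit <- list(idx = as.integer(idx), dim = dim(idx), plan = scatter_plan(idx))
    ad_env$im2col_cache[[key]] <- hit
  }
  ad_gather(x, hit$idx, hit$dim, plan = hit$plan)
}

## -- fused losses ------------------------------------------------------------

## Binary cross-entropy with logits over selected indices, divided by `norm`.
ad_bce_logits <- function(logits, targets, sel = NULL, norm = NULL) {
  logits <- as_ad(logits)
  l <- as.numeric(logits$value)
  if (is.null(sel)) sel <- seq_along(l)
  norm <- norm %||% length(sel)
  v <- sum(stable_bce_logits(l[sel], targets)) / norm
  ad_make(v, list(logits), function(g) {
    gl <- numeric(length(l))
    gl[sel] <- as.numeric(g) * (sigmoid(l[sel]) - targets) / norm
    dim(gl) <- dim(logits$value) %||% NULL
    list(gl)
  })
}

## Softmax cross-entropy over rows of an N x C logit matrix with integer
## labels in 1..C; mean over rows.
ad_softmax_ce <- function(logits, labels) {
  logits <- as_ad(logits)
  lv <- logits$value
  n <- nrow(lv)
  mx <- apply(lv, 1, max)
  ex <- exp(lv - mx)
  z <- rowSums(ex)
  probs <- ex / z
  v <- mean(log(z) + mx - lv[cbind(seq_len(n), labels)])
  ad_make(v, list(logits), function(g) {
    gm <- probs
    gm[cbind(seq_len(n), labels)] <- gm[cbind(seq_len(n), labels)] - 1
    list(as.numeric(g) * gm / n)
  })
}

## Smooth-L1 (Huber at 1) summed over all elements of pred - target, / norm.
ad_smooth_l1 <- function(pred, target, norm) {
  pred <- as_ad(pred)
  d <- pred$value - target
  a <- abs(d)
  v <- sum(ifelse(a < 1, 0.5 * d * d, a - 0.5)) / norm
  ad_make(v, list(pred), function(g) {
    gd <- ifelse(a < 1, d, sign(d))
    list(as.numeric(g) * gd / norm)
  })
}

## Pixelwise BCE-with-logits of an M x n logit matrix against M x n targets,
## weighted by an M x n mask, each column divided by its own normalizer,
## averaged over columns (columns = instances, mask = gt-bbox crop).
ad_masked_bce_logits <- function(logits, targets, mask, colnorm) {
  logits <- as_ad(logits)
  l <- logits$value
  n <- ncol(l)
  per <- stable_bce_logits(l, targets) * mask
  v <- sum(sweep(per, 2, colnorm, `/`)) / n
  ad_make(v, list(logits), function(g) {
    gl <- (sigmoid(l) - targets) * mask
    gl <- sweep(gl, 2, colnorm, `/`)
    list(as.numeric(g) * gl / n)
  })
}

## Mean squared error to a constant target.
ad_mse_to <- function(pred, target) {
  pred <- as_ad(pred)
  d <- pred$value - target
  v <- mean(d * d)
  n <- length(d)
  ad_make(v, list(pred), function(g) list(as.numeric(g) * 2 * d / n))
}
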