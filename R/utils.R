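#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif quantile
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so callers' random streams are unaffected.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# numerically stable log(1 + exp(x))
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

stable_bce_logits <- function(l, t) pmax(l, 0) - l * t + log1p(exp(-abs(l)))

## ---- polygon geometry ------------------------------------------------------
## Polygons are n x 2 matrices, columns (x, y), in continuous 0-based pixel
## coordinates (origin top-left, x rightward, y downward).

polygon_signed_area <- function(v) {
  n <- nrow(v)
  if (n < 3) return(0)
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

#' Polygon area (shoelace formula)
#' @param v n x 2 vertex matrix, columns (x, y).
#' @return nonnegative area in squared pixels.
#' @export
polygon_area <- function(v) abs(polygon_signed_area(v))

#' Area-weighted polygon centroid
#' @param v n x 2 vertex matrix.
#' @return length-2 numeric (x, y).
#' @keywords internal
polygon_centroid <- function(v) {
  a <- polygon_signed_area(v)
  if (abs(a) < 1e-12) stop("cannot compute the centroid of a zero-area polygon")
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

polygon_bbox <- function(v) {
  c(min(v[, 1]), min(v[, 2]), max(v[, 1]) - min(v[, 1]), max(v[, 2]) - min(v[, 2]))
}

## Sutherland-Hodgman clip of a polygon against an axis-aligned rectangle
## [x0, x1] x [y0, y1].  Returns a (possibly empty) vertex matrix.
clip_polygon_rect <- function(v, x0, y0, x1, y1) {
  clip_half <- function(v, inside, intersect) {
    n <- nrow(v)
    if (n == 0) return(v)
    out <- vector("list", 2L * n)
    m <- 0L
    for (i in seq_len(n)) {
      cur <- v[i, ]; prv <- v[if (i == 1L) n else i - 1L, ]
      ci <- inside(cur); pi <- inside(prv)
      if (ci) {
        if (!pi) { m <- m + 1L; out[[m]] <- intersect(prv, cur) }
        m <- m + 1L; out[[m]] <- cur
      } else if (pi) {
        m <- m + 1L; out[[m]] <- intersect(prv, cur)
      }
    }
    if (m == 0L) matrix(numeric(0), 0, 2) else do.call(rbind, out[seq_len(m)])
  }
  ix <- function(p, q, t) p + (q - p) * t
  v <- clip_half(v, function(p) p[1] >= x0,
                 function(p, q) ix(p, q, (x0 - p[1]) / (q[1] - p[1])))
  v <- clip_half(v, function(p) p[1] <= x1,
                 function(p, q) ix(p, q, (x1 - p[1]) / (q[1] - p[1])))
  v <- clip_half(v, function(p) p[2] >= y0,
                 function(p, q) ix(p, q, (y0 - p[2]) / (q[2] - p[2])))
  v <- clip_half(v, function(p) p[2] <= y1,
                 function(p, q) ix(p, q, (y1 - p[2]) / (q[2] - p[2])))
  v
}

#' Rasterize a polygon to a binary mask
#'
#' Even-odd scanline fill sampled at pixel centers (col - 0.5, row - 0.5) in
#' 0-based continuous coordinates.
#'
#' @param v n x 2 vertex matrix.
#' @param h,w mask dimensions in pixels.
#' @return h x w logical matrix.
#' @export
rasterize_polygon <- function(v, h, w) {
  mask <- matrix(FALSE, h, w)
  if (nrow(v) < 3) return(mask)
  x1 <- v[, 1]; y1 <- v[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  r0 <- max(1L, floor(min(y1) + 0.5) + 1L)
  r1 <- min(h, ceiling(max(y1) + 0.5))
  if (r0 > r1) return(mask)
  for (r in r0:r1) {
    yc <- r - 0.5
    crosses <- (y1 <= yc) != (y2 <= yc)
    if (!any(crosses)) next
    xi <- x1[crosses] + (yc - y1[crosses]) * (x2[crosses] - x1[crosses]) / (y2[crosses] - y1[crosses])
    xi <- sort(xi)
    for (k in seq(1, length(xi) - 1, by = 2)) {
      ## columns whose center xc = c - 0.5 satisfies xi[k] <= xc <= xi[k+1]
      c0 <- max(1L, ceiling(xi[k] + 0.5))
      c1 <- min(w, floor(xi[k + 1] + 0.5))
      if (c0 <= c1) mask[r, c0:c1] <- TRUE
    }
  }
  mask
}

## ---- boxes -----------------------------------------------------------------
## Boxes are (x, y, w, h) with half-open extent [x, x+w) x [y, y+h).

boxes_xywh_to_corners <- function(b) {
  cbind(b[, 1], b[, 2], b[, 1] + b[, 3], b[, 2] + b[, 4])
}

boxes_cxcywh_to_corners <- function(b) {
  cbind(b[, 1] - b[, 3] / 2, b[, 2] - b[, 4] / 2,
        b[, 1] + b[, 3] / 2, b[, 2] + b[, 4] / 2)
}

#' Pairwise IoU of two sets of boxes
#' @param a n x 4 matrix of corner boxes (x0, y0, x1, y1).
#' @param b m x 4 matrix of corner boxes.
#' @return n x m IoU matrix.
#' @keywords internal
box_iou_matrix <- function(a, b) {
  n <- nrow(a); m <- nrow(b)
  if (n == 0 || m == 0) return(matrix(0, n, m))
  ix0 <- outer(a[, 1], b[, 1], pmax); iy0 <- outer(a[, 2], b[, 2], pmax)
  ix1 <- outer(a[, 3], b[, 3], pmin); iy1 <- outer(a[, 4], b[, 4], pmin)
  iw <- pmax(ix1 - ix0, 0); ih <- pmax(iy1 - iy0, 0)
  inter <- iw * ih
  aa <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  ab <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  un <- outer(aa, ab, `+`) - inter
  ifelse(un > 0, inter / un, 0)
}

## ---- resampling ------------------------------------------------------------

## 1-D bilinear resampling weights mapping n_in samples to n_out, with
## edge clamping; rows sum to 1.
resize_weights <- function(n_out, n_in) {
  if (n_out == n_in) return(diag(n_in))
  pos <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  pos <- pmin(pmax(pos, 0), n_in - 1)
  lo <- floor(pos)
  hi <- pmin(lo + 1, n_in - 1)
  f <- pos - lo
  w <- matrix(0, n_out, n_in)
  w[cbind(seq_len(n_out), lo + 1)] <- 1 - f
  w[cbind(seq_len(n_out), hi + 1)] <- w[cbind(seq_len(n_out), hi + 1)] + f
  w
}

#' Bilinear resize of a matrix
#' @param m numeric matrix.
#' @param h,w target dimensions.
#' @return h x w matrix.
#' @keywords internal
resize_bilinear <- function(m, h, w) {
  resize_weights(h, nrow(m)) %*% m %*% t(resize_weights(w, ncol(m)))
}

## Sum-pooling over fh x fw blocks (exact integer downscale).
block_sum_pool <- function(m, fh, fw) {
  h2 <- nrow(m) %/% fh; w2 <- ncol(m) %/% fw
  m2 <- rowsum(m, rep(seq_len(h2), each = fh))
  out <- t(rowsum(t(m2), rep(seq_len(w2), each = fw)))
  dimnames(out) <- NULL
  out
}
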