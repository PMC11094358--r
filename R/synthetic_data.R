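## Seeded synthetic field scenes: golden textured ellipse "ears" with an
## awn-like fringe over a cluttered green-brown vegetation background, with
## exact 16-vertex polygon ground truth, at four density levels.

## Per-level instance-count ranges.  At the reference 1024 px scale the
## ranges span sparse (L1) to very dense (L4) field plots; below 512 px a
## fixed test-scale table keeps the painted-area fraction comparable while
## retaining at least a few instances per scene.
level_count_table <- function(size) {
  area <- prod(size)
  if (sqrt(area) >= 512) {
    base <- rbind(c(5, 15), c(15, 40), c(40, 80), c(80, 150))
    pmax(matrix(1, 4, 2), round(base * area / 1024^2))
  } else {
    base <- rbind(c(4, 8), c(8, 16), c(16, 28), c(28, 40))
    pmax(matrix(1, 4, 2), round(base * area / 128^2))
  }
}

#' Synthetic scene configuration
#'
#' @param image_size scene side in pixels (square scenes; 1024 reference
#'   scale, 128 for desk-scale tests).
#' @param level density level 1 (sparse) to 4 (very dense).
#' @param count_range optional `(min, max)` instance count override;
#'   defaults to the per-level table for the image size.
#' @param major_axis,minor_axis `(min, max)` ellipse semi-axis ranges in
#'   pixels; defaults scale with image size.
#' @param background `"cluttered"` (leaf-like strokes in ear-similar hues)
#'   or `"plain"`.
#' @param overlap_allowance fraction of the mean major axis by which ear
#'   centers may approach each other; higher levels allow closer packing.
#' @param seed integer seed.
#' @return list of class "scene_config".
#' @export
scene_config <- function(image_size = 1024, level = 1, count_range = NULL,
                         major_axis = NULL, minor_axis = NULL,
                         background = c("cluttered", "plain"),
                         overlap_allowance = NULL, seed = 0) {
  background <- match.arg(background)
  stopifnot(level %in% 1:4, image_size >= 32)
  size <- rep(as.integer(image_size), length.out = 2)
  small <- sqrt(prod(size)) < 512
  count_range <- count_range %||% level_count_table(size)[level, ]
  stopifnot(count_range[1] >= 1, count_range[2] >= count_range[1])
  structure(list(
    image_size = size, level = as.integer(level),
    count_range = count_range,
    major_axis = major_axis %||% if (small) c(7, 11) else c(45, 75) / 2,
    minor_axis = minor_axis %||% if (small) c(3, 5) else c(16, 28) / 2,
    background = background,
    ## min center spacing = (1 - allowance) * mean major semi-axis * 2
    overlap_allowance = overlap_allowance %||% c(0.1, 0.3, 0.5, 0.65)[level],
    seed = as.integer(seed)), class = "scene_config")
}

## low-frequency multiplicative field for background variation
smooth_field <- function(h, w, cells = 8) {
  resize_bilinear(matrix(runif(cells * cells, 0.8, 1.2), cells, cells), h, w)
}

paint_stroke <- function(img, x0, y0, angle, len, col, width = 1) {
  h <- dim(img)[1]; w <- dim(img)[2]
  t <- seq(0, len, by = 0.7)
  xs <- round(x0 + t * cos(angle)); ys <- round(y0 + t * sin(angle))
  for (dx in -width:width) for (dy in -width:width) {
    xi <- xs + dx; yi <- ys + dy
    ok <- xi >= 1 & xi <= w & yi >= 1 & yi <= h
    if (!any(ok)) next
    idx <- cbind(yi[ok], xi[ok])
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[idx] <- 0.65 * pl[idx] + 0.35 * col[ch]
      img[, , ch] <- pl
    }
  }
  img
}

ellipse_polygon <- function(cx, cy, a, b, phi, n = 16) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- cx + a * cos(th) * cos(phi) - b * sin(th) * sin(phi)
  y <- cy + a * cos(th) * sin(phi) + b * sin(th) * cos(phi)
  cbind(x, y)
}

paint_ear <- function(img, cx, cy, a, b, phi, brightness) {
  h <- dim(img)[1]; w <- dim(img)[2]
  r <- ceiling(max(a, b)) + 1
  x0 <- max(1, floor(cx - r)); x1 <- min(w, ceiling(cx + r))
  y0 <- max(1, floor(cy - r)); y1 <- min(h, ceiling(cy + r))
  xs <- x0:x1; ys <- y0:y1
  ## pixel centers relative to the ellipse frame
  gx <- outer(rep(1, length(ys)), xs - 0.5) - cx
  gy <- outer(ys - 0.5, rep(1, length(xs))) - cy
  u <- gx * cos(phi) + gy * sin(phi)
  v <- -gx * sin(phi) + gy * cos(phi)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  if (!any(inside)) return(img)
  ## golden base with spikelet-like longitudinal banding and speckle
  base <- c(0.80, 0.66, 0.28) * brightness
  band <- 1 + 0.15 * cos(u * (2 * pi / max(2, a / 2.2)))
  spec <- matrix(runif(length(u), -0.07, 0.07), nrow(u))
  for (ch in 1:3) {
    pl <- img[ys, xs, ch]
    val <- pmin(1, pmax(0, base[ch] * band + spec))
    pl[inside] <- val[inside]
    img[ys, xs, ch] <- pl
  }
  ## awn fringe: short bright strokes leaving the ellipse tip regions
  n_awn <- sample(3:6, 1)
  for (i in seq_len(n_awn)) {
    th <- runif(1, -0.5, 0.5) + sample(c(0, pi), 1)
    px <- cx + a * cos(th) * cos(phi) - b * sin(th) * sin(phi)
    py <- cy + a * cos(th) * sin(phi) + b * sin(th) * cos(phi)
    img <- paint_stroke(img, px, py, phi + runif(1, -0.4, 0.4) + (th > pi / 2) * pi,
                        runif(1, 0.2, 0.5) * a,
                        c(0.85, 0.75, 0.4) * brightness, width = 0)
  }
  img
}

#' Generate one synthetic field scene
#'
#' Ears are placed by rejection sampling under the level's center-spacing
#' rule, each rendered as a textured rotated ellipse with an awn fringe;
#' the ground-truth polygon is the 16-vertex ellipse outline (clipped to
#' the image).  Deterministic under the config seed.
#'
#' @param config a [scene_config()].
#' @return list of class "ear_scene": `image` (H x W x 3 array in [0, 1]),
#'   `annotations` (polygon annotations), `centers` (n x 2 matrix),
#'   `level`, `seed`.
#' @export
generate_scene <- function(config = scene_config()) {
  with_seed(config$seed, {
    h <- config$image_size[1]; w <- config$image_size[2]
    n <- sample(config$count_range[1]:config$count_range[2], 1)
    ## background: dark green-brown vegetation with low-frequency variation
    img <- array(0, c(h, w, 3))
    fld <- smooth_field(h, w)
    base <- c(0.22, 0.30, 0.12)
    for (ch in 1:3)
      img[, , ch] <- pmin(1, pmax(0, base[ch] * fld +
                                    matrix(rnorm(h * w, 0, 0.02), h, w)))
    if (config$background == "cluttered") {
      n_strokes <- max(4L, round(h * w / 1500))
      for (i in seq_len(n_strokes)) {
        hue <- runif(1)
        col <- if (hue < 0.6) c(0.30, 0.42, 0.16) * runif(1, 0.7, 1.1)
               else c(0.55, 0.50, 0.22) * runif(1, 0.6, 0.9)  # dry-leaf, ear-like hue
        img <- paint_stroke(img, runif(1, 1, w), runif(1, 1, h),
                            runif(1, 0, pi), runif(1, 0.05, 0.2) * h, col,
                            width = sample(0:1, 1))
      }
    }
    ## place ears
    mean_major <- mean(config$major_axis)
    min_dist <- (1 - config$overlap_allowance) * 2 * mean_major
    margin <- max(config$minor_axis)
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(centers) < n) {
      tries <- tries + 1L
      if (tries > 4000L)
        stop("could not place all ears; lower the count or enlarge the image")
      cx <- runif(1, margin + 1, w - margin - 1)
      cy <- runif(1, margin + 1, h - margin - 1)
      if (nrow(centers) > 0 &&
          min(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)) < min_dist)
        next
      centers <- rbind(centers, c(cx, cy))
    }
    anns <- vector("list", n)
    for (i in seq_len(n)) {
      a <- runif(1, config$major_axis[1], config$major_axis[2])
      b <- runif(1, config$minor_axis[1], config$minor_axis[2])
      phi <- runif(1, 0, pi)
      brightness <- runif(1, 0.85, 1.15)
      img <- paint_ear(img, centers[i, 1], centers[i, 2], a, b, phi, brightness)
      poly <- ellipse_polygon(centers[i, 1], centers[i, 2], a, b, phi)
      poly[, 1] <- pmin(pmax(poly[, 1], 0), w)
      poly[, 2] <- pmin(pmax(poly[, 2], 0), h)
      anns[[i]] <- new_polygon_annotation(i, 1L, poly)
    }
    structure(list(image = img, annotations = anns, centers = centers,
                   level = config$level, seed = config$seed,
                   config = config),
              class = "ear_scene")
  })
}

#' Generate a synthetic dataset across the four density levels
#'
#' `4 * n_per_level` scenes with seeds derived deterministically from
#' `seed`; optionally written to disk as PNG images plus a COCO instances
#' document and a manifest recording every scene seed.
#'
#' @param n_per_level scenes per density level.
#' @param image_size scene side in pixels.
#' @param seed base seed; scene i at level l uses `seed + 1000 l + i`.
#' @param out_dir optional output directory.
#' @param density also write ground-truth density maps (NPY format)?
#' @param sigma Gaussian sigma for those maps.
#' @param background passed to [scene_config()].
#' @return list with `scenes`, `images` (records), `annotations`, and
#'   `manifest`.
#' @export
generate_dataset <- function(n_per_level, image_size = 1024, seed = 0,
                             out_dir = NULL, density = FALSE, sigma = NULL,
                             background = "cluttered") {
  stopifnot(n_per_level >= 1)
  scenes <- list(); images <- list(); annotations <- list()
  manifest <- list(seed = seed, scenes = list())
  next_ann <- 1L
  img_id <- 0L
  for (lv in 1:4) for (i in seq_len(n_per_level)) {
    sc_seed <- as.integer(seed + 1000L * lv + i)
    sc <- generate_scene(scene_config(image_size = image_size, level = lv,
                                      background = background, seed = sc_seed))
    img_id <- img_id + 1L
    fn <- sprintf("scene_L%d_%03d.png", lv, i)
    images[[img_id]] <- new_image_record(img_id, fn, dim(sc$image)[2],
                                         dim(sc$image)[1])
    for (a in sc$annotations) {
      annotations[[length(annotations) + 1L]] <- new_polygon_annotation(
        next_ann, img_id, a$vertices)
      next_ann <- next_ann + 1L
    }
    manifest$scenes[[img_id]] <- list(image_id = img_id, file = fn,
                                      level = lv, seed = sc_seed,
                                      n_ears = length(sc$annotations))
    scenes[[img_id]] <- sc
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      png::writePNG(sc$image, file.path(out_dir, fn))
      if (density) {
        dm <- generate_density_map(sc$centers, dim(sc$image)[1:2],
                                   density_config(sigma = sigma %||%
                                                    (8 * image_size / 1024)))
        write_npy(dm$values, file.path(out_dir, sub("\\.png$", ".npy", fn)))
      }
    }
  }
  if (!is.null(out_dir)) {
    to_coco(images, annotations, file.path(out_dir, "coco.json"))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE),
               file.path(out_dir, "manifest.json"))
  }
  list(scenes = scenes, images = images, annotations = annotations,
       manifest = manifest)
}
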