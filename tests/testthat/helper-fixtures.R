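## Shared fixtures: random polygons, toy head outputs, naive loss oracles.

random_polygon <- function(cx, cy, r = 10, n = sample(3:8, 1)) {
  th <- sort(runif(n, 0, 2 * pi))
  cbind(cx + r * runif(n, 0.5, 1) * cos(th),
        cy + r * runif(n, 0.5, 1) * sin(th))
}

labelme_json <- function(shapes, width = 100, height = 80) {
  jsonlite::toJSON(list(
    version = "5.0.1",
    imagePath = "img.png", imageWidth = width, imageHeight = height,
    shapes = shapes), auto_unbox = TRUE, digits = NA)
}

polygon_shape <- function(pts, label = "ear", type = "polygon") {
  list(label = label, shape_type = type,
       points = lapply(seq_len(nrow(pts)), function(i) as.list(pts[i, ])))
}

## Minimal hand-built head outputs: one pyramid level, explicit priors.
## Lets loss functions be exercised against scalar-loop oracles without a
## real forward pass.
toy_outputs <- function(n_priors = 8, C = 2, k = 3, Hp = 8, seed = 1,
                        with_density = FALSE, S_density = 4) {
  set.seed(seed)
  S <- ceiling(sqrt(n_priors))
  priors <- cbind(cx = runif(n_priors, 0.2, 0.8), cy = runif(n_priors, 0.2, 0.8),
                  w = runif(n_priors, 0.1, 0.3), h = runif(n_priors, 0.1, 0.3))
  lev <- list(obj = earcount:::as_ad(matrix(rnorm(n_priors), ncol = 1)),
              cls = earcount:::as_ad(matrix(rnorm(n_priors * C), n_priors, C)),
              box = earcount:::as_ad(matrix(rnorm(n_priors * 4), n_priors, 4)),
              coef = earcount:::as_ad(matrix(rnorm(n_priors * k), n_priors, k)),
              shape = c(S, S))
  density <- if (with_density)
    list(earcount:::as_ad(matrix(abs(rnorm(S_density^2)), S_density, S_density)))
  list(levels = list(lev),
       protos = earcount:::as_ad(array(rnorm(Hp * Hp * k), c(Hp, Hp, k))),
       density = density,
       priors = list(priors = priors, level = rep(1L, n_priors),
                     sizes = S, A = 1L))
}

## naive scalar-loop oracles -------------------------------------------------

oracle_bce <- function(logits, targets) {
  s <- 0
  for (i in seq_along(logits)) {
    p <- 1 / (1 + exp(-logits[i]))
    s <- s - (targets[i] * log(p) + (1 - targets[i]) * log(1 - p))
  }
  s
}

oracle_smooth_l1 <- function(pred, target) {
  s <- 0
  for (i in seq_along(pred)) {
    d <- abs(pred[i] - target[i])
    s <- s + if (d < 1) 0.5 * d^2 else d - 0.5
  }
  s
}

oracle_softmax_ce <- function(logits, labels) {
  s <- 0
  for (i in seq_len(nrow(logits))) {
    z <- exp(logits[i, ] - max(logits[i, ]))
    s <- s - log(z[labels[i]] / sum(z))
  }
  s / nrow(logits)
}

oracle_assemble <- function(protos, coef) {
  d <- dim(protos)
  out <- matrix(0, d[1], d[2])
  for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    acc <- 0
    for (j in seq_len(d[3])) acc <- acc + coef[j] * protos[r, c, j]
    out[r, c] <- 1 / (1 + exp(-acc))
  }
  out
}

## small training fixture -----------------------------------------------------

tiny64_config <- function(...) {
  model_config("tiny", input_size = 64, ...)
}

## 64-px scenes with ear sizes matched to the tiny model's 16-px prior
## scale (ears much smaller than the priors would never reach the IoU-0.5
## matching threshold and the detector could not train)
make_scene64 <- function(level = 1, seed = 0, count_range = NULL) {
  generate_scene(scene_config(image_size = 64, level = level, seed = seed,
                              count_range = count_range,
                              major_axis = c(7, 10), minor_axis = c(3, 4.5)))
}

scene_to_sample <- function(s) {
  list(image = s$image, annotations = s$annotations, centers = s$centers)
}
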