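## Annotation documents.
##
## An image record is a list(image_id, file_name, width, height).
## A polygon annotation is a list(annotation_id, image_id, category,
## vertices (n x 2 matrix of (x, y)), bbox (x, y, w, h), area).
## The single category is "ear" with COCO id 1.

EAR_CATEGORY <- list(id = 1L, name = "ear", supercategory = "plant")

new_image_record <- function(image_id, file_name, width, height) {
  stopifnot(width > 0, height > 0)
  list(image_id = as.integer(image_id), file_name = as.character(file_name),
       width = as.integer(width), height = as.integer(height))
}

new_polygon_annotation <- function(annotation_id, image_id, vertices,
                                   category = "ear") {
  vertices <- matrix(as.numeric(vertices), ncol = 2)
  if (nrow(vertices) < 3)
    stop("polygon must have at least 3 vertices")
  area <- polygon_area(vertices)
  if (area <= 0) stop("polygon has zero area")
  list(annotation_id = as.integer(annotation_id),
       image_id = as.integer(image_id),
       category = category,
       vertices = vertices,
       bbox = polygon_bbox(vertices),
       area = area)
}

#' Parse a labelme annotation document
#'
#' Reads a labelme JSON document (the format written by the labelme polygon
#' annotation tool) and returns the image record plus one polygon annotation
#' per polygon shape.  Non-polygon shapes are skipped with a warning.
#'
#' @param document labelme JSON as a single string, or a path to a file.
#' @param image_id integer id to assign to the image.
#' @param first_annotation_id id given to the first polygon; subsequent
#'   polygons count up from it.
#' @return list with elements `image` (image record) and `annotations`
#'   (list of polygon annotations, vertex order preserved).
#' @export
parse_labelme <- function(document, image_id = 1L, first_annotation_id = 1L) {
  doc <- if (length(document) == 1 && !grepl("[{]", document) && file.exists(document))
    jsonlite::fromJSON(document, simplifyVector = FALSE)
  else jsonlite::fromJSON(paste(document, collapse = "\n"), simplifyVector = FALSE)
  if (is.null(doc$shapes)) stop("not a labelme document: missing 'shapes'")
  img <- new_image_record(image_id, doc$imagePath %||% "unknown.png",
                          doc$imageWidth %||% stop("missing imageWidth"),
                          doc$imageHeight %||% stop("missing imageHeight"))
  anns <- list()
  aid <- as.integer(first_annotation_id)
  for (i in seq_along(doc$shapes)) {
    sh <- doc$shapes[[i]]
    st <- sh$shape_type %||% "polygon"
    if (!identical(st, "polygon")) {
      warning(sprintf("shape %d has type '%s'; skipped (only polygons are supported)", i, st))
      next
    }
    pts <- do.call(rbind, lapply(sh$points, function(p) c(p[[1]], p[[2]])))
    if (is.null(pts) || nrow(pts) < 3)
      stop(sprintf("shape %d: polygon needs at least 3 points", i))
    anns[[length(anns) + 1L]] <- new_polygon_annotation(aid, img$image_id, pts,
                                                        sh$label %||% "ear")
    aid <- aid + 1L
  }
  list(image = img, annotations = anns)
}

#' Write image records and polygon annotations as a COCO instances document
#'
#' Produces a COCO "instances" document with polygon segmentations stored as
#' flat `[x1, y1, x2, y2, ...]` lists and the single category "ear" (id 1).
#' `parse_coco(to_coco(x))` reproduces the vertex coordinates exactly.
#'
#' @param images list of image records.
#' @param annotations list of polygon annotations; every `image_id` must
#'   occur among `images`.
#' @param file optional path; when given the JSON is written there.
#' @return the COCO document as a JSON string (invisibly when `file` is set).
#' @export
to_coco <- function(images, annotations, file = NULL) {
  ids <- vapply(images, `[[`, integer(1), "image_id")
  if (anyDuplicated(ids)) stop("duplicate image_id among images")
  for (a in annotations)
    if (!a$image_id %in% ids)
      stop(sprintf("annotation %d references unknown image_id %d",
                   a$annotation_id, a$image_id))
  doc <- list(
    images = lapply(images, function(im)
      list(id = im$image_id, file_name = im$file_name,
           width = im$width, height = im$height)),
    annotations = lapply(annotations, function(a)
      list(id = a$annotation_id, image_id = a$image_id,
           category_id = EAR_CATEGORY$id,
           segmentation = list(as.vector(t(a$vertices))),
           bbox = a$bbox, area = a$area, iscrowd = 0L)),
    categories = list(EAR_CATEGORY))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17))
  if (!is.null(file)) {
    writeLines(json, file)
    return(invisible(json))
  }
  json
}

#' Parse a COCO instances document
#'
#' Inverse of [to_coco()] on documents this package writes.  Multi-part
#' segmentations yield one polygon annotation per part, sharing the COCO
#' annotation's id and metadata.  RLE-encoded segmentations are not
#' supported.
#'
#' @param document COCO JSON string or file path.
#' @return list with `images` (list of image records) and `annotations`
#'   (list of polygon annotations).
#' @export
parse_coco <- function(document) {
  doc <- if (length(document) == 1 && !grepl("[{]", document) && file.exists(document))
    jsonlite::fromJSON(document, simplifyVector = FALSE)
  else jsonlite::fromJSON(paste(document, collapse = "\n"), simplifyVector = FALSE)
  for (key in c("images", "annotations", "categories"))
    if (is.null(doc[[key]])) stop(sprintf("COCO document is missing '%s'", key))
  cats <- list()
  for (ct in doc$categories) cats[[as.character(ct$id)]] <- ct$name
  images <- lapply(doc$images, function(im)
    new_image_record(im$id, im$file_name %||% "unknown.png", im$width, im$height))
  anns <- list()
  for (a in doc$annotations) {
    seg <- a$segmentation
    if (is.null(seg) || !is.null(seg$counts))
      stop("RLE segmentation encodings are not supported; polygons only")
    for (part in seg) {
      xy <- as.numeric(unlist(part))
      verts <- matrix(xy, ncol = 2, byrow = TRUE)
      anns[[length(anns) + 1L]] <- new_polygon_annotation(
        a$id, a$image_id, verts, cats[[as.character(a$category_id)]] %||% "ear")
    }
  }
  list(images = images, annotations = anns)
}

#' Instance center of a polygon annotation
#'
#' Returns the area-weighted centroid of the polygon, the point used as the
#' instance's center when building Gaussian density-map targets.  The
#' centroid is invariant to the starting vertex and to vertex density along
#' the outline, unlike a plain vertex mean.
#'
#' @param annotation a polygon annotation, or a bare n x 2 vertex matrix.
#' @return length-2 numeric (x, y) in pixel coordinates.
#' @export
instance_center <- function(annotation) {
  v <- if (is.matrix(annotation)) annotation else annotation$vertices
  polygon_centroid(v)
}

#' Tile layout for an image
#'
#' Non-overlapping grid of `tile`-sized windows anchored at the top-left;
#' trailing remainders smaller than a tile are discarded.
#'
#' @param width,height image dimensions in pixels.
#' @param tile `(w, h)` tile size (a single number is used for both).
#' @return data.frame with columns `x`, `y` (0-based offsets), `w`, `h`.
#' @export
tile_grid <- function(width, height, tile) {
  tile <- rep(as.integer(tile), length.out = 2)
  tw <- tile[1]; th <- tile[2]
  if (tw > width || th > height) stop("tile is larger than the image")
  nx <- width %/% tw; ny <- height %/% th
  g <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L)
  data.frame(x = g$ix * tw, y = g$iy * th, w = tw, h = th)
}

#' Cut an image (and its annotations) into non-overlapping tiles
#'
#' Annotations are clipped to each tile; a clipped polygon is kept only when
#' its clipped area is at least `min_area_frac` of the original area (sliver
#' ground truth from boundary-crossing instances is dropped).  Clipped
#' polygon coordinates are shifted into the tile's own frame.
#'
#' @param image H x W matrix or H x W x C array of pixel values.
#' @param tile `(w, h)` tile size.
#' @param annotations optional list of polygon annotations on the image.
#' @param min_area_frac minimum retained area fraction for clipped polygons.
#' @return list of tiles, each `list(image, offset = c(x, y), annotations)`.
#' @export
tile_image <- function(image, tile, annotations = list(), min_area_frac = 0.25) {
  dm <- dim(image)
  h <- dm[1]; w <- dm[2]
  grid <- tile_grid(w, h, tile)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    x0 <- grid$x[i]; y0 <- grid$y[i]; tw <- grid$w[i]; th <- grid$h[i]
    sub <- if (length(dm) == 2) image[(y0 + 1):(y0 + th), (x0 + 1):(x0 + tw), drop = FALSE]
    else image[(y0 + 1):(y0 + th), (x0 + 1):(x0 + tw), , drop = FALSE]
    kept <- list()
    for (a in annotations) {
      cl <- clip_polygon_rect(a$vertices, x0, y0, x0 + tw, y0 + th)
      if (nrow(cl) < 3) next
      if (polygon_area(cl) < min_area_frac * a$area) next
      cl[, 1] <- cl[, 1] - x0; cl[, 2] <- cl[, 2] - y0
      kept[[length(kept) + 1L]] <- new_polygon_annotation(
        a$annotation_id, a$image_id, cl, a$category)
    }
    out[[i]] <- list(image = sub, offset = c(x0, y0), annotations = kept)
  }
  out
}

#' Split image ids into train/validation/test sets (8:1:1)
#'
#' Deterministic under `seed`: `round(0.8 n)` train, `round(0.1 n)`
#' validation, remainder test.  Splitting is by image so tiles of one
#' photograph never leak across sets.
#'
#' @param image_ids vector of unique ids (at least 10).
#' @param seed integer seed.
#' @return list with `train`, `val`, `test` id vectors and `seed`.
#' @export
split_dataset <- function(image_ids, seed) {
  image_ids <- unique(image_ids)
  n <- length(image_ids)
  if (n < 10) stop("need at least 10 images to realize an 8:1:1 split")
  n_train <- round(0.8 * n); n_val <- round(0.1 * n)
  perm <- with_seed(seed, sample(image_ids))
  list(train = perm[seq_len(n_train)],
       val = perm[n_train + seq_len(n_val)],
       test = perm[(n_train + n_val + 1):n],
       seed = as.integer(seed))
}
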