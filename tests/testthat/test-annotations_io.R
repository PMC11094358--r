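test_that("labelme polygons parse with vertices preserved in order", {
  tri <- rbind(c(1, 2), c(30, 4), c(10, 25))
  doc <- labelme_json(list(polygon_shape(tri)))
  res <- parse_labelme(doc)
  expect_length(res$annotations, 1)
  expect_equal(res$annotations[[1]]$vertices, unname(tri), ignore_attr = TRUE)
  expect_equal(res$image$width, 100)
  expect_equal(res$image$height, 80)
})

test_that("degenerate and non-polygon labelme shapes are handled", {
  two_pt <- list(label = "ear", shape_type = "polygon",
                 points = list(list(0, 0), list(5, 5)))
  expect_error(parse_labelme(labelme_json(list(two_pt))), "at least 3 points")
  rect <- polygon_shape(rbind(c(0, 0), c(5, 0), c(5, 5), c(0, 5)), type = "rectangle")
  tri <- polygon_shape(rbind(c(1, 1), c(9, 1), c(5, 8)))
  expect_warning(res <- parse_labelme(labelme_json(list(rect, tri))), "skipped")
  expect_length(res$annotations, 1)
  expect_error(parse_labelme("{not json"), regexp = ".")
})

test_that("polygon area and bbox follow the shoelace formula", {
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  ann <- earcount:::new_polygon_annotation(1, 1, sq)
  expect_equal(ann$area, 100)
  expect_equal(ann$bbox, c(0, 0, 10, 10))
})

test_that("COCO round-trip is vertex-exact on random polygons", {
  set.seed(42)
  images <- lapply(1:3, function(i)
    earcount:::new_image_record(i, sprintf("im%d.png", i), 200, 150))
  anns <- lapply(1:50, function(j)
    earcount:::new_polygon_annotation(j, sample(3, 1),
                                      random_polygon(runif(1, 30, 170), runif(1, 30, 120))))
  doc <- to_coco(images, anns)
  back <- parse_coco(doc)
  expect_length(back$images, 3)
  expect_length(back$annotations, 50)
  for (j in 1:50) {
    expect_identical(back$annotations[[j]]$vertices, anns[[j]]$vertices)
    expect_equal(back$annotations[[j]]$image_id, anns[[j]]$image_id)
  }
})

test_that("to_coco validates inputs and formats the document", {
  empty <- jsonlite::fromJSON(to_coco(list(), list()), simplifyVector = FALSE)
  expect_length(empty$images, 0)
  expect_length(empty$annotations, 0)
  expect_length(empty$categories, 1)
  expect_equal(empty$categories[[1]]$name, "ear")

  img <- earcount:::new_image_record(1, "a.png", 50, 50)
  tri <- earcount:::new_polygon_annotation(1, 1, rbind(c(0, 0), c(9, 0), c(4, 7)))
  doc <- jsonlite::fromJSON(to_coco(list(img), list(tri)), simplifyVector = FALSE)
  expect_length(doc$annotations[[1]]$segmentation[[1]], 6)  # 2 numbers per vertex

  dangling <- earcount:::new_polygon_annotation(2, 9, rbind(c(0, 0), c(9, 0), c(4, 7)))
  expect_error(to_coco(list(img), list(dangling)), "unknown image_id")
})

test_that("parse_coco rejects RLE and missing keys", {
  rle <- '{"images":[{"id":1,"file_name":"a.png","width":5,"height":5}],
           "annotations":[{"id":1,"image_id":1,"category_id":1,
             "segmentation":{"counts":"abc","size":[5,5]}}],
           "categories":[{"id":1,"name":"ear"}]}'
  expect_error(parse_coco(rle), "RLE")
  expect_error(parse_coco('{"images":[]}'), "missing")
})

test_that("instance_center is the area-weighted centroid", {
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  expect_equal(instance_center(sq), c(5, 5))
  tri <- rbind(c(0, 0), c(6, 0), c(0, 6))
  expect_equal(instance_center(tri), c(2, 2))
  ## translation equivariance and starting-vertex invariance
  set.seed(7)
  p <- random_polygon(50, 40)
  expect_equal(instance_center(p + 13.5), instance_center(p) + 13.5)
  rot <- p[c(3:nrow(p), 1:2), ]
  expect_equal(instance_center(rot), instance_center(p))
  degenerate <- rbind(c(0, 0), c(1, 1), c(2, 2))
  expect_error(instance_center(degenerate), "zero-area")
})

test_that("tile_grid floors partial tiles (field-camera geometry)", {
  g <- tile_grid(4624, 3472, 1024)
  expect_equal(nrow(g), 12)   # 4 x 3
  expect_equal(sort(unique(g$x)), c(0, 1024, 2048, 3072))
  expect_error(tile_grid(512, 512, 1024), "larger")
})

test_that("tile_image clips annotations and partitions pixels", {
  img <- matrix(seq_len(48 * 64), 48, 64)
  inner <- earcount:::new_polygon_annotation(1, 1, rbind(c(2, 2), c(12, 2), c(7, 12)))
  crosser <- earcount:::new_polygon_annotation(2, 1,
    rbind(c(10, 2), c(22, 2), c(22, 10), c(10, 10)))  # crosses x = 16
  tiles <- tile_image(img, 16, list(inner, crosser))
  expect_length(tiles, 12)
  ## identity single tile
  one <- tile_image(img, c(64, 48))
  expect_identical(one[[1]]$image, img)
  ## interior annotation appears once, unchanged, in tile (0,0)
  t00 <- tiles[[1]]
  expect_length(t00$annotations, 2)  # inner + left half of crosser (50% area)
  expect_equal(t00$annotations[[1]]$vertices, inner$vertices)
  n_with_inner <- sum(vapply(tiles, function(t)
    any(vapply(t$annotations, function(a) a$annotation_id == 1L, logical(1))),
    logical(1)))
  expect_equal(n_with_inner, 1)
  ## pixel partition: each retained tile pixel maps to exactly one source value
  vals <- unlist(lapply(tiles, function(t) as.vector(t$image)))
  expect_equal(length(vals), length(unique(vals)))
  ## sliver dropped: 25% threshold
  sliver <- earcount:::new_polygon_annotation(3, 1,
    rbind(c(14, 2), c(30, 2), c(30, 10), c(14, 10)))  # only 2/16 in tile 1
  t2 <- tile_image(img, 16, list(sliver))
  expect_length(t2[[1]]$annotations, 0)
})

test_that("split_dataset follows the 8:1:1 rule deterministically", {
  sp <- split_dataset(1:100, seed = 11)
  expect_equal(lengths(sp[c("train", "val", "test")]),
               c(train = 80, val = 10, test = 10))
  sp2 <- split_dataset(1:100, seed = 11)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_dataset(1:100, seed = 12)))
  all_ids <- sort(c(sp$train, sp$val, sp$test))
  expect_equal(all_ids, 1:100)
  big <- split_dataset(1:1000, seed = 0)
  expect_equal(lengths(big[c("train", "val", "test")]),
               c(train = 800, val = 100, test = 100))
  expect_error(split_dataset(1:9, seed = 0), "at least 10")
})
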