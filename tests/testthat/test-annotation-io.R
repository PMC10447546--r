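# LabelMe dialect parsing, polygon rasterization against the even-odd
# oracle, mask intersection, ROI cropping.

write_fixture_json <- function(path, shapes) {
  jsonlite::write_json(list(imageHeight = 100, imageWidth = 100,
                            shapes = shapes),
                       path, auto_unbox = TRUE, digits = NA)
}

test_that("read_labelme maps rectangles, polygons and points", {
  path <- withr::local_tempfile(fileext = ".json")
  write_fixture_json(path, list(
    # points are [x, y] = [col, row]
    list(label = "left_eye", shape_type = "rectangle",
         points = list(c(20, 10), c(60, 30))),
    list(label = "left_iris", shape_type = "polygon",
         points = list(c(5, 5), c(9, 5), c(7, 12))),
    list(label = "subnasale", shape_type = "point", points = list(c(50, 70))),
    list(label = "mystery", shape_type = "point", points = list(c(1, 1)))
  ))
  expect_warning(ann <- read_labelme(path), "mystery")
  expect_equal(unlist(ann$boxes$left_eye),
               c(row_min = 10, col_min = 20, row_max = 30, col_max = 60))
  expect_equal(nrow(ann$polygons[[1]]$vertices), 3)
  expect_equal(ann$polygons[[1]]$vertices[1, ], c(row = 5, col = 5))
  expect_equal(ann$landmarks$row[ann$landmarks$name == "subnasale"], 70)
  expect_equal(ann$unknown_labels, "mystery")
})

test_that("malformed annotations raise typed errors", {
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(read_labelme(bad), class = "iriscal_io_error")
  expect_error(read_labelme(file.path(tempdir(), "nope.json")),
               class = "iriscal_io_error")

  short <- withr::local_tempfile(fileext = ".json")
  write_fixture_json(short, list(
    list(label = "eye", shape_type = "rectangle", points = list(c(1, 1)))))
  expect_error(read_labelme(short), class = "iriscal_validation_error",
               regexp = "eye")
})

test_that("polygon_to_mask handles squares, triangles and degenerate input", {
  sq <- polygon_annotation(rbind(c(0, 0), c(0, 9), c(9, 9), c(9, 0)))
  expect_equal(sum(polygon_to_mask(sq, c(20, 20))), 100)

  tri <- polygon_annotation(rbind(c(0, 0), c(0, 9), c(9, 9)))
  got <- polygon_to_mask(tri, c(20, 20))
  # interior from the ray-casting oracle, plus the boundary-inclusion rule
  oracle_interior <- oracle_polygon_mask(tri$vertices, c(20, 20))
  expect_true(all(got[oracle_interior]))
  # triangle area 40.5 -> raster count close to half the square
  expect_gte(sum(got), 50)
  expect_lte(sum(got), 60)

  outside <- polygon_annotation(rbind(c(30, 30), c(30, 40), c(40, 40)))
  expect_equal(sum(polygon_to_mask(outside, c(20, 20))), 0)

  degenerate <- polygon_annotation(rbind(c(1, 1), c(5, 5), c(3, 3)))
  expect_warning(m <- polygon_to_mask(degenerate, c(10, 10)), "zero area")
  expect_equal(sum(m), 0)
})

test_that("polygon_to_mask matches the even-odd oracle on random polygons", {
  withr::with_seed(42, {
    for (rep in 1:6) {
      k <- sample(3:12, 1)
      # non-lattice vertices: no centre lies exactly on an edge, so the
      # boundary tie-break cannot mask an interior disagreement
      v <- cbind(runif(k, 0, 23), runif(k, 0, 23)) + 0.131
      poly <- polygon_annotation(v)
      expect_identical(polygon_to_mask(poly, c(24, 24)),
                       oracle_polygon_mask(v, c(24, 24)))
    }
  })
})

test_that("mask intersection is commutative, idempotent and monotone", {
  a <- matrix(FALSE, 20, 20); a[1:10, 1:10] <- TRUE
  b <- matrix(FALSE, 20, 20); b[6:15, 6:15] <- TRUE
  expect_identical(intersect_masks(a, a), a)
  expect_equal(sum(intersect_masks(a, b)), 25)
  expect_identical(intersect_masks(a, b), intersect_masks(b, a))
  disjoint <- matrix(FALSE, 20, 20); disjoint[15:20, 15:20] <- TRUE
  expect_equal(sum(intersect_masks(a, disjoint)), 0)
  expect_error(intersect_masks(a, matrix(FALSE, 5, 5)),
               class = "iriscal_validation_error")

  withr::with_seed(7, {
    for (rep in 1:10) {
      x <- matrix(runif(400) < 0.4, 20, 20)
      y <- matrix(runif(400) < 0.4, 20, 20)
      expect_lte(sum(intersect_masks(x, y)), min(sum(x), sum(y)))
    }
  })

  # two-annotator rule: one polygon used as-is, two intersected
  p1 <- polygon_annotation(rbind(c(0, 0), c(0, 9), c(9, 9), c(9, 0)))
  p2 <- polygon_annotation(rbind(c(0, 5), c(0, 14), c(9, 14), c(9, 5)))
  expect_equal(sum(ground_truth_mask(list(p1), c(20, 20))), 100)
  expect_equal(sum(ground_truth_mask(list(p1, p2), c(20, 20))), 50)
})

test_that("crop_roi yields an invertible transform and contains the iris", {
  img <- matrix(1:400, 20, 20)
  whole <- crop_roi(img, bbox(0, 0, 19, 19), margin = 0)
  expect_identical(whole$image, img)
  expect_equal(whole$transform$row_offset, 0)

  crop <- crop_roi(img, bbox(3, 5, 10, 12), margin = 2)
  withr::with_seed(1, {
    pts <- cbind(runif(100, 0, 19), runif(100, 0, 19))
    back <- transform_points(transform_points(pts, crop$transform),
                             crop$transform, inverse = TRUE)
    expect_equal(back, pts, tolerance = 1e-12)
  })

  expect_error(crop_roi(img, bbox(30, 30, 40, 40)),
               class = "iriscal_validation_error")

  sc <- tiny_scene()
  for (side in c("left", "right")) {
    mcrop <- crop_roi(sc$iris_masks[[side]], sc$eye_boxes[[side]])
    expect_equal(sum(mcrop$image), sum(sc$iris_masks[[side]]))
  }
})
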