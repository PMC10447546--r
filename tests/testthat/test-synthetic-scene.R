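# Scene generator: geometry arithmetic, determinism, occlusion behaviour,
# population sampling, export round-trips.

test_that("iris diameter and landmark separations follow from the magnification", {
  sc <- make_scene(scene_params(hvid_mm = 12.2, magnification = 5,
                                canthal_distance_mm = 98.06))
  expect_equal(sc$iris_diameter_px, 61)

  lm <- sc$landmarks_px
  pt <- function(nm) unlist(lm[lm$name == nm, c("row", "col")])
  expect_equal(pixel_distance(pt("left_canthus"), pt("right_canthus")),
               490.3, tolerance = 1e-12)
  expect_equal(pixel_distance(pt("subnasale"), pt("submental")),
               69.11 * 5, tolerance = 1e-12)

  # unoccluded chord equals the rasterization oracle on the disk itself
  for (side in c("left", "right")) {
    ctr <- sc$iris_centers[side, ]
    oracle <- oracle_disk(sc$image_size, ctr[1], ctr[2], 61 / 2)
    expect_identical(sc$iris_masks[[side]], oracle)
    expect_equal(hvid_pixels(sc$iris_masks[[side]]), max(rowSums(oracle)))
  }
})

test_that("rendering is deterministic and invalid geometry is rejected", {
  p <- scene_params(magnification = 3, noise_sd = 4, seed = 99L)
  expect_identical(make_scene(p)$image, make_scene(p)$image)

  expect_error(scene_params(hvid_mm = -1), class = "iriscal_invalid_parameter")
  expect_error(scene_params(occlusion_fraction = 0.5),
               class = "iriscal_invalid_parameter")
  expect_error(make_scene(scene_params(image_size = c(50, 50))),
               class = "iriscal_invalid_parameter")
})

test_that("population sampling reproduces the configured distributions", {
  pars <- sample_population_params(500, seed = 5L)
  # SE of the mean is 0.49/sqrt(500) ~ 0.022; 0.1 is > 4 SE
  expect_lt(abs(mean(pars$hvid_mm) - 12.2), 0.1)
  expect_true(all(pars$magnification >= 3 & pars$magnification <= 8))
  expect_true(all(pars$canthal_distance_mm >= 88 &
                    pars$canthal_distance_mm <= 110.7))
  expect_true(all(pars$subnasale_submental_mm >= 47.25 &
                    pars$subnasale_submental_mm <= 86))

  # degenerate distribution
  one <- sample_population(1, hvid_sd = 0, render = FALSE, seed = 2L)
  expect_equal(one[[1]]$params$hvid_mm, 12.2)

  # determinism
  expect_identical(sample_population_params(20, seed = 3L),
                   sample_population_params(20, seed = 3L))

  expect_error(sample_population_params(5, hvid_sd = -1),
               class = "iriscal_invalid_parameter")
  expect_error(sample_population_params(
    5, distance_ranges = list(lateral_canthi = c(110, 88),
                              subnasale_submental = c(47.25, 86))),
    class = "iriscal_invalid_parameter")
})

test_that("oracle calibration on ground truth recovers the true distances", {
  for (seed in 1:4) {
    pars <- sample_population_params(1, seed = seed)
    sc <- make_scene(scene_params(
      hvid_mm = pars$hvid_mm, magnification = pars$magnification,
      canthal_distance_mm = pars$canthal_distance_mm,
      subnasale_submental_mm = pars$subnasale_submental_mm,
      occlusion_fraction = pars$occlusion_fraction), render = FALSE)
    m <- measure_scene_oracle(sc)
    cal <- magnification_ratio(m$hvid_px[["left"]], m$hvid_px[["right"]],
                               assigned_mm = sc$params$hvid_mm)
    pred <- estimate_mm(m$distances_px, cal)
    tol <- 2 / sc$magnification
    expect_lt(abs(pred[["lateral_canthi"]] -
                    sc$true_distances_mm[["lateral_canthi"]]), tol)
    expect_lt(abs(pred[["subnasale_submental"]] -
                    sc$true_distances_mm[["subnasale_submental"]]), tol)
  }
})

test_that("upper-eyelid occlusion spares the widest chord and the eye box", {
  sc0 <- tiny_scene(occlusion_fraction = 0)
  sc3 <- tiny_scene(occlusion_fraction = 0.3)
  for (side in c("left", "right")) {
    expect_equal(hvid_pixels(sc3$iris_masks[[side]]),
                 hvid_pixels(sc0$iris_masks[[side]]))
    expect_lt(sum(sc3$iris_masks[[side]]), sum(sc0$iris_masks[[side]]))
    # every mask pixel lies inside its eye box
    bb <- mask_bbox(sc3$iris_masks[[side]])
    eb <- sc3$eye_boxes[[side]]
    expect_true(bb$row_min >= eb$row_min && bb$row_max <= eb$row_max)
    expect_true(bb$col_min >= eb$col_min && bb$col_max <= eb$col_max)
  }
})

test_that("export round-trips through the annotation reader", {
  dir <- withr::local_tempdir()
  sc <- tiny_scene(occlusion_fraction = 0.15)
  paths <- export_scene(sc, dir, subject_id = "T01")
  expect_true(all(file.exists(paths)))

  ann <- read_labelme(paths[["annotation"]])
  expect_equal(ann$image_size, as.numeric(sc$image_size))
  for (side in c("left", "right")) {
    b <- ann$boxes[[paste0(side, "_eye")]]
    e <- sc$eye_boxes[[side]]
    expect_equal(unlist(b), unlist(e))
  }
  expect_equal(dplyr::arrange(ann$landmarks, .data$name)$row,
               dplyr::arrange(sc$landmarks_px, .data$name)$row,
               tolerance = 1e-9)

  # polygons rasterize back to (nearly) the stored masks
  for (p in ann$polygons) {
    side <- sub("_iris$", "", p$label)
    back <- polygon_to_mask(p, sc$image_size)
    truth <- sc$iris_masks[[side]]
    mismatch <- sum(xor(back, truth)) / sum(truth)
    expect_lt(mismatch, 0.06)  # polygon-vertex quantization only
  }

  truth_csv <- readr::read_csv(paths[["truth"]], show_col_types = FALSE)
  expect_equal(truth_csv$lateral_canthi_mm,
               sc$true_distances_mm[["lateral_canthi"]])
  expect_equal(truth_csv$subnasale_submental_mm,
               sc$true_distances_mm[["subnasale_submental"]])

  # dialect sanity: raw JSON carries the pinned keys
  doc <- jsonlite::fromJSON(paths[["annotation"]], simplifyVector = FALSE)
  expect_true(all(c("imageHeight", "imageWidth", "shapes") %in% names(doc)))
  expect_setequal(unique(vapply(doc$shapes, `[[`, "", "shape_type")),
                  c("rectangle", "polygon", "point"))
})
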