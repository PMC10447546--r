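# Reference detector behaviour and the AP metrics against a brute-force
# PR-curve oracle.

test_that("detector finds both eyes on clean scenes and orders them", {
  for (seed in 1:3) {
    pars <- sample_population_params(1, occlusion_max = 0, seed = seed)
    sc <- make_scene(scene_params(
      hvid_mm = pars$hvid_mm, magnification = pars$magnification,
      canthal_distance_mm = pars$canthal_distance_mm,
      subnasale_submental_mm = pars$subnasale_submental_mm))
    det <- detect_eyes(sc$image)
    expect_equal(det$eye, c("left", "right"))
    for (side in c("left", "right")) {
      b <- det[det$eye == side, ]
      eb <- sc$eye_boxes[[side]]
      ctr <- c((eb$row_min + eb$row_max) / 2, (eb$col_min + eb$col_max) / 2)
      expect_true(b$row_min <= ctr[1] && ctr[1] <= b$row_max)
      expect_true(b$col_min <= ctr[2] && ctr[2] <= b$col_max)
    }
  }
})

test_that("detection failures are typed and count the blobs found", {
  expect_error(detect_eyes(matrix(128, 100, 100)),
               class = "iriscal_detection_failure", regexp = "0 candidate")
  # a single dark blob on a light field: one candidate only
  img <- matrix(220, 120, 120)
  img[30:50, 30:50] <- 30
  expect_error(detect_eyes(img), class = "iriscal_detection_failure",
               regexp = "1 candidate")
})

test_that("mirroring the image mirrors the detections", {
  sc <- tiny_scene()
  det <- detect_eyes(sc$image)
  mirrored <- sc$image[, ncol(sc$image):1]
  det_m <- detect_eyes(mirrored)
  w <- ncol(sc$image) - 1
  expect_equal(det_m$col_min[det_m$eye == "left"],
               w - det$col_max[det$eye == "right"])
  expect_equal(det_m$col_max[det_m$eye == "right"],
               w - det$col_min[det$eye == "left"])
  expect_equal(det_m$row_min, det$row_min)
})

test_that("box IoU follows area arithmetic", {
  a <- bbox(0, 0, 9, 9)
  expect_equal(box_iou(a, a), 1)
  expect_equal(box_iou(a, bbox(20, 20, 29, 29)), 0)
  # 10x10 boxes overlapping in a 5x10 region
  b <- bbox(5, 0, 14, 9)
  expect_equal(box_iou(a, b), 50 / 150)
  expect_equal(box_iou(b, a), box_iou(a, b))
})

test_that("average precision matches the brute-force PR oracle", {
  expect_error(average_precision(tibble::tibble(), tibble::tibble()),
               class = "iriscal_undefined_metric")

  truths <- tibble::tibble(image = c(1, 1),
                           row_min = c(0, 50), col_min = c(0, 50),
                           row_max = c(9, 59), col_max = c(9, 59))
  expect_equal(average_precision(NULL, truths), 0)

  # perfect detections, no false positives -> 100
  perfect <- dplyr::mutate(truths, score = c(0.9, 0.8))
  expect_equal(average_precision(perfect, truths, 0.5), 100)
  expect_equal(average_precision(perfect, truths, 0.75), 100)

  # one perfect + one spurious detection
  dets <- tibble::tibble(
    image = c(1, 1),
    row_min = c(0, 100), col_min = c(0, 100),
    row_max = c(9, 109), col_max = c(9, 109),
    score = c(0.9, 0.8))
  for (interp in c("101", "all")) {
    expect_equal(average_precision(dets, truths, 0.5, interp),
                 oracle_average_precision(dets, truths, 0.5, interp))
  }

  # randomized 3-box cases, exact agreement with the oracle
  withr::with_seed(21, {
    for (rep in 1:8) {
      tr <- tibble::tibble(image = 1,
                           row_min = c(0, 40, 80), col_min = c(0, 40, 80),
                           row_max = c(19, 59, 99), col_max = c(19, 59, 99))
      jit <- sample(0:15, 3, replace = TRUE)
      de <- tibble::tibble(image = 1,
                           row_min = tr$row_min + jit,
                           col_min = tr$col_min,
                           row_max = tr$row_max + jit,
                           col_max = tr$col_max,
                           score = runif(3))
      for (thr in c(0.3, 0.5, 0.75)) {
        expect_equal(average_precision(de, tr, thr),
                     oracle_average_precision(de, tr, thr))
      }
    }
  })
})

test_that("AP is non-increasing in the IoU threshold", {
  withr::with_seed(9, {
    for (rep in 1:5) {
      tr <- tibble::tibble(image = rep(1:2, each = 2),
                           row_min = rep(c(0, 50), 2), col_min = rep(c(0, 50), 2),
                           row_max = rep(c(19, 69), 2), col_max = rep(c(19, 69), 2))
      de <- dplyr::mutate(tr,
                          row_min = .data$row_min + sample(0:10, 4, TRUE),
                          row_max = .data$row_max + sample(0:10, 4, TRUE),
                          score = runif(4))
      aps <- vapply(c(0.3, 0.5, 0.7, 0.9),
                    function(t) average_precision(de, tr, t), 0)
      expect_true(all(diff(aps) <= 1e-9))
    }
  })
})

test_that("the reference detector is perfect on noiseless scenes", {
  scenes <- sample_population(6, occlusion_max = 0, seed = 31L)
  metrics <- evaluate_detector(scenes)
  expect_equal(metrics$ap_by_threshold$ap, c(100, 100))
  expect_equal(metrics$map, 100)
  expect_equal(glance(metrics)$map, 100)
  expect_equal(tidy(metrics)$iou_threshold, c(0.5, 0.75))
})
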