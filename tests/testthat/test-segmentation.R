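# Reference segmenter, confusion counts, metric identities, CV folds and
# the fold-wise evaluation harness.

make_iris_roi <- function(radius = 30, occlusion = 0, size = 101,
                          bg = 200, fg = 60) {
  img <- matrix(bg, size, size)
  ctr <- (size - 1) / 2
  rows <- 0:(size - 1)
  disk <- outer((rows - ctr)^2, (rows - ctr)^2, `+`) <= radius^2
  if (occlusion > 0) disk[rows < ctr - radius + occlusion * 2 * radius, ] <- FALSE
  img[disk] <- fg
  list(image = img, truth = disk)
}

test_that("segmenter recovers a clean iris disk within 5% of its area", {
  roi <- make_iris_roi(radius = 30)
  mask <- segment_iris(roi$image)
  expect_lt(abs(sum(mask) - pi * 30^2) / (pi * 30^2), 0.05)
  expect_error(segment_iris(matrix(128, 64, 64)),
               class = "iriscal_segmentation_failure")
})

test_that("20% upper occlusion leaves the widest mask row at full diameter", {
  roi <- make_iris_roi(radius = 30, occlusion = 0.2)
  mask <- segment_iris(roi$image)
  expect_gte(hvid_pixels(mask), 59)
  expect_lte(hvid_pixels(mask), 63)
})

test_that("confusion counts follow overlap arithmetic", {
  tr <- matrix(FALSE, 20, 20); tr[6:15, 6:15] <- TRUE
  expect_equal(confusion_counts(tr, tr),
               tibble::tibble(tp = 100, fp = 0, fn = 0, tn = 300))
  empty <- matrix(FALSE, 20, 20)
  cc <- confusion_counts(empty, tr)
  expect_equal(cc$tp, 0); expect_equal(cc$fn, 100)
  shifted <- matrix(FALSE, 20, 20); shifted[6:15, 8:17] <- TRUE
  expect_equal(confusion_counts(shifted, tr),
               tibble::tibble(tp = 80, fp = 20, fn = 20, tn = 280))
  expect_error(confusion_counts(tr, matrix(FALSE, 5, 5)),
               class = "iriscal_validation_error")
})

test_that("segmentation metrics match the formulas and their identities", {
  m <- segmentation_metrics(list(tp = 8, fp = 2, fn = 2, tn = 88))
  expect_equal(m$dice, 80)
  expect_equal(m$iou, 100 * 2 / 3)
  expect_equal(m$precision, 80)
  expect_equal(m$recall, 80)
  expect_equal(m$jaccard_distance, 1 / 3)

  perfect <- segmentation_metrics(list(tp = 50, fp = 0, fn = 0, tn = 50))
  expect_equal(perfect$dice, 100)
  expect_equal(perfect$iou, 100)

  disjoint <- segmentation_metrics(list(tp = 0, fp = 10, fn = 10, tn = 80))
  expect_equal(disjoint$dice, 0)
  expect_equal(disjoint$iou, 0)

  expect_error(segmentation_metrics(list(tp = 0, fp = 0, fn = 0, tn = 0)),
               class = "iriscal_undefined_metric")

  withr::with_seed(17, {
    for (rep in 1:20) {
      counts <- list(tp = sample(1:500, 1), fp = sample(0:100, 1),
                     fn = sample(0:100, 1), tn = sample(0:1000, 1))
      mm <- segmentation_metrics(counts)
      iou_f <- mm$iou / 100
      expect_equal(mm$dice / 100, 2 * iou_f / (1 + iou_f), tolerance = 1e-12)
      expect_equal(mm$jaccard_distance, 1 - iou_f, tolerance = 1e-12)
      expect_gte(mm$precision, mm$iou)
      expect_gte(mm$recall, mm$iou)
    }
  })
})

test_that("cross-validation folds partition the items evenly", {
  folds <- cross_validation_folds(500, k = 5, seed = 4L)
  sizes <- vapply(folds, function(f) length(f$validation), 0L)
  expect_equal(sizes, rep(100L, 5))
  all_val <- sort(unlist(lapply(folds, `[[`, "validation")))
  expect_equal(all_val, 1:500)
  for (f in folds) {
    expect_length(intersect(f$train, f$validation), 0)
    expect_equal(sort(c(f$train, f$validation)), 1:500)
  }
  expect_identical(cross_validation_folds(37, seed = 2L),
                   cross_validation_folds(37, seed = 2L))
  expect_error(cross_validation_folds(3, k = 5),
               class = "iriscal_invalid_parameter")
  expect_error(cross_validation_folds(10, k = 1),
               class = "iriscal_invalid_parameter")
})

test_that("evaluation harness: oracle is perfect, empty has zero recall", {
  scenes <- sample_population(5, seed = 8L)
  folds <- cross_validation_folds(10, k = 5, seed = 1L)

  ev <- evaluate_segmenter(scenes, segmenter = oracle_segmenter, folds = folds)
  expect_true(all(abs(ev$summary$mean[ev$summary$metric != "jaccard_distance"]
                      - 100) < 1e-9))
  expect_true(all(ev$summary$sd < 1e-9))
  expect_equal(ev$n_failures, 0)

  ev0 <- evaluate_segmenter(scenes, segmenter = empty_segmenter, folds = folds)
  expect_equal(ev0$summary$mean[ev0$summary$metric == "recall"], 0)
})

test_that("reference segmenter clears the dice floor on clean scenes", {
  scenes <- sample_population(5, occlusion_max = 0, seed = 12L)
  ev <- evaluate_segmenter(scenes)
  expect_gte(ev$summary$mean[ev$summary$metric == "dice"], 95)
  expect_equal(ev$n_failures, 0)
  g <- glance(ev)
  expect_gte(g$accuracy, 95)
})

test_that("published segmentation tables satisfy 1 - IoU = Jaccard distance", {
  tab <- readr::read_csv(
    system.file("extdata", "published_segmentation_summary.csv",
                package = "iriscal"),
    show_col_types = FALSE)
  checked <- validate_segmentation_summary(tab)
  expect_true(all(checked$consistent))
})
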