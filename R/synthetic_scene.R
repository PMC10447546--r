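# Synthetic frontal-scene generator.
#
# Scenes are schematic frontal "faces" with exhaustively known ground truth:
# a light background, a skin-tone face ellipse, two bright eye openings
# (palpebral fissures), dark circular irises with darker pupils, optional
# upper-eyelid occlusion, and four landmarks (left/right lateral canthus,
# subnasale, submental). Every quantity the measurement pipeline is supposed
# to recover -- iris diameter in px, magnification in px/mm, landmark
# distances in mm and px -- is stored exactly, pre-rasterization, so
# detection, segmentation, calibration and error analysis can all be tested
# against a perfect oracle.

# Gray levels used by the renderer (8-bit scale).
.scene_gray <- list(background = 230, face = 190, sclera = 250,
                    iris = 60, pupil = 20, eyelid = 170)

# Face layout in millimetre space, as fractions of the two measured
# distances. Origin is the midpoint between the eyes on the inter-canthal
# line; +y runs down the face, +x to the subject's image-right.
.scene_layout <- list(
  iris_x_frac    = 0.32,  # iris centre at +/- 0.32 * canthal distance
  eye_half_h     = 1.1,   # eye-opening vertical semi-axis, in iris radii
  subnasale_frac = 0.55,  # eye line -> subnasale, as fraction of the
                          # subnasale-submental distance
  forehead_mm    = 30,    # face ellipse extends this far above the eye line
  cheek_mm       = 12,    # face ellipse half-width beyond the canthi
  margin_px      = 10     # background margin around the face ellipse
)

#' Parameters of a synthetic frontal scene
#'
#' Defaults describe one "average" subject: HVID 12.2 mm, inter-canthal
#' distance 98.06 mm and subnasale-submental distance 69.11 mm (population
#' means of the two distances this calibration technique is validated on),
#' rendered at 5 px/mm with no occlusion and no noise.
#'
#' @param hvid_mm True horizontal visible iris diameter, mm.
#' @param magnification Scene scale, px per mm.
#' @param canthal_distance_mm Distance between the lateral canthi, mm
#'   (the horizontal test distance).
#' @param subnasale_submental_mm Distance from subnasale to submental, mm
#'   (the vertical test distance).
#' @param occlusion_fraction Fraction of the iris height hidden by the upper
#'   eyelid, in `[0, 0.4]`. Up to 0.4 the horizontal equator of the iris
#'   stays visible, so the widest chord is unaffected.
#' @param image_size Optional `(rows, cols)` in px. `NULL` (default) sizes
#'   the image to fit the face with a small margin; an explicit size that
#'   cannot contain the face is an error.
#' @param noise_sd Additive Gaussian pixel noise SD in gray levels, clipped
#'   to `[0, 255]`. Default 0: renders are exact and bit-reproducible.
#' @param seed Integer seed controlling the (optional) noise.
#' @return A `scene_params` object.
#' @export
scene_params <- function(hvid_mm = 12.2,
                         magnification = 5,
                         canthal_distance_mm = 98.06,
                         subnasale_submental_mm = 69.11,
                         occlusion_fraction = 0,
                         image_size = NULL,
                         noise_sd = 0,
                         seed = 1L) {
  if (!is.finite(hvid_mm) || hvid_mm <= 0) stop_invalid("hvid_mm must be > 0")
  if (!is.finite(magnification) || magnification <= 0) {
    stop_invalid("magnification must be > 0")
  }
  if (canthal_distance_mm <= 0 || subnasale_submental_mm <= 0) {
    stop_invalid("landmark distances must be > 0")
  }
  if (occlusion_fraction < 0 || occlusion_fraction > 0.4) {
    stop_invalid("occlusion_fraction must lie in [0, 0.4]")
  }
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  if (!is.null(image_size) &&
      (length(image_size) != 2 || any(image_size < 8))) {
    stop_invalid("image_size must be (rows, cols), both >= 8")
  }
  structure(
    list(hvid_mm = hvid_mm, magnification = magnification,
         canthal_distance_mm = canthal_distance_mm,
         subnasale_submental_mm = subnasale_submental_mm,
         occlusion_fraction = occlusion_fraction,
         image_size = image_size, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "scene_params"
  )
}

# mm-space geometry of a scene: landmark positions, ellipse axes, extents.
scene_geometry <- function(params) {
  L <- .scene_layout
  C <- params$canthal_distance_mm
  V <- params$subnasale_submental_mm
  r <- params$hvid_mm / 2
  y_sn <- L$subnasale_frac * V
  y_sub <- y_sn + V
  eye_b <- L$eye_half_h * r
  face_b <- (y_sub + L$forehead_mm) / 2
  face_cy <- (y_sub - L$forehead_mm) / 2
  # the face ellipse must cover the eye openings: at the canthus x its
  # upper boundary has to clear the eye box by a few mm
  q <- (face_cy + eye_b + 3) / face_b
  face_a <- max(C / 2 + L$cheek_mm, (C / 2) / sqrt(1 - q^2))
  list(
    iris_x = L$iris_x_frac * C,
    iris_r = r,
    eye_a = C / 2 - L$iris_x_frac * C,  # eye-opening horizontal semi-axis
    eye_b = eye_b,                      # eye-opening vertical semi-axis
    y_sn = y_sn, y_sub = y_sub,
    face_a = face_a,
    face_b = face_b,
    face_cy = face_cy,
    y_top = -L$forehead_mm, y_bot = y_sub
  )
}

# Paint an axis-aligned ellipse onto img (pixel-centre inclusion, boundary
# included); operates on the local bounding window only.
paint_ellipse <- function(img, cr, cc, sr, sc, value, row_min_keep = -Inf) {
  r0 <- max(floor(cr - sr), 0); r1 <- min(ceiling(cr + sr), nrow(img) - 1)
  c0 <- max(floor(cc - sc), 0); c1 <- min(ceiling(cc + sc), ncol(img) - 1)
  if (r0 > r1 || c0 > c1) return(img)
  rows <- r0:r1; cols <- c0:c1
  inside <- outer(((rows - cr) / sr)^2, ((cols - cc) / sc)^2, `+`) <= 1
  if (row_min_keep > -Inf) inside <- inside & (rows >= row_min_keep)
  sub <- img[rows + 1, cols + 1, drop = FALSE]
  sub[inside] <- value
  img[rows + 1, cols + 1] <- sub
  img
}

# Rasterize a disk into a full-frame logical mask, optionally clipped below
# an occlusion row (pixel centres with row < occl_row are hidden).
disk_mask <- function(shape, cr, cc, radius, occl_row = -Inf) {
  mask <- matrix(FALSE, shape[1], shape[2])
  r0 <- max(floor(cr - radius), 0); r1 <- min(ceiling(cr + radius), shape[1] - 1)
  c0 <- max(floor(cc - radius), 0); c1 <- min(ceiling(cc + radius), shape[2] - 1)
  if (r0 > r1 || c0 > c1) return(mask)
  rows <- r0:r1; cols <- c0:c1
  inside <- outer((rows - cr)^2, (cols - cc)^2, `+`) <= radius^2
  if (occl_row > -Inf) inside <- inside & (rows >= occl_row)
  mask[rows + 1, cols + 1] <- inside
  mask
}

#' Generate one synthetic frontal scene
#'
#' Deterministic for a fixed `params` (the seed only feeds the optional
#' noise). The returned ground truth stores the pre-rasterization iris
#' diameter `hvid_mm * magnification` exactly and landmark pixel positions
#' unrounded, so calibration against the oracle is exact up to
#' rasterization.
#'
#' @param params A [scene_params()] object.
#' @param render If `FALSE`, skip rendering the raster and the iris masks
#'   (geometry and ground truth only). Useful for large measurement-level
#'   simulations where the image itself is never inspected.
#' @return A `synthetic_scene`: list with `params`, `image` (numeric matrix,
#'   0..255), `iris_centers` (2 x 2 matrix, rows left/right), `iris_diameter_px`,
#'   `eye_boxes` (list of two [bbox()]), `iris_masks` (list of two logical
#'   matrices, full-image frame), `landmarks_px` (tibble `name`, `row`, `col`),
#'   `true_distances_mm` (named vector), `magnification`.
#' @export
#' @examples
#' sc <- make_scene(scene_params(magnification = 3))
#' sc$iris_diameter_px # 12.2 * 3
make_scene <- function(params, render = TRUE) {
  stopifnot(inherits(params, "scene_params"))
  g <- scene_geometry(params)
  m <- params$magnification
  L <- .scene_layout

  width_px  <- 2 * g$face_a * m + 2 * L$margin_px
  height_px <- (g$y_bot - g$y_top) * m + 2 * L$margin_px
  if (is.null(params$image_size)) {
    shape <- c(ceiling(height_px), ceiling(width_px))
  } else {
    shape <- as.integer(params$image_size)
    if (shape[1] < height_px || shape[2] < width_px) {
      stop_invalid(sprintf(
        "face geometry (%.0f x %.0f px) does not fit image_size (%d x %d)",
        height_px, width_px, shape[1], shape[2]))
    }
  }
  # mm -> px mapping: face centred horizontally, eye line below the margin
  col0 <- (shape[2] - 1) / 2
  row0 <- L$margin_px - g$y_top * m
  to_px <- function(x_mm, y_mm) c(row0 + y_mm * m, col0 + x_mm * m)

  iris_d_px <- params$hvid_mm * m
  iris_r_px <- iris_d_px / 2
  centers <- rbind(left  = to_px(-g$iris_x, 0),
                   right = to_px(+g$iris_x, 0))
  colnames(centers) <- c("row", "col")

  landmarks_px <- tibble::tibble(
    name = c("left_canthus", "right_canthus", "subnasale", "submental"),
    row  = c(to_px(-params$canthal_distance_mm / 2, 0)[1],
             to_px(+params$canthal_distance_mm / 2, 0)[1],
             to_px(0, g$y_sn)[1], to_px(0, g$y_sub)[1]),
    col  = c(to_px(-params$canthal_distance_mm / 2, 0)[2],
             to_px(+params$canthal_distance_mm / 2, 0)[2],
             to_px(0, g$y_sn)[2], to_px(0, g$y_sub)[2])
  )

  eye_boxes <- lapply(1:2, function(i) {
    cr <- centers[i, 1]; cc <- centers[i, 2]
    bbox(floor(cr - g$eye_b * m), floor(cc - g$eye_a * m),
         ceiling(cr + g$eye_b * m), ceiling(cc + g$eye_a * m))
  })
  names(eye_boxes) <- c("left", "right")
  for (b in eye_boxes) {
    if (b$row_min < 0 || b$col_min < 0 ||
        b$row_max > shape[1] - 1 || b$col_max > shape[2] - 1) {
      stop_invalid("eye boxes do not fit inside the image")
    }
  }

  occ <- params$occlusion_fraction
  occl_rows <- centers[, 1] - iris_r_px + occ * iris_d_px

  image <- NULL
  iris_masks <- NULL
  if (render) {
    gl <- .scene_gray
    img <- matrix(gl$background, shape[1], shape[2])
    face_c <- to_px(0, g$face_cy)
    img <- paint_ellipse(img, face_c[1], face_c[2],
                         g$face_b * m, g$face_a * m, gl$face)
    for (i in 1:2) {
      cr <- centers[i, 1]; cc <- centers[i, 2]
      img <- paint_ellipse(img, cr, cc, g$eye_b * m, g$eye_a * m, gl$sclera)
      img <- paint_ellipse(img, cr, cc, iris_r_px, iris_r_px, gl$iris,
                           row_min_keep = if (occ > 0) occl_rows[i] else -Inf)
      img <- paint_ellipse(img, cr, cc, 0.35 * iris_r_px, 0.35 * iris_r_px,
                           gl$pupil,
                           row_min_keep = if (occ > 0) occl_rows[i] else -Inf)
      if (occ > 0) {
        # eyelid arc: the hidden top of the iris painted in lid tone
        lid <- disk_mask(shape, cr, cc, iris_r_px)
        lid_rows <- which(lid, arr.ind = TRUE)
        hide <- lid_rows[lid_rows[, 1] - 1 < occl_rows[i], , drop = FALSE]
        img[hide] <- gl$eyelid
      }
    }
    if (params$noise_sd > 0) {
      img <- withr::with_seed(params$seed, {
        img + matrix(stats::rnorm(length(img), 0, params$noise_sd),
                     nrow(img), ncol(img))
      })
    }
    image <- round(pmin(pmax(img, 0), 255))
    iris_masks <- lapply(1:2, function(i) {
      disk_mask(shape, centers[i, 1], centers[i, 2], iris_r_px,
                occl_row = if (occ > 0) occl_rows[i] else -Inf)
    })
    names(iris_masks) <- c("left", "right")
  }

  structure(
    list(
      params = params,
      image = image,
      image_size = shape,
      iris_centers = centers,
      iris_diameter_px = iris_d_px,
      magnification = m,
      eye_boxes = eye_boxes,
      iris_masks = iris_masks,
      landmarks_px = landmarks_px,
      true_distances_mm = c(lateral_canthi = params$canthal_distance_mm,
                            subnasale_submental = params$subnasale_submental_mm)
    ),
    class = "synthetic_scene"
  )
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene %dx%d px, HVID %.3g mm @ %.3g px/mm (iris %.3g px)%s>\n",
    x$image_size[1], x$image_size[2], x$params$hvid_mm, x$magnification,
    x$iris_diameter_px, if (is.null(x$image)) ", unrendered" else ""))
  invisible(x)
}

#' Draw per-subject scene parameters for a simulated population
#'
#' True HVID is drawn from a normal distribution (defaults: mean 12.2 mm,
#' SD 0.49 mm -- the population variability reported for adult HVID);
#' magnification and the two landmark distances are drawn uniformly from
#' their ranges; occlusion uniformly from `[0, occlusion_max]`.
#'
#' @param n Number of subjects.
#' @param hvid_mean,hvid_sd Normal distribution of true HVID, mm.
#' @param magnification_range `(min, max)` px/mm.
#' @param distance_ranges Named list with `lateral_canthi` and
#'   `subnasale_submental`, each `(min, max)` mm.
#' @param occlusion_max Maximal upper-eyelid occlusion fraction.
#' @param noise_sd Pixel noise SD passed to every scene.
#' @param seed Integer seed; the whole draw (including per-scene render
#'   seeds) is reproducible from it.
#' @return A tibble with one row per subject: `subject_id`, `hvid_mm`,
#'   `magnification`, `canthal_distance_mm`, `subnasale_submental_mm`,
#'   `occlusion_fraction`, `noise_sd`, `seed`.
#' @export
sample_population_params <- function(n,
                                     hvid_mean = 12.2, hvid_sd = 0.49,
                                     magnification_range = c(3, 8),
                                     distance_ranges = list(
                                       lateral_canthi = c(88, 110.7),
                                       subnasale_submental = c(47.25, 86)),
                                     occlusion_max = 0.2,
                                     noise_sd = 0,
                                     seed = 1L) {
  if (n < 1) stop_invalid("n must be >= 1")
  if (hvid_sd < 0) stop_invalid("hvid_sd must be >= 0")
  if (diff(magnification_range) < 0) stop_invalid("magnification_range inverted")
  for (nm in c("lateral_canthi", "subnasale_submental")) {
    rg <- distance_ranges[[nm]]
    if (is.null(rg) || length(rg) != 2 || diff(rg) < 0) {
      stop_invalid(sprintf("distance_ranges$%s missing or inverted", nm))
    }
  }
  if (occlusion_max < 0 || occlusion_max > 0.4) {
    stop_invalid("occlusion_max must lie in [0, 0.4]")
  }
  withr::with_seed(as.integer(seed), {
    hvid <- stats::rnorm(n, hvid_mean, hvid_sd)
    while (any(hvid <= 0)) { # pathological tails only
      hvid[hvid <= 0] <- stats::rnorm(sum(hvid <= 0), hvid_mean, hvid_sd)
    }
    tibble::tibble(
      subject_id = sprintf("S%04d", seq_len(n)),
      hvid_mm = hvid,
      magnification = stats::runif(n, magnification_range[1],
                                   magnification_range[2]),
      canthal_distance_mm = stats::runif(n, distance_ranges$lateral_canthi[1],
                                         distance_ranges$lateral_canthi[2]),
      subnasale_submental_mm = stats::runif(
        n, distance_ranges$subnasale_submental[1],
        distance_ranges$subnasale_submental[2]),
      occlusion_fraction = stats::runif(n, 0, occlusion_max),
      noise_sd = noise_sd,
      seed = sample.int(.Machine$integer.max, n)
    )
  })
}

#' Generate a simulated population of scenes
#'
#' Convenience wrapper: [sample_population_params()] followed by
#' [make_scene()] per subject.
#'
#' @inheritParams sample_population_params
#' @param render Render rasters and masks (`TRUE`) or ground truth only.
#' @param ... Passed to [sample_population_params()].
#' @return List of `synthetic_scene` objects; subject ids in
#'   `names()` and in each scene's `subject_id` field.
#' @export
sample_population <- function(n, ..., render = TRUE) {
  pars <- sample_population_params(n, ...)
  scenes <- purrr::pmap(pars, function(subject_id, hvid_mm, magnification,
                                       canthal_distance_mm,
                                       subnasale_submental_mm,
                                       occlusion_fraction, noise_sd, seed) {
    sc <- make_scene(scene_params(
      hvid_mm = hvid_mm, magnification = magnification,
      canthal_distance_mm = canthal_distance_mm,
      subnasale_submental_mm = subnasale_submental_mm,
      occlusion_fraction = occlusion_fraction,
      noise_sd = noise_sd, seed = seed), render = render)
    sc$subject_id <- subject_id
    sc
  })
  names(scenes) <- pars$subject_id
  scenes
}

# Boundary polygon of the visible iris (circle arc plus, when occluded, the
# eyelid chord closing the top). Used by export_scene.
iris_polygon <- function(center, radius, occlusion_fraction, n_vertices = 72) {
  cr <- center[1]; cc <- center[2]
  if (occlusion_fraction > 0) {
    s0 <- 2 * occlusion_fraction - 1        # sin of the chord elevation
    a0 <- asin(s0); a1 <- pi - a0           # visible arc, through the bottom
    a <- seq(a0, a1, length.out = n_vertices)
  } else {
    a <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  }
  polygon_annotation(cbind(row = cr + radius * sin(a),
                           col = cc + radius * cos(a)),
                     label = "iris")
}

#' Export a scene as image + annotation + truth table
#'
#' Writes the study's artifact set for one subject: `<id>.png` (the image),
#' `<id>.json` (LabelMe-dialect annotation with the two eye rectangles, two
#' iris polygons and four landmark points) and `<id>.csv` (one row of true
#' millimetre distances -- the synthetic counterpart of the caliper table).
#'
#' @param scene A rendered `synthetic_scene`.
#' @param directory Output directory (created if missing).
#' @param subject_id File stem; defaults to the scene's id or `"scene"`.
#' @return Invisibly, the named character vector of written paths.
#' @export
export_scene <- function(scene, directory, subject_id = NULL) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (is.null(scene$image)) stop_validation("scene was generated with render = FALSE")
  subject_id <- subject_id %||% scene$subject_id %||% "scene"
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_io(sprintf("cannot create directory '%s'", directory))
  }
  paths <- c(image = file.path(directory, paste0(subject_id, ".png")),
             annotation = file.path(directory, paste0(subject_id, ".json")),
             truth = file.path(directory, paste0(subject_id, ".csv")))

  png::writePNG(scene$image / 255, paths[["image"]])

  boxes <- scene$eye_boxes
  polys <- lapply(c("left", "right"), function(side) {
    p <- iris_polygon(scene$iris_centers[side, ], scene$iris_diameter_px / 2,
                      scene$params$occlusion_fraction)
    p$label <- paste0(side, "_iris")
    p
  })
  landmarks <- scene$landmarks_px
  write_labelme(paths[["annotation"]],
                image_size = scene$image_size,
                boxes = list(left_eye = boxes$left, right_eye = boxes$right),
                polygons = polys,
                landmarks = landmarks)

  readr::write_csv(tibble::tibble(
    subject_id = subject_id,
    lateral_canthi_mm = scene$true_distances_mm[["lateral_canthi"]],
    subnasale_submental_mm = scene$true_distances_mm[["subnasale_submental"]]
  ), paths[["truth"]])
  invisible(paths)
}

#' Export a population: per-scene artifacts plus a pooled truth table
#'
#' @param scenes List of rendered scenes (as from [sample_population()]).
#' @param directory Output directory.
#' @return Invisibly, the path of the pooled `truth.csv`.
#' @export
export_population <- function(scenes, directory) {
  ids <- names(scenes) %||% sprintf("S%04d", seq_along(scenes))
  rows <- purrr::map2(scenes, ids, function(sc, id) {
    export_scene(sc, directory, subject_id = id)
    tibble::tibble(subject_id = id,
                   lateral_canthi_mm = sc$true_distances_mm[["lateral_canthi"]],
                   subnasale_submental_mm =
                     sc$true_distances_mm[["subnasale_submental"]])
  })
  path <- file.path(directory, "truth.csv")
  readr::write_csv(dplyr::bind_rows(rows), path)
  invisible(path)
}
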