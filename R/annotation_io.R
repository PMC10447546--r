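# Annotation I/O: a pinned LabelMe-style JSON dialect (rectangles for eye
# boxes, polygons for iris contours, points for landmarks), polygon
# rasterization with a deterministic pixel-centre even-odd rule, and the
# two-annotator intersection rule for ground-truth masks.
#
# Dialect: top-level `imageHeight`, `imageWidth`, `shapes[]`, each shape
# carrying `label`, `points` (list of [x, y] with x = column first, as
# LabelMe stores them) and `shape_type` in {rectangle, polygon, point}.
# Internally everything is (row, col).

.landmark_names <- c("left_canthus", "right_canthus", "subnasale", "submental")

#' Create a polygon annotation
#'
#' @param vertices Numeric matrix (n x 2) of real-valued `(row, col)`
#'   vertices; the polygon is implicitly closed.
#' @param label Annotation label.
#' @return A `polygon_annotation`.
#' @export
polygon_annotation <- function(vertices, label = "polygon") {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3 || ncol(vertices) != 2 || any(!is.finite(vertices))) {
    stop_validation(sprintf(
      "polygon '%s' needs >= 3 finite (row, col) vertices", label))
  }
  colnames(vertices) <- c("row", "col")
  structure(list(vertices = vertices, label = label),
            class = "polygon_annotation")
}

#' @export
print.polygon_annotation <- function(x, ...) {
  cat(sprintf("<polygon_annotation '%s', %d vertices>\n",
              x$label, nrow(x$vertices)))
  invisible(x)
}

shoelace_area <- function(v) {
  r <- v[, 1]; c <- v[, 2]
  rn <- c(r[-1], r[1]); cn <- c(c[-1], c[1])
  abs(sum(c * rn - cn * r)) / 2
}

#' Rasterize a polygon to a binary mask
#'
#' A pixel is a member iff its centre lies inside the implicitly closed
#' polygon under the even-odd rule; centres lying exactly on an edge are
#' included (deterministic tie-break). Scanline implementation with
#' half-open vertex handling.
#'
#' @param polygon A [polygon_annotation()].
#' @param shape `(rows, cols)` of the target mask.
#' @return Logical matrix of dimension `shape`.
#' @export
#' @examples
#' sq <- polygon_annotation(rbind(c(0, 0), c(0, 9), c(9, 9), c(9, 0)))
#' sum(polygon_to_mask(sq, c(20, 20))) # 100
polygon_to_mask <- function(polygon, shape) {
  stopifnot(inherits(polygon, "polygon_annotation"))
  shape <- as.integer(shape)
  mask <- matrix(FALSE, shape[1], shape[2])
  v <- polygon$vertices
  if (shoelace_area(v) == 0) {
    rlang::warn(sprintf("polygon '%s' has zero area; returning an empty mask",
                        polygon$label))
    return(mask)
  }
  n <- nrow(v)
  r1 <- v[, 1]; c1 <- v[, 2]
  r2 <- c(r1[-1], r1[1]); c2 <- c(c1[-1], c1[1])

  # interior: per-row scanline, half-open edge rule (min <= y < max)
  row_lo <- max(0L, floor(min(r1)))
  row_hi <- min(shape[1] - 1L, ceiling(max(r1)))
  if (row_lo <= row_hi) {
    for (i in row_lo:row_hi) {
      lo <- pmin(r1, r2); hi <- pmax(r1, r2)
      hit <- which(lo <= i & i < hi)
      if (length(hit) == 0) next
      t <- (i - r1[hit]) / (r2[hit] - r1[hit])
      x <- sort(c1[hit] + t * (c2[hit] - c1[hit]))
      for (k in seq(1, length(x) - 1, by = 2)) {
        j0 <- max(0L, ceiling(x[k]))
        j1 <- min(shape[2] - 1L, ceiling(x[k + 1]) - 1L)
        if (j0 <= j1) mask[i + 1, (j0:j1) + 1] <- TRUE
      }
    }
  }

  # boundary: integer centres lying exactly on an edge are members
  eps <- 1e-9
  for (e in seq_len(n)) {
    if (r1[e] == r2[e]) {           # horizontal edge
      if (abs(r1[e] - round(r1[e])) < eps) {
        i <- round(r1[e])
        if (i >= 0 && i <= shape[1] - 1) {
          j0 <- max(0L, ceiling(min(c1[e], c2[e]) - eps))
          j1 <- min(shape[2] - 1L, floor(max(c1[e], c2[e]) + eps))
          if (j0 <= j1) mask[i + 1, (j0:j1) + 1] <- TRUE
        }
      }
    } else {
      ii <- seq(max(0, ceiling(min(r1[e], r2[e]) - eps)),
                min(shape[1] - 1, floor(max(r1[e], r2[e]) + eps)))
      if (length(ii) == 0 || ii[1] > ii[length(ii)]) next
      t <- (ii - r1[e]) / (r2[e] - r1[e])
      xx <- c1[e] + t * (c2[e] - c1[e])
      on <- which(abs(xx - round(xx)) < eps &
                    round(xx) >= 0 & round(xx) <= shape[2] - 1)
      if (length(on)) mask[cbind(ii[on] + 1, round(xx[on]) + 1)] <- TRUE
    }
  }
  mask
}

#' Ground-truth mask from one or two iris polygons
#'
#' Implements the two-annotator rule: with two polygons the agreed mask is
#' the intersection of their rasterizations; with a single polygon the
#' intersection step is skipped.
#'
#' @param polygons List of one or two [polygon_annotation()]s.
#' @param shape `(rows, cols)` of the mask.
#' @return Logical matrix.
#' @export
ground_truth_mask <- function(polygons, shape) {
  if (length(polygons) == 0) stop_validation("no polygons supplied")
  masks <- lapply(polygons, polygon_to_mask, shape = shape)
  Reduce(intersect_masks, masks)
}

labelme_shape <- function(label, type, points_rc) {
  # points are stored [x, y] = [col, row]
  list(label = label,
       points = lapply(seq_len(nrow(points_rc)),
                       function(i) c(points_rc[i, 2], points_rc[i, 1])),
       shape_type = type)
}

#' Write a LabelMe-dialect annotation file
#'
#' @param path Output JSON path.
#' @param image_size `(rows, cols)` of the annotated image.
#' @param boxes Named list of [bbox()] (names become labels).
#' @param polygons List of [polygon_annotation()]s.
#' @param landmarks Tibble/data frame with `name`, `row`, `col` (optional).
#' @return Invisibly, `path`.
#' @export
write_labelme <- function(path, image_size, boxes = list(),
                          polygons = list(), landmarks = NULL) {
  shapes <- list()
  for (lab in names(boxes)) {
    b <- boxes[[lab]]
    shapes <- c(shapes, list(labelme_shape(
      lab, "rectangle",
      rbind(c(b$row_min, b$col_min), c(b$row_max, b$col_max)))))
  }
  for (p in polygons) {
    shapes <- c(shapes, list(labelme_shape(p$label, "polygon", p$vertices)))
  }
  if (!is.null(landmarks)) {
    for (i in seq_len(nrow(landmarks))) {
      shapes <- c(shapes, list(labelme_shape(
        landmarks$name[i], "point",
        matrix(c(landmarks$row[i], landmarks$col[i]), 1))))
    }
  }
  doc <- list(imageHeight = image_size[1], imageWidth = image_size[2],
              shapes = shapes)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a LabelMe-dialect annotation file
#'
#' Rectangles become [bbox()]es, polygons stay [polygon_annotation()]s,
#' point shapes whose labels name one of the four facial landmarks
#' (`left_canthus`, `right_canthus`, `subnasale`, `submental`) populate the
#' landmark table. Shapes with unknown labels are returned (and warned
#' about), never silently dropped.
#'
#' @param path JSON path.
#' @return List: `image_size` (rows, cols), `boxes` (named list of `bbox`),
#'   `polygons` (list of `polygon_annotation`), `landmarks` (tibble `name`,
#'   `row`, `col`), `unknown_labels` (character).
#' @export
read_labelme <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("annotation file '%s' not found", path))
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop_io(sprintf("cannot parse '%s': %s", path,
                                    conditionMessage(e)))
                  })
  if (is.null(doc$imageHeight) || is.null(doc$imageWidth)) {
    stop_validation("annotation lacks imageHeight/imageWidth")
  }
  boxes <- list(); polygons <- list()
  lm_rows <- list(); unknown <- character()
  for (sh in doc$shapes) {
    pts <- do.call(rbind, lapply(sh$points, function(p) {
      c(row = as.numeric(p[[2]]), col = as.numeric(p[[1]]))
    }))
    type <- sh$shape_type %||% "polygon"
    lab <- sh$label %||% "unlabelled"
    if (type == "rectangle") {
      if (is.null(pts) || nrow(pts) < 2) {
        stop_validation(sprintf("rectangle '%s' needs 2 corner points", lab))
      }
      boxes[[lab]] <- bbox(min(pts[, 1]), min(pts[, 2]),
                           max(pts[, 1]), max(pts[, 2]))
    } else if (type == "polygon") {
      if (is.null(pts) || nrow(pts) < 3) {
        stop_validation(sprintf("polygon '%s' needs >= 3 points", lab))
      }
      polygons <- c(polygons, list(polygon_annotation(pts, label = lab)))
    } else if (type == "point") {
      if (is.null(pts) || nrow(pts) < 1) {
        stop_validation(sprintf("point '%s' has no coordinates", lab))
      }
      if (lab %in% .landmark_names) {
        lm_rows[[lab]] <- tibble::tibble(name = lab,
                                         row = as.numeric(pts[1, 1]),
                                         col = as.numeric(pts[1, 2]))
      } else {
        unknown <- c(unknown, lab)
      }
    } else {
      unknown <- c(unknown, lab)
    }
  }
  if (length(unknown)) {
    rlang::warn(sprintf("unrecognized annotation labels: %s",
                        paste(unique(unknown), collapse = ", ")))
  }
  landmarks <- if (length(lm_rows)) dplyr::bind_rows(lm_rows) else
    tibble::tibble(name = character(), row = numeric(), col = numeric())
  list(
    image_size = c(as.numeric(doc$imageHeight), as.numeric(doc$imageWidth)),
    boxes = boxes, polygons = polygons, landmarks = landmarks,
    unknown_labels = unique(unknown)
  )
}

#' Write a binary mask as a 0/255 PNG
#' @param mask Logical matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' Read a 0/255 PNG mask back to a logical matrix
#' @param path PNG path.
#' @return Logical matrix.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img >= 0.5
}
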