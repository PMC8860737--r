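# Annotation data model: PF/CV structures as boxes or points in WSI pixel
# coordinates.  Convention used throughout the package: 0-based pixel indices,
# x rightward, y downward; a box is half-open [x_min,x_max) x [y_min,y_max);
# pixel (ix, iy) covers [ix, ix+1) x [iy, iy+1), its center is (ix+.5, iy+.5).

STRUCTURE_CLASSES <- c("PF", "CV")

#' Create an annotation set
#'
#' Container for portal-field (PF) and central-vein (CV) annotations of a
#' single whole-slide image.  Boxes (axis-aligned "tight boxes", optionally
#' scored) and points may coexist.
#'
#' @param boxes data.frame with columns `class`, `x_min`, `y_min`, `x_max`,
#'   `y_max` and optionally `score` (in `[0,1]`; `NA` marks ground truth), or
#'   `NULL`.
#' @param points data.frame with columns `class`, `x`, `y`, or `NULL`.
#' @param resolution_nm_per_px image resolution in nanometres per pixel
#'   (isotropic); mandatory, all physical-unit computations derive from it.
#' @param image_extent integer vector `c(width, height)` in pixels.
#' @return An object of class `annotation_set`: a data.frame with columns
#'   `class`, `type` (`"box"`/`"point"`), `x`, `y`, `x_min`, `y_min`,
#'   `x_max`, `y_max`, `score`, carrying `resolution_nm_per_px` and
#'   `image_extent` attributes.
#' @export
annotation_set <- function(boxes = NULL, points = NULL,
                           resolution_nm_per_px, image_extent) {
  stopifnot(is.numeric(resolution_nm_per_px), resolution_nm_per_px > 0,
            length(image_extent) == 2, all(image_extent > 0))
  cols <- c("class", "type", "x", "y", "x_min", "y_min", "x_max", "y_max",
            "score")
  empty <- data.frame(class = character(), type = character(),
                      x = numeric(), y = numeric(),
                      x_min = numeric(), y_min = numeric(),
                      x_max = numeric(), y_max = numeric(),
                      score = numeric(), stringsAsFactors = FALSE)
  items <- empty
  if (!is.null(boxes) && nrow(boxes) > 0) {
    b <- as.data.frame(boxes)
    if (is.null(b$score)) b$score <- NA_real_
    items <- rbind(items, data.frame(
      class = as.character(b$class), type = "box",
      x = NA_real_, y = NA_real_,
      x_min = as.numeric(b$x_min), y_min = as.numeric(b$y_min),
      x_max = as.numeric(b$x_max), y_max = as.numeric(b$y_max),
      score = as.numeric(b$score), stringsAsFactors = FALSE))
  }
  if (!is.null(points) && nrow(points) > 0) {
    p <- as.data.frame(points)
    items <- rbind(items, data.frame(
      class = as.character(p$class), type = "point",
      x = as.numeric(p$x), y = as.numeric(p$y),
      x_min = NA_real_, y_min = NA_real_,
      x_max = NA_real_, y_max = NA_real_,
      score = NA_real_, stringsAsFactors = FALSE))
  }
  items <- items[, cols]
  rownames(items) <- NULL
  structure(items,
            resolution_nm_per_px = resolution_nm_per_px,
            image_extent = as.numeric(image_extent),
            class = c("annotation_set", "data.frame")) |>
    validate_annotation_set()
}

validate_annotation_set <- function(set) {
  bad <- setdiff(unique(set$class), STRUCTURE_CLASSES)
  if (length(bad) > 0)
    stop("unknown structure class(es): ", paste(bad, collapse = ", "))
  ext <- attr(set, "image_extent")
  b <- set[set$type == "box", , drop = FALSE]
  if (nrow(b) > 0) {
    if (any(!is.finite(b$x_min) | !is.finite(b$y_min) |
            !is.finite(b$x_max) | !is.finite(b$y_max)))
      stop("non-finite box coordinates")
    if (any(b$x_min >= b$x_max | b$y_min >= b$y_max))
      stop("degenerate box: require x_min < x_max and y_min < y_max")
    if (any(b$x_min < 0 | b$y_min < 0 | b$x_max > ext[1] | b$y_max > ext[2]))
      stop("box outside image extent")
    sc <- b$score[!is.na(b$score)]
    if (any(sc < 0 | sc > 1)) stop("scores must lie in [0,1]")
  }
  p <- set[set$type == "point", , drop = FALSE]
  if (nrow(p) > 0) {
    if (any(!is.finite(p$x) | !is.finite(p$y)))
      stop("non-finite point coordinates")
    if (any(p$x < 0 | p$y < 0 | p$x > ext[1] | p$y > ext[2]))
      stop("point outside image extent")
  }
  set
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d items (%d boxes, %d points), %g nm/px, extent %dx%d\n",
              nrow(x), sum(x$type == "box"), sum(x$type == "point"),
              attr(x, "resolution_nm_per_px"),
              as.integer(attr(x, "image_extent")[1]),
              as.integer(attr(x, "image_extent")[2])))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Extract box or point items from an annotation set
#'
#' @param set an [annotation_set()].
#' @param cls optional class filter, `"PF"` or `"CV"`.
#' @return data.frame of the box (resp. point) rows.
#' @export
ann_boxes <- function(set, cls = NULL) {
  b <- as.data.frame(set)[set$type == "box",
                          c("class", "x_min", "y_min", "x_max", "y_max", "score")]
  if (!is.null(cls)) b <- b[b$class == cls, , drop = FALSE]
  rownames(b) <- NULL
  b
}

#' @rdname ann_boxes
#' @export
ann_points <- function(set, cls = NULL) {
  p <- as.data.frame(set)[set$type == "point", c("class", "x", "y")]
  if (!is.null(cls)) p <- p[p$class == cls, , drop = FALSE]
  rownames(p) <- NULL
  p
}

#' Read annotations from CSV or GeoJSON
#'
#' CSV schema: boxes use columns `class,x_min,y_min,x_max,y_max,score`
#' (score may be empty), points use `class,x,y`; a mixed file carries the
#' union of columns with empty cells.  GeoJSON uses a FeatureCollection of
#' Polygon (axis-aligned box ring) and Point geometries with a `class`
#' property (and optional `score`).
#'
#' @param path file path.
#' @param dialect `"csv"` or `"geojson"`.
#' @inheritParams annotation_set
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path, dialect = c("csv", "geojson"),
                             resolution_nm_per_px, image_extent) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "csv") {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    boxcols <- c("x_min", "y_min", "x_max", "y_max")
    has_box <- all(boxcols %in% names(d))
    has_pt <- all(c("x", "y") %in% names(d))
    if (!has_box && !has_pt)
      stop("CSV schema error: need columns x,y and/or x_min,y_min,x_max,y_max")
    boxes <- points <- NULL
    if (has_box) {
      rows <- stats::complete.cases(d[, boxcols])
      boxes <- d[rows, c("class", boxcols,
                         if ("score" %in% names(d)) "score"), drop = FALSE]
    }
    if (has_pt) {
      rows <- stats::complete.cases(d[, c("x", "y")])
      points <- d[rows, c("class", "x", "y"), drop = FALSE]
    }
    return(annotation_set(boxes, points, resolution_nm_per_px, image_extent))
  }
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("GeoJSON parse error: not a FeatureCollection")
  boxes <- list(); points <- list()
  for (i in seq_along(gj$features)) {
    f <- gj$features[[i]]
    cls <- f$properties$class
    if (is.null(cls)) stop("schema error: feature ", i, " has no class property")
    g <- f$geometry
    if (g$type == "Point") {
      points[[length(points) + 1]] <- data.frame(
        class = cls, x = g$coordinates[[1]], y = g$coordinates[[2]])
    } else if (g$type == "Polygon") {
      ring <- g$coordinates[[1]]
      xs <- vapply(ring, function(v) as.numeric(v[[1]]), 0)
      ys <- vapply(ring, function(v) as.numeric(v[[2]]), 0)
      if (length(xs) < 4) stop("malformed geometry at feature ", i)
      sc <- if (is.null(f$properties$score)) NA_real_ else f$properties$score
      boxes[[length(boxes) + 1]] <- data.frame(
        class = cls, x_min = min(xs), y_min = min(ys),
        x_max = max(xs), y_max = max(ys), score = sc)
    } else stop("malformed geometry at feature ", i, ": ", g$type)
  }
  annotation_set(if (length(boxes)) do.call(rbind, boxes),
                 if (length(points)) do.call(rbind, points),
                 resolution_nm_per_px, image_extent)
}

#' Write annotations to CSV or GeoJSON
#'
#' Lossless round trip with [read_annotations()] (up to double precision).
#'
#' @inheritParams read_annotations
#' @param set an [annotation_set()].
#' @export
write_annotations <- function(set, path, dialect = c("csv", "geojson")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    has_box <- any(set$type == "box"); has_pt <- any(set$type == "point")
    cols <- c("class",
              if (has_pt || !has_box) c("x", "y"),
              if (has_box || !has_pt) c("x_min", "y_min", "x_max", "y_max", "score"))
    if (!has_box && !has_pt) cols <- c("class", "x", "y")
    utils::write.csv(as.data.frame(set)[, cols, drop = FALSE], path,
                     row.names = FALSE, na = "")
    return(invisible(path))
  }
  feats <- lapply(seq_len(nrow(set)), function(i) {
    r <- set[i, ]
    if (r$type == "point") {
      list(type = "Feature",
           geometry = list(type = "Point", coordinates = c(r$x, r$y)),
           properties = list(class = r$class))
    } else {
      ring <- list(c(r$x_min, r$y_min), c(r$x_max, r$y_min),
                   c(r$x_max, r$y_max), c(r$x_min, r$y_max),
                   c(r$x_min, r$y_min))
      props <- list(class = r$class)
      if (!is.na(r$score)) props$score <- r$score
      list(type = "Feature",
           geometry = list(type = "Polygon", coordinates = list(ring)),
           properties = props)
    }
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Replace boxes by their center points
#'
#' Each box is replaced by its center, the arithmetic mean of the four box
#' vertices; the class is preserved.
#'
#' @param set an [annotation_set()] containing only boxes.
#' @return An [annotation_set()] of points.
#' @export
boxes_to_points <- function(set) {
  if (any(set$type == "point"))
    stop("boxes_to_points: input contains point annotations")
  b <- ann_boxes(set)
  annotation_set(points = data.frame(class = b$class,
                                     x = (b$x_min + b$x_max) / 2,
                                     y = (b$y_min + b$y_max) / 2),
                 resolution_nm_per_px = attr(set, "resolution_nm_per_px"),
                 image_extent = attr(set, "image_extent"))
}

#' Create a dense deformation field
#'
#' A 2-component displacement grid, typically produced by external image
#' registration; displacement at an arbitrary location is obtained by
#' bilinear interpolation between grid nodes.  Node `(gx, gy)` (0-based)
#' sits at image location `(gx, gy) * spacing`.
#'
#' @param dx,dy matrices (rows = y, cols = x) of the x/y displacement in
#'   pixels at the grid nodes.
#' @param spacing grid node spacing in pixels.
#' @return An object of class `deformation_field`.
#' @export
deformation_field <- function(dx, dy, spacing = 1) {
  stopifnot(is.matrix(dx), is.matrix(dy), all(dim(dx) == dim(dy)),
            all(is.finite(dx)), all(is.finite(dy)), spacing > 0)
  structure(list(dx = dx, dy = dy, spacing = spacing),
            class = "deformation_field")
}

# bilinear sample of one displacement component at (x, y) in pixels
bilinear_at <- function(m, x, y, spacing) {
  gx <- x / spacing; gy <- y / spacing
  x0 <- pmin(pmax(floor(gx), 0), ncol(m) - 2)
  y0 <- pmin(pmax(floor(gy), 0), nrow(m) - 2)
  fx <- gx - x0; fy <- gy - y0
  i <- cbind(y0 + 1, x0 + 1)
  v00 <- m[i]; v10 <- m[cbind(y0 + 1, x0 + 2)]
  v01 <- m[cbind(y0 + 2, x0 + 1)]; v11 <- m[cbind(y0 + 2, x0 + 2)]
  v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
    v01 * (1 - fx) * fy + v11 * fx * fy
}

#' Transform annotation points by a deformation field
#'
#' Displaces every point by the bilinearly interpolated displacement of an
#' externally computed registration field (e.g. to carry PF/CV positions
#' detected on an H&E section over to a neighboring section with the
#' staining of interest).  Classes are preserved.
#'
#' @param set an [annotation_set()] of points.
#' @param field a [deformation_field()] covering all points.
#' @param image_extent optional extent `c(width, height)` of the target
#'   image; defaults to the extent of `set`.
#' @return A displaced [annotation_set()] of points.
#' @export
apply_deformation <- function(set, field, image_extent = NULL) {
  stopifnot(inherits(field, "deformation_field"))
  if (any(set$type == "box"))
    stop("apply_deformation: convert boxes with boxes_to_points() first")
  p <- ann_points(set)
  W <- (ncol(field$dx) - 1) * field$spacing
  H <- (nrow(field$dx) - 1) * field$spacing
  out <- which(p$x < 0 | p$y < 0 | p$x > W | p$y > H)
  if (length(out) > 0)
    stop("points outside deformation-field domain at rows: ",
         paste(out, collapse = ", "))
  if (nrow(p) > 0) {
    ux <- bilinear_at(field$dx, p$x, p$y, field$spacing)
    uy <- bilinear_at(field$dy, p$x, p$y, field$spacing)
    p$x <- p$x + ux
    p$y <- p$y + uy
  }
  annotation_set(points = p[, c("class", "x", "y")],
                 resolution_nm_per_px = attr(set, "resolution_nm_per_px"),
                 image_extent = if (is.null(image_extent))
                   attr(set, "image_extent") else image_extent)
}
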