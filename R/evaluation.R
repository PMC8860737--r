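# Class-stratified detection metrics.  Two matching modes exist, depending
# on which side of the comparison carries the boxes:
#   points vs. ground-truth boxes (calibration/evaluation on box-annotated
#   data), and boxes vs. ground-truth points (point-annotated data, where
#   the meaning of precision and recall is exchanged but F1 is unaffected).
# Containment uses the package's half-open box convention: a point on a
# box's min edge is inside, on its max edge outside.

point_in_box_matrix <- function(px, py, bx0, by0, bx1, by1) {
  # points x boxes containment matrix
  outer(px, bx0, ">=") & outer(px, bx1, "<") &
    outer(py, by0, ">=") & outer(py, by1, "<")
}

#' Match detected points against ground-truth boxes
#'
#' Per class: a true positive is a ground-truth box containing at least one
#' same-class point; a false negative is a ground-truth box containing
#' none; a false positive is a point lying inside no same-class
#' ground-truth box.  The matching is not one-to-one: one point inside two
#' overlapping same-class boxes makes both boxes true positives.
#'
#' @param points [annotation_set()] of detected points.
#' @param gt_boxes [annotation_set()] of ground-truth boxes.
#' @return data.frame with one row per class: `class`, `TP`, `FP`, `FN`.
#' @export
match_points_to_boxes <- function(points, gt_boxes) {
  if (any(points$type == "box"))
    stop("wrong mode: detections must be points here")
  if (any(gt_boxes$type == "point"))
    stop("wrong mode: ground truth must be boxes here")
  do.call(rbind, lapply(STRUCTURE_CLASSES, function(cl) {
    p <- ann_points(points, cl); b <- ann_boxes(gt_boxes, cl)
    if (nrow(b) == 0) {
      return(data.frame(class = cl, TP = 0, FP = nrow(p), FN = 0))
    }
    if (nrow(p) == 0) {
      return(data.frame(class = cl, TP = 0, FP = 0, FN = nrow(b)))
    }
    inb <- point_in_box_matrix(p$x, p$y, b$x_min, b$y_min, b$x_max, b$y_max)
    hit_box <- apply(inb, 2, any)    # box contains >= 1 point
    hit_pt <- apply(inb, 1, any)     # point inside >= 1 box
    data.frame(class = cl, TP = sum(hit_box), FP = sum(!hit_pt),
               FN = sum(!hit_box))
  }))
}

#' Match detected boxes against ground-truth points
#'
#' The reversed mode for point-annotated ground truth: a true positive is a
#' detected box containing at least one same-class ground-truth point; a
#' false positive is a detected box containing none; a false negative is a
#' ground-truth point inside no same-class detected box.
#'
#' @param det_boxes [annotation_set()] of detected boxes.
#' @param gt_points [annotation_set()] of ground-truth points.
#' @return data.frame with one row per class: `class`, `TP`, `FP`, `FN`.
#' @export
match_boxes_to_points <- function(det_boxes, gt_points) {
  if (any(det_boxes$type == "point"))
    stop("wrong mode: detections must be boxes here")
  if (any(gt_points$type == "box"))
    stop("wrong mode: ground truth must be points here")
  do.call(rbind, lapply(STRUCTURE_CLASSES, function(cl) {
    b <- ann_boxes(det_boxes, cl); p <- ann_points(gt_points, cl)
    if (nrow(b) == 0) {
      return(data.frame(class = cl, TP = 0, FP = 0, FN = nrow(p)))
    }
    if (nrow(p) == 0) {
      return(data.frame(class = cl, TP = 0, FP = nrow(b), FN = 0))
    }
    inb <- point_in_box_matrix(p$x, p$y, b$x_min, b$y_min, b$x_max, b$y_max)
    hit_box <- apply(inb, 2, any)
    hit_pt <- apply(inb, 1, any)
    data.frame(class = cl, TP = sum(hit_box), FP = sum(!hit_box),
               FN = sum(!hit_pt))
  }))
}

#' Precision, recall and F1 from match counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`, `f1` their harmonic
#' mean.  With `TP = 0` and any error present all three are 0; with all
#' counts zero the row is flagged undefined (`defined = FALSE`, metrics
#' `NA`).
#'
#' @param counts data.frame with columns `TP`, `FP`, `FN` (and optionally
#'   `class`), one row per class.
#' @return the input with `precision`, `recall`, `f1`, `defined` columns
#'   appended (unrounded).
#' @export
metrics_from_counts <- function(counts) {
  if (any(counts$TP < 0 | counts$FP < 0 | counts$FN < 0))
    stop("negative counts")
  out <- counts
  out$precision <- NA_real_
  out$recall <- NA_real_
  out$f1 <- NA_real_
  out$defined <- !(counts$TP == 0 & counts$FP == 0 & counts$FN == 0)
  for (i in seq_len(nrow(out))) {
    if (!out$defined[i]) next
    tp <- counts$TP[i]; fp <- counts$FP[i]; fn <- counts$FN[i]
    if (tp == 0) {
      out$precision[i] <- out$recall[i] <- out$f1[i] <- 0
    } else {
      p <- tp / (tp + fp); r <- tp / (tp + fn)
      out$precision[i] <- p; out$recall[i] <- r
      out$f1[i] <- 2 * p * r / (p + r)
    }
  }
  out
}

#' Mean metrics over the two structure classes
#'
#' Detecting PFs and CVs is of equal importance, so summary performance is
#' the arithmetic mean of the two class rows — computed from the unrounded
#' class metrics (and the mean of the counts, which may be half-integer).
#'
#' @param rows result of [metrics_from_counts()] with both classes present.
#' @return one-row data.frame `class = "Mean"` with mean counts and mean
#'   metrics.
#' @export
mean_class_metrics <- function(rows) {
  if (!all(STRUCTURE_CLASSES %in% rows$class))
    stop("both classes (PF, CV) must be present")
  r <- rows[match(STRUCTURE_CLASSES, rows$class), ]
  data.frame(class = "Mean",
             TP = mean(r$TP), FP = mean(r$FP), FN = mean(r$FN),
             precision = mean(r$precision), recall = mean(r$recall),
             f1 = mean(r$f1), defined = all(r$defined))
}

#' Full metrics report (class rows plus mean row)
#'
#' @param counts per-class counts as from [match_points_to_boxes()] or
#'   [match_boxes_to_points()].
#' @param digits if non-`NULL`, metrics are rounded (half-even) to this
#'   many decimals for display; counts are never rounded.
#' @return data.frame with the two class rows and a `"Mean"` row.
#' @export
metrics_report <- function(counts, digits = NULL) {
  rows <- metrics_from_counts(counts)
  rep <- rbind(rows, mean_class_metrics(rows))
  if (!is.null(digits)) {
    for (col in c("precision", "recall", "f1"))
      rep[[col]] <- round(rep[[col]], digits)
  }
  rep$defined <- NULL
  rownames(rep) <- NULL
  rep
}
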