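# Detector backend seam and merging of tile-wise detections into WSI-level
# point detections.
#
# A detector backend is a function(tile_image, x_origin, y_origin, s) that
# returns a data.frame of tile-local detections with columns
# class, score, x_min, y_min, x_max, y_max (boxes within [0,s)^2, scores in
# [0,1]).  The trained CNN of a production deployment is wrapped behind this
# seam; the package ships a synthetic noisy oracle backend for closed-loop
# testing and calibration experiments.

empty_detections <- function() {
  data.frame(class = character(), score = numeric(),
             x_min = numeric(), y_min = numeric(),
             x_max = numeric(), y_max = numeric(),
             tile_id = integer(), stringsAsFactors = FALSE)
}

# order-free per-tile RNG stream: seed derived from global seed + tile origin
tile_seed <- function(seed, x_origin, y_origin) {
  as.integer((as.numeric(seed) * 7919 + x_origin * 104729 +
                y_origin * 1299709 + 17) %% 2147483647)
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Synthetic noisy oracle detector backend
#'
#' Emulates an imperfect tile detector against known ground truth: every
#' ground-truth box whose center is visible in the tile is emitted with
#' Gaussian positional jitter, except that a fraction `miss_rate` of the
#' structures is never reported (the miss is decided per structure, so a
#' missed structure is missed consistently in every tile that sees it);
#' additionally `Poisson(fp_rate)` false boxes are placed uniformly in each
#' tile.  Deterministic given `seed` and independent of the order in which
#' tiles are processed.
#'
#' @param truth an [annotation_set()] of ground-truth boxes (WSI frame).
#' @param jitter_sd positional jitter SD in pixels applied to each emitted
#'   box (whole-box shift).
#' @param miss_rate per-structure miss probability in `[0,1]`.
#' @param fp_rate expected number of false-positive boxes per tile (>= 0).
#' @param seed integer RNG seed.
#' @param fp_size edge length in pixels of false-positive boxes.
#' @return a detector backend function.
#' @export
oracle_detector <- function(truth, jitter_sd = 0, miss_rate = 0,
                            fp_rate = 0, seed = 1, fp_size = 20) {
  stopifnot(miss_rate >= 0, miss_rate <= 1, fp_rate >= 0, jitter_sd >= 0)
  tb <- ann_boxes(truth)
  missed <- if (nrow(tb) > 0)
    with_local_seed(seed, stats::runif(nrow(tb)) < miss_rate) else logical(0)
  function(tile_image, x_origin, y_origin, s) {
    cx <- (tb$x_min + tb$x_max) / 2
    cy <- (tb$y_min + tb$y_max) / 2
    vis <- which(cx >= x_origin & cx < x_origin + s &
                 cy >= y_origin & cy < y_origin + s & !missed)
    with_local_seed(tile_seed(seed, x_origin, y_origin), {
      out <- empty_detections()
      if (length(vis) > 0) {
        jx <- stats::rnorm(length(vis), 0, jitter_sd)
        jy <- stats::rnorm(length(vis), 0, jitter_sd)
        out <- data.frame(class = tb$class[vis],
                          score = stats::runif(length(vis), 0.8, 1),
                          x_min = tb$x_min[vis] - x_origin + jx,
                          y_min = tb$y_min[vis] - y_origin + jy,
                          x_max = tb$x_max[vis] - x_origin + jx,
                          y_max = tb$y_max[vis] - y_origin + jy,
                          stringsAsFactors = FALSE)
      }
      nfp <- stats::rpois(1, fp_rate)
      if (nfp > 0) {
        fx <- stats::runif(nfp, 0, s - fp_size)
        fy <- stats::runif(nfp, 0, s - fp_size)
        out <- rbind(out[, 1:6], data.frame(
          class = sample(STRUCTURE_CLASSES, nfp, replace = TRUE),
          score = stats::runif(nfp, 0, 1),
          x_min = fx, y_min = fy,
          x_max = fx + fp_size, y_max = fy + fp_size,
          stringsAsFactors = FALSE))
      }
      # clip to the tile so local boxes satisfy the backend contract
      if (nrow(out) > 0) {
        out$x_min <- pmax(out$x_min, 0); out$y_min <- pmax(out$y_min, 0)
        out$x_max <- pmin(out$x_max, s); out$y_max <- pmin(out$y_max, s)
        out <- out[out$x_min < out$x_max & out$y_min < out$y_max, ]
      }
      out
    })
  }
}

#' Map tile-local detections to WSI coordinates
#'
#' Adds the source tile origin as an offset to the local box coordinates
#' (merging step a).
#'
#' @param dets data.frame of tile-local detections with a `tile_id` column.
#' @param grid the [make_tile_grid()] the detections came from.
#' @return data.frame of WSI-frame detections.
#' @export
globalize <- function(dets, grid) {
  if (nrow(dets) == 0) return(dets)
  m <- match(dets$tile_id, grid$tile_id)
  if (anyNA(m)) stop("unknown tile id(s): ",
                     paste(unique(dets$tile_id[is.na(m)]), collapse = ", "))
  dets$x_min <- dets$x_min + grid$x_origin[m]
  dets$x_max <- dets$x_max + grid$x_origin[m]
  dets$y_min <- dets$y_min + grid$y_origin[m]
  dets$y_max <- dets$y_max + grid$y_origin[m]
  dets
}

# pairwise IoU of half-open boxes given as data.frames
box_iou <- function(a, b) {
  ix <- pmax(0, pmin(a$x_max, b$x_max) - pmax(a$x_min, b$x_min))
  iy <- pmax(0, pmin(a$y_max, b$y_max) - pmax(a$y_min, b$y_min))
  inter <- ix * iy
  ua <- (a$x_max - a$x_min) * (a$y_max - a$y_min) +
    (b$x_max - b$x_min) * (b$y_max - b$y_min) - inter
  ifelse(ua > 0, inter / ua, 0)
}

# intersection area of box row with rectangle (vectorized over boxes)
rect_intersection_area <- function(boxes, x_min, y_min, x_max, y_max) {
  ix <- pmax(0, pmin(boxes$x_max, x_max) - pmax(boxes$x_min, x_min))
  iy <- pmax(0, pmin(boxes$y_max, y_max) - pmax(boxes$y_min, y_min))
  ix * iy
}

#' Merge duplicate detections of one structure (merging step b)
#'
#' A structure lying in the interior of some tile is detected exactly once
#' with its box contained in that interior; a structure straddling interior
#' boundaries may be detected in up to four overlapping tiles.  Boxes are
#' grouped per class by pairwise IoU (only boxes from the same or adjacent
#' tiles can pair); within a group, boxes fully contained in their own
#' tile's interior are kept, otherwise the box maximizing the intersection
#' area with its own tile's interior is kept (ties broken by the smallest
#' source-tile origin, y then x).
#'
#' @param dets WSI-frame detections with `tile_id`.
#' @param grid the source [make_tile_grid()].
#' @param iou_group_threshold same-class IoU at or above which two boxes
#'   are considered duplicates of one structure.
#' @return deduplicated WSI-frame detections.
#' @export
deduplicate <- function(dets, grid, iou_group_threshold = 0.5) {
  n <- nrow(dets)
  if (n == 0) return(dets)
  s <- attr(grid, "s")
  it <- tile_interiors(grid)
  m <- match(dets$tile_id, it$tile_id)
  ia <- rect_intersection_area(dets, it$x_min[m], it$y_min[m],
                               it$x_max[m], it$y_max[m])
  contained <- dets$x_min >= it$x_min[m] & dets$x_max <= it$x_max[m] &
    dets$y_min >= it$y_min[m] & dets$y_max <= it$y_max[m]
  ox <- grid$x_origin[match(dets$tile_id, grid$tile_id)]
  oy <- grid$y_origin[match(dets$tile_id, grid$tile_id)]

  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  cls <- dets$class
  bx0 <- dets$x_min; bx1 <- dets$x_max; by0 <- dets$y_min; by1 <- dets$y_max
  area <- (bx1 - bx0) * (by1 - by0)
  for (i in seq_len(max(n - 1, 0))) {
    cand <- which(cls[(i + 1):n] == cls[i] &
                    abs(ox[(i + 1):n] - ox[i]) <= s / 2 &
                    abs(oy[(i + 1):n] - oy[i]) <= s / 2) + i
    if (length(cand) == 0) next
    iw <- pmax(0, pmin(bx1[cand], bx1[i]) - pmax(bx0[cand], bx0[i]))
    ih <- pmax(0, pmin(by1[cand], by1[i]) - pmax(by0[cand], by0[i]))
    inter <- iw * ih
    iou <- inter / (area[cand] + area[i] - inter)
    for (j in cand[iou >= iou_group_threshold]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  keep <- logical(n)
  for (g in split(seq_len(n), root)) {
    if (any(contained[g])) {
      keep[g[contained[g]]] <- TRUE
    } else {
      best <- g[order(-ia[g], oy[g], ox[g])][1]
      keep[best] <- TRUE
    }
  }
  out <- dets[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reduce detections to center points (merging step c)
#'
#' The point of each box is the arithmetic mean of its vertices, i.e. the
#' box center; classes are preserved.
#'
#' @param dets deduplicated WSI-frame detections.
#' @param resolution_nm_per_px,image_extent metadata for the result set.
#' @return An [annotation_set()] of points.
#' @export
detections_to_points <- function(dets, resolution_nm_per_px, image_extent) {
  pts <- if (nrow(dets) == 0) NULL else
    data.frame(class = dets$class,
               x = (dets$x_min + dets$x_max) / 2,
               y = (dets$y_min + dets$y_max) / 2)
  annotation_set(points = pts,
                 resolution_nm_per_px = resolution_nm_per_px,
                 image_extent = image_extent)
}

#' Run tile-based detection over a whole slide and merge
#'
#' Applies the backend to every tile of the grid, maps detections to WSI
#' coordinates, merges duplicates and reduces boxes to center points.
#' Per-tile backend calls are independent, so the result does not depend on
#' the tile processing order.
#'
#' @param wsi image raster (may be `NULL` for backends, like the oracle,
#'   that ignore pixel data).
#' @param grid a [make_tile_grid()] result.
#' @param backend a detector backend function.
#' @param resolution_nm_per_px resolution metadata for the output set.
#' @param iou_group_threshold see [deduplicate()].
#' @param score_threshold optional minimum detection score applied before
#'   merging (`NULL` = keep all).
#' @return list with `points` (an [annotation_set()]), `boxes` (the
#'   deduplicated WSI-frame box detections) and `n_raw` (count before
#'   merging).
#' @export
run_wsi_detection <- function(wsi, grid, backend, resolution_nm_per_px,
                              iou_group_threshold = 0.5,
                              score_threshold = NULL) {
  s <- attr(grid, "s")
  per_tile <- lapply(seq_len(nrow(grid)), function(i) {
    img <- if (is.null(wsi)) NULL else
      extract_tile_image(wsi, grid, grid$tile_id[i])
    d <- backend(img, grid$x_origin[i], grid$y_origin[i], s)
    if (nrow(d) > 0) d$tile_id <- grid$tile_id[i]
    d
  })
  dets <- do.call(rbind, c(list(empty_detections()), per_tile))
  if (!is.null(score_threshold) && nrow(dets) > 0)
    dets <- dets[dets$score >= score_threshold, , drop = FALSE]
  glob <- globalize(dets, grid)
  dedup <- deduplicate(glob, grid, iou_group_threshold)
  ext <- attr(grid, "image_extent")
  # centers of border-clipped boxes could fall a hair outside; clamp
  list(points = detections_to_points(dedup, resolution_nm_per_px, ext),
       boxes = dedup, n_raw = nrow(dets))
}

#' Select the best training checkpoint by validation F1
#'
#' Given per-epoch WSI point detections and validation ground-truth boxes,
#' returns the epoch maximizing the mean-over-classes F1 score; ties go to
#' the earliest epoch.
#'
#' @param per_epoch_points list of [annotation_set()] point sets, one per
#'   epoch.
#' @param validation_truth [annotation_set()] of ground-truth boxes.
#' @return list with `epoch` (1-based index) and `f1` (vector of mean F1
#'   per epoch).
#' @export
select_best_checkpoint <- function(per_epoch_points, validation_truth) {
  if (length(per_epoch_points) == 0) stop("no epochs supplied")
  f1 <- vapply(per_epoch_points, function(pts) {
    counts <- match_points_to_boxes(pts, validation_truth)
    mean_class_metrics(metrics_from_counts(counts))$f1
  }, numeric(1))
  list(epoch = which.max(f1), f1 = f1)
}
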