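# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive loops and literal definitions, not the
# package's code paths.

bf_match_points_to_boxes <- function(points, boxes) {
  # points, boxes: plain data.frames (class, x, y) / (class, x_min, ...)
  do.call(rbind, lapply(c("PF", "CV"), function(cl) {
    p <- points[points$class == cl, , drop = FALSE]
    b <- boxes[boxes$class == cl, , drop = FALSE]
    tp <- fn <- 0
    if (nrow(b) > 0) for (i in seq_len(nrow(b))) {
      hit <- FALSE
      if (nrow(p) > 0) for (j in seq_len(nrow(p))) {
        if (p$x[j] >= b$x_min[i] && p$x[j] < b$x_max[i] &&
            p$y[j] >= b$y_min[i] && p$y[j] < b$y_max[i]) hit <- TRUE
      }
      if (hit) tp <- tp + 1 else fn <- fn + 1
    }
    fp <- 0
    if (nrow(p) > 0) for (j in seq_len(nrow(p))) {
      inside <- FALSE
      if (nrow(b) > 0) for (i in seq_len(nrow(b))) {
        if (p$x[j] >= b$x_min[i] && p$x[j] < b$x_max[i] &&
            p$y[j] >= b$y_min[i] && p$y[j] < b$y_max[i]) inside <- TRUE
      }
      if (!inside) fp <- fp + 1
    }
    data.frame(class = cl, TP = tp, FP = fp, FN = fn)
  }))
}

bf_otsu_sigma <- function(gray) {
  # between-class variance for every candidate threshold t = 1..255
  v <- as.integer(gray)
  n <- length(v)
  vapply(1:255, function(t) {
    lo <- v[v < t]; hi <- v[v >= t]
    if (length(lo) == 0 || length(hi) == 0) return(-Inf)
    w0 <- length(lo) / n; w1 <- length(hi) / n
    w0 * w1 * (mean(lo) - mean(hi))^2
  }, numeric(1))
}

bf_nn_radii <- function(x, y, res_nm) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) if (j != i) {
      d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      if (d < best) best <- d
    }
    r[i] <- 0.5 * best * res_nm / 1000
  }
  r
}

bf_zonated_means <- function(intensity, lobuli, zones) {
  out <- list()
  for (l in sort(unique(lobuli[lobuli > 0]))) {
    for (z in sort(unique(zones[lobuli == l]))) {
      sel <- lobuli == l & zones == z
      out[[length(out) + 1]] <- data.frame(
        lobulus = l, zone = z,
        mean_intensity = mean(intensity[sel]), n_pixels = sum(sel))
    }
  }
  do.call(rbind, out)
}

bf_deduplicate <- function(dets, grid, iou_thr = 0.5) {
  # literal rule: group same-class boxes of nearby tiles by IoU (transitive
  # closure over the pair relation); keep interior-contained members, else
  # the max interior-intersection member (tie: smallest y, then x origin)
  s <- attr(grid, "s")
  n <- nrow(dets)
  iou <- function(i, j) {
    ix <- max(0, min(dets$x_max[i], dets$x_max[j]) -
                max(dets$x_min[i], dets$x_min[j]))
    iy <- max(0, min(dets$y_max[i], dets$y_max[j]) -
                max(dets$y_min[i], dets$y_min[j]))
    inter <- ix * iy
    a1 <- (dets$x_max[i] - dets$x_min[i]) * (dets$y_max[i] - dets$y_min[i])
    a2 <- (dets$x_max[j] - dets$x_min[j]) * (dets$y_max[j] - dets$y_min[j])
    if (a1 + a2 - inter <= 0) 0 else inter / (a1 + a2 - inter)
  }
  g <- grid[match(dets$tile_id, grid$tile_id), ]
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { adj[i, j] <- TRUE; next }
    if (dets$class[i] != dets$class[j]) next
    if (abs(g$x_origin[i] - g$x_origin[j]) > s / 2) next
    if (abs(g$y_origin[i] - g$y_origin[j]) > s / 2) next
    if (iou(i, j) >= iou_thr) adj[i, j] <- TRUE
  }
  reach <- adj
  for (k in seq_len(n)) reach <- reach | (reach %*% reach > 0)
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (i in seq_len(n)) if (is.na(comp[i])) {
    cid <- cid + 1
    comp[reach[i, ]] <- cid
  }
  ia <- numeric(n); contained <- logical(n)
  for (i in seq_len(n)) {
    x0 <- g$x_origin[i] + s / 4; y0 <- g$y_origin[i] + s / 4
    x1 <- g$x_origin[i] + 3 * s / 4; y1 <- g$y_origin[i] + 3 * s / 4
    ix <- max(0, min(dets$x_max[i], x1) - max(dets$x_min[i], x0))
    iy <- max(0, min(dets$y_max[i], y1) - max(dets$y_min[i], y0))
    ia[i] <- ix * iy
    contained[i] <- dets$x_min[i] >= x0 && dets$x_max[i] <= x1 &&
      dets$y_min[i] >= y0 && dets$y_max[i] <= y1
  }
  keep <- logical(n)
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    if (any(contained[idx])) keep[idx[contained[idx]]] <- TRUE
    else {
      o <- idx[order(-ia[idx], g$y_origin[idx], g$x_origin[idx])]
      keep[o[1]] <- TRUE
    }
  }
  dets[keep, , drop = FALSE]
}

random_annotations <- function(n_boxes, n_points, extent = c(1000, 800),
                               res = 4000) {
  boxes <- NULL
  if (n_boxes > 0) {
    x0 <- runif(n_boxes, 0, extent[1] - 60)
    y0 <- runif(n_boxes, 0, extent[2] - 60)
    boxes <- data.frame(class = sample(c("PF", "CV"), n_boxes, TRUE),
                        x_min = x0, y_min = y0,
                        x_max = x0 + runif(n_boxes, 5, 60),
                        y_max = y0 + runif(n_boxes, 5, 60),
                        score = ifelse(runif(n_boxes) < 0.5, NA,
                                       round(runif(n_boxes), 4)))
  }
  points <- NULL
  if (n_points > 0) {
    points <- data.frame(class = sample(c("PF", "CV"), n_points, TRUE),
                         x = runif(n_points, 0, extent[1]),
                         y = runif(n_points, 0, extent[2]))
  }
  annotation_set(boxes, points, res, extent)
}

# small cached phantom shared by several test files
small_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      lay <- generate_layout(c(512, 512), 4000, lobule_radius_um = 300,
                             seed = 11)
      cache <<- list(layout = lay, phantom = render_hne_phantom(lay, seed = 11))
    }
    cache
  }
})
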