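test_that("noise-free oracle backend reproduces truth boxes per tile", {
  truth <- annotation_set(
    data.frame(class = c("PF", "CV"), x_min = c(100, 300),
               y_min = c(120, 330), x_max = c(140, 360), y_max = c(150, 390)),
    NULL, 4000, c(512, 512))
  bk <- oracle_detector(truth)
  d <- bk(NULL, 0, 0, 512)
  expect_equal(nrow(d), 2)
  expect_equal(sort(d$x_min), c(100, 300))
  # a tile that sees neither center
  far <- bk(NULL, 0, 0, 64)
  expect_equal(nrow(far), 0)
  # total miss
  none <- oracle_detector(truth, miss_rate = 1)(NULL, 0, 0, 512)
  expect_equal(nrow(none), 0)
})

test_that("globalize adds tile origins as offsets", {
  g <- make_tile_grid(c(1024, 1024), 512)
  id <- g$tile_id[g$x_origin == 256 & g$y_origin == 256]
  d <- data.frame(class = "PF", score = 0.9, x_min = 10, y_min = 10,
                  x_max = 20, y_max = 20, tile_id = id)
  gd <- globalize(d, g)
  expect_equal(unlist(gd[, c("x_min", "y_min", "x_max", "y_max")],
                      use.names = FALSE), c(266, 266, 276, 276))
  d0 <- d; d0$tile_id <- g$tile_id[g$x_origin == 0 & g$y_origin == 0]
  expect_equal(globalize(d0, g)$x_min, 10)
  dbad <- d; dbad$tile_id <- -1
  expect_error(globalize(dbad, g), "unknown tile")
})

test_that("deduplication keeps the max interior-intersection duplicate", {
  g <- make_tile_grid(c(1024, 1024), 512)
  tA <- g$tile_id[g$x_origin == 0 & g$y_origin == 0]     # interior [128,384)^2
  tB <- g$tile_id[g$x_origin == 256 & g$y_origin == 0]   # interior [384,640)x[128,384)
  # one structure straddling x = 384: 40x30 px in A's interior, 30x30 in B's
  d <- data.frame(class = "CV", score = 0.9,
                  x_min = 344, y_min = 200, x_max = 414, y_max = 230,
                  tile_id = c(tA, tB))
  out <- deduplicate(d, g)
  expect_equal(nrow(out), 1)
  expect_equal(out$tile_id, tA)

  # four-tile corner duplicate at (384, 384): intersections 100/200/200/400
  tiles <- c(tA,
             g$tile_id[g$x_origin == 256 & g$y_origin == 0],
             g$tile_id[g$x_origin == 0 & g$y_origin == 256],
             g$tile_id[g$x_origin == 256 & g$y_origin == 256])
  d4 <- data.frame(class = "PF", score = 0.5, x_min = 374, y_min = 374,
                   x_max = 404, y_max = 404, tile_id = tiles)
  out4 <- deduplicate(d4, g)
  expect_equal(nrow(out4), 1)
  expect_equal(out4$tile_id, tiles[4])
  # and the exhaustive oracle agrees
  expect_equal(bf_deduplicate(d4, g)$tile_id, out4$tile_id)

  # symmetric duplicate: tie broken by smallest (y, x) tile origin
  dt <- data.frame(class = "PF", score = 0.5, x_min = 369, y_min = 369,
                   x_max = 399, y_max = 399, tile_id = tiles)
  # centered at (384,384): all four intersections equal
  dt$x_min <- 384 - 15; dt$x_max <- 384 + 15
  dt$y_min <- 384 - 15; dt$y_max <- 384 + 15
  outt <- deduplicate(dt, g)
  expect_equal(outt$tile_id, tA)
})

test_that("deduplication matches the exhaustive oracle on random instances", {
  g <- make_tile_grid(c(1024, 1024), 512)
  set.seed(99)
  for (trial in 1:30) {
    n_struct <- sample(3:8, 1)
    x0 <- runif(n_struct, 10, 950); y0 <- runif(n_struct, 10, 950)
    w <- runif(n_struct, 15, 60); h <- runif(n_struct, 15, 60)
    cls <- sample(c("PF", "CV"), n_struct, TRUE)
    rows <- list()
    for (k in seq_len(n_struct)) {
      src <- which(g$x_origin <= x0[k] & x0[k] + w[k] <= g$x_origin + 512 &
                   g$y_origin <= y0[k] & y0[k] + h[k] <= g$y_origin + 512)
      for (t in src) {
        jx <- runif(1, -1, 1); jy <- runif(1, -1, 1)
        rows[[length(rows) + 1]] <- data.frame(
          class = cls[k], score = runif(1),
          x_min = x0[k] + jx, y_min = y0[k] + jy,
          x_max = x0[k] + w[k] + jx, y_max = y0[k] + h[k] + jy,
          tile_id = g$tile_id[t])
      }
    }
    d <- do.call(rbind, rows)
    got <- deduplicate(d, g)
    want <- bf_deduplicate(d, g)
    key <- function(z) paste(round(z$x_min, 6), round(z$y_min, 6), z$class,
                             z$tile_id)
    expect_setequal(key(got), key(want))
    # no same-class surviving pair above the grouping IoU
    if (nrow(got) > 1) {
      for (i in 1:(nrow(got) - 1)) for (j in (i + 1):nrow(got)) {
        if (got$class[i] != got$class[j]) next
        ix <- max(0, min(got$x_max[i], got$x_max[j]) -
                    max(got$x_min[i], got$x_min[j]))
        iy <- max(0, min(got$y_max[i], got$y_max[j]) -
                    max(got$y_min[i], got$y_min[j]))
        a <- (got$x_max[i] - got$x_min[i]) * (got$y_max[i] - got$y_min[i]) +
          (got$x_max[j] - got$x_min[j]) * (got$y_max[j] - got$y_min[j])
        expect_lt(ix * iy / (a - ix * iy), 0.5)
      }
    }
  }
})

test_that("whole-slide detection is exact with a perfect backend and
           invariant to tile order", {
  sp <- small_phantom()
  truth <- sp$phantom$annotations
  grid <- make_tile_grid(c(512, 512), 128)
  res <- run_wsi_detection(NULL, grid, oracle_detector(truth), 4000)
  b <- ann_boxes(truth)
  got <- ann_points(res$points)
  got <- got[order(got$x, got$y), ]
  cx <- (b$x_min + b$x_max) / 2; cy <- (b$y_min + b$y_max) / 2
  o <- order(cx, cy)
  expect_equal(got$x, cx[o], tolerance = 1e-9)
  expect_equal(got$y, cy[o], tolerance = 1e-9)
  expect_equal(got$class, b$class[o])

  # permuted grid (same tiles, different order) yields the same points
  perm <- grid[sample(nrow(grid)), ]
  attributes(perm) <- c(attributes(perm)[c("names", "row.names")],
                        attributes(grid)[c("s", "image_extent", "class")])
  res2 <- run_wsi_detection(NULL, perm, oracle_detector(truth), 4000)
  g2 <- ann_points(res2$points); g2 <- g2[order(g2$x, g2$y), ]
  rownames(g2) <- rownames(got) <- NULL
  expect_equal(got, g2)

  # empty backend
  none <- run_wsi_detection(NULL, grid,
                            function(img, ox, oy, s) hepazone:::empty_detections(),
                            4000)
  expect_equal(nrow(none$points), 0)
})

test_that("checkpoint selection maximizes mean F1 with earliest-tie rule", {
  sp <- small_phantom()
  truth <- sp$phantom$annotations
  grid <- make_tile_grid(c(512, 512), 128)
  run_at <- function(miss, seed) {
    run_wsi_detection(NULL, grid,
                      oracle_detector(truth, miss_rate = miss, seed = seed),
                      4000)$points
  }
  epochs <- list(run_at(0.8, 1), run_at(0, 2), run_at(0, 2), run_at(0.4, 3))
  sel <- select_best_checkpoint(epochs, truth)
  expect_equal(sel$epoch, 2)  # perfect epoch, earliest of the tie
  expect_equal(sel$f1[2], 1)
  # agrees with independently computed mean F1 per epoch
  f1_direct <- vapply(epochs, function(p) {
    evaluate_detections(p, truth, digits = NULL)$f1[3]
  }, numeric(1))
  expect_equal(sel$f1, f1_direct)
  expect_equal(select_best_checkpoint(epochs[1], truth)$epoch, 1)
  expect_error(select_best_checkpoint(list(), truth), "no epochs")
})
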