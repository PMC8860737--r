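pt_set <- function(cv, pf, extent = c(64, 64)) {
  annotation_set(points = rbind(
    data.frame(class = "CV", x = cv[, 1], y = cv[, 2]),
    data.frame(class = "PF", x = pf[, 1], y = pf[, 2])),
    resolution_nm_per_px = 4000, image_extent = extent)
}

test_that("portality is 0 at CVs, 1 at PFs, 0.5 at the midpoint", {
  p <- portality_field(c(64, 64), pf_points = data.frame(x = 50.5, y = 32.5),
                       cv_points = data.frame(x = 10.5, y = 32.5))
  expect_equal(p[33, 11], 0)     # CV seed pixel
  expect_equal(p[33, 51], 1)     # PF seed pixel
  expect_equal(p[33, 31], 0.5)   # midpoint pixel (30.5, 32.5)
  expect_true(all(p >= 0 & p <= 1))
  expect_error(portality_field(c(64, 64),
                               pf_points = data.frame(x = 1, y = 1),
                               cv_points = data.frame(x = numeric(), y = numeric())),
               "CV point")
})

test_that("portality equals the brute-force nearest-seed oracle", {
  set.seed(3)
  for (trial in 1:5) {
    cv <- cbind(runif(3, 0, 64), runif(3, 0, 64))
    pf <- cbind(runif(5, 0, 64), runif(5, 0, 64))
    p <- portality_field(c(64, 64), data.frame(x = pf[, 1], y = pf[, 2]),
                         data.frame(x = cv[, 1], y = cv[, 2]))
    # oracle on rasterized seed pixel centers
    cvc <- cbind(floor(cv[, 1]) + 0.5, floor(cv[, 2]) + 0.5)
    pfc <- cbind(floor(pf[, 1]) + 0.5, floor(pf[, 2]) + 0.5)
    want <- matrix(0, 64, 64)
    for (iy in 0:63) for (ix in 0:63) {
      cx <- ix + 0.5; cy <- iy + 0.5
      dcv <- min(sqrt((cvc[, 1] - cx)^2 + (cvc[, 2] - cy)^2))
      dpf <- min(sqrt((pfc[, 1] - cx)^2 + (pfc[, 2] - cy)^2))
      want[iy + 1, ix + 1] <- if (dcv + dpf > 0) dcv / (dcv + dpf) else 0.5
    }
    expect_equal(unclass(p), want, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("watershed basins: single CV spans the extent, symmetric pair
           splits at the perpendicular bisector", {
  cv1 <- data.frame(x = 32.5, y = 32.5)
  p1 <- portality_field(c(64, 64), data.frame(x = c(5, 60), y = c(5, 60)),
                        cv1)
  b1 <- preflooded_watershed(p1, cv1, preflood_h = 0)
  expect_equal(max(b1), 1)
  expect_true(all(b1 == 1))

  # two CVs mirrored about x = 32, PFs mirrored likewise
  cv2 <- data.frame(x = c(16.5, 48.5), y = c(48.5, 48.5))
  p2 <- portality_field(c(64, 64),
                        pf_points = data.frame(x = c(10.5, 54.5), y = c(10.5, 10.5)),
                        cv_points = cv2)
  b2 <- preflooded_watershed(p2, cv2, preflood_h = 0)
  expect_equal(max(b2), 2)
  expect_false(b2[49, 17] == b2[49, 49])
  # boundary within 1 px of the bisector column x = 32 in the CV row
  row <- b2[49, ]
  flip <- which(diff(row) != 0)
  expect_true(any(abs(flip - 32) <= 1))
})

test_that("preflooding merges basins separated by a shallow saddle", {
  # two CVs close together, PFs far away: the saddle between the CVs is
  # shallow in portality
  cvs <- data.frame(x = c(42.5, 53.5), y = c(24.5, 24.5))
  p <- portality_field(c(96, 48),
                       pf_points = data.frame(x = c(4.5, 91.5), y = c(24.5, 24.5)),
                       cv_points = cvs)
  # saddle level = ridge top along the connecting path (minimax over paths)
  saddle <- max(p[25, 44:53])
  depth <- saddle - 0   # CV minima sit at portality 0
  expect_equal(max(preflooded_watershed(p, cvs, preflood_h = 0)), 2)
  expect_equal(max(preflooded_watershed(p, cvs, preflood_h = depth - 0.01)), 2)
  expect_equal(max(preflooded_watershed(p, cvs, preflood_h = depth + 0.02)), 1)
  expect_error(preflooded_watershed(p, cvs[0, ], 0.05), "CV seed")
})

test_that("zone quantization clamps to 1..n_zones with width-1/12 bins", {
  f <- matrix(c(0, 1, 0.5, 1 / 12 - 1e-9, 1 / 12, 11.5 / 12), 2, 3)
  z <- quantize_zones(f, 12)
  expect_equal(as.vector(z), c(1L, 12L, 7L, 1L, 2L, 12L))
  expect_equal(unique(as.vector(quantize_zones(f, 1))), 1L)
})

test_that("assembled maps partition the mask and renumber densely", {
  sp <- small_phantom()
  lay <- sp$layout
  pts <- layout_points(lay)
  mask <- matrix(1L, 512, 512)
  mask[, 1:250] <- 0L   # half-plane mask
  attr(mask, "resolution_nm_per_px") <- 4000
  z <- zonate(pts, mask, n_zones = 12, preflood_h = 0.05)
  lob <- z$maps$lobuli; zon <- z$maps$zones
  # labels nonzero exactly on the mask; dense renumbering
  expect_true(all((lob > 0) == (mask == 1)))
  expect_true(all((zon > 0) == (mask == 1)))
  expect_equal(sort(unique(lob[lob > 0])), seq_len(max(lob)))
  # conservation: lobulus pixel counts sum exactly to the mask area
  expect_equal(sum(tabulate(lob[lob > 0])), sum(mask))
  expect_equal(sum(lobulus_areas(z$maps)), mask_area_mm2(mask),
               tolerance = 1e-12)
  # half-plane lobulus count does not exceed the full-mask basin count
  full <- matrix(1L, 512, 512)
  attr(full, "resolution_nm_per_px") <- 4000
  zf <- zonate(pts, full, n_zones = 12, preflood_h = 0.05)
  expect_lte(max(lob), max(zf$maps$lobuli))
  expect_error(assemble_zonation(lob, zon, mask[1:10, 1:10]), "extent")
  empty <- matrix(0L, 512, 512)
  expect_error(assemble_zonation(lob, zon, empty), "empty tissue mask")
})

test_that("with h = 0.05 the phantom yields one lobulus per CV", {
  sp <- small_phantom()
  pts <- layout_points(sp$layout)
  mask <- matrix(1L, 512, 512)
  attr(mask, "resolution_nm_per_px") <- 4000
  z <- zonate(pts, mask)
  expect_equal(max(z$maps$lobuli), nrow(sp$layout$cv))
})
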