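test_that("optical density transform and its inverse", {
  img <- array(255, c(1, 2, 3))
  img[1, 2, ] <- 25.5
  od0 <- rgb_to_od(img, eps = 0)
  expect_equal(as.vector(od0[1, 1, ]), c(0, 0, 0))
  expect_equal(as.vector(od0[1, 2, ]), c(1, 1, 1))  # -log10(25.5/255)
  expect_true(all(rgb_to_od(img) >= 0))

  set.seed(6)
  rgb <- array(sample(10:255, 30 * 3, TRUE), c(5, 6, 3))
  round_trip <- od_to_rgb(rgb_to_od(rgb, eps = 0))
  expect_true(all(abs(round_trip - rgb) <= 1))
})

test_that("Macenko recovers known stain vectors from synthetic mixtures", {
  v1 <- c(0.65, 0.70, 0.29); v1 <- v1 / sqrt(sum(v1^2))
  v2 <- c(0.07, 0.99, 0.11); v2 <- v2 / sqrt(sum(v2^2))
  set.seed(12)
  n <- 4000
  # concentrations spanning the wedge, incl. near-pure pixels
  c1 <- runif(n, 0, 1.5) * rbinom(n, 1, 0.9)
  c2 <- runif(n, 0, 1.5) * rbinom(n, 1, 0.9)
  X <- outer(c1, v1) + outer(c2, v2)
  got <- macenko_stain_vectors(X)
  ang <- function(a, b) acos(pmin(1, abs(sum(a * b))))
  expect_lt(ang(got[, 1], v1), 1e-3)
  expect_lt(ang(got[, 2], v2), 1e-3)
  expect_equal(attr(got, "source"), "macenko")

  # 1% OD noise: recovery within 2 degrees
  Xn <- X + matrix(rnorm(3 * n, 0, 0.01), n, 3)
  Xn[Xn < 0] <- 0
  gotn <- macenko_stain_vectors(Xn)
  expect_lt(ang(gotn[, 1], v1), 2 * pi / 180)
  expect_lt(ang(gotn[, 2], v2), 2 * pi / 180)

  # single stain: degenerate cloud
  expect_error(macenko_stain_vectors(outer(runif(500, 0.2, 1), v1)),
               "degenerate")
})

test_that("stain projection solves the exact two-vector least squares", {
  vecs <- stain_vectors(c(0.65, 0.70, 0.29), c(0.07, 0.99, 0.11))
  V <- unclass(vecs)
  od <- array(0, c(2, 2, 3))
  od[1, 1, ] <- 0.7 * V[, 1]
  set.seed(9)
  a <- 0.4; b <- 1.1
  od[1, 2, ] <- a * V[, 1] + b * V[, 2]
  proj <- project_onto_stains(od, vecs)
  expect_equal(proj$channel1[1, 1], 0.7, tolerance = 1e-9)
  expect_equal(proj$channel2[1, 1], 0, tolerance = 1e-9)
  expect_equal(proj$channel1[1, 2], a, tolerance = 1e-9)
  expect_equal(proj$channel2[1, 2], b, tolerance = 1e-9)
  expect_equal(proj$channel1[2, 1], 0)
  # reconstruction on random non-negative mixtures
  n <- 50
  ca <- runif(n); cb <- runif(n)
  odr <- array(t(outer(ca, V[, 1]) + outer(cb, V[, 2])), c(3, 1, n))
  odr <- aperm(odr, c(3, 2, 1))
  pr <- project_onto_stains(odr, vecs)
  rec <- outer(as.vector(pr$channel1), V[, 1]) +
    outer(as.vector(pr$channel2), V[, 2])
  expect_equal(rec, outer(ca, V[, 1]) + outer(cb, V[, 2]), tolerance = 1e-9)
  expect_error(stain_vectors(c(1, 0, 0), c(1, 1e-9, 0)), "collinear")
})

test_that("zonated quantification equals the brute-force group-by", {
  set.seed(15)
  for (trial in 1:8) {
    H <- 30; W <- 40
    lob <- matrix(sample(0:4, H * W, TRUE), H, W)
    zon <- matrix(sample(1:12, H * W, TRUE), H, W)
    zon[lob == 0] <- 0L
    maps <- structure(list(lobuli = lob, zones = zon, n_zones = 12L,
                           resolution_nm_per_px = 4000),
                      class = "zonation_maps")
    intensity <- matrix(runif(H * W), H, W)
    got <- zonated_quantification(intensity, maps)
    want <- bf_zonated_means(intensity, lob, zon)
    expect_equal(got$mean_intensity, want$mean_intensity, tolerance = 1e-12)
    expect_equal(got$n_pixels, want$n_pixels)
    expect_equal(sum(got$n_pixels), sum(lob > 0))
  }
  # constant intensity -> every cell mean equals the constant
  lob <- matrix(1L, 10, 10); zon <- matrix(rep(1:10, each = 10), 10, 10)
  maps <- structure(list(lobuli = lob, zones = zon, n_zones = 12L,
                         resolution_nm_per_px = 4000),
                    class = "zonation_maps")
  q <- zonated_quantification(matrix(3.5, 10, 10), maps)
  expect_true(all(q$mean_intensity == 3.5))
  expect_error(zonated_quantification(matrix(0, 5, 5), maps), "extent")
})

test_that("portality used as intensity lands each zone near its bin center", {
  sp <- small_phantom()
  pts <- layout_points(sp$layout)
  mask <- matrix(1L, 512, 512)
  attr(mask, "resolution_nm_per_px") <- 4000
  z <- zonate(pts, mask)
  q <- zonated_quantification(unclass(z$field), z$maps)
  for (zi in 2:11) {
    m <- q$mean_intensity[q$zone == zi]
    expect_true(all(abs(m - (zi - 0.5) / 12) <= 0.5 / 12))
  }
})

test_that("zone profile summary aggregates one value per lobulus per zone", {
  prof <- data.frame(lobulus = rep(1:2, each = 3), zone = rep(1:3, 2),
                     mean_intensity = c(1, 2, 3, 3, 4, 5),
                     n_pixels = rep(10, 6))
  class(prof) <- c("zonated_profile", "data.frame")
  s <- zone_profile_summary(prof)
  expect_equal(s$mean, c(2, 3, 4))
  expect_equal(s$n_lobuli, rep(2, 3))
  one <- zone_profile_summary(prof[prof$lobulus == 1, ])
  expect_equal(one$mean, c(1, 2, 3))
  expect_equal(one$median, one$mean)
})
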