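# Foreground/background segmentation of histological images:
# grayscale -> Otsu threshold -> contour-area filtering -> morphological
# smoothing.  Masks are integer 0/1 matrices (rows = y, cols = x) with a
# resolution_nm_per_px attribute.

#' Convert RGB to grayscale
#'
#' Weighted luminance `Y = 0.299 R + 0.587 G + 0.114 B`, rounded half-even
#' to 8-bit levels.
#'
#' @param rgb H x W x 3 array, values 0..255.
#' @return H x W matrix of integers 0..255 (resolution attribute kept).
#' @export
to_grayscale <- function(rgb) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3)
    stop("expected a 3-channel RGB array")
  y <- matrix(round(0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] +
                      0.114 * rgb[, , 3]),
              dim(rgb)[1], dim(rgb)[2])
  attr(y, "resolution_nm_per_px") <- attr(rgb, "resolution_nm_per_px")
  y
}

#' Otsu's threshold
#'
#' Chooses the threshold `t` maximizing the between-class intensity
#' variance over the 256-bin histogram, splitting pixels into `Y < t`
#' (dark; tissue in bright-field histology) and `Y >= t` (bright;
#' background).  Ties go to the smallest maximizing `t`.
#'
#' @param gray matrix of integers 0..255.
#' @return scalar threshold in 1..255.
#' @export
otsu_threshold <- function(gray) {
  v <- as.integer(gray)
  if (length(unique(v)) < 2) stop("constant image: Otsu threshold undefined")
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  levels <- 0:255
  w0 <- cumsum(p)                  # weight of class {0..k}
  mu <- cumsum(p * levels)         # first moment of class {0..k}
  mu_t <- mu[256]
  # candidate threshold t = k+1 splits {0..k} vs {k+1..255}
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, 256)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  which.max(sigma_b)  # returns k+1 = t, smallest maximizer
}

label_components <- function(mask) {
  # 4-connected labeling of nonzero pixels (EBImage, x/y-transpose agnostic)
  lab <- EBImage::bwlabel(mask)
  matrix(as.integer(lab), nrow(mask), ncol(mask))
}

#' Filter mask components by physical area
#'
#' Removes foreground components smaller than `min_tissue_area_mm2`
#' (default: the area of a circle of 1 mm diameter, 0.785 mm^2) and fills
#' enclosed holes of area at most `min_hole_area_mm2` (default
#' 0.00785 mm^2); larger enclosed empty spaces — e.g. gaps between two
#' tissue segments — are left as background.
#'
#' @param mask 0/1 matrix with a `resolution_nm_per_px` attribute (or pass
#'   `resolution_nm_per_px` explicitly).
#' @param min_tissue_area_mm2,min_hole_area_mm2 area thresholds in mm^2.
#' @param resolution_nm_per_px resolution override in nm/pixel.
#' @param fill_large_holes if `TRUE`, holes above the threshold are filled
#'   too (alternative reading of hole handling); default keeps them open.
#' @return filtered 0/1 matrix.
#' @export
filter_contours <- function(mask,
                            min_tissue_area_mm2 = pi * 0.5^2,
                            min_hole_area_mm2 = pi * 0.5^2 / 100,
                            resolution_nm_per_px = attr(mask, "resolution_nm_per_px"),
                            fill_large_holes = FALSE) {
  if (is.null(resolution_nm_per_px) || resolution_nm_per_px <= 0)
    stop("positive resolution_nm_per_px required")
  if (min_tissue_area_mm2 <= 0 || min_hole_area_mm2 <= 0)
    stop("area thresholds must be positive")
  px_mm2 <- (resolution_nm_per_px * 1e-6)^2   # mm^2 per pixel
  res <- resolution_nm_per_px

  fg <- label_components(mask)
  if (max(fg) > 0) {
    areas <- tabulate(fg[fg > 0]) * px_mm2
    keep <- which(areas >= min_tissue_area_mm2)
    mask <- matrix(as.integer(fg %in% keep & fg > 0), nrow(mask), ncol(mask))
  }
  bg <- label_components(1L - mask)
  if (max(bg) > 0) {
    border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
    border <- border[border > 0]
    areas <- tabulate(bg[bg > 0]) * px_mm2
    holes <- setdiff(seq_along(areas), border)
    fill <- if (fill_large_holes) holes else
      holes[areas[holes] <= min_hole_area_mm2]
    if (length(fill) > 0)
      mask[bg %in% fill] <- 1L
  }
  attr(mask, "resolution_nm_per_px") <- res
  mask
}

#' Smooth mask edges
#'
#' Median blur followed by a morphological opening with a disk structuring
#' element.
#'
#' @param mask 0/1 matrix.
#' @param median_kernel odd kernel edge length in pixels (`1` disables).
#' @param opening_radius disk radius in pixels (`0` disables).
#' @return smoothed 0/1 matrix.
#' @export
smooth_mask <- function(mask, median_kernel = 11, opening_radius = 5) {
  if (median_kernel %% 2 != 1) stop("median kernel must be odd")
  res <- attr(mask, "resolution_nm_per_px")
  out <- mask
  if (median_kernel > 1) {
    f <- EBImage::medianFilter(out + 0, (median_kernel - 1) / 2)
    out <- matrix(as.integer(f > 0.5), nrow(mask), ncol(mask))
  }
  if (opening_radius > 0) {
    brush <- EBImage::makeBrush(2 * opening_radius + 1, shape = "disc")
    o <- EBImage::opening(out, brush)
    out <- matrix(as.integer(o > 0.5), nrow(mask), ncol(mask))
  }
  attr(out, "resolution_nm_per_px") <- res
  out
}

#' Compute a tissue mask for an RGB image
#'
#' Composition: grayscale conversion, Otsu thresholding (tissue = dark
#' side), contour-area filtering, edge smoothing.
#'
#' @param rgb H x W x 3 array, values 0..255.
#' @param resolution_nm_per_px resolution in nm/pixel.
#' @param min_tissue_area_mm2,min_hole_area_mm2 see [filter_contours()].
#' @param median_kernel,opening_radius see [smooth_mask()].
#' @return 0/1 matrix of class `tissue_mask` with resolution attribute.
#' @export
compute_tissue_mask <- function(rgb,
                                resolution_nm_per_px = attr(rgb, "resolution_nm_per_px"),
                                min_tissue_area_mm2 = pi * 0.5^2,
                                min_hole_area_mm2 = pi * 0.5^2 / 100,
                                median_kernel = 11, opening_radius = 5) {
  if (is.null(resolution_nm_per_px))
    stop("resolution_nm_per_px required")
  gray <- to_grayscale(rgb)
  t <- otsu_threshold(gray)
  mask <- matrix(as.integer(gray < t), nrow(gray), ncol(gray))
  attr(mask, "resolution_nm_per_px") <- resolution_nm_per_px
  mask <- filter_contours(mask, min_tissue_area_mm2, min_hole_area_mm2,
                          resolution_nm_per_px)
  mask <- smooth_mask(mask, median_kernel, opening_radius)
  if (sum(mask) == 0) stop("no tissue found after filtering")
  attr(mask, "resolution_nm_per_px") <- resolution_nm_per_px
  class(mask) <- c("tissue_mask", class(mask))
  mask
}

#' Mask area in mm^2
#'
#' @param mask 0/1 matrix with resolution attribute.
#' @return foreground pixel count times the pixel area.
#' @export
mask_area_mm2 <- function(mask) {
  sum(mask == 1) * (attr(mask, "resolution_nm_per_px") * 1e-6)^2
}
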