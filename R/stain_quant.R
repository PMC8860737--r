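# Color-deconvolution-based stain signal detection and zonated
# quantification.  RGB transmittance is converted to optical density
# (Beer-Lambert, base-10 log), the OD pixel cloud is decomposed onto two
# principal stain color vectors (estimated by the Macenko method or
# supplied manually), and the resulting per-pixel stain intensities are
# averaged per (lobulus, zone).

#' RGB to optical density
#'
#' `OD_c = -log10((I_c + eps) / I0)` per channel, with small negative
#' values (from `I_c + eps > I0`) clipped to 0.
#'
#' @param rgb H x W x 3 array, values 0..255.
#' @param I0 incident (background) intensity, default 255.
#' @param eps additive offset avoiding `log(0)`, default 1.
#' @return H x W x 3 array of optical densities (>= 0).
#' @export
rgb_to_od <- function(rgb, I0 = 255, eps = 1) {
  od <- -log10((rgb + eps) / I0)
  od[od < 0] <- 0
  od
}

#' Optical density to RGB
#'
#' Inverse transform `I_c = I0 * 10^-OD_c`, rounded and clipped to 8-bit.
#'
#' @param od H x W x 3 array of optical densities.
#' @param I0 incident intensity, default 255.
#' @return H x W x 3 array of values 0..255.
#' @export
od_to_rgb <- function(od, I0 = 255) {
  pmin(pmax(round(I0 * 10^(-od)), 0), 255)
}

#' Construct a stain-vector pair
#'
#' @param v1,v2 numeric length-3 stain color vectors in OD space;
#'   normalized to unit length.
#' @param source `"macenko"` or `"manual"`.
#' @param min_angle_deg minimum angle between the two vectors.
#' @return object of class `stain_vectors`: 3 x 2 matrix with columns
#'   `v1`, `v2`.
#' @export
stain_vectors <- function(v1, v2, source = c("manual", "macenko"),
                          min_angle_deg = 1) {
  source <- match.arg(source)
  v1 <- v1 / sqrt(sum(v1^2)); v2 <- v2 / sqrt(sum(v2^2))
  if (any(v1 < -1e-9) || any(v2 < -1e-9))
    stop("stain vectors must have non-negative components")
  ang <- acos(pmin(1, sum(v1 * v2))) * 180 / pi
  if (ang < min_angle_deg) stop("stain vectors are collinear")
  structure(cbind(v1 = v1, v2 = v2), source = source,
            class = "stain_vectors")
}

#' Macenko stain-vector estimation
#'
#' Estimates the two principal stain colors of an image from its OD pixel
#' cloud: background pixels (all channels below `beta`) are discarded, the
#' cloud is projected onto the plane of its top-2 principal directions,
#' and the extreme directions at the `alpha` / `100 - alpha` percentiles
#' of the angular distribution are returned as unit vectors.  The first
#' vector is the more hematoxylin-like one (largest blue component).
#'
#' @param od H x W x 3 OD array (or an N x 3 matrix of OD pixels).
#' @param alpha angular percentile (default 1).
#' @param beta background OD threshold (default 0.15).
#' @return a [stain_vectors()] object with source `"macenko"`.
#' @export
macenko_stain_vectors <- function(od, alpha = 1, beta = 0.15) {
  X <- if (is.matrix(od)) od else
    cbind(as.vector(od[, , 1]), as.vector(od[, , 2]), as.vector(od[, , 3]))
  X <- X[apply(X, 1, max) >= beta, , drop = FALSE]
  if (nrow(X) < 2) stop("too few non-background OD pixels")
  sv <- svd(X, nu = 0, nv = 3)
  if (sv$d[2] < 1e-8 * sv$d[1])
    stop("degenerate OD cloud (single stain): cannot estimate two vectors")
  V <- sv$v[, 1:2]
  # orient the plane basis so projections land in a consistent half-plane
  if (sum(V[, 1]) < 0) V[, 1] <- -V[, 1]
  if (sum(V[, 2]) < 0) V[, 2] <- -V[, 2]
  proj <- X %*% V
  phi <- atan2(proj[, 2], proj[, 1])
  q <- stats::quantile(phi, c(alpha / 100, 1 - alpha / 100), names = FALSE)
  back <- function(a) {
    v <- V %*% c(cos(a), sin(a))
    if (sum(v) < 0) v <- -v
    v[v < 0] <- 0
    v / sqrt(sum(v^2))
  }
  v_a <- back(q[1]); v_b <- back(q[2])
  # hematoxylin-like vector (largest blue weight) first
  if (v_a[3] >= v_b[3]) {
    out <- stain_vectors(v_a, v_b, source = "macenko")
  } else {
    out <- stain_vectors(v_b, v_a, source = "macenko")
  }
  out
}

#' Project OD pixels onto the stain vectors
#'
#' Per-pixel least-squares concentrations for the two stain color vectors;
#' negative concentrations are clipped to 0.
#'
#' @param od H x W x 3 OD array.
#' @param vectors a [stain_vectors()] object.
#' @return list of two H x W intensity matrices (`channel1` = first/
#'   hematoxylin-like vector, `channel2` = second).
#' @export
project_onto_stains <- function(od, vectors) {
  stopifnot(inherits(vectors, "stain_vectors"))
  H <- dim(od)[1]; W <- dim(od)[2]
  X <- cbind(as.vector(od[, , 1]), as.vector(od[, , 2]), as.vector(od[, , 3]))
  V <- unclass(vectors)                # 3 x 2
  C <- t(solve(crossprod(V), t(X %*% V)))   # N x 2 least squares
  C[C < 0] <- 0
  list(channel1 = matrix(C[, 1], H, W), channel2 = matrix(C[, 2], H, W))
}

#' Zonated quantification of a stain intensity image
#'
#' Means the per-pixel stain intensity over each zone of each lobulus.
#'
#' @param intensity H x W matrix of stain intensity (OD units).
#' @param maps a `zonation_maps` object of the same extent.
#' @return `zonated_profile`: data.frame with one row per nonempty
#'   (lobulus, zone) cell — columns `lobulus`, `zone`, `mean_intensity`,
#'   `n_pixels`.
#' @export
zonated_quantification <- function(intensity, maps) {
  if (!all(dim(intensity) == dim(maps$lobuli)))
    stop("extent mismatch between intensity image and zonation maps")
  sel <- maps$lobuli > 0
  lob <- maps$lobuli[sel]; zon <- maps$zones[sel]; val <- intensity[sel]
  key <- (lob - 1) * (maps$n_zones + 1L) + zon
  sums <- rowsum(val, key)
  cnts <- rowsum(rep(1L, length(val)), key)
  k <- as.integer(rownames(sums))
  out <- data.frame(lobulus = k %/% (maps$n_zones + 1L) + 1L,
                    zone = k %% (maps$n_zones + 1L),
                    mean_intensity = as.vector(sums) / as.vector(cnts),
                    n_pixels = as.vector(cnts))
  out <- out[order(out$lobulus, out$zone), ]
  rownames(out) <- NULL
  class(out) <- c("zonated_profile", "data.frame")
  out
}

#' Per-zone summary of a zonated profile
#'
#' Each lobulus contributes one value (its zone mean) per zone; the
#' summary aggregates these over lobuli.
#'
#' @param profile a [zonated_quantification()] result.
#' @return data.frame with one row per zone: `zone`, `n_lobuli`, `mean`,
#'   `median`, `q25`, `q75`.
#' @export
zone_profile_summary <- function(profile) {
  if (nrow(profile) == 0) stop("empty profile")
  do.call(rbind, lapply(sort(unique(profile$zone)), function(z) {
    v <- profile$mean_intensity[profile$zone == z]
    data.frame(zone = z, n_lobuli = length(v), mean = mean(v),
               median = stats::median(v),
               q25 = stats::quantile(v, 0.25, names = FALSE),
               q75 = stats::quantile(v, 0.75, names = FALSE))
  }))
}
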