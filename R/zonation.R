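# Lobule/zone tessellation.  The portality p of a pixel encodes its
# relative position along the CV -> PF axis: p = d_CV / (d_CV + d_PF) with
# Euclidean distances to the nearest CV and PF point, so p = 0 at central
# veins and p = 1 at portal fields.  Catchment basins of the preflooded
# watershed transform of the portality field are the computed lobuli;
# quantizing the portality into equal-width ranges yields the zones.

#' Compute the portality field
#'
#' `p(x) = d_CV(x) / (d_CV(x) + d_PF(x))` at every pixel center, with
#' Euclidean distances to the nearest CV resp. PF seed.  Seed points are
#' rasterized to the pixel containing them; distances are computed between
#' pixel centers, so `p` is exactly 0 at CV seed pixels and 1 at PF seed
#' pixels.
#'
#' @param extent `c(width, height)` in pixels.
#' @param pf_points,cv_points data.frames with `x`, `y` columns (pixel
#'   coordinates), or an [annotation_set()] of points from which the two
#'   classes are taken.
#' @param resolution_nm_per_px optional resolution attribute to carry.
#' @return H x W matrix with values in `[0,1]`, class `portality_field`.
#' @export
portality_field <- function(extent, pf_points, cv_points = NULL,
                            resolution_nm_per_px = NULL) {
  if (inherits(pf_points, "annotation_set") && is.null(cv_points)) {
    set <- pf_points
    pf_points <- ann_points(set, "PF")
    cv_points <- ann_points(set, "CV")
    if (is.null(resolution_nm_per_px))
      resolution_nm_per_px <- attr(set, "resolution_nm_per_px")
  }
  if (is.null(pf_points) || nrow(pf_points) == 0)
    stop("at least one PF point required")
  if (is.null(cv_points) || nrow(cv_points) == 0)
    stop("at least one CV point required")
  W <- as.integer(extent[1]); H <- as.integer(extent[2])
  seed_mask <- function(pts) {
    m <- matrix(1L, H, W)
    ix <- pmin(pmax(floor(pts$x), 0), W - 1)
    iy <- pmin(pmax(floor(pts$y), 0), H - 1)
    m[cbind(iy + 1, ix + 1)] <- 0L
    m
  }
  d_cv <- EBImage::distmap(seed_mask(cv_points))
  d_pf <- EBImage::distmap(seed_mask(pf_points))
  denom <- d_cv + d_pf
  p <- matrix(ifelse(denom > 0, d_cv / denom, 0.5), H, W)
  attr(p, "resolution_nm_per_px") <- resolution_nm_per_px
  class(p) <- c("portality_field", class(p))
  p
}

#' Preflooded watershed tessellation of the portality field
#'
#' Floods the portality field from its regional minima — the CV seed
#' pixels, where `p = 0` — by ascending value (deterministic
#' priority-queue flood, ties broken by insertion order, 8-connectivity).
#' Two basins whose floods meet at a saddle below their minima's level
#' plus `preflood_h` are merged, so a shallow saddle between two nearby
#' CVs yields a single basin.  Every pixel is assigned to exactly one
#' basin (the background is masked later, by [assemble_zonation()]);
#' seeding at the CVs guarantees each basin contains at least one CV.
#'
#' @param field a [portality_field()].
#' @param cv_points CV seed points, data.frame with `x`, `y` in pixels.
#' @param preflood_h preflood depth in portality units (>= 0).
#' @return integer matrix of basin labels `1..L`, `L <= nrow(cv_points)`.
#' @export
preflooded_watershed <- function(field, cv_points, preflood_h = 0.05) {
  stopifnot(preflood_h >= 0)
  if (is.null(cv_points) || nrow(cv_points) == 0)
    stop("no minima: at least one CV seed required")
  ix <- pmin(pmax(floor(cv_points$x), 0), ncol(field) - 1)
  iy <- pmin(pmax(floor(cv_points$y), 0), nrow(field) - 1)
  seeded_watershed_cpp(unclass(field), as.integer(iy), as.integer(ix),
                       preflood_h)
}

#' Quantize portality into zones
#'
#' Zone `z(x) = min(floor(p(x) * n_zones) + 1, n_zones)`: `n_zones`
#' value ranges of width `1/n_zones`, zone 1 pericentral (at the CV),
#' zone `n_zones` periportal (at the PF).
#'
#' @param field a [portality_field()].
#' @param n_zones number of zones (default 12).
#' @return integer matrix of zone labels `1..n_zones`.
#' @export
quantize_zones <- function(field, n_zones = 12) {
  stopifnot(n_zones >= 1)
  z <- pmin(floor(unclass(field) * n_zones) + 1, n_zones)
  matrix(as.integer(z), nrow(field), ncol(field))
}

#' Assemble zonation maps, masking out the background
#'
#' Restricts basin and zone labels to the tissue mask; each masked basin is
#' a computed lobulus.  Lobulus labels are renumbered densely `1..L` over
#' the basins with nonempty masked support, in order of their original
#' label; zone labels are zeroed outside the mask.
#'
#' @param basins integer basin label matrix from [preflooded_watershed()].
#' @param zones integer zone label matrix from [quantize_zones()].
#' @param mask 0/1 tissue mask of the same extent.
#' @param n_zones number of zones encoded in `zones`.
#' @return object of class `zonation_maps`: list with `lobuli` and `zones`
#'   label matrices (0 = background), `n_zones`, and the resolution
#'   attribute of the mask.
#' @export
assemble_zonation <- function(basins, zones, mask, n_zones = max(zones)) {
  if (!all(dim(basins) == dim(mask)) || !all(dim(zones) == dim(mask)))
    stop("extent mismatch between basins/zones/mask")
  if (sum(mask) == 0) stop("empty tissue mask")
  lob <- basins * (mask == 1)
  surviving <- sort(unique(lob[lob > 0]))
  relabel <- integer(max(basins))
  relabel[surviving] <- seq_along(surviving)
  lob[lob > 0] <- relabel[lob[lob > 0]]
  zon <- zones * (mask == 1)
  structure(list(lobuli = matrix(as.integer(lob), nrow(mask), ncol(mask)),
                 zones = matrix(as.integer(zon), nrow(mask), ncol(mask)),
                 n_zones = as.integer(n_zones),
                 resolution_nm_per_px = attr(mask, "resolution_nm_per_px")),
            class = "zonation_maps")
}

#' @export
print.zonation_maps <- function(x, ...) {
  cat(sprintf("<zonation_maps> %d lobuli, %d zones, extent %dx%d\n",
              max(x$lobuli), x$n_zones, ncol(x$lobuli), nrow(x$lobuli)))
  invisible(x)
}

#' Full zonation pipeline from points to label maps
#'
#' Convenience composition: portality field, preflooded watershed,
#' zone quantization, background masking.
#'
#' @param points [annotation_set()] with PF and CV points.
#' @param mask tissue mask matrix (0/1) of the target extent.
#' @param n_zones number of zones (default 12).
#' @param preflood_h preflood depth (portality units).
#' @return list with `field` (the [portality_field()]) and `maps`
#'   (a `zonation_maps` object).
#' @export
zonate <- function(points, mask, n_zones = 12, preflood_h = 0.05) {
  extent <- c(ncol(mask), nrow(mask))
  field <- portality_field(extent, points)
  basins <- preflooded_watershed(field, ann_points(points, "CV"), preflood_h)
  zones <- quantize_zones(field, n_zones)
  maps <- assemble_zonation(basins, zones, mask, n_zones)
  list(field = field, maps = maps)
}
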