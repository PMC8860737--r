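# Lobulus/acinus size metrics from point patterns and label images.

#' Nearest-neighbor radii of a point class
#'
#' Approximates lobulus radii (CV points) or acinus radii (PF points) as
#' half the distance from each point to its nearest same-class neighbor,
#' converted to micrometres via the resolution.
#'
#' @param set an [annotation_set()] containing points.
#' @param cls `"CV"` (lobulus radii) or `"PF"` (acinus radii).
#' @param resolution_nm_per_px resolution override; defaults to the set's.
#' @return numeric vector of radii in micrometres, one per point of `cls`.
#' @export
nn_radii <- function(set, cls = c("CV", "PF"),
                     resolution_nm_per_px = attr(set, "resolution_nm_per_px")) {
  cls <- match.arg(cls)
  p <- ann_points(set, cls)
  if (nrow(p) < 2)
    stop("need at least 2 points of class ", cls)
  d <- as.matrix(stats::dist(cbind(p$x, p$y)))
  diag(d) <- Inf
  nn <- unname(apply(d, 1, min))
  0.5 * nn * resolution_nm_per_px / 1000
}

#' Lobulus areas from the label image
#'
#' `area(l)` = pixel count of label `l` times the pixel area.
#'
#' @param maps a `zonation_maps` object (see [assemble_zonation()]).
#' @param resolution_nm_per_px resolution override; defaults to the maps'.
#' @return numeric vector of areas in mm^2, indexed by lobulus label.
#' @export
lobulus_areas <- function(maps,
                          resolution_nm_per_px = maps$resolution_nm_per_px) {
  if (is.null(resolution_nm_per_px))
    stop("resolution_nm_per_px required")
  lob <- maps$lobuli
  counts <- tabulate(lob[lob > 0], nbins = max(lob))
  counts * (resolution_nm_per_px * 1e-6)^2
}

#' Root-mean-square difference relative to the mean
#'
#' `sqrt(mean((a - b)^2)) / mean(c(a, b))` for paired samples: the summary
#' used to compare size distributions derived from manual vs. detected
#' points.
#'
#' @param a,b paired numeric vectors of equal length.
#' @return scalar fraction.
#' @export
rms_relative_difference <- function(a, b) {
  if (length(a) != length(b)) stop("samples must be paired (equal length)")
  m <- mean(c(a, b))
  if (m == 0) stop("zero mean: relative difference undefined")
  sqrt(mean((a - b)^2)) / m
}
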