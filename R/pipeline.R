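# Pipeline orchestration: validated run configuration and stage wrappers.
# These functions (plus the thin command-line script in inst/cli/) are the
# interface for running the whole analysis: tiling + detection + merging,
# evaluation, masking + zonation + size metrics, and zonated stain
# quantification.

#' Validated run configuration
#'
#' Defaults mirror the reference operating point of the pipeline: tile
#' size 1024 px at the working resolution, 4x downsampling from full
#' resolution, 12 zones.
#'
#' @param tile_size tile edge length s in pixels (even).
#' @param downsample_factor integer resampling factor from full resolution.
#' @param n_zones number of zones.
#' @param preflood_h watershed preflood depth in portality units.
#' @param iou_group_threshold duplicate-grouping IoU, see [deduplicate()].
#' @param score_threshold detection score cutoff (`NULL` = none).
#' @param min_tissue_area_mm2,min_hole_area_mm2 tissue-mask thresholds.
#' @param median_kernel,opening_radius tissue-mask smoothing parameters.
#' @param seed global RNG seed.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(tile_size = 1024, downsample_factor = 4,
                       n_zones = 12, preflood_h = 0.05,
                       iou_group_threshold = 0.5, score_threshold = NULL,
                       min_tissue_area_mm2 = pi * 0.5^2,
                       min_hole_area_mm2 = pi * 0.5^2 / 100,
                       median_kernel = 11, opening_radius = 5, seed = 1) {
  stopifnot(tile_size %% 2 == 0, tile_size > 0,
            downsample_factor >= 1,
            n_zones >= 1, preflood_h >= 0,
            iou_group_threshold > 0, iou_group_threshold <= 1,
            min_tissue_area_mm2 > 0, min_hole_area_mm2 > 0,
            median_kernel %% 2 == 1, opening_radius >= 0)
  structure(list(tile_size = tile_size,
                 downsample_factor = downsample_factor,
                 n_zones = n_zones, preflood_h = preflood_h,
                 iou_group_threshold = iou_group_threshold,
                 score_threshold = score_threshold,
                 min_tissue_area_mm2 = min_tissue_area_mm2,
                 min_hole_area_mm2 = min_hole_area_mm2,
                 median_kernel = median_kernel,
                 opening_radius = opening_radius, seed = seed),
            class = "run_config")
}

#' Detect PF/CV points on a whole-slide image
#'
#' Builds the overlapping tile grid, runs the backend per tile, merges
#' tile-wise boxes and reduces them to WSI points.
#'
#' @param wsi image raster (or `NULL` for pixel-free backends).
#' @param image_extent `c(width, height)`; defaults to the raster's.
#' @param resolution_nm_per_px resolution of `wsi`.
#' @param backend detector backend function (see [oracle_detector()]).
#' @param config a [run_config()].
#' @return see [run_wsi_detection()].
#' @export
detect_structures <- function(wsi, backend, config = run_config(),
                              image_extent = NULL,
                              resolution_nm_per_px = attr(wsi, "resolution_nm_per_px")) {
  if (is.null(image_extent))
    image_extent <- c(dim(wsi)[2], dim(wsi)[1])
  grid <- make_tile_grid(image_extent, config$tile_size)
  run_wsi_detection(wsi, grid, backend, resolution_nm_per_px,
                    iou_group_threshold = config$iou_group_threshold,
                    score_threshold = config$score_threshold)
}

#' Evaluate detections against ground truth
#'
#' Chooses the matching mode from the geometries: point detections vs.
#' box ground truth, or box detections vs. point ground truth.
#'
#' @param detections [annotation_set()] of detected points or boxes.
#' @param truth [annotation_set()] ground truth (boxes or points).
#' @param digits display rounding for the report (default 3).
#' @return metrics report data.frame (class rows + mean row).
#' @export
evaluate_detections <- function(detections, truth, digits = 3) {
  det_boxes <- any(detections$type == "box")
  gt_boxes <- any(truth$type == "box") || nrow(truth) == 0
  counts <- if (!det_boxes && gt_boxes)
    match_points_to_boxes(detections, truth)
  else if (det_boxes && !gt_boxes)
    match_boxes_to_points(detections, truth)
  else stop("unsupported mode: need points-vs-boxes or boxes-vs-points")
  metrics_report(counts, digits = digits)
}

#' Zonate a slide: mask, portality, lobuli, zones and size metrics
#'
#' @param points [annotation_set()] with detected (or manual) PF and CV
#'   points.
#' @param rgb RGB raster of the slide (used for the tissue mask); pass a
#'   precomputed mask via `mask` instead to skip masking.
#' @param config a [run_config()].
#' @param mask optional 0/1 tissue mask.
#' @return list: `mask`, `field`, `maps`, `lobulus_areas_mm2`,
#'   `cv_radii_um`, `pf_radii_um`.
#' @export
zonate_slide <- function(points, rgb = NULL, config = run_config(),
                         mask = NULL) {
  if (is.null(mask)) {
    if (is.null(rgb)) stop("need either rgb or mask")
    mask <- compute_tissue_mask(
      rgb, attr(points, "resolution_nm_per_px"),
      min_tissue_area_mm2 = config$min_tissue_area_mm2,
      min_hole_area_mm2 = config$min_hole_area_mm2,
      median_kernel = config$median_kernel,
      opening_radius = config$opening_radius)
  }
  z <- zonate(points, mask, n_zones = config$n_zones,
              preflood_h = config$preflood_h)
  list(mask = mask, field = z$field, maps = z$maps,
       lobulus_areas_mm2 = lobulus_areas(z$maps),
       cv_radii_um = nn_radii(points, "CV"),
       pf_radii_um = nn_radii(points, "PF"))
}

#' Zonated quantification of a stain image
#'
#' OD transform, stain-vector estimation (Macenko) or manual vectors,
#' projection, and per-(lobulus, zone) averaging of the first channel.
#'
#' @param rgb RGB raster of the stained slide.
#' @param maps `zonation_maps` for the same geometry (after applying any
#'   registration deformation to the points upstream).
#' @param vectors optional manual [stain_vectors()]; default: Macenko
#'   estimation on the image.
#' @param channel which projected channel to quantify (1 or 2).
#' @return list: `vectors`, `profile` (zonated profile of the channel),
#'   `summary` (per-zone summary over lobuli).
#' @export
quantify_stain <- function(rgb, maps, vectors = NULL, channel = 1) {
  od <- rgb_to_od(rgb)
  if (is.null(vectors)) vectors <- macenko_stain_vectors(od)
  proj <- project_onto_stains(od, vectors)
  intensity <- proj[[channel]]
  profile <- zonated_quantification(intensity, maps)
  list(vectors = vectors, profile = profile,
       summary = zone_profile_summary(profile))
}
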