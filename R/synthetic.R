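# Synthetic lobular-tissue generator.  Liver lobuli are modelled as a
# (perturbed) hexagonal lattice: central veins at the hexagon centers,
# portal fields at the hexagon vertices, lobule radius a few hundred um.
# The generator emits ground truth (points, tight boxes, tissue raster,
# per-pixel portality) alongside every artifact, enabling closed-loop
# tests of detection, zonation and quantification without real slides.

#' Generate a perturbed hexagonal PF/CV layout
#'
#' Central veins on a triangular lattice with spacing `sqrt(3) * R`
#' (so the induced hexagonal lobule has circumradius `R`), portal fields
#' on the dual honeycomb vertex set (each PF at distance `R` from its
#' three surrounding CVs), optional Gaussian positional jitter, points
#' outside the extent (minus `margin_um`) dropped.
#'
#' @param extent `c(width, height)` in pixels.
#' @param resolution_nm_per_px image resolution in nm/pixel.
#' @param lobule_radius_um lobule circumradius R in micrometres.
#' @param jitter_sd_um positional jitter SD in micrometres.
#' @param margin_um border margin inside which points are dropped.
#' @param seed integer RNG seed; layout is deterministic given it.
#' @return object of class `lobular_layout`: list with `cv` and `pf`
#'   data.frames (`x`, `y` in pixels) and the generating parameters.
#' @export
generate_layout <- function(extent, resolution_nm_per_px = 4000,
                            lobule_radius_um = 300, jitter_sd_um = 0,
                            margin_um = 0, seed = 1) {
  W <- extent[1]; H <- extent[2]
  um_per_px <- resolution_nm_per_px / 1000
  R <- lobule_radius_um / um_per_px
  if (R <= 0) stop("lobule radius must be positive")
  if (2 * R > max(W, H)) stop("lobule radius larger than extent")
  a <- sqrt(3) * R                       # CV lattice spacing, px
  ni <- ceiling(W / a) + 2; nj <- ceiling(H / (a * sqrt(3) / 2)) + 2
  ij <- expand.grid(i = -1:ni, j = -1:nj)
  cx <- ij$i * a + ij$j * a / 2
  cy <- ij$j * a * sqrt(3) / 2
  # honeycomb vertices: the two triangle centroids per lattice cell
  px <- c(cx + a / 2, cx + a)
  py <- c(cy + a * sqrt(3) / 6, cy + a * sqrt(3) / 3)
  jit <- jitter_sd_um / um_per_px
  pts <- with_local_seed(seed, {
    list(cv = data.frame(x = cx + stats::rnorm(length(cx), 0, jit),
                         y = cy + stats::rnorm(length(cy), 0, jit)),
         pf = data.frame(x = px + stats::rnorm(length(px), 0, jit),
                         y = py + stats::rnorm(length(py), 0, jit)))
  })
  mar <- margin_um / um_per_px
  inside <- function(d) d[d$x >= mar & d$x < W - mar &
                          d$y >= mar & d$y < H - mar, , drop = FALSE]
  cv <- inside(pts$cv); pf <- inside(pts$pf)
  rownames(cv) <- rownames(pf) <- NULL
  structure(list(cv = cv, pf = pf, extent = c(W, H),
                 resolution_nm_per_px = resolution_nm_per_px,
                 lobule_radius_um = lobule_radius_um,
                 jitter_sd_um = jitter_sd_um, margin_um = margin_um,
                 seed = seed),
            class = "lobular_layout")
}

#' Convert a layout to an annotation set of points
#'
#' @param layout a [generate_layout()] result.
#' @return [annotation_set()] with the CV and PF ground-truth points.
#' @export
layout_points <- function(layout) {
  annotation_set(points = rbind(
    data.frame(class = "CV", x = layout$cv$x, y = layout$cv$y),
    data.frame(class = "PF", x = layout$pf$x, y = layout$pf$y)),
    resolution_nm_per_px = layout$resolution_nm_per_px,
    image_extent = layout$extent)
}

#' Phantom rendering parameters
#'
#' @param tissue_rgb base tissue color (eosinophilic pink), 8-bit RGB.
#' @param cv_lumen_um central-vein lumen radius in micrometres.
#' @param pf_lumen_um portal-vein lumen radius; the PF is rendered as a
#'   compound structure (portal vein lumen plus two smaller duct/artery
#'   lumens).
#' @param tissue_margin_um white border between image edge and tissue.
#' @param noise_sd per-channel Gaussian texture noise SD (8-bit levels).
#' @return parameter list of class `phantom_spec`.
#' @export
phantom_spec <- function(tissue_rgb = c(205, 145, 175),
                         cv_lumen_um = 30, pf_lumen_um = 15,
                         tissue_margin_um = 150, noise_sd = 3) {
  stopifnot(length(tissue_rgb) == 3, all(tissue_rgb >= 0 & tissue_rgb <= 255))
  structure(list(tissue_rgb = tissue_rgb, cv_lumen_um = cv_lumen_um,
                 pf_lumen_um = pf_lumen_um,
                 tissue_margin_um = tissue_margin_um, noise_sd = noise_sd),
            class = "phantom_spec")
}

# paint a disk of value `val` into channel matrices (list), in place-ish
paint_disk <- function(channels, cx, cy, r, val) {
  H <- nrow(channels[[1]]); W <- ncol(channels[[1]])
  x0 <- max(floor(cx - r), 0); x1 <- min(ceiling(cx + r), W - 1)
  y0 <- max(floor(cy - r), 0); y1 <- min(ceiling(cy + r), H - 1)
  if (x0 > x1 || y0 > y1) return(channels)
  xs <- x0:x1; ys <- y0:y1
  dx2 <- ((xs + 0.5) - cx)^2; dy2 <- ((ys + 0.5) - cy)^2
  hit <- outer(dy2, dx2, "+") <= r^2
  for (c in seq_along(channels)) {
    sub <- channels[[c]][ys + 1, xs + 1]
    sub[hit] <- val[min(c, length(val))]
    channels[[c]][ys + 1, xs + 1] <- sub
  }
  channels
}

#' Render an H&E-like phantom image with ground-truth boxes
#'
#' White background, pink tissue slab (inset by the spec's margin), white
#' central-vein lumens (disks) and compound portal-field structures (a
#' portal-vein lumen flanked by two smaller duct lumens), plus seeded
#' Gaussian texture noise on the tissue.  Tight ground-truth boxes are
#' emitted around every rendered structure, and the true tissue raster is
#' returned for closed-loop mask tests.
#'
#' @param layout a [generate_layout()] result.
#' @param spec a [phantom_spec()].
#' @param seed RNG seed for the texture noise.
#' @return list with `image` (H x W x 3, 0..255, resolution attribute),
#'   `annotations` ([annotation_set()] of tight boxes) and `tissue`
#'   (0/1 truth raster).
#' @export
render_hne_phantom <- function(layout, spec = phantom_spec(), seed = 1) {
  W <- layout$extent[1]; H <- layout$extent[2]
  um_per_px <- layout$resolution_nm_per_px / 1000
  mar <- spec$tissue_margin_um / um_per_px
  tissue <- matrix(0L, H, W)
  ys <- seq_len(H) - 1; xs <- seq_len(W) - 1
  tissue[ys >= mar & ys < H - mar, xs >= mar & xs < W - mar] <- 1L

  ch <- lapply(1:3, function(c) {
    m <- matrix(255, H, W)
    m[tissue == 1L] <- spec$tissue_rgb[c]
    m
  })
  r_cv <- spec$cv_lumen_um / um_per_px
  r_pf <- spec$pf_lumen_um / um_per_px
  r_duct <- r_pf * 0.45
  duct_off <- r_pf * 1.6

  boxes <- list()
  clipbox <- function(cls, x0, y0, x1, y1) {
    data.frame(class = cls, x_min = max(x0, 0), y_min = max(y0, 0),
               x_max = min(x1, W), y_max = min(y1, H))
  }
  for (k in seq_len(nrow(layout$cv))) {
    cx <- layout$cv$x[k]; cy <- layout$cv$y[k]
    ch <- paint_disk(ch, cx, cy, r_cv, 255)
    boxes[[length(boxes) + 1]] <-
      clipbox("CV", cx - r_cv, cy - r_cv, cx + r_cv, cy + r_cv)
  }
  for (k in seq_len(nrow(layout$pf))) {
    cx <- layout$pf$x[k]; cy <- layout$pf$y[k]
    ch <- paint_disk(ch, cx, cy, r_pf, 255)
    ch <- paint_disk(ch, cx + duct_off, cy, r_duct, 255)
    ch <- paint_disk(ch, cx - duct_off * 0.5, cy + duct_off * 0.8,
                     r_duct, 255)
    ext <- duct_off + r_duct
    boxes[[length(boxes) + 1]] <-
      clipbox("PF", cx - ext, cy - ext, cx + ext, cy + ext)
  }
  img <- array(0, dim = c(H, W, 3))
  with_local_seed(seed + 211, {
    for (c in 1:3) {
      m <- ch[[c]]
      noise <- matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W)
      m <- m + noise * (tissue == 1L)
      img[, , c] <- pmin(pmax(round(m), 0), 255)
    }
  })
  attr(img, "resolution_nm_per_px") <- layout$resolution_nm_per_px
  ann <- annotation_set(boxes = do.call(rbind, boxes),
                        resolution_nm_per_px = layout$resolution_nm_per_px,
                        image_extent = layout$extent)
  list(image = img, annotations = ann, tissue = tissue)
}

#' Render a stain phantom with a known zonation profile
#'
#' Per-pixel optical density `f(p(x)) * v1 + baseline * v2 + noise`
#' (portality `p` computed from the layout's ground-truth points), turned
#' into an RGB image via the inverse OD transform.  `f` encodes the true
#' zonation: a constant emulates a homogeneous (H&E-like) negative
#' control, a decreasing profile a pericentral (GS-like) marker.
#'
#' @param layout a [generate_layout()] result.
#' @param f vectorized profile function mapping portality in `[0,1]` to
#'   OD concentration (>= 0).
#' @param vectors a [stain_vectors()] pair; the first vector carries the
#'   signal.  Default: hematoxylin/eosin-like pair.
#' @param baseline concentration on the second vector: a constant, or a
#'   vectorized function of portality (e.g. increasing where the first
#'   stain fades, which gives the image near-pure pixels of both stains
#'   as in real counter-stained tissue).
#' @param noise_sd Gaussian OD noise SD.
#' @param seed RNG seed for the noise.
#' @return list with `image` (H x W x 3), `portality` (the true field)
#'   and `vectors`.
#' @export
render_stain_phantom <- function(layout, f,
                                 vectors = stain_vectors(c(0.65, 0.70, 0.29),
                                                         c(0.07, 0.99, 0.11)),
                                 baseline = 0, noise_sd = 0, seed = 1) {
  W <- layout$extent[1]; H <- layout$extent[2]
  p <- portality_field(layout$extent, layout$pf, layout$cv,
                       layout$resolution_nm_per_px)
  pv <- as.vector(unclass(p))
  conc <- f(pv)
  if (any(conc < 0) || any(!is.finite(conc)))
    stop("profile function must be finite and >= 0 on [0,1]")
  base <- if (is.function(baseline)) baseline(pv) else baseline
  if (any(base < 0) || any(!is.finite(base)))
    stop("baseline must be finite and >= 0 on [0,1]")
  V <- unclass(vectors)
  od <- array(0, dim = c(H, W, 3))
  with_local_seed(seed + 977, {
    for (c in 1:3) {
      m <- conc * V[c, 1] + base * V[c, 2]
      if (noise_sd > 0) m <- m + stats::rnorm(length(m), 0, noise_sd)
      od[, , c] <- matrix(pmax(m, 0), H, W)
    }
  })
  list(image = od_to_rgb(od), portality = p, vectors = vectors)
}

#' Deformation-field fixtures
#'
#' @param kind `"identity"`, `"translation"` (params: `t = c(tx, ty)`),
#'   `"affine"` (params: `A` 2x2 matrix, `b` length-2 offset; the
#'   displacement at position q is `A %*% q + b - q`) or `"smooth_warp"`
#'   (params: `amplitude` px, `wavelength` px; seeded sinusoidal warp).
#' @param extent `c(width, height)` covered by the field, pixels.
#' @param spacing grid node spacing in pixels.
#' @param params parameter list for `kind`.
#' @param seed RNG seed (smooth_warp only).
#' @return a [deformation_field()].
#' @export
make_deformation_fixture <- function(kind = c("identity", "translation",
                                              "affine", "smooth_warp"),
                                     extent, spacing = 1, params = list(),
                                     seed = 1) {
  kind <- match.arg(kind)
  nx <- floor(extent[1] / spacing) + 1
  ny <- floor(extent[2] / spacing) + 1
  gx <- matrix(rep((0:(nx - 1)) * spacing, each = ny), ny, nx)
  gy <- matrix(rep((0:(ny - 1)) * spacing, nx), ny, nx)
  zero <- matrix(0, ny, nx)
  if (kind == "identity") {
    return(deformation_field(zero, zero, spacing))
  }
  if (kind == "translation") {
    t <- params$t
    return(deformation_field(zero + t[1], zero + t[2], spacing))
  }
  if (kind == "affine") {
    A <- params$A; b <- params$b
    dx <- A[1, 1] * gx + A[1, 2] * gy + b[1] - gx
    dy <- A[2, 1] * gx + A[2, 2] * gy + b[2] - gy
    return(deformation_field(dx, dy, spacing))
  }
  with_local_seed(seed + 389, {
    amp <- if (is.null(params$amplitude)) 2 else params$amplitude
    wl <- if (is.null(params$wavelength)) max(extent) / 4 else params$wavelength
    ph <- stats::runif(4, 0, 2 * pi)
    dx <- amp * sin(2 * pi * gx / wl + ph[1]) * cos(2 * pi * gy / wl + ph[2])
    dy <- amp * cos(2 * pi * gx / wl + ph[3]) * sin(2 * pi * gy / wl + ph[4])
    deformation_field(dx, dy, spacing)
  })
}
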