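---
title: "Detecting portal fields and central veins and quantifying zonation with hepazone"
author: "hepazone authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting portal fields and central veins and quantifying zonation with hepazone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Background

Many hepatic processes are zonated: they vary systematically along the
blood-flow axis from the portal fields (PFs), where portal vein, hepatic
artery and bile duct enter the lobule, to the central vein (CV) that
drains it. Quantifying a biomarker "in zonated form" therefore requires
knowing where the PFs and CVs are in a whole-slide image (WSI), and
manually annotating hundreds of such structures per slide is the
bottleneck. `hepazone` implements the full computational pipeline around
an interchangeable PF/CV detector:

1. an overlapping tile grid and balanced tile sampling for detector
   calibration (`make_tile_grid()`, `classify_tiles()`,
   `sample_balanced()`);
2. merging of tile-wise box detections into slide-level points
   (`run_wsi_detection()`);
3. class-stratified precision/recall/F1 evaluation in two matching modes
   (`match_points_to_boxes()`, `match_boxes_to_points()`);
4. tissue masking (`compute_tissue_mask()`);
5. tessellation of the tissue into lobuli and 12 zones from the detected
   points (`zonate()`);
6. lobulus size metrics (`nn_radii()`, `lobulus_areas()`); and
7. stain deconvolution and zonated quantification
   (`macenko_stain_vectors()`, `quantify_stain()`).

The trained convolutional detector itself is outside the package's scope:
any function mapping a tile image to scored class-labelled boxes can be
plugged in as a backend. The package ships `oracle_detector()`, a
synthetic backend that perturbs known ground truth with controlled miss
rates, jitter and false positives, which makes every downstream stage
testable in closed loop against the synthetic phantom generator.

## Tile grid and merging

Tiles of size $s \times s$ are placed with 50% overlap per direction, at
origins $(i\,s/2,\ j\,s/2)$ for integers $i, j \ge 0$; tiles not fully
inside the image are dropped rather than padded, which avoids synthetic
border artifacts at the cost of a detection margin narrower than $s/2$
along the image edge. The *interior* of a tile is its central
quarter-area region $[s/4, 3s/4)^2$ in tile coordinates. By construction
the interiors of the grid are mutually disjoint and abut exactly, so
every WSI location in the core region is interior to exactly one tile.
Half-open intervals make this sharp: a box center on a shared interior
boundary belongs to exactly one tile.

Merging tile detections proceeds in three steps: (a) tile-local box
coordinates are shifted by the tile origin; (b) duplicates are resolved —
a box contained in its own tile's interior is kept (interiors are
disjoint, so such a box is unique), while a structure straddling interior
boundaries, which can be detected in up to four overlapping tiles, is
reduced to the copy with the largest intersection area with its own
tile's interior; (c) surviving boxes are reduced to their centers (the
arithmetic mean of the vertices).

Two details are deliberate package choices. Duplicate *grouping* uses
same-class IoU $\ge 0.5$ (configurable) restricted to boxes from the same
or adjacent tiles, which prevents chains of overlaps from merging
distinct structures. And a group that contains an interior-contained copy
keeps that copy and suppresses the straddling ones; applying the keep and
group rules independently would leave one duplicate per straddling copy.
Ties on intersection area are broken by the smallest source-tile origin
(y, then x), making merging invariant to tile enumeration order. Scores
are carried through but never used for ranking; an optional score
threshold can be applied before merging (off by default).

Structures larger than half a tile can never be interior-contained; they
are still reduced to a single box by the max-intersection rule, but their
localization is less reliable. This is a known limitation inherited from
the tiling strategy.

## Evaluation metrics

Evaluation is class-stratified and point-in-box based (no IoU matching):
a ground-truth box containing at least one same-class detected point is a
true positive, one containing none a false negative, and a point inside
no same-class box a false positive. When the ground truth consists of
points and the detections of boxes, the same containment test is applied
with the roles reversed, which exchanges the meaning of precision and
recall but leaves F1 unchanged — the two modes are verified against each
other in the test suite. The matching is deliberately not one-to-one: one
point inside two overlapping same-class boxes makes both true positives,
which is the literal reading of the definitions; overlapping ground-truth
boxes are rare in practice. Summary performance is the arithmetic mean of
the two class rows, computed from *unrounded* class metrics; rounding
before averaging changes the third decimal.

Zero-count conventions: with $TP = 0$ and any error present, precision,
recall and F1 are all 0; with all counts zero the row is flagged
undefined rather than given an arbitrary value.

## Tissue mask

The mask is computed on the RGB image at working resolution: luminance
conversion ($Y = 0.299R + 0.587G + 0.114B$), Otsu's threshold on the
256-bin histogram with tissue taken as the *dark* side of the split
(bright-field background is near-white), then physical-area filtering:
foreground components smaller than 0.785&nbsp;mm² (the area of a circle of
1&nbsp;mm diameter) are removed, and enclosed empty spaces are filled only
if they are at most 0.00785&nbsp;mm² — larger enclosed spaces, e.g. between
two tissue segments, remain background. Finally the edges are smoothed by
a median blur (kernel 11&nbsp;px by default) and a morphological opening
(disk radius 5&nbsp;px). Kernel sizes are configurable; the defaults are
chosen for a working resolution around 1–4&nbsp;µm/px, where they span
roughly one cell diameter. Connected components use 4-connectivity for
both foreground and holes (the labelling provided by EBImage); at these
scales the masked objects are compact blobs and the choice of
connectivity does not measurably change the result.

## Portality, watershed, zones

The relative position of a pixel along the CV→PF axis is its *portality*

$$p(x) \;=\; \frac{d_{CV}(x)}{d_{CV}(x) + d_{PF}(x)},$$

with Euclidean distances to the nearest CV and PF point; $p$ is 0 at CVs
and 1 at PFs. This parameter-free form is the natural reading of
"relative distance to the closest PF in the CV–PF direction"; seed points
are rasterized to the pixel containing them and distances are taken
between pixel centers (via a Euclidean distance transform), so the field
hits 0 and 1 exactly at the seed pixels. Isotropic pixels are assumed.

Lobuli are the catchment basins of the preflooded watershed transform of
$p$. The implementation floods from the CV seed pixels by ascending
portality with a deterministic priority queue (ties broken by insertion
order, 8-connectivity), so every basin contains its CV and the
tessellation covers the whole extent. Preflooding with depth $h$ merges
two basins whose floods meet below level $h$: since CV minima sit at
$p = 0$, two CVs separated by a saddle shallower than $h$ become one
lobulus. The default $h = 0.05$ suppresses pixelation artifacts without
merging true lobuli in the synthetic tests; it is configurable, and
$h = 0$ gives exactly one basin per CV.

Zones quantize portality into `n_zones = 12` ranges of width $1/12$:
$z(x) = \min(\lfloor p(x) \cdot 12\rfloor + 1, 12)$, zone 1 pericentral,
zone 12 periportal. Masking the background leaves each masked basin as a
*computed lobulus*; lobulus labels are renumbered densely and both label
images are 0 outside the mask, so lobulus areas (pixel counts times the
pixel area) sum exactly to the mask area.

Because lobuli and zones are derived from *points*, the first and last
zones largely coincide with intravascular lumina, where most stains are
near zero; zone profiles are therefore best read over zones 2–11. Using
segmented vessel contours instead of points would remove this artifact
but is outside the package's scope.

## Lobulus size metrics

Lobulus radii are approximated as half the distance from each CV point to
its nearest CV neighbor, acinus radii likewise from the PF points
(reported in µm via the resolution metadata); lobulus areas come from the
label-image pixel counts. `rms_relative_difference()` summarizes paired
samples as the root-mean-square difference divided by the pooled mean,
the statistic used to compare sizes derived from manual versus detected
points. Nearest-neighbor search is brute force, which is exact and fast
at the point counts of interest (hundreds per slide).

## Stain signal and zonated quantification

RGB values are converted to optical density per channel,
$OD_c = -\log_{10}((I_c + \varepsilon)/I_0)$ with $I_0 = 255$ and
$\varepsilon = 1$ to avoid $\log 0$ (base and offset are package choices;
intensities are uncalibrated throughout, so only relative comparisons are
meaningful). The two principal stain vectors are estimated by the Macenko
procedure — discard background pixels with all-channel OD below
$\beta = 0.15$, project the OD cloud on its top-2 singular plane, and take
the directions at the 1st/99th percentiles of the angular distribution —
or supplied manually for stains where automatic estimation is unreliable.
Vectors are ordered hematoxylin-like first (largest blue OD component).
Per-pixel concentrations are the least-squares coordinates on the two
vectors with negative values clipped to zero. The zonated profile is the
mean concentration per (lobulus, zone) with pixel counts, and the
per-zone summary aggregates one value per lobulus per zone.

The accuracy of Macenko estimation depends on near-pure pixels of both
stains being present; on phantoms whose two stains fade in opposite
directions the vectors are recovered to a few degrees, with the residual
dominated by the percentile margin, not noise.

## The synthetic phantom generator

`generate_layout()` models the lobular architecture as a hexagonal
lattice: CVs on a triangular lattice with spacing $\sqrt{3}R$, PFs on the
dual honeycomb vertices, so each PF is equidistant (distance $R$) from
its three surrounding CVs, with optional Gaussian jitter. Default
$R = 300$&nbsp;µm (a lobule radius of a few hundred µm), rendered at
4&nbsp;µm/px — a 6×6&nbsp;mm field is a 1500² image with roughly 100
lobuli. `render_hne_phantom()` draws pink tissue on a white background
with white vessel lumens (CV lumen radius 30&nbsp;µm; PFs as a compound of
a portal lumen and two duct blobs, ~40&nbsp;µm overall) plus seeded
Gaussian texture, and emits tight ground-truth boxes and the true tissue
raster. `render_stain_phantom()` builds an OD image
$f(p)\,v_1 + b(p)\,v_2 + \text{noise}$ from a designed zonation profile
$f$ and converts it to RGB, so the designed profile is exactly known.

What the phantoms do *not* emulate: cellular texture, nuclei, staining
variability between slides, folds, pen marks and other artifacts,
anisotropy, or out-of-distribution pathology such as steatosis. Passing
the closed-loop tests therefore demonstrates the correctness of the
geometry, merging, masking, tessellation and quantification machinery —
not the performance of any particular trained detector on real tissue,
which must be established on annotated slides.

## Numerical and reproducibility choices

* Coordinates are 0-based with half-open boxes $[x_{min}, x_{max})$;
  pixel $(i_x, i_y)$ covers $[i_x, i_x+1) \times [i_y, i_y+1)$.
* Downsampling is block averaging with round-half-up to 8-bit; grayscale
  conversion rounds half-even.
* Otsu's threshold maximizes between-class variance over all 256
  candidates; ties take the smallest threshold.
* All stochastic components (balanced sampling, the oracle backend,
  phantom noise, layout jitter) are seeded; the oracle backend derives a
  per-tile stream from the global seed and the tile origin, so results
  are independent of tile processing order. Structure misses are decided
  per structure, not per tile — otherwise a structure seen by up to four
  tiles would almost never be missed and the configured miss rate would
  not be interpretable.
* The test suite and the acceptance script use phantoms between 512² and
  1500² pixels (2–6&nbsp;mm fields at 4&nbsp;µm/px), sizes at which every
  stage runs in seconds while containing dozens of lobuli.

## Known limitations

* The detector seam ships only the synthetic oracle; integrating a real
  CNN requires wrapping its inference as a backend function.
* Point-based lobuli inherit the first/last-zone intravascular artifact
  discussed above.
* The evaluation's non-one-to-one matching can overcount true positives
  when same-class ground-truth boxes overlap.
* Stain intensities are uncalibrated and not comparable across slides
  without external normalization.
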