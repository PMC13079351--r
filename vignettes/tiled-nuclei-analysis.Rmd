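---
title: "Tiled detection, fusion and morphometry of nuclei deposits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tiled detection, fusion and morphometry of nuclei deposits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Membrane lungs (MemL) used in extracorporeal membrane oxygenation (ECMO)
accumulate cell deposits on their hollow-fiber mats. A standard way to
quantify that burden is fluorescence microscopy of DAPI-stained fibers:
each deposit nucleus appears as a bright blob on a darker fiber background,
and the clinically interesting quantities are *how many* nuclei there are,
*how much area* they cover, and *how they aggregate* into clusters.

Manual counting does not scale (a single 40x field holds on the order of a
hundred nuclei, counts vary between human raters) and classical
single-threshold segmentation fails on exactly the nuclei that matter:
overlapping ones, u-shaped ones, and dim low-DNA-density ones. The
practical pipeline is therefore: a *detector* produces instance masks per
image tile, and a deterministic post-processing chain turns those per-tile
detections into per-image biology. This package implements that chain —
everything around the detector — plus the evaluation statistics used to
validate it, with the detector itself behind a pluggable backend contract.

## The processing chain

For a full-scale image (typically 2,048 x 2,048 px, 16-bit, single channel
or the blue channel of an RGB export):

1. **Tiling** (`tile_grid()`, `slice_image()`). Square tiles of
   `tile_size = 400` px with `overlap_fraction = 0.2` (80 px). Starts
   advance by `stride = round(tile_size * (1 - overlap))`; when a window
   would cross the border, one final window is emitted flush with the
   border and the axis stops. Tiles are always full-size and inside the
   image. A 2,048-px axis gives starts 0, 320, ..., 1600, 1648: 7 per
   axis, 49 tiles per image — hence 8,330 tiles for 170 images and 2,107
   for 43, the bookkeeping the whole dataset arithmetic rests on.
   The 80-px overlap exceeds a nucleus diameter, so every nucleus lies
   wholly inside at least one tile.

2. **Detection** (backend contract, `register_backend()`). Any function
   mapping a tile image to scored instance masks plugs in. The package
   ships `"toy-threshold"` (Otsu threshold, connected components, minimum
   area 30 px^2), which is *not* a segmentation model — it exists so the
   chain is exercisable and testable without trained weights.

3. **Fusion** (`reconstruct_predictions()`). Per tile: detections scoring
   below the backend's confidence threshold are discarded (a score exactly
   at the threshold survives: "below" is dropped), then greedy
   non-maximum suppression on box IoU (> 0.5 suppresses). Survivors are
   shifted to the global frame and fused across tiles by non-maximum
   merging (NMM): walk detections by descending score; the current
   survivor absorbs every remaining detection whose mask *intersection
   over smaller area* (IoS) reaches 0.5; the merged mask is the union, the
   score the max, and the grown survivor is re-tested until stable so
   chains of fragments collapse. NMM is idempotent, never increases the
   count, and conserves union area.

4. **Clustering and morphometry** (`analyze_detections()`). Two nuclei are
   connected when they share a relevant mask overlap (IoS > 2%) **or**
   their centroids are closer than an adaptive threshold
   `T = alpha * (r_i + r_j) / (1 + beta * rho)` (radii `r` =
   area-equivalent-circle radii, `rho` = the pair's mean local density).
   Connected components of size >= 2 are clusters numbered 1, 2, ... by
   their topmost-then-leftmost member; isolated nuclei keep the reserved
   cluster id 0. Each nucleus gets area, centroid, perimeter,
   eccentricity, mean intensity, local density and nearest-neighbour
   distance; clusters and images get count/area aggregates with union
   areas (overlapping pixels counted once).

```{r example}
library(fibernuclei)
sc <- synthesize_scene(scene_spec(width = 1024, height = 1024,
                                  n_nuclei = 40, seed = 1))
cfg <- pipeline_config(out_dir = tempfile())
res <- run_pipeline(list(scene = sc$image), cfg)
glance(res)       # per-image summary
res$nuclei        # one row per nucleus
res$clusters      # one row per cluster
```

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `tile_size` | 400 | px | the tiling geometry the dataset arithmetic assumes |
| `overlap_fraction` | 0.2 | — | 80 px; larger than one nucleus diameter, so border nuclei are seen whole by some tile |
| `min_visible_fraction` | 0.1 | — | a clipped instance with < 10% of its area in a tile carries no usable context and is dropped from that tile's annotations |
| `score_threshold` | 0.98 / per backend | — | operating point of a trained network; each backend carries its own calibrated default (the reference thresholding detector: 0.5) |
| `nms_iou_threshold` | 0.5 | — | class-agnostic greedy NMS on boxes within a tile |
| `nmm_ios_threshold` | 0.5 | — | merge criterion across tiles, on masks |
| `overlap_threshold` | 0.02 | — | the "relevant mask overlap" of the cluster rule |
| `alpha`, `beta` | 1.2, 0.05 | —, per neighbour | see below |
| `vicinity_radius` | 100 | px | local-density neighbourhood, about five typical nucleus diameters at 40x |

Three structural choices deserve explanation:

* **IoS denominator.** "Mask overlap" needs a denominator; this package
  uses the *smaller* mask throughout, for both the 0.5 merge criterion and
  the 2% cluster criterion. It is the only overlap normalisation that
  makes a fragment wholly contained in a larger detection always merge
  (IoS = 1 regardless of size ratio), which is exactly the cross-tile
  duplicate case. The threshold is configurable.

* **The adaptive distance formula.** The clustering rule needs a
  centre-distance threshold that grows with nucleus size and shrinks with
  crowding. The form `T = alpha (r_i + r_j) / (1 + beta rho)` is this
  package's construction: at `alpha = 1.2`, `beta = 0.05`, two touching
  average nuclei (r about 10 px) link (`T = 24` px at `rho = 0`), while in
  a field where each nucleus has 20 neighbours within 100 px the threshold
  halves, so incidental proximity in dense fields is not over-linked. The
  density entering `T` is the *pair mean* of the two local densities.
  All three knobs are exposed in `pipeline_config()`.

* **Union areas.** Every "area covered" aggregate — per cluster, per
  image, per tile — is the union of masks, counting overlapping pixels
  once. Summing member areas would double-count precisely in the clusters
  the analysis is about.

## Numerical conventions

* Coordinates are 0-based, half-open, `x` = column, `y` = row, origin
  top-left (the COCO convention); boxes are `[x0, x1) x [y0, y1)`.
  Pixel `(x, y)` has its centre at `(x + 0.5, y + 0.5)`.
* Area is the raw mask pixel count, so counts are integers and every
  overlap measure is oracle-checkable by per-pixel counting.
* Polygon export traces the mask boundary *along pixel edges* (vertices on
  the integer corner lattice, collinear vertices pruned): an axis-aligned
  rectangle exports as its 4 corners and re-rasterization reproduces the
  mask exactly for simply-connected shapes. Interior holes are filled
  before export — real nuclei masks are effectively simply connected, and
  COCO consumers rarely honour hole semantics anyway. A component pinched
  at a diagonal corner exports one polygon per 4-connected part.
* Perimeter is the length of the marching-squares 0.5-level contour of the
  mask (sub-pixel). On a binary raster this contour runs slightly outside
  the ideal smooth outline: a disk of r = 20 measures a few percent above
  `2 pi r`. A pixel-edge-count perimeter is available as an option.
* Eccentricity comes from the second central moments of the pixel
  coordinates: with eigenvalues `l1 >= l2` of their covariance,
  `e = sqrt(1 - l2/l1)`; 0 is circular, values near 1 elongated. On
  rasterized ellipses with semi-axes >= 8 px this tracks the analytic
  value within 0.02.
* 16-bit images are converted to 8 bits by the fixed linear map
  `v8 = round(v16 / 257)` (half-up), identical for every image so
  intensities stay comparable across a dataset; per-image min–max
  stretching is available but deliberately not the default.
* The Mann-Whitney U test uses average ranks under ties; for samples of at
  most 10 each the two-sided p-value is computed by exact enumeration of
  all pooled assignments (valid under ties), otherwise by the normal
  approximation with tie and continuity correction. Average precision is
  the COCO-style evaluator: score-sorted greedy matching at IoU >= 0.5
  (boxes or masks) and 101-point interpolated precision, reported on a
  0–100 scale.
* Degenerate inputs: empty masks, zero-area polygons, self-intersecting
  polygons, annotations referencing missing images, and RLE-only
  segmentations all raise explicit errors naming the offending object.

## The synthetic scene generator

`synthesize_scene()` renders DAPI-like fields with exact ground truth:
filled rotated ellipses (u-shapes as crescents, an ellipse minus a shifted
copy — the shape that splits naive detectors), nucleus radii 8–20 px,
intensities spanning dim to bright (90–240 on the 8-bit scale, emulating
low versus high DNA density), a configurable fraction of nuclei placed in
overlapping chains (centre distance 0.8x the radius sum, so masks
genuinely overlap), constant background (20) with Gaussian noise and blur,
and an optional halo ring. Ground truth is recorded pre-blur; every
rendered nucleus has exactly one annotation, and the scene is a pure
function of its spec (same seed, bytewise-identical output).

What the generator does *not* emulate: real PSF optics and
depth-of-focus compositing, fiber geometry and contact points,
autofluorescence texture, staining variability within a nucleus, or
camera noise models. Tests passing on synthetic scenes therefore validate
the *deterministic pipeline arithmetic* — tiling, fusion, clustering,
measurement, evaluation — not detector quality on real tissue.

One interaction is worth stating precisely. The end-to-end recovery
property (slice, detect with the reference detector, fuse, analyze
recovers the ground-truth count exactly on noise-free, non-touching
scenes) conditions its scenes on the *bright* intensity band (150–240).
That is deliberate: a global Otsu split inside a tile that contains both
dim and bright nuclei lands above the dim ones, and a threshold detector
then misses them entirely — the very low-DNA-density failure mode that
motivates trained detectors. The recovery property is about the plumbing
around the detector, so its scenes must lie within the reference
detector's operating range; the generator's own defaults keep the full
dim-to-bright range.

## Problem sizes

The shipped test-suite and acceptance script run at sizes chosen to keep
the whole suite fast while still exercising every code path across tile
borders: scenes of 400–1,024 px with 5–50 nuclei, grids of 9–49 tiles,
oracle comparisons on rasters up to 64 x 64 px, enumeration tests at
sample sizes up to 7, and AP cross-checks on sets of up to 10 instances.
The tile-total bookkeeping (8,330 / 2,107) is computed on the real
full-scale geometry, 2,048 x 2,048 at tile 400 / overlap 0.2, which is
instant.

## Known limitations

* The detector backends that made the original pipeline accurate (trained
  Mask R-CNN variants) are out of scope; the reference detector is a
  plumbing exerciser with the sensitivity limits of global thresholding.
* Polygon export ignores interior holes by design.
* The adaptive-distance formula is this package's construction; only its
  inputs (radii, local density) are fixed by the method it implements.
  Conclusions that depend on fine cluster granularity should report
  `alpha`/`beta`.
* Per-tile evaluation pools tiles for the Mann-Whitney comparison
  (two-sided, unpaired); a tile-paired design would need the per-tile
  correspondence to be meaningful for the detector under test.
* Nearest-neighbour distance is centroid-to-centroid, not
  boundary-to-boundary.
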