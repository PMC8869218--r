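---
title: "Few-shot dataset construction for bacterial colony counting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Few-shot dataset construction for bacterial colony counting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonyforge)
```

## The problem

Bacterial colony counting (BCC) from plate photographs is a detection task
with awkward data economics: a single plate can hold hundreds of colonies,
each needing a bounding-box annotation, and a new plate costs a day or two
of culture time. Training an object detector therefore stalls on both data
collection and annotation. colonyforge implements a dataset-construction
strategy for this regime: start from a handful of fully annotated source
photographs and multiply them into a training pool through three
annotation-preserving transforms — random target coverage, quarter-cutting,
and right-angle rotation. With 5 sources and the default schedule the pool
holds `5 * 12 * 4 * 4 = 960` images, split 90/10 into 864 training and 96
validation items.

The package also ships the two classical baseline counters (threshold
segmentation without and with an area filter), the counting metrics used to
compare counters, and a synthetic plate generator with exact ground truth
so that the entire pipeline is testable without any real photographs.

## Random target coverage

The augmentation core operates on the observation that colony plates
photographed in a dark enclosure have a near-uniform, near-black background
(gray values below about 20). An annotated colony can therefore be *erased*
— overwritten with a disc of the local background colour — and the result
is a structurally new image whose annotation file is the source's minus the
erased boxes. No re-annotation is needed.

One augmentation call proceeds as follows.

1. **Segment.** Convert to grayscale (luma weights 0.299/0.587/0.114) and
   binarize at a threshold `tau` (default 40): above `tau` is a candidate
   target. Label 8-connected components and describe each by the minimum
   enclosing circle of its pixels plus its pixel area.
2. **Filter.** Keep candidates whose area lies strictly inside the
   effective band `(60, 3500)` px² — smaller is noise, larger is a fused
   clump or the dish rim — and whose center lies in the central rectangle
   excluding a 10% margin per side, so that partial rim arcs and
   edge-touching blobs are never erased.
3. **Cover.** Draw a seeded uniform permutation of the eligible set and
   cover its first `min(k, n_eligible)` members, one at a time. Each
   cover's colour is the per-channel mean of the background pixels (gray
   `< 20`) in the 20 × 20 px window anchored at the target center and
   extending to its bottom-right, computed on the image as already modified
   by the previous covers. The covering primitive paints the enclosing
   circle, so the whole component drops below `tau` and disappears from any
   re-segmentation.
4. **Prune.** Remove every annotation box whose center lies inside a
   covered disc; all other boxes and all pixels outside the covered discs
   are passed through bit-identically.

Because selection is a prefix of one fixed permutation, runs with the same
seed and increasing `k` erase nested sets of targets: the iteration count
is a monotone "how much structure to remove" dial.

Several points in this procedure are deliberate design choices rather than
forced moves, and are worth stating explicitly:

* **The sampling window sits to the bottom-right of the target center**, so
  it typically overlaps the colony being covered. The gray-`< 20` mask is
  what makes the estimate correct anyway: colony pixels fail the mask and
  are excluded. We keep the anchored window because it is the formulation
  the cover-colour formulas define, and the masked mean over any nearby
  window is equivalent under the uniform-background assumption.
* **Large colonies can swallow the whole window** (radius beyond ~28 px
  leaves no background pixel in a 20 px window). The window mean is then
  undefined (`N = 0`); rather than failing mid-pipeline, the cover colour
  falls back to the global mean over all background pixels of the image and
  the result is flagged (`fallback = TRUE`). Within one augmentation call
  the global fallback colour is computed at most once, on the image as of
  its first use; covers only ever repaint discs with background-band
  colours, so later recomputation would change the estimate by far less
  than the 8-bit rounding of the painted colour.
* **Strict area bounds.** The effective range `(60, 3500)` is read as an
  open interval: areas of exactly 60 or 3500 px² are excluded. The same
  strict convention is used by the comprehensive threshold counter.
* **Box pruning is automated** by the center-in-covered-disc rule. Manual
  removal of redundant boxes is the natural workflow with a GUI annotator;
  a programmatic pipeline needs an unambiguous rule, and a box whose center
  is inside an erased disc no longer has an object under it.
* **Segmentation happens once per call.** Re-segmenting after each cover
  would let previously split components merge or vanish mid-run and make
  the iteration semantics path-dependent; covering from one fixed candidate
  list keeps `k` interpretable and the prefix property exact.

## Cutting and rotating

Colonies are small relative to a full plate photograph, which hurts
detectors biased against tiny objects. Cutting the image into `D` equal
parts leaves a colony's absolute size unchanged while the image width
shrinks by `sqrt(D)`, so the colony's *relative* linear size grows by
`sqrt(D)` (for the default `D = 4`: doubled; `relative_scale()` exposes
both the linear and the area factor). `quarter_cut()` produces the four
quadrants in reading order and clips annotations: a box intersecting a cut
line is kept in a quadrant only if at least 30% (configurable) of its area
survives there — a sliver of a colony is not a learnable example of one.

Rotations by 90/180/270 degrees are implemented by axis transposition and
flips, so they are lossless: the pixel multiset is exactly preserved. Box
corners are mapped with the center-anchored transform

```
xR =  cos(t) (xo - w/2) + sin(t) (yo - h/2) + W/2
yR = -sin(t) (xo - w/2) + cos(t) (yo - h/2) + H/2
```

with `(W, H) = (h, w)` for 90/270. The sign convention is pinned by a
pixel-level test: rotating a one-hot mask with `rotate_image()` must land
the pixel exactly where the transformed box says. (Quoted forms of this
transform sometimes carry a sign slip in the `y` row that maps the image
center off-center for 90/270; the form above is the self-consistent one.)

## The dataset pipeline

`build_augmented_pool()` composes the stages: per source, the original plus
`variants_per_source - 1` cover-variants at `k = 1, 2, ...` (so the amount
of erased structure grows across variants); each variant quarter-cut; each
quadrant kept at rotation 0 plus the three rotations. The pool size is
always `sources x variants x 4 x 4`. Items carry annotations, dimensions
and a provenance tuple; rasters are computed for every item but retained or
written only on request, since a 960-item pool of full-resolution plates
would not fit in memory as R arrays. `split_dataset()` shuffles with a
seed and takes the first `round(0.9 n)` items for training. Note that the
split operates at the augmented-image level (that is what the construction
recipe prescribes); all 16 descendants of one source share content, so
validation loss on such a split measures fit to the sources, not
generalization to new plates.

`read_yolo_labels()` / `write_yolo_labels()` implement the darknet label
format (`class cx cy w h`, normalized). Six decimals of normalized
precision bound the round-trip error at `1e-6 * image_size / 2` — well
under half a pixel at any realistic resolution. `export_darknet()` writes
the `images/`, `labels/`, `train.txt`, `valid.txt`, `colony.names` layout
that darknet-style trainers consume.

## Baseline counters and metrics

`simple_threshold_count()` is deliberately naive: binarize, label
8-connected components, one detection each. `comprehensive_threshold_count()`
adds the strict area-band filter. Neither attempts declumping, so fused
colony pairs count once (or zero times, if the fused area exceeds the
band) — the characteristic failure that motivates learned counters.

Counting quality is scored from one-to-one matches between detections and
truth boxes. The matching rule is configurable (`match_detections()`):
greedy descending-IoU at a 0.5 threshold by default, or center-in-box for
centroid-only counters. With `TN = 0` (background is not an enumerable
negative class on a plate),

```
ACC = TP / (TP + FP + FN),  TPR = TP / (TP + FN),  FNR = FN / (TP + FN)
```

so `TPR + FNR = 1` exactly and `ACC <= TPR` with equality only at `FP = 0`.
These formulas are applied as printed in the benchmark they come from; two
cells of that benchmark's table (the simple-threshold TPR of 73.8% and the
tiny-network ACC of 85.9%) disagree with the values their own TP/FP/FN
imply (73.6%, 86.0%) — presumably transcription slips — and the package's
tests assert only the self-consistent cells.

`colony_size_stats()` reduces boxes to width/height/area and a histogram
over user-supplied half-open area bins; values outside the bins are
reported as `n_below`/`n_above` rather than silently clamped.

## The synthetic plate generator

The generator emulates the imaging regime the pipeline assumes, not plate
photography in general:

* **Background**: clamped Gaussian gray noise (mean 12, sd 3, clamped to
  `[0, 17]`), plus independent per-channel jitter in `[-2, 2]` — every
  background channel stays strictly below the gray-20 ceiling, matching
  dark-enclosure photography with no reflections.
* **Colonies**: integer-radius discs (default 6–32 px), flat at a peak
  sampled in `[90, 160]` out to 80% of the radius, then a cosine falloff to
  background at the radius — soft low-contrast edges. The default radius
  range keeps above-threshold colony areas inside the effective `(60, 3500)`
  band. Ground-truth boxes are the exact disc bounding boxes.
* **Adherence**: an `overlap_fraction` of colonies is placed as pairs at
  55–90% of their radius-sum, so they fuse into one segmented component;
  everything else keeps 3 px clearance.
* **Rim**: optionally a 4 px bright ring at 98% of the inscribed radius,
  exercising the border-exclusion rule (the rim segments as a huge
  component that the area band and margin filter must reject).

Determinism is strict: a `plate_spec` (including its seed) fully determines
layout and raster, and generation never perturbs the caller's RNG state.

What the generator does *not* model: agar texture, lighting gradients, lens
distortion, colony colour and morphology diversity, condensation, writing
on the dish. Tests passing on synthetic plates therefore certify the
*bookkeeping* — segmentation, coverage, annotation propagation, geometry,
metrics — not detection difficulty on real photographs. In particular the
headline accuracies reported for trained detectors on real plates are
properties of a trained network plus real data, and are touched here only
as metric arithmetic on their published confusion counts.

## Problem sizes and numerics

The test suite exercises the full-scale pipeline once — five 2560 × 2590
synthetic sources with 250 colonies each (a density inside the standard
30–300 countable-plate band, toward the dense end typical of the plates
this pipeline targets), twelve variants, 960 items —
and otherwise works on plates of a few hundred pixels, which keeps the
whole suite within a few minutes while covering every code path at full
scale at least once. Other numerical choices worth recording:

* Connected components use 8-connectivity (the blob-counting standard).
* The minimum enclosing circle is computed exactly on the convex hull of
  component pixels (deterministic incremental algorithm); the radius is
  floored at 0.5 px so single-pixel components get a positive radius.
* Greedy IoU matching ties are broken by prediction index then truth
  index, making evaluation deterministic. Greedy matching can differ from
  the optimal assignment in adversarial IoU patterns; on random small
  instances the tests compare it against exhaustive enumeration.
* Covers are painted with the colour rounded to 8-bit; all raster
  arithmetic is integer in `0:255`.
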