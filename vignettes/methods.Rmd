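---
title: "Reconstructing sparsely sampled histology stacks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing sparsely sampled histology stacks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(histostack)
```

## The problem

Whole-mount histology sections are cut from an organ at intervals that, in
clinical practice, are often 3000–4000 µm — far sparser than the ~5 µm
serial sectioning most registration methods assume. At such intervals,
adjacent sections no longer share fine structures (small glands, nuclei,
tumour outlines): a structure thinner than the slice interval appears on at
most one slide. What adjacent sections *do* share is coarse anatomy — the
organ outline, large nodules, zonal architecture. `histostack` therefore
registers a stack of section images into a common 3-D frame using coarse,
patch-grid ("global") features rather than local keypoints, with a strictly
rigid per-slide transform, and propagates the result to any resolution
level.

The pipeline runs in a fixed order:

1. **Preprocess** — tissue mask per slide (Otsu threshold on luminance,
   morphological cleanup), stain normalization to a stack-median color
   space, resampling to one common processing resolution, padding to a
   common square frame. RGB is preserved throughout; no grayscale
   conversion.
2. **Initialize** — fit a moment-equivalent enclosing ellipse to each
   tissue mask; map every slide's ellipse center and orientation
   (modulo 180°) onto those of the reference slide (the middle of the
   stack).
3. **Resolve flips** — the ellipse is symmetric, so a 180° ambiguity
   remains. Working outward from the reference, each slide is kept in
   whichever of its two poses has the higher cosine similarity of global
   feature maps with its already-resolved neighbor.
4. **Refine** — for each slide outward from the reference, dense feature
   matches against the already-aligned neighbor feed a RANSAC rigid
   estimation; the consensus-refined rotation and translation are composed
   onto the slide's pose. Scale and shear are deliberately not estimable:
   true size differences between adjacent sections are anatomy, not error.
5. **Optional deformable refinement** — a thin-plate-spline field per
   slide, off by default, intended for densely sampled stacks only.
6. **Propagate** — all transforms are parameterized so they scale linearly
   with resolution; tile-decomposable backward maps apply them to images
   of any size with bounded memory.

## Quality metrics

Three complementary quantities grade a reconstruction of `k` slides:

* **Orientation accuracy.** Per slide, the signed angular deviation from
  the annotated (or planted) rotation, measured relative to the reference
  slide and wrapped to (−180°, 180°]. A case counts as accurate when every
  slide deviates by at most 15°. The threshold reflects both what a
  visually smooth reconstruction needs and the uncertainty of manual
  orientation annotation.
* **Overlap.** For each adjacent pair, `|A ∩ B| / min(|A|, |B|)` of the
  registered tissue masks, averaged over the `k − 1` pairs. The smaller
  mask is the denominator because genuine size differences between
  adjacent sections must not be penalized.
* **Target registration error (TRE).** For each adjacent pair, the median
  Euclidean distance over matched point pairs; the TRE is the mean of the
  per-pair medians, reported in pixels and mm. With landmarks (the
  phantom's fiducial rods) this is exact; without landmarks the same
  formula is evaluated over RANSAC-inlier dense matches of the registered
  stack — the *estimated* TRE, which needs no ground truth and also grades
  externally registered stacks (`evaluate_stack()` never modifies poses).

## Feature backends

The registration consumes two capabilities behind a pluggable backend
interface: a whole-image patch-grid descriptor (`global_descriptor`) and
dense correspondence proposal (`dense_match`).

The **classical** backend is the deterministic, weight-free default. The
image is divided into `g × g` cells of `patch × patch` pixels
(`g = floor(side / patch)`; with the contract defaults `side = 1036`,
`patch = 14`, the grid is 74 × 74). Each cell is summarized by 12 numbers:
mean RGB absorbance (1 − mean intensity, 3), luminance standard deviation
(1), and an 8-bin signed gradient-orientation histogram (8). Cells of blank
background get the zero vector so that comparisons are driven by tissue.

Two deliberate choices here:

* Cell descriptors are **not** normalized per cell for the flip test. The
  signal that distinguishes a slide from its 180° rotation is *where the
  strongly stained structures sit*; per-cell normalization erases exactly
  that intensity contrast (pink stroma and purple nodules are nearly
  parallel unit vectors), and the luminance gradient field of a roughly
  convex tissue section is radial, hence itself largely 180°-invariant.
  Intensity-weighted flattened cosines discriminate reliably; normalized
  ones do not. Dense matching normalizes descriptors at comparison time
  instead, where only the direction should matter.
* Alignment uses the coarse cell matches as-is (`refine = FALSE`); the
  estimated TRE refines each matched pair to sub-pixel precision by a
  local block-SSD search with parabolic interpolation (`refine = TRUE`).
  The coarse matches carry the robust global signal; local refinement on
  sparsely sampled pairs can lock onto decorrelated fine structure, which
  is acceptable noise in an error *estimate* but harmful inside the
  *alignment* loop.

The **oracle** backend is first-class test instrumentation: built from a
phantom's ground-truth record, it emits planted true correspondences
(optionally noised, plus a configurable fraction of planted outliers)
mapped through the current slide poses. It lets every pipeline stage be
tested against exact expectations.

The **pretrained** slot is the contract for externally supplied neural
feature extractors and dense matchers (vision-transformer global features,
CNN fine features). No weights ship with the package and nothing else
depends on this backend; any list providing `global` and `match` functions
with the same signatures plugs in.

## Rigid estimation

`estimate_rigid()` is RANSAC over minimal 2-point samples. Each sample
gives a closed-form candidate (rotation from the angle between paired
difference vectors, translation from pair midpoints); matches with residual
below the threshold form the consensus; the best consensus is re-fitted by
closed-form least squares — rotation from the SVD of the centered
cross-covariance with the reflection branch excluded, translation from
centroids — and inlier flags are recomputed under the refined fit. Every
returned transform satisfies the rigidity invariant (both singular values
of the linear part equal 1 within 1e-9).

Defaults: threshold 3 px at processing resolution, 1000 iterations, seeded
deterministically from the single pipeline seed. Inside the stack-alignment
loop a rotation cap of 30° is additionally applied to candidates: the
global initialization has already fixed each slide's orientation to within
a few degrees, so a large pairwise rotation at this stage can only be a
spurious consensus.

## Transform application

All transforms use backward (pull) semantics: for every output pixel, the
source coordinate is computed as the inverse rigid map of the output
coordinate, plus the thin-plate displacement evaluated at the output
coordinate when a deformable field is present. Because each output pixel
depends only on its own absolute coordinates, the backward map restricted
to a tile equals the global map on that tile: images of any size are warped
tile-by-tile with bounded live pixels, and the tiled result is
bit-identical to a monolithic warp (bilinear interpolation uses one fixed
evaluation order). Bilinear is the default for images, nearest for masks;
out-of-source samples take the configured background color (white, the
glass-slide appearance).

Resolution scaling is exact by construction: rotations are dimensionless
and translations/centers scale linearly (`scale_rigid()`); thin-plate
fields scale their control points and displacements, recomputing spline
weights from the scaled control points only. The bordered-system side
conditions (`Σw = 0`, `Σw·p = 0`) make the interpolant exactly equivariant
under similarity transforms, and the smoothing weight scales as `s²`
(bending energy is scale-invariant in 2-D while squared residuals pick up
`s²`), so a field fitted at processing resolution applies at level 0
without re-fitting to matches. Fields are stored on a Cartesian control
grid; resampling onto the grid is exact for affine residuals and exact at
the grid nodes in general.

Pixel coordinates are 0-based pixel centers, x = column, y = row; the
level-0 frame is canonical and transforms are stored in level-0 pixel
units. Slide output is a multi-page TIFF (one page per factor-2 pyramid
level) with lossless deflate compression and a JSON sidecar carrying the
spacing and level ladder; rasters are quantized to 8 bits on write
(`round(x·255)/255`) so a read-back is bit-exact. The tile-stream writer
validates exact single coverage of the output extent and flushes each
incoming tile immediately, tracking the maximum number of simultaneously
live tiles.

## The synthetic phantom

`generate_phantom()` builds the study object for every test: a 3-D
organ-like volume with known ground truth. Defaults: 256 × 256 × 96 voxels,
40 µm in-plane and 400 µm between sections (whole-mount blocks are
anisotropic: a ~10 mm cross-section over ~38 mm of depth), sliced at
4000 µm into ~10 slides. The components are

* an **organ outline**: a superellipse whose axes taper toward the poles,
  with a slow per-section rotation (0.1°/section) and center drift — so
  adjacent sparse sections share coarse shape but are not identical — and
  an egg-shaped widening of the minor axis toward one end of the major
  axis, so the outline itself has no 180° self-symmetry;
* a planted **off-center nodule** following the organ pose through every
  section — the guaranteed asymmetry that makes flip detection decidable
  (a perfectly symmetric section leaves the 180° pose undecidable in
  principle);
* random **coarse blobs** (σ_z = 8 sections; diameter well above the slice
  interval) that persist across adjacent sparse sections, placed in the
  organ's interior;
* random **fine blobs** (σ_z = 0.8 sections; diameter well below the
  interval) that decorrelate between sparse sections — the sparse-sampling
  premise. The size invariants (coarse diameter > interval > fine
  diameter) are enforced at construction;
* ≥ 2 vertical **fiducial rods** traversing all sections (the synthetic
  analog of laser-induced landmark holes), giving exact landmark TRE.

Sections are rendered on demand in an H&E-like palette (white background,
pink stroma, purple nodules, near-black rods); the full RGB volume is never
materialized. `perturb_stack()` applies independent per-slide rigid
perturbations (rotation uniform in [0°, 360°), translation, optional
planted 180° flips), channel-wise affine stain jitter, and records the
exact transforms and transformed landmarks. Horizontal mirror flips are
never generated: the workflow's precondition is that mirrored slides have
been corrected upstream.

What the phantom does *not* emulate: nuclei-level texture, realistic stain
chemistry and scanner characteristics, tissue deformation (folds, tears,
compression), and genuinely missing slides. Passing tests on phantoms
therefore demonstrate the correctness and internal consistency of the
algorithmic chain under the sparse-sampling geometry — not clinical-grade
performance on real slides, which additionally depends on the feature
backend used.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `target_pixels` | 2000 | px | processing resolution: the common spacing is chosen from the largest slide's pyramid ladder (extended by integer factors) to bring its longer side closest to this; ties go to the coarser spacing. 2000 px balances registration detail against cost. |
| `feature_patch` | 14 | px | token cell side; with a 1036-px input, a 74 × 74 grid. |
| `ransac$threshold` | 3 | px | inlier residual bound at processing resolution. |
| `ransac$iterations` | 1000 | — | sampling budget; deterministic given the seed. |
| `ransac$max_rotation` | 30 | deg | cap on pairwise refinement rotations (see above). |
| `accuracy_threshold` | 15 | deg | per-slide orientation pass bound. |
| `deformable$enabled` | FALSE | — | thin-plate refinement; reserve for dense sampling. |
| `tile_size` | 512 | px | streaming tile side for full-resolution output. |
| `seed` | 1 | — | single run seed, expanded deterministically into per-stage seeds. |

One configuration governs a whole run; all defaults are materialized,
echoed into the run manifest together with per-pair diagnostics (match
count, inlier count, residuals, failure flags) and stage timings, and
unknown keys are rejected.

## Numerical choices and degenerate inputs

* Otsu threshold: computed on the 8-bit luminance histogram by the
  cumulative-moment formulation; ties resolve to the smallest threshold;
  constant images return an all-background mask with a degenerate flag.
  Mask cleanup = closing then opening with a 2-px-radius disc, then
  removal of components below 0.1% of the foreground area.
* Stain statistics live in the decorrelated lαβ space (log-LMS), computed
  over foreground pixels only — background would bias the means; the
  common space is the element-wise median of the per-slide (mean, sd)
  statistics; zero-variance slides pass through flagged.
* Ellipse orientation comes from second-order mask moments; masks with an
  axis ratio below 1.05 are flagged degenerate and fall back to
  centroid-only initialization.
* Flip ties (cosine gain below 1e-6) keep the unflipped pose, so
  point-symmetric inputs resolve deterministically. The 180° rotation is
  applied about the reference content center (the aligned tissue
  centroid), not the geometric frame center — flipping about the frame
  center would translate off-center tissue.
* Flip comparisons render the posed slides at up to 2× downsampling for
  speed, never letting the token grid drop below 8 × 8.
* Pairwise failures (fewer than 3 matches, no consensus) leave the slide
  at its initialization pose and are recorded per pair; the pipeline
  continues.
* Even-`k` stacks take the lower-middle slide as reference
  (`floor((k − 1)/2)`, 0-based).

## Problem sizes in the test suite

The test and acceptance runs use the phantom defaults above (9–10 slides of
256 × 256 px, processed at native resolution) and a smaller 128 × 128 × 48
fixture for unit tests; tile-equivalence is exercised on 512 × 512 images
with tile sizes 64/128/256; the slice-distance experiment holds the stack
at 6 slides from a densely sliced (400 µm) phantom and thins it one-in-`n`
for `n` = 1…5, so only the inter-slide distance varies. These sizes are the
package's chosen desk-scale study conditions: large enough that every
stage runs exactly as it would on clinical stacks, small enough to keep the
whole suite fast.

## Known limitations

* **Error accumulation.** Alignment is iterative and pairwise; a per-pair
  angular error ε can accumulate to ε·(k − 1) at the stack ends. The
  phantom tests make this bound observable; joint multi-slide optimization
  is out of scope.
* **End slides are hardest.** The last slide in each direction has the
  least coarse-anatomy overlap with its neighbor; residual orientation
  errors and the rare flip mistake concentrate there.
* **Symmetric tissue.** Flip resolution is only as decidable as the
  tissue is asymmetric; near-point-symmetric sections tie and stay
  unflipped by convention.
* **Rigid-only by default.** Tissues that deform substantially between
  sectioning and scanning need the deformable stage, whose benefit cannot
  be verified without a ground-truth shape; it is therefore opt-in.
* **The classical backend is a floor, not a ceiling.** It is deterministic
  and dependency-free, sufficient for the phantom geometry; on real stain
  and texture variation, a pretrained feature backend plugged into the
  same contract is expected to be stronger.
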