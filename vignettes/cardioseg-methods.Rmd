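---
title: "cardioseg: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cardioseg: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Ventricular volumes and ejection fraction from short-axis cine MR are the
clinical reference for cardiac function, but tracing endocardial contours by
hand on every slice of an end-diastolic (ED) and end-systolic (ES) stack is
slow and observer-dependent.  `cardioseg` implements a semiautomatic
alternative that reduces user interaction to a single mouse click inside the
ventricular blood pool of one midventricular ED frame, and derives every
other contour deterministically from it.  Because the procedure is a pure
function of the image data and the click, repeated analyses of the same
study give identical measurements — the variability that remains is between
the method and a human observer, not within the method.

## The segmentation pipeline

Images are integer matrices normalized per study to 0–255.  For one frame
and one seed `(row, col)` the pipeline is:

1. **Edge detection.** Gradient magnitude `sqrt(Gx^2 + Gy^2)` with a 3×3
   Sobel (default) or Prewitt operator, reflective borders, min–max
   renormalized to 0–255.  Edges are intensity discontinuities — in
   particular the endocardial border.

2. **Iterative thresholding of the edge image.** A square kernel (default
   9×9) is centred on the click and the classic isodata iteration is run on
   its pixels: starting from `k0` (default 128), split the kernel sample at
   `k` into the class below (`< k`) and at-or-above (`>= k`), and update

   `k1 = round((mean_below + mean_above) / 2)`

   until `k1 == k`.  If one class is empty the update degenerates to the
   rounded mean of all kernel pixels — the limit of the formula as the
   classes merge — and iteration continues from there.  Binary image 1
   takes the *flat* pixels (magnitude `<= k_e`) as object, so edge ridges
   become background barriers.

3. **Iterative thresholding of the gray-scale image.** The same iteration
   on the original frame yields `k_g`; binary image 2 takes bright pixels
   (`>= k_g`, the blood pool under bright-blood cine contrast) as object.

4. **Background overlap.** The backgrounds of the two binaries are OR-ed,
   i.e. the objects are AND-ed: the bright pool, fenced wherever an edge
   ridge runs.  This is what seals the leaks of pure intensity
   thresholding — a bright channel into a neighbouring structure is crossed
   by its own edge ridge and cut there.

5. **Region growing, hole filling.** All object pixels of binary image 3
   inside the kernel window seed an 8-connected flood fill; the component
   containing (or nearest to) the click is kept.  Enclosed background —
   papillary muscles and trabeculae — is then filled, because by convention
   those structures count as part of the cavity volume.

### Numerical conventions that the pipeline forces

Three conventions are not arbitrary; each is the only choice under which
the pipeline works on a clean image:

* **Thresholds are integers, rounded half up.** The state space of the
  isodata iteration is then finite, so it either reaches a fixpoint or
  provably cycles (an error, never observed on random or phantom kernels).

* **`object_below` means `<= k`, not `< k`.** On a noiseless frame the
  kernel sees a flat region of the edge image, `k_e` converges to 0, and
  the flat interior must still be object; with a strict inequality binary
  image 1 would be empty and the pipeline could never segment anything.

* **The empty-class rule iterates rather than returns.** Starting at
  `k0 = 0` every kernel pixel is in the upper class; returning the grand
  mean immediately would make the result depend on `k0`, while iterating
  from the grand mean restores the bimodal fixpoint and with it the
  documented insensitivity to `k0`.

### The gradient-ridge band and boundary reclaim

A 3×3 gradient operator responds on *both* sides of an intensity step: the
last cavity column and the first myocardial column carry the same
magnitude.  Step 4 therefore erodes the grown region by the one-pixel ridge
on the cavity side of the endocardial border — at a 17-pixel cavity radius
that is a ~12% volume deficit, far larger than the rasterization noise.
The ridge band *straddles* the true border: its inner half is blood, its
outer half myocardium.  `segment_frame()` therefore finishes with a bounded
reclaim (`boundary_reclaim = TRUE`, at most `reclaim_passes = 2` sweeps):
ridge pixels at blood intensity (object in binary 2, background in binary
1) that touch the grown region are reassigned to the cavity.  Leak channels
stay sealed — the reclaim only ever enters edge-classified pixels, advances
at most two pixels, and never grows past the far, myocardial half of a
seal.  On the noiseless phantom this recovers the rasterized cavity
exactly; without it the contour would sit one pixel inside the border
everywhere.

A final plausibility guard rejects masks that reach the image border: a
ventricular cavity is interior to the thorax, and a region that runs off
the image is the flooded background of a misplaced click.  This is what
turns a background click into a clean seed error instead of a
quarter-image "ventricle".

### Seed propagation

The user clicks once.  Every other frame is seeded by centroid chaining:
neighbouring slices (outward toward base and apex) take the rounded
centroid of the nearest segmented mask of the same phase, and the ES frame
of each slice takes the centroid of that slice's ED mask.  For non-convex
regions — the right ventricular crescent — the centroid can fall outside
the object and is snapped to the nearest object pixel.  A frame whose
segmentation fails is recorded with its error and skipped; only the
initial seed frame is fatal.  ED/ES phase indices are configuration; when
absent, `select_phases()` picks the phases of maximal and minimal
segmented midventricular area.

## Quantification

Per-slice cavity areas (object pixels × pixel footprint, anisotropic
spacing respected) are summed per phase and multiplied by the effective
slice spacing — Simpson's method:

`V = sum(A_i) * t * (1 + g) / 1000` (mL), `EF = (EDV − ESV) · 100 / EDV`.

The inter-slice gap fraction `g` defaults to 0 because it is absent from
image headers; acquisitions commonly use a 20% gap, so `g = 0.2` is a
one-flag option and every report states the spacing used.  Slices whose
segmentation failed contribute no area (only slices showing blood pool are
contoured), and the most basal contoured slice may differ between ED and
ES by at most one position, reflecting through-plane motion of the base.

## Method agreement

For paired series of EDV, ESV or EF measured by two methods on the same
subjects, `agreement_report()` computes Pearson's r, a two-tailed paired
t-test (sample n−1 standard deviations throughout), and the Bland–Altman
bias with 95% limits of agreement at bias ± 1.96 SD of the differences.
Normality is checked with a one-sample Kolmogorov–Smirnov statistic against
a normal with parameters estimated from the data; since estimation breaks
the classical null distribution, the p-value comes from Monte-Carlo
simulation (10 000 replicates under a fixed internal seed — reproducible,
and cross-checked in the tests against the analytic Lilliefors
approximation).  Biases of at least 10 mL (volumes) or 3 percentage points
(EF) are flagged as clinically relevant, inclusive at the boundary.

## The synthetic phantom

No public cine study accompanies the method, so validation uses a phantom
with known ground truth.  The default configuration emulates a typical
adult short-axis acquisition: 10 slices × 25 phases, 156×192 matrix,
2.083 mm pixels, 6 mm slices; blood/myocardium/background intensities
200/80/30; an LV cavity of radius 17 px at ED tapering to 55% at the apex
(truth EDV ≈ 147 mL), contracting cosinusoidally to 11 px at mid-cycle
(truth EF ≈ 58%); papillary muscles at 30% of the cavity radius; an RV
crescent (outer disk minus the LV epicardial disk) with trabecular
inclusions near its centroid; Gaussian noise of 10 gray levels
(blood-to-noise ratio ≈ 20).  Truth masks are the noiseless rasterized
cavities *including* the dark inclusions, and truth volumes are computed
from those masks through `simpson_volume()` itself, so segmentation
accuracy is never confounded with rasterization error.

The papillary and trabecular inclusions are not decoration: a 9×9 kernel
lying wholly inside a featureless pool has a unimodal sample, and the
isodata threshold then converges to the pool mean, discarding half the
cavity under noise.  Real ventricles provide the dark intracavitary
structure that makes the kernel sample bimodal; the phantom must too, and
the smooth-pool failure mode is exactly what the tests observe when the
inclusions are absent.  An optional `es_apex_dropout` models through-plane
motion: the most apical slices leave the imaging plane around ES and
rasterize as pure background, exercising the missing-frame path.

What the phantom does **not** emulate: coil shading beyond a simple
multiplicative bias field (`perturb_study()`), SSFP banding, flow and
motion artifacts, partial-volume blur at the endocardial border, irregular
cavity shapes, and arrhythmic phase sampling.  Passing the phantom tests
therefore demonstrates the internal correctness and determinism of the
pipeline and its quantification — not clinical accuracy on patient data,
for which the RV in particular is known to be the harder target.

## Problem sizes and runtime

The validation suite segments the full 10×25 default phantom (noiseless
and noisy) in a few seconds; property tests use 1 000 random 9×9 kernels
against an exhaustive 0–255 threshold scan, 500 random 32×32 masks against
a scalar breadth-first flood-fill oracle, and 10 000 simulated measurement
pairs for Bland–Altman calibration.  Unit tests run on 5×8 phantoms at
96×128 to keep the default test run under half a minute.

## Known limitations

* DICOM series are not read directly; studies are supplied as an image
  directory with a YAML sidecar (`load_cine_series()`), e.g. exported by
  any DICOM converter.  Slice ordering is the writer's responsibility.
* The boundary reclaim assumes the gradient ridge is at most two pixels
  wide; heavily blurred borders would be reclaimed only partially (a
  conservative, under-segmenting failure mode).
* Centroid chaining assumes the cavity moves slowly across neighbouring
  slices; gross slice-to-slice displacement can strand a seed.
* Epicardial contours, myocardial mass and regional function are out of
  scope.
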