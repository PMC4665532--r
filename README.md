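# cardioseg

One-click semiautomatic segmentation of the left and right ventricular
blood pools in short-axis cardiac cine MR stacks, with Simpson's-method
volumetry and Bland–Altman method-agreement statistics.

Quantifying cardiac function from cine MR means contouring the endocardium
on every slice of the end-diastolic (ED) and end-systolic (ES) stacks —
tedious by hand and observer-dependent. `cardioseg` reduces user
interaction to a single mouse click inside the blood pool of one
midventricular ED frame. From that click it runs a deterministic pipeline
per frame:

1. **Edge detection** — Sobel/Prewitt gradient magnitude, renormalized to
   0–255;
2. **Iterative (isodata) thresholding of the edge image** on a 9×9 kernel
   around the click: iterate `k1 = round((mean_below + mean_above)/2)` to
   its fixpoint `k_e`; flat pixels (≤ `k_e`) become the object of binary
   image 1, so edge ridges are background barriers;
3. **Iterative thresholding of the gray-scale image** (threshold `k_g`):
   bright blood (≥ `k_g`) is the object of binary image 2;
4. **Background overlap** — OR of the backgrounds (AND of the objects):
   the blood pool, fenced by its edge ridges;
5. **Region growing** — 8-connected flood fill from the kernel's object
   pixels — followed by hole filling, so papillary muscles and trabeculae
   count as cavity.

Seeds for all other frames are chained from mask centroids; the ES phase
can be picked automatically as the phase of minimal midventricular area.
Per-slice areas then give Simpson's-method volumes
`V = Σ areas × slice spacing`, the ejection fraction
`EF = (EDV − ESV)·100/EDV`, and optional BSA-indexed volumes. The
`agreement` module compares two measurement series (e.g. semiautomatic vs
manual) with Pearson's r, a two-tailed paired t-test, a Monte-Carlo
Kolmogorov–Smirnov normality check, and Bland–Altman bias with 95% limits
of agreement (bias ± 1.96 SD), flagging clinically relevant biases
(≥ 10 mL for volumes, ≥ 3 EF percentage points).

Because no public cine study accompanies the method, the package ships a
synthetic cine phantom (`generate_phantom()`) — bright LV disk and RV
crescent with papillary/trabecular inclusions, myocardial ring, cosine
contraction, apical taper, Gaussian noise — whose ground-truth masks and
volumes make the whole chain testable offline.

## Worked example

```r
library(cardioseg)

phantom <- generate_phantom(phantom_config())   # default noisy 10x25 study
phantom$study
#> cine_study: 10 slices (base->apex) x 25 phases, 156 x 192 px
#>   pixel spacing 2.083 x 2.083 mm, slice thickness 6.0 mm, gap fraction 0.00

# one click at the LV centre of a midventricular ED frame
seg <- segment_study(phantom$study, seed_point(78, 115, slice_index = 5),
                     ed_phase = 0, es_phase = 12)
length(seg$results)   # 20 frames: 10 slices x {ED, ES}

vf <- quantify_study(seg, phantom$study)
vf
#> ventricle_function (slice spacing 6.00 mm):
#>   EDV 147.2 mL   ESV 61.6 mL   EF 58.2%
```

The phantom's rasterized ground truth for this configuration is
EDV 147.2 mL, ESV 61.6 mL, EF 58.2% — the one-click segmentation recovers
it exactly, noise included. EDV/ESV are the cavity volumes at maximal and
minimal filling; EF is the ejected percentage per beat (healthy range
roughly 55–70%).

Comparing two measurement series:

```r
set.seed(1)
manual <- rnorm(20, 150, 40)                 # reference EDVs, mL
semi   <- manual + rnorm(20, -4, 9)          # second method, small bias
agreement_report(paired_series(semi, manual, "EDV"), mc_reps = 2000)
#> agreement_report: EDV (mL), n = 20
#>   r = 0.977   paired t = -2.314 (df 19, p = 0.032)
#>   bias -4.06 mL, 95% LoA [-19.43, 11.31]
#>   KS normality p: 0.097 / 0.740   clinically relevant: FALSE
```

The −4 mL bias is statistically detectable (p = 0.032) but below the
10 mL clinical-relevance threshold.

## Command line

A thin wrapper over the same functions (installed under
`inst/cli/cardioseg`):

```sh
cardioseg simulate --config phantom.yaml --out study/
cardioseg segment  --study study/ --click 78,115 --slice 5 --out seg/
cardioseg quantify --masks seg/ --study study/ --out report.json
cardioseg compare  --a semi.csv --b manual.csv --out agreement.json
```

Exit codes: 0 success, 1 usage error, 2 data/processing error. All
reports are JSON (plus CSV contours); masks are 8-bit PNGs.

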