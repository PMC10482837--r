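---
title: "Measuring lower-limb alignment from segmentation masks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring lower-limb alignment from segmentation masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

limbalign measures the sixteen standard frontal-plane alignment parameters
of the lower limb from per-bone binary segmentation masks. This vignette is
the package's own account of the underlying model: the coordinate and angle
conventions, the landmark detectors and their assumptions, the synthetic
phantom that serves as ground truth, the numerical choices, and the known
limitations.

## Coordinate and angle conventions

All raster coordinates are 0-based `(row, col)` with row increasing
downward (superior → inferior on an upright radiograph); boxes are
half-open. Laterality is an explicit flag: *medial/lateral labels derive
from the `side` argument, never from image content*. For a left limb the
lateral structure has the smaller column. Internally every right-side mask
is mirrored to left orientation, processed by one set of left-convention
detectors, and un-mirrored; left/right symmetry of the pipeline is
therefore exact rather than approximate, and the tie-break rules
(extremal-point ties resolve toward the lateral column) need only be
defined once.

Each named joint angle is the angle between two rays at the joint:

* the ray of the **joint orientation line** pointing to the named side
  (e.g. the lateral ray of the femoral condylar line for mLDFA, the medial
  ray of the tibial plateau line for mMPTA), and
* the ray of the **bone axis** pointing into the bone as drawn — proximally
  when the bone is proximal to the joint (femur at the knee, tibia at the
  ankle), distally when it is distal to it (femur at the hip, tibia at the
  knee).

This pair of rules reproduces the standard Paley values: with a straight
limb and a knee joint line ~2.5° oblique, mLDFA ≈ mMPTA ≈ 87.5° and
mTFA ≈ 0°. mJLCA and the tibiofemoral angles are acute angles between two
lines. MAD is the unsigned perpendicular distance from the tibial knee
centre to the hip–ankle line (a signed medial/lateral variant is available
via `compute_report(..., signed_mad = TRUE)`).

Normal ranges are closed intervals: mLPFA 85–95°, mLDFA 85–90°, mMPTA
85–90°, mLDTA 86–92°, MAD 0–3 mm, mJLCA 0–2°, mTFA 0–3°, aMPFA 80–89°,
aLDFA 79–83°, NSA 124–136°, aMPTA 85–90°, aTFA 0–3°; lengths are not
flagged. The published table this list follows prints its aLDFA row twice
and omits aLDTA; we read the duplicate as a misprint for aLDTA and assign
aLDTA the standard range 86–92° (identical to mLDTA — the tibial
anatomical and mechanical axes are nearly coincident, so the two angles are
clinically interchangeable). Note also that a published aTFA range of 0–3°
is internally inconsistent with aLDFA 79–83° + mLDFA 85–90°, which imply a
~6° femoral anatomical–mechanical offset and hence aTFA ≈ 6° in a neutral
limb; flags follow the published table regardless, so a geometrically
normal limb is typically flagged "abnormal" for aTFA. This is a property of
the table, not of the measurement.

## Landmark detectors

**Femoral head** (`head_landmarks`). The head centre/radius are estimated
by the distance-transform maximum (initialisation) followed by an algebraic
Kåsa circle fit — minimising $\sum (x^2+y^2+Dx+Ey+F)^2$, exact on
noise-free circles — to boundary pixels restricted to an annulus
(0.8–1.2 r) on the superior-medial half, which keeps the neck junction out
of the fit; the fit is iterated three times. The neck axis passes through
the head centre and the mid-point of the narrowest neck cross-section:
cross-sections are 3 px bins along an initial neck direction, and the
isthmus search walks distally from the head only while the section width
stays neck-like, so the greater trochanter (which only ever widens a
section) cannot capture it. The trochanter tip is the most superior mask
point lateral of the neck axis and outside 1.1 r of the head disc. A bare
disc with no neck reports `trochanter_found = FALSE` rather than guessing.

**Shaft axes** (`shaft_axis`). For each occupied row in the central 60% of
the mask's vertical extent (a configurable fraction; the trimming excludes
metaphyseal flare) the midpoint of the foreground run is computed, and a
total-least-squares line is fitted through the midpoints. Masks with
multiple runs in more than 20% of rows are rejected as fragmented;
occasional split rows use the longest run.

**Joint lines** (`joint_line`). Knee masks are split into femoral and
tibial components at the row of least foreground occupancy (the joint
space) — this is robust even if the two components touch after heavy
noise. The two articular extremal points per surface (condyles, plateau
edges, plafond corners) are discrete extrema of the per-column boundary
profile, separated by an exclusion window of 0.3 × the profile width and
required to be split by a notch at least 2 px shallower; each extremum is
refined to sub-pixel position by a local parabola fit (window ≈ 8% of the
extremum separation), which is exact for the locally circular surfaces of
the phantom up to rasterisation. Single-lobed contours raise an error
naming the bone.

## The phantom

Real radiographs and reader annotations are not redistributable, so
correctness is established against a parametric phantom with closed-form
ground truth. Each bone is a union of analytic primitives: the femoral
head is a disc; the neck a rectangle at the neck-shaft angle to the
anatomical axis; shafts are rectangles; the condyles, plateau and plafond
are trapezoid bodies carrying small circular bulges whose extremal points
*are* the joint-line endpoints. The construction is gauge-fixed with a
vertical femoral mechanical axis; the condylar tilt is then
$90° - \mathrm{mLDFA}$, the plateau tilt follows from the JLCA, the tibial
axis tilt from mMPTA, and so on, so that every requested angle is realised
exactly. Ground truth is evaluated from the continuous geometry *before*
rasterisation: the pipeline error measured against it deliberately includes
discretisation error.

Defaults emulate a realistic adult population: femoral length 435–480 mm,
tibial length 345–380 mm (leg ≈ 0.8–0.87 m), head radius 22–27 mm, neck
length 45–55 mm, shaft width 26–34 mm, condyle width 75–88 mm, plafond
width 45–58 mm, pixel spacing 0.48 mm/px on a 768 × 1920 px canvas
(roughly a 4× downsample of a ~3000 × 7000 clinical full-leg image; the
canvas is sized so the longest sampled leg fits with ~40 mm margins). The
`normal` population samples every parameterised angle uniformly inside its
normal range; `varus`/`valgus` push mLDFA/mMPTA (and JLCA for varus)
outside in the respective direction; `lld` shortens the tibia by 2–6 cm.
One seed governs spec sampling and a second (derived) seed governs noise.

Three joint-centre landmarks (knee femoral/tibial centre, ankle centre) are
midpoints of joint lines and so sit in the articular *void* between the
bulges — inside no mask, as on a real radiograph. Containment tests allow
them a tolerance of one bulge radius.

**Boundary jitter.** Segmentation noise is emulated by displacing the
boundary polygon (one vertex every ~2.5 px) with zero-mean Gaussian noise
smoothed along the boundary (moving average over 9 vertices, rescaled to
the requested marginal sd). The smoothing reflects the spatial coherence of
real segmentation error; uncorrelated vertex noise at sd ≥ 2 px folds the
outline over itself, which no segmentation produces. Jittered polygons are
rasterised with the nonzero winding rule so local self-intersections do not
punch spurious holes. At sd = 1 px the shaft masks keep Dice > 0.98 against
the clean masks and mean angle error stays below 0.5°.

What passing phantom tests does **not** show: robustness to the texture,
overlap and exposure variation of real radiographs, to segmentation
failures that change topology (missing condyle, fused joint space), or to
pathology outside the modelled geometry (implants, dysplasia, bowing).
The phantom validates the geometry layer, not a segmentation model.

## Preprocessing operators

The deterministic operators applied ahead of any learning-based stage are
exposed with exact coordinate bookkeeping: every geometric operator
(`pad_to_square`, `resize_fixed`, `crop_roi`, `flip_right_to_left`)
composes an affine per-axis transform (orig = a·cur + b) so points map back
to the original frame to better than 0.5 px. Padding fills with black and
centres the content. Resizing is bilinear (pixel-centre convention). CLAHE
uses tiles (8, 8) and clip limit 2.0 by default, delegating to EBImage;
dimensions not divisible by the tile grid are edge-replicated and cropped
back, so edge tiles absorb the remainder, and constant images are returned
unchanged. CLAHE widens the dynamic range of low-contrast content but its
output range need not contain the input range (the per-tile equalisation
recentres intensities); its transfer function is monotone for any fixed
tile histogram.

## Numerical choices

* Sub-pixel refinement windows: parabola fits use ±8% of the extremum
  separation for joint surfaces, ±0.4 r for the head apex, ±9 px for the
  trochanter cap; a fit falling outside its window or with the wrong
  curvature falls back to the discrete extremum.
* Ties at discrete extrema resolve toward the lateral column (after
  left-canonicalisation, the smaller column), making detection
  deterministic.
* ICC defaults to ICC(2,1) — two-way random effects, absolute agreement,
  single rater — the standard for method comparison; ICC(3,1) is a flag.
  Lin's CCC uses 1/n (biased) moments per the original estimator.
  Bland–Altman limits are mean ± 1.96 sd of the differences. The package
  distinguishes mechanical axis deviation (mm, `MAD`) from the mean
  absolute deviation of paired differences (`mad_abs_dev`), which share an
  acronym in the clinical literature.
* Hausdorff distance defaults to the undirected maximum over boundary
  pixel sets (95th-percentile variant by flag); mAP uses all-point
  precision–recall interpolation over IoU 0.50:0.05:0.95 (101-point
  variant by flag), with greedy score-ordered matching.
* Degenerate inputs fail loudly and specifically: collinear circle fits,
  fragmented or too-short shafts, single-lobed joint contours, missing ROI
  classes, zero-variance agreement series (correlations reported as `NA`
  with a warning, error indices still computed).

## Problem sizes used in validation

The test-suite and the acceptance script validate recovery on 100 seeded
noise-free phantoms (all 13 angles within 0.5°, lengths within 2 px ×
spacing ≈ 1 mm), 50 phantoms at 1 px jitter (mean angle error < 1°, no
failures), 200 random mask pairs against brute-force Dice/Hausdorff
oracles, and agreement statistics against an independent ANOVA
decomposition and a cross-language reference implementation, frozen to
1e-10. These sizes keep a full run within a few minutes on one CPU while
exercising the full parameter population.

## Known limitations

* The measurement is 2-D frontal-plane only; rotation and flexion of the
  limb during acquisition bias the projected angles and are not modelled.
* The phantom's bones are piecewise-analytic idealisations; detector
  thresholds (annulus bounds, notch depth, neck-likeness margin) were
  chosen for realistic adult geometry and may need retuning for paediatric
  or severely dysplastic anatomy.
* Masks must arrive as one ROI per bone class per side; the package does
  not segment images and does not read DICOM.
* The normal-range table is reproduced as published, including its aTFA
  range (see above).
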