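---
title: "Measuring and diagnosing DDH on pelvic radiographs with DDHdx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and diagnosing DDH on pelvic radiographs with DDHdx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DDHdx)
```

## The clinical problem

Developmental dysplasia of the hip (DDH) spans a spectrum from a shallow
acetabulum to complete dislocation. On an anteroposterior pelvic
radiograph of a child, the standard reading starts from a handful of
anatomical key points: the top of each triradiate cartilage, each
lateral acetabular edge, and the inner and outer points of each proximal
femoral metaphysis. From these, the reader constructs Hilgenreiner's
line (through the two triradiate tops), a Perkin's line per hip
(perpendicular to Hilgenreiner's line through the lateral acetabular
edge) and a 45-degree diagonal through their junction, then measures the
acetabular index (AI), the lateral center-edge angle (LCEA), and the
IHDI displacement grade of the H-point — the midpoint of the proximal
femoral metaphysis, chosen because it is visible before the femoral head
ossifies. DDHdx implements this workflow as a semi-automatic pipeline:
the user supplies clicked landmarks, the software rectifies imprecise
clicks against the bony rim, measures the angles, and applies a
clinical decision rule stratified by the patient's nationality, sex and
age.

## The measurement model

All constructs are expressed in a per-hip orthonormal frame anchored at
the Perkin-Hilgenreiner junction: `u` runs along Hilgenreiner's line
away from the pelvic midline (the midpoint of the two triradiate tops)
and `v` is perpendicular to it pointing superiorly. With the roof vector
`d` = lateral acetabular edge − triradiate top written as `(d_u, d_v)`,

* **AI** = `atan2(d_v, d_u)` in degrees — positive when the acetabular
  edge lies superior to Hilgenreiner's line; the steeper the roof, the
  shallower the acetabulum.
* **LCEA** = `atan2(e_u, e_v)` with `e` the vector from the femoral-head
  center to the lateral acetabular edge — positive when the edge lies
  lateral to the "vertical" through the center.
* **IHDI grade**: with `p` the H-point relative to the junction,
  grade 4 if `p_v > 0`, else grade 1 if `p_u <= 0`, else grade 2 if
  `p_u <= -p_v`, else grade 3. Every boundary tie ("at or medial", "at
  or inferior") resolves to the lower grade.

Two realization choices deserve comment. First, "vertical" means
*perpendicular to Hilgenreiner's line*, not parallel to the image edge:
Perkin's line is defined as that perpendicular, and using the same frame
for LCEA makes every angle invariant to in-plane tilt of the radiograph.
Second, the superior orientation of `v` is determined anatomically
rather than from the image axes: the lateral acetabular edges always lie
on the iliac side of Hilgenreiner's line, so their mean perpendicular
offset fixes the sign (with the femoral metaphyses, which lie inferior,
as a fallback vote, and the image orientation as a last resort for fully
degenerate inputs). This makes AI, LCEA and the IHDI grade invariant
under arbitrary rotation, translation and uniform scaling of the
annotation coordinates — a property the test suite checks to 1e-6
degrees — where an image-axis rule would flip beyond 90 degrees of
rotation.

The annotation list contains no femoral-head center, since the ossific
nucleus is frequently absent or eccentric in the relevant age range.
`measureLCEA()` therefore accepts an explicit center when the reader can
click one and otherwise substitutes the H-point, flagging the provenance
(`h_point_proxy`) in the output so downstream consumers can audit the
approximation. LCEA is reported but deliberately kept out of the
decision rule, which is stated on AI alone; `diagnoseStudy()` leaves a
hook (`dislocatedGrade`) for stricter variants.

```{r}
ann <- annotationSet(
  label = c("triradiate_top", "triradiate_top", "lateral_acetabular_edge",
            "metaphysis_inner", "metaphysis_outer"),
  side  = c("right", "left", "left", "left", "left"),
  x = c(100, 300, 340, 330, 350), y = c(200, 200, 180, 225, 235))
g <- buildReferenceGeometry(ann)
measureAI(g, ann, "left")$aiDeg
classifyIhdi(g, "left")
```

## Landmark rectification

Clicked points rarely sit exactly on the bony rim. `refinePoint()`
intercepts a square window (default 30 x 30 px) around the click,
smooths it with a small Gaussian (kernel 5, sigma 1 px), thresholds it
against the local block mean (block 11 px, offset 2 intensity units;
bone is radiodense, hence bright), and snaps the click to the rim pixel
minimizing the Euclidean distance `Ed = sqrt((x - a)^2 + (y - b)^2)`.
Ties break to the smallest row, then column, so the result is
deterministic; a snap farther than `maxSnapDistance` (default 15 px) is
refused to avoid capture by unrelated structures, and the operation is
idempotent (a snapped point re-snaps to itself).

The rim itself is defined as the foreground pixels of the threshold mask
that have a 4-adjacent background neighbor whose smoothed intensity is
lower by at least the threshold offset. The darker-neighbor condition
matters: a local-mean threshold marks a *band* along each intensity
transition, and without the condition the band's interior side — where
the neighboring background pixel is equally bright — would be reported
as spurious rim. Filtering parameters are deliberately conservative and
all exposed in `refinementConfig()`; all snapping is integer-pixel, as
sub-pixel refinement would suggest a precision the 8-bit input does not
support. By default all eight landmark labels are eligible for
refinement, with the distance guard as the safety net; per-label opt-out
is available for workflows where some clicks are trusted.

## The decision rule

A hip is dysplastic when its AI *strictly exceeds* `mean + 2 sd` of the
normal range for the matching stratum of nationality, sex, side and
half-open age bracket `[age_min, age_max)`; equality counts as normal,
and any AI within 0.5 degrees of the threshold carries a borderline
warning in either direction. Non-dysplastic hips split into "other
dislocation" when displaced — realized as IHDI grade >= 2, i.e. the
H-point lateral to Perkin's line, since grade 1 is defined by a located
H-point — and "normal" otherwise. Only a high AI is abnormal; there is
no lower bound, matching the one-sided direction of the `mean + 2 sd`
criterion. Dysplastic hips carry their IHDI grade as severity.

The package ships only a **synthetic criteria template**
(`defaultCriteriaTable()` and
`inst/extdata/criteria_synthetic_template.tsv`, mean 23, sd 4 degrees in
every stratum, threshold 31): plausible magnitudes for exercising the
machinery, not transcriptions of the published normal-range references.
Clinical use requires transcribing those references into the same TSV
format; `readCriteria()` validates positive sd and non-overlapping age
brackets per stratum at load time.

```{r}
entry <- data.frame(mean_deg = 23, sd_deg = 4)
diagnoseHip(32, 1L, entry)
diagnoseHip(30, 3L, entry)
```

## What the phantom generator emulates

Because no radiographs accompany the method, validation rests on a
parametric pelvis phantom with exact ground truth. `makePhantom()`
constructs the geometry analytically — triradiate tops on a possibly
tilted Hilgenreiner line symmetric about the midline (11% of the image
width to each side), a lateral acetabular edge placed so the roof makes
*exactly* the specified AI at the specified roof length, an H-point at
the specified lateral/superior offset from the junction — and rasterizes
bright bone on a darker background: the acetabular roof as a 6 px bar
whose superior boundary runs through both roof landmarks, an iliac block
10 px above it (the gap keeps the roof's landmark-bearing boundary a
detectable edge), a metaphysis bar whose superior edge joins the inner
and outer metaphysis points, and optionally a femoral-head disc. Seeded
Gaussian noise (default sd 2 intensity units against a bone-background
contrast of 160, emulating mild detector noise) is added and clipped to
[0, 255]; exact pre-noise landmark coordinates are returned as truth.

`phantomBatch()` samples per-hip truth classes (normal, dysplastic with
IHDI 1-4, other dislocation) from a stated mix, keeping every sampled AI
at least 1 degree from the diagnostic threshold and every H-point offset
at least 2 px from every IHDI boundary, so truth labels remain
unambiguous under rounding. `jitterAnnotations()` emulates imprecise
clicks with integer-rounded Gaussian displacements. All randomness flows
from the seeds; batches regenerate bit-exactly.

The phantom is deliberately stylized. It shares with real radiographs
exactly the properties the pipeline depends on — correct reference-line
geometry, snappable bone-background edges through the landmarks,
8-bit noise — and nothing else: no projection physics, no soft tissue,
no pelvic rotation or tilt artifacts, no anatomy-shaped bones. Passing
phantom suites therefore demonstrates geometric and algorithmic
correctness, not clinical performance.

## Problem sizes and numerical choices

The shipped suites use sizes chosen to exercise the properties well
beyond their failure modes while staying comfortably interactive:
10,000 random points for the IHDI half-plane oracle, 60-study batches
(120 hips) for end-to-end agreement, 12 rendered phantoms (96
landmarks) for refinement comparisons, n = 500-2,000 for the
ICC/kappa independence limits, and 20,000 bootstrap resamples for the
DeLong oracle. Angle invariance is asserted to 1e-6 degrees; phantom AI
recovery to 0.5 degrees (the contract allows rendering quantization,
though measuring the analytic truth is exact to machine precision);
grade recovery is exact thanks to the 2 px boundary margins.

Statistical conventions: standard deviations use the n − 1 denominator
throughout; Bland-Altman limits are bias ± 1.96 sd of the paired
differences, with the bias tested by a one-sample t-test on the
differences (the statistically coherent reading for paired
measurements); the ICC is the two-way, absolute-agreement,
single-measurement form, the standard choice for test-retest data,
computed from `aov()` mean squares; weighted kappa uses linear weights
`|i - j| / (k - 1)`; and the AUC of a single-threshold binary reader is
the two-point trapezoid `(sensitivity + specificity) / 2`, which is the
assumption under which the published reader AUCs are reproducible from
their confusion counts. DeLong's paired AUC test is delegated to pROC,
with the degenerate identical-scores case reported as z = 0, p = 1.

## Known limitations

* Rim detection is threshold-based and erodes sharp corners by about a
  pixel. On the stylized phantoms — where two landmarks sit on exact
  90-degree corners — this imparts a small (~0.5 degree) negative bias
  to refined AI. Snapping therefore reliably reduces landmark and AI
  *measurement error*, but for hips whose true AI lies within 1-2
  degrees of the diagnostic threshold a biased-but-tighter measurement
  can flip the borderline call more often than unbiased click noise
  does; such hips are exactly the ones the borderline warning flags.
  Real acetabular rims are longer arcs, where the erosion argument does
  not apply in the same way, but this remains untested on clinical
  images.
* The diagnosis depends on the triradiate cartilage: hips with a closed
  or surgically altered triradiate cartilage are out of scope, as is
  screening the radiograph itself for rotation/tilt adequacy.
* The criteria values shipped are placeholders (see above); every
  diagnosis records the criteria source used so this is auditable.
* Agreement statistics are point estimates for two raters; confidence
  intervals and multi-reader generalizations are not provided.
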