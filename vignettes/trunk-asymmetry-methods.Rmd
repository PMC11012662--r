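---
title: "Measuring trunk asymmetry from back-view photograph landmarks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring trunk asymmetry from back-view photograph landmarks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trunkmetrics)
```

## The measurement problem

Adolescent idiopathic scoliosis deforms the visible trunk: shoulders tilt,
one waist crease deepens, the pelvis shifts. Radiographs quantify the spinal
curve but involve cumulative radiation across a follow-up that can span
years, and they only partially reflect the cosmetic asymmetry that concerns
patients. A back-view clinical photograph, taken with an ordinary camera at
about a metre, carries enough information to quantify trunk asymmetry — if
the measurement is restricted to quantities that survive unknown scale and
framing.

`trunkmetrics` implements such a measurement. An evaluator tags nine
anatomical landmarks on the photograph (two acromion endpoints, the two
most superior points of the posterior axillary folds, the two minimal-waist
points, the two most external iliac crest points, and the C7 spinous
process), and the package computes ten parameters that are all
calibration-free: six angles and four left/right area ratios. No calibration
object, pixel spacing, or image content is needed — only the landmark
coordinates.

## Coordinate and sign conventions

All geometry is in the raster image frame: origin top-left, x rightward,
y **downward**. Side labels are patient-anatomical; in a back view the
patient's left appears on the image left, so `left.x < right.x` for every
landmark pair. A violation is a hard validation error ("side inversion"),
because it almost always means the annotator swapped sides.

Height angles use the clockwise-positive convention of an observer facing
the patient's back: the signed tilt of a left-right pair is
`atan2(right.y - left.y, right.x - left.x)` in degrees, positive when the
patient's right-side point sits lower in the image. The three worked
anchors are: a horizontal pair gives 0; left (0,0), right (10,10) gives
+45; left (0,0), right (8,2) gives +14.036.

## The ten parameters

* **SHA, AHA, WHA** — shoulder, axilla and waist height angles: signed tilts
  of the respective landmark pairs.
* **LWA, RWA** — left and right waistline angles: the interior angle at the
  minimal-waist point between the ray to the same-side axilla point and the
  ray to the same-side iliac crest point, in (0, 180]. A straight flank
  approaches 180 degrees; a deep waist indentation lowers the angle. This
  construction uses only the nine declared landmarks and needs no
  calibration; it yields obtuse values in the 128–164 degree range observed
  clinically. Alternative constructions in the photogrammetry literature
  (e.g. against the vertical, or using auxiliary points) exist; this one was
  chosen as the simplest that is fully determined by the tagged points, and
  it is locked by tests.
* **WAD** = LWA − RWA, sign retained. The sign choice is fixed by the
  convention that a deeper left waist (smaller LWA) gives negative WAD; it
  reproduces the arithmetic of the published summary tables
  (144.8 − 147.9 = −3.1).
* **SA, WA, PA, TA** — hemitrunk area ratios. The vertical plumbline through
  C7 splits the trunk; per side, three quadrilaterals are formed between the
  plumbline and the landmark chain: shoulder region (shoulder level to
  axilla level), waist region (axilla to waist) and pelvic region (waist to
  iliac). Areas are absolute shoelace areas in square pixels; each parameter
  is the left/right ratio, and TA is the ratio of summed areas. Ratios were
  chosen over raw square-pixel values or differences because they are
  dimensionless (a raw pixel area depends on camera distance, which the
  acquisition protocol deliberately leaves uncalibrated); the raw per-side
  areas remain available in the `hemitrunk_areas` object. Since each corner
  on the plumbline takes the *same-side* landmark's y, the left and right
  regions need not share horizontal edges when landmark heights differ —
  this keeps every region a simple quadrilateral and makes the construction
  exactly symmetric under mirroring.

The C7-prime point sometimes drawn on annotated figures (the foot of the
vertical through C7) is a construction, not a stored landmark; only the
nine tagged points are input.

These definitions give the profile a set of exact invariances that the test
suite asserts: translation and uniform-scale invariance; mirror antisymmetry
(reflecting about the plumbline and swapping side labels negates
SHA/AHA/WHA/WAD, swaps LWA and RWA, and inverts every ratio); the identity
WAD = LWA − RWA on every profile; the mediant bound (TA always lies between
the smallest and largest of SA, WA, PA); and strict monotonicity of TA in
the plumbline position.

Degenerate inputs — coincident points, the plumbline outside a landmark
pair — raise typed errors rather than returning NaN, so annotation mistakes
surface immediately in batch runs. Angles are kept at full precision in the
core; report writers round to 2 decimals (angles, SEM, aggregates) and 3
decimals (ICCs).

## Validation and quality checking

The structural validator enforces completeness, finiteness and side order as
hard errors. Everything else is advisory: per-side vertical ordering
(shoulder above axilla above waist above iliac, in image coordinates), C7
above the axillae, and a low-resolution warning when recorded image
dimensions fall below a configurable short-side threshold (default 200 px).
The original tool performed an automatic image-quality check whose algorithm
is not public; this package deliberately implements only the structural
part and reports everything else as coded warnings, never failures.

## Reliability statistics

The observer-variability analysis is the standard two-way crossed ANOVA
decomposition of a complete subject-by-rater grid of single ratings:
MSR (between subjects), MSC (between raters), MSE (residual), with
(n−1), (k−1) and (n−1)(k−1) degrees of freedom. All four two-way ICC forms
are implemented:

| form | formula |
|---|---|
| single, consistency | (MSR − MSE) / (MSR + (k−1) MSE) |
| single, agreement | (MSR − MSE) / (MSR + (k−1) MSE + (k/n)(MSC − MSE)) |
| average, consistency | (MSR − MSE) / MSR = 1 − 1/F |
| average, agreement | (MSR − MSE) / (MSR + (MSC − MSE)/n) |

with F = MSR/MSE. Confidence intervals use the exact F construction for the
consistency forms and the Satterthwaite degrees-of-freedom construction for
the agreement forms (average-agreement bounds via the Spearman–Brown
step-up). A perfect-fit grid (MSE = 0) gives consistency ICC exactly 1 with
an infinite F and a degenerate point interval.

The phrase "two-way mixed random model" that reliability reports often use
is ambiguous about the exact form. The package's defaults are:
**average-measures agreement** for the inter-observer (reproducibility)
study — the published per-measure ICCs track 1 − 1/F from slightly below,
which is the signature of the average-measures agreement form — and
**single-measures consistency** on the k = 2 occasion grid for the
intra-observer (repeatability) study. Both defaults are overridable, and
every report header records the form actually used.

Supporting statistics follow the conventions of the validation study:

* **SEM** = SD·sqrt(1 − ICC). The SD is taken from the n per-subject means
  over raters at occasion 1, paired with the inter-observer ICC of the same
  slice; this pairing reproduces the published waistline SEM cells exactly.
  Some published SEM cells (the axilla angle and the area parameters) are
  not reproducible from any printed SD/ICC pairing and are treated as
  outside the package's reproduction scope.
* **Summary rows** ("Total Mean") are unweighted column-wise means over the
  ten measures — including the mean of per-measure minima and maxima for
  the repeatability aggregation. This convention is validated by exact
  reproduction of the published summaries (e.g. the 0.779 mean of minima).
* **Group comparison** uses the classical pooled-variance two-sided
  Student's t (no Welch correction) at the 5% threshold.
* **Normality** is checked with the one-sample Kolmogorov–Smirnov statistic
  against a normal with the sample mean and SD. Because the parameters are
  estimated from the same data this p-value is conservative; the Lilliefors
  correction is available (`method = "lilliefors"`). The flag is advisory
  and never blocks an analysis. No multiple-testing correction is applied
  anywhere, matching the analysis convention the package reproduces.
* Quartiles use linear interpolation (R's default type 7); SDs use the n−1
  denominator.

## The synthetic rater-study generator

Real annotated photographs cannot ship with the package, so end-to-end
testing uses a landmark-level simulator that replays the validation study
design: 15 subjects, 12 raters, 2 rounds. It generates:

1. a perfectly symmetric template (C7 on the midline; landmark rows at
   fixed anatomical fractions of the image);
2. one deformity per subject: rigid rotation of each left/right pair about
   its midpoint by a drawn tilt (so the induced SHA/AHA/WHA equal the drawn
   tilts *exactly*), a lateral C7 trunk shift, and per-side waist-depth
   offsets that vary LWA/RWA;
3. per rater-and-occasion retagging with isotropic Gaussian jitter on all
   nine landmarks, using substreams derived by stable hashing of
   (rater, occasion, subject) from one master seed — deterministic, and
   adding raters never perturbs existing draws. An optional per-rater
   systematic vertical offset (default 0) exercises the
   agreement-versus-consistency distinction.

Default magnitudes, chosen once as clinically plausible for this design and
then fixed: subject tilt SD 3 degrees, trunk shift SD 15 px, waist depth SD
10 px on a 1000 × 1500 template, landmark jitter SD 2 px. On the template's
560 px shoulder span, 2 px of jitter propagates to a first-order angle
error of `sqrt(2)·2/560·180/π ≈ 0.29` degrees
(`expected_angle_error_sd()`), so simulated angle SDs fall in the 2–15
degree range and simulated ICCs in the 0.93–0.99 regime observed with real
observers.

The simulator emulates tagging noise and subject heterogeneity; it does
**not** emulate landmark ambiguity on soft tissue, BMI or clothing
occlusion effects, rater learning between rounds, or any correlation
between landmark errors. Passing parameter-recovery tests therefore shows
that the statistical machinery is correct under the declared noise model,
not that real observers behave like the model.

Calibration tests exploit the one-way variance decomposition: for an angle
measure, the population single-measures consistency ICC is
σ²subj/(σ²subj + σ²err). With a 3-degree subject tilt SD and jitter tuned
to a 1-degree angle error, the recovered ICC is 9/10; the suite checks the
mean over 20 seeded studies at the 15 × 12 design within ±0.05, empirical
SEM recovery of the injected error within ±20%, and 95% CI coverage within
[0.91, 0.99] over 500 replicates at a population ICC of 0.8.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on generated data:
ICC oracle checks use 40 random grids with n ≤ 8, k ≤ 5 against an
independent sums-of-squares implementation at 1e-10; geometry invariants
use 25 random deformities at double-precision tolerances; the Monte-Carlo
area oracle uses 40,000 points per polygon and a 3-standard-error band;
parameter recovery uses 20 seeded 15 × 12 studies; coverage and type-I
error use 500 replicates each. These sizes make the full suite complete in
well under a minute while leaving the Monte-Carlo bands comfortably
non-trivial.

Numerical details worth recording: the interior-angle computation clamps
the cosine into [−1, 1] before `acos`; the shoelace area is
orientation-independent by absolute value; the ANOVA residual sum of
squares is computed by subtraction and floored at zero; ICC interpretation
bands are left-closed (0.75 classifies as "good", 0.9 as "excellent");
landmark files serialise coordinates with 17 significant digits so round
trips are bit-exact.

## Known limitations

Only the back view is modelled — no lateral or forward-bend metrics, and no
link to radiographic angles or patient-reported scores. The waistline-angle
construction is one documented choice among plausible ones, locked by
tests rather than by an external ground truth. The published per-measure
ICC values themselves cannot be recomputed without the study's raw ratings,
which were never released; the package reproduces every published
*relationship* (SEM identities, the WAD sign, all aggregation conventions)
and validates the ICC machinery against independent oracles and
simulation instead.
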