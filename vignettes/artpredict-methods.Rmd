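---
title: "Methods: predicting adaptive re-planning need from VMAT plan features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting adaptive re-planning need from VMAT plan features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Head-and-neck VMAT with concurrent cisplatin frequently causes oral and
pharyngeal mucositis. When mucositis becomes severe mid-course, the plan is
re-optimized — adaptive radiotherapy (ART). `artpredict` implements a
pre-treatment screening pipeline: from a patient's DICOM RT Plan, RT
Structure Set and RT Dose it derives a compact geometric/dosimetric
signature and classifies the patient as likely-ART vs non-ART.

The signature is a set of eleven five-dimensional *feature lists* per
patient. Each arc of a VMAT plan is resampled into 4° gantry sectors
("segments"); each segment's MLC aperture area \(A\) is converted to an
equivalent-square field side \(s = \sqrt{A}\) (EQIF) and snapped to the
nominal grid \(\{3,4,5,6,8,10,12,14,16,18,20\}\) cm; the per-fraction dose
delivered in each segment (beam dose × meterset-weight increment) is
accumulated per bin. One list per bin carries

1. the nominal EQIF size (cm),
2. the dose accumulated in that bin (Gy per fraction),
3. CTV-high volume per unit BMI (cm³·m²/kg),
4. total plan monitor units,
5. mean oral-cavity dose (Gy, course scale),

with the last three shared by all eleven lists of a patient — a point that
matters below. Lists are labelled ±1 by ART status and classified with an
RBF-kernel soft-margin SVM (γ = 0.05, C = 10) and a KNN (k = 5), sweeping
the test fraction 0.1–0.9 over split seeds 1–100 and averaging accuracy.

## Geometry and dosimetry choices

**EQIF definition.** The equal-area square \(s=\sqrt{A}\) is used, not the
Sterling \(4A/P\) equivalent square: the feature is meant to index "a square
field of the same area". `eqif_side(method = "sterling")` exists for
sensitivity checks only.

**Bin assignment.** Nearest nominal size, ties to the smaller size; sides
beyond the grid clamp to the end bins. Zero-area apertures get no bin and
contribute no dose. These rules are the minimal-assumption completion of a
grid that is published without an assignment rule.

**Arc resampling.** Control points are treated as linear-motion
checkpoints, so leaf/jaw positions are linearly interpolated at each 4°
sector midpoint, and the sector meterset fraction is the increment of the
cumulative meterset weight across the sector — which makes meterset (and
hence dose) conservation exact by construction: fractions sum to 1 within
1e-9 regardless of control-point spacing. A non-multiple-of-4° span ends in
a truncated sector; a static-gantry beam degrades to a single segment with
a warning. Gantry angles are unwrapped modulo 360° assuming a clockwise
sweep; genuinely non-monotonic sweeps are rejected.

**Jaw clipping** of the MLC aperture is on by default (whether the original
analysis clipped is unstated; clipping is the physically correct choice).

**Per-fraction bin doses.** The published per-bin dose profiles sum to
≈1.95 Gy, i.e. the 2 Gy fraction dose minus sub-threshold bins — so bin
doses are accumulated per fraction by default (`course_total` is available).
The oral-cavity mean dose is course-scale (~30 Gy), read from the dose
grid; the plan's per-beam dose, when absent, is split across beams
proportionally to MU.

**Volumes and mean doses.** Contour stacks are integrated slice-wise
(shoelace area × slice spacing, holes not modelled); mean structure dose
samples voxel centers with an even-odd point-in-polygon test and no
partial-volume weighting, matching typical DVH engines at planning-grid
resolution. A structure capturing no voxel center is an error rather than
a silent zero.

## Group statistics

The two-sample comparison defaults to Welch's t (safer at 43 vs 18 than the
pooled test; pooled available via `var_equal = TRUE`), "5% precision" is
read as two-sided α = 0.05, and the z-test is the large-sample two-sample
variant with per-group sample variances. Per-bin medians are computed over
per-patient bin doses (one value per patient per bin), then compared across
groups; relative differences are \(100(\mathrm{ART}-\mathrm{nonART})/
\mathrm{nonART}\), undefined (reported "–") when the reference is zero. No
multiple-testing correction is applied, mirroring the original analysis.

## Classifiers

The SVM dual is solved by sequential minimal optimization with
maximal-violating-pair selection on a precomputed kernel matrix (C++ via
Rcpp); correctness is asserted through KKT-condition tests rather than a
reference library, since none exists in this environment. KNN is exact
brute-force Euclidean majority vote; distance ties break by training order
and vote ties (even k only) fall back to the nearer class.

**Scaling is the consequential unstated choice.** The five features live on
wildly different scales (MU ≈ 640, oral dose tens of Gy, bin doses < 1).
The default standardizes features by training-partition z-scores. The
`"none"` mode reproduces raw Euclidean geometry, in which MU dominates all
inter-patient distances — and, because sibling lists share MU exactly,
raw-scale neighborhoods are sibling-dominated (see below).

Split semantics: the seed randomizes only the split (classifiers are
deterministic); the test partition has `floor(test_size * N)` lists
(minimum 1); list-level splitting is the replicated protocol, patient-level
splitting (a patient's 11 lists move together) is provided as the leakage
control. Sweep summaries (mean, SD, CV) are computed over the nine
per-size means, matching the published table's structure.

## The synthetic world

No clinical data are distributable, so the generator *states* a cohort
calibrated to the published summary statistics:

* 43 non-ART / 18 ART patients; group means 3.70/6.21 cm³·m²/kg
  (CTV-high/BMI), 28.70/32.98 Gy (oral dose), 636/644 MU; per-bin profile
  means from the published bin table.
* Group SDs are not published. They are back-solved from the published
  p-values by `calibrate_sds()`: with equal SDs the Welch df are
  SD-independent, so the SD that makes the expected Welch statistic hit the
  published p is unique (root-found to 1e-6). This yields SD ≈ 4.08 for
  CTV-high/BMI, 7.12 Gy for oral dose, 112 MU for MU, and per-bin SDs from
  the per-bin p-values (identically-zero bins get SD 0).
* Patient-level features are drawn from zero-left-truncated normals whose
  **post-truncation mean is matched to the target** by shifting the
  location parameter. Naive truncation would inflate the non-ART
  CTV-high/BMI mean by ~9% and break mean recovery; matching the SD as
  well is impossible for that group (it would need a coefficient of
  variation of 4.08/3.70 > 1, above the supremum of a zero-truncated
  normal), so the mean is matched and the realized SDs shrink somewhat.
  Bin doses are plain normals with negatives clipped to zero, per-bin
  independent. BMI ~ N(22, 3) truncated at 15 and the 1-vs-2-arc coin flip
  (p = 0.5) exist only to materialize DICOM files.
* A consequence worth stating: calibrating an SD to a published p of 0.040
  pins the α = 0.05 rejection rate of future cohorts at the noncentral-t
  power of that effect, ≈ 0.55 — a cohort calibrated to a marginal p-value
  *cannot* be significant much more often than half the time. The test
  suite asserts that analytic expectation, not a wished-for rate.

The DICOM generator materializes each synthetic patient as a readable
RTPLAN / RTSTRUCT / RTDOSE triplet (explicit-VR little-endian, written by
the package's own minimal codec — no DICOM toolkit exists in this R
stack): 1–2 full clockwise arcs with control points every 2°, square MLC
apertures of the nominal bin sizes allocated to 4° sectors by
largest-remainder dose share, cumulative weights encoding the drawn
profile, square contour stacks encoding the drawn CTV-high volume, and a
uniform dose grid at the drawn oral mean. Because sector midpoints coincide
with control points and aperture sides sit exactly on the nominal grid, the
end-to-end round trip (write → read → extract) reproduces the drawn
features nearly exactly — well inside the stated tolerances (10% bin dose,
2% oral dose, exact MU).

**What the generator does not emulate:** anatomically realistic dose
distributions, correlated or smooth per-patient bin profiles, correlation
between oral dose and CTV size (independence by default),
counter-clockwise arcs, leaf transmission/tongue-and-groove, or
inter-feature correlations within a group. A green end-to-end test
establishes that the *pipeline* is self-consistent on well-formed input —
not that real DICOM idiosyncrasies are covered, and not that the published
accuracies are reproduced (next section).

## Leakage and the headline accuracies

With list-level splits, a test list's 5-NN candidates include its own
sibling lists, identical in three of five features — the published
protocol embeds this leakage, and the package quantifies it: list-level
KNN accuracy exceeds patient-level accuracy on calibrated cohorts
(~0.79 vs ~0.71 at test size 0.5, z-scored).

It does **not** reach the published worst-case 0.905 under z-scoring: the
p-value-calibrated group separation (Cohen's d ≈ 0.6 per shared feature)
leaves the groups heavily overlapped, and z-scoring spreads siblings along
the EQIF-size and bin-dose axes, so measured sibling capture is only ~1.2
of 5 neighbors. The corresponding acceptance check is therefore left
failing, deliberately, with this analysis. Under the protocol's own
raw-unit Euclidean metric (`scaling = "none"`), where siblings are
near-duplicates, leakage is much stronger — KNN ≈ 0.88 at test size 0.5
and ≈ 0.96 at 0.1, raw-unit SVM ≈ 0.97 — which is the more plausible
mechanism behind near-perfect published accuracies computed from features
whose univariate group differences are only marginally significant.

## Numerical conventions

Geometry is cm at the isocenter plane, converted once from DICOM mm on
read; doses are Gy internally with cGy only in mirrored reports; DICOM
decimal strings are written with 10 significant digits (round-trip error
~1e-10 relative); the dose grid is quantized by its scaling factor (1e-4
Gy by default). The SMO stops at a KKT gap of 1e-3; support vectors are
α > 1e-8. Degenerate inputs fail loudly: empty partitions, single-class
training sets, structures below grid resolution, all-zero dose profiles,
non-monotonic sweeps.

## Limitations

Single-time-point features only (pre-treatment); no CTCAE grading, no
re-planning logic, no fluence or transmission modelling; cumulative/
differential DVH curves are out of scope (only the mean dose is used); the
DICOM codec reads the explicit-VR little-endian subset this package writes
and is not a general-purpose DICOM implementation.
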