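---
title: "Dose and complexity metrics for dual-arc VMAT plans: models, conventions, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose and complexity metrics for dual-arc VMAT plans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmatmetrics)
```

This vignette is the package's account of what it computes and why:
the plan model, the metric definitions and their degenerate-case
conventions, the synthetic-cohort generator that stands in for patient
data, and the numerical choices that keep the analytic limits exact.

## The plan model

A VMAT plan is a list of arcs; an arc is an ordered sequence of
control points, each holding the gantry angle, the MLC bank positions
(one leaf-edge coordinate per leaf pair and bank, in mm, IEC-style:
opening = right-bank edge − left-bank edge ≥ 0) and the cumulative
meterset weight in [0, 1]. The MU delivered by segment $(i, i+1)$ is
$(w_{i+1}-w_i)\,MU_{arc}$, which conserves the arc meterset exactly.
Each arc carries its *increment* (sector width, 15° or 30° here) as
metadata: an arc split into $S$ sectors reverses the leaf travel
direction at the $S-1$ interior sector boundaries. (The two counts —
sectors and reversals — are both recorded on the arc object, because
prose descriptions of this relationship are easy to get backwards; the
convention used throughout is $S-1$ reversals per 360° arc.)

Plans arrive three ways: the JSON fixture dialect (schema in
`inst/extdata/plan-schema.json`), DICOM-RT Plan files (a minimal
explicit-VR-little-endian reader/writer covering beam, control-point,
MLCX-position and fraction-group attributes; the arc increment, which
has no standard DICOM attribute, travels in `BeamDescription`), or the
seeded generator below. `validate_plan()` reports every structural
invariant violation (monotone anchored weights, nonnegative openings,
full 360° span, positive MU) without raising, so partially broken
inputs can be inspected.

Leaf pairs have fixed width $t$ = 5 mm. Pairs whose opening never
exceeds the *closed gap* (default 0.5 mm, configurable) anywhere in an
arc are treated as parked: real MLCs keep closed pairs at a small
dosimetric gap, and the complexity metrics are defined over the
exposed leaves only. Jaw positions are not modelled; "in-field" is
therefore *opens somewhere in the arc*, which coincides with the jaw
criterion for any plan whose jaws track the open aperture.

## Complexity metrics

Per control point and bank, the leaf-sequence variability is
$$\mathrm{LSV} = \prod_{\text{banks}} \frac{\sum_{n=1}^{N-1}
  (pos_{max} - |pos_n - pos_{n+1}|)}{(N-1)\,pos_{max}},$$
with $pos_{max}$ the within-bank spread at that control point.
Conventions: a bank with zero spread contributes factor 1 (the
quotient is 0/0 there, and the modulation-free limit must reach
MCS = 1); a single in-field pair likewise gives 1. The aperture-area
variability is the summed per-leaf opening divided by the summed
per-leaf *maximum* openings over the arc. The quantity "per-leaf arc
maximum" is deliberately the maximum of the pair opening, not the
difference of per-bank extreme positions: the two differ when the two
banks attain their extremes at different control points, and only the
former keeps AAV ≤ 1 with equality exactly when every pair sits at its
arc-maximal opening. An arc that never opens would have denominator
zero; AAV is then 1 by convention and flagged.

$\mathrm{MCS}_{arc}$ weights the pairwise control-point averages of
AAV·LSV by segment MU; $\mathrm{MCS}_v$ is the plain $1/K$ mean over
arcs — *not* MU-weighted, following the defining tabulation exactly
even though part of the literature weights by arc MU. A static
uniform rectangular aperture gives exactly 1; heavy modulation drives
it toward 0.

The aperture-geometry family starts from the open-pair rectangles:
area $AA = \sum_k t\,(x2_k - x1_k)$, perimeter $AP$ = boundary length
of their union, irregularity $AI = AP^2/(4\pi AA)$ (undefined for a
closed aperture; bounded below by $4/\pi$, attained by a square).
$AP$ and the arc-level union area $U$ are computed *exactly* — the
union of leaf-pair rectangles is a stack of axis-aligned rows, so the
perimeter has a closed form (2$t$ of vertical edge per open row plus
the exposed horizontal lengths at each row interface, summed over
connected components) and $U$ reduces to per-pair interval unions.
The test suite checks both against an independent 0.1 mm
pixel-marching rasterizer on alias-free shapes.

Beam level: $BA_i$, $BI_i$ are MU-weighted means of area and
irregularity; $BM_i = 1 - \sum_j MU_{ij} AA_{ij} / (MU_i\, U)$
measures how little of the union aperture the individual segments
cover (0 for a static beam). Plan level: PA, PI, PM are the
MU-weighted means of the beam values. The defining table indexes
apertures by control point but MU by segment; by default each segment
takes the *mean of its two bounding control-point apertures*,
consistent with the pairwise-average structure of the MCS sum
(`attribution = "per-cp"` switches to splitting each segment's MU
half-and-half onto its endpoints). Segments whose aperture is fully
closed have undefined irregularity and are dropped from the BI
average with the weights renormalized; a beam with *all* apertures
closed is an error. A numerically zero BM ($|BM| < 10^{-9}$) is
snapped to 0 so the no-modulation limit is exact.

## Dose metrics

Dose grids are 3-D arrays in Gy with voxel spacing in mm; masks are
binary voxel-center membership (no partial volumes) at the grid
resolution, 2 mm by default. The cumulative DVH bins masked voxel
doses (default bin 0.01 Gy) and accumulates from the top; the mean
dose is kept from the *raw* voxels at construction, never from the
binned curve, which would inherit half-bin bias.

Query conventions, chosen so the defining limits are exact:

* $D_{x\%}$ / $D_{v\,cc}$ resolve to the **highest bin edge** whose
  at-or-above volume still meets the target, ties toward the higher
  dose. Piecewise-linear interpolation across the final jump would
  misplace queries on plateaued (step) distributions — e.g. it would
  report $D_{2\%}$ slightly *above* the physical maximum for a
  uniformly irradiated target, breaking HI = 0 — while the edge rule
  is exact there and within one bin width of the voxel-sort oracle in
  general (the suite verifies both properties on random fields, at
  0.1 and 0.01 Gy bins).
* $V_{d\,Gy}$ interpolates linearly between edges (no plateau issue
  arises on the volume axis, and at bin edges the value is an exact
  voxel count).
* Covered volumes for CN and GI ($V_{ref}$, $V_{100\%}$, $V_{50\%}$)
  are **exact voxel counts over the whole grid**, not DVH reads: the
  defining expressions are total covered volumes, including dose
  spilled outside any structure.

Plans are normalized so 100% of the prescription covers 95% of the
PTV: the scale factor is $rx / D_{95\%}$ with $D_{95\%}$ taken from
the raw-voxel order statistic, so the post-condition holds exactly on
the voxel grid. CN, HI, GI then follow their definitions; CN is 0
when nothing reaches prescription, GI errors when $V_{100\%}$ is
empty.

## Paired comparison

Groups are compared with the paired Wilcoxon signed-rank test. Zero
differences are dropped before ranking (the original convention —
the software stack behind the reference tables does not document its
choice, so the classical one is used and stated); tied absolute
differences get average ranks. For $n \le 25$ the two-sided p-value
is exact: the distribution of $W^+$ over all $2^n$ sign assignments
is built by dynamic programming over doubled ranks (integers even
with half-ranks from ties), and the smaller tail is doubled, capped
at 1. This matters because the stock exact routines decline ties and
zeros, falling back to the normal approximation exactly where a
10-patient cohort lives. Above $n = 25$ a normal approximation with
continuity and tie corrections takes over; the suite checks it stays
within 0.01 of the exact tail at the crossover. Mean ± SD tables use
the $n-1$ SD; each pair is tested at α = 0.05 with no multiplicity
correction, mirroring the conventional reporting (a Holm option
exists, off by default). Percent reductions are
$100\,(\bar{x}_{ref} - \bar{x}_{cmp})/\bar{x}_{ref}$, rounded
half-away-from-zero to one decimal in reports (banker's rounding
would corrupt printed values like 26.05 → 26.0 vs 26.1).

## The synthetic cohort

The generator emulates the study design the package targets: 10
patients, three paired plans each at increments 30°/30° (A), 15°/15°
(B), 30°/15° (C), 70 Gy in 35 fractions, dual full 360° arcs,
collimator 45°/315°, anatomies sampled uniformly within the envelope
of the shipped head-and-neck table (`hn_anatomy()`: PTV 323–771 cc;
spinal cord, brain stem and parotid volumes and center-to-center
distances). All randomness flows from one integer seed through a
fixed splitting scheme (documented in the cohort manifest), so every
plan and phantom regenerates bit-identically.

**Plans.** Control points sit every 3° (the spacing must divide both
increments; 2° would not divide 15°, and 3° is within the clinically
typical 2–4° range). The base aperture is a static rectangle whose
area equals the target's circular projection $\pi R^2$ — rectangular
rather than elliptical on purpose, because the no-modulation limit
MCS = 1 requires zero leaf-position spread per bank. On top of it,
each leaf draws a sweep amplitude and sign per bank and follows a
triangle carrier with vertices at the sector boundaries: monotone
travel within each sector, reversal at each interior boundary. The
amplitude scales with `modulation_level` (default 0.5) *and* with
$\sqrt{30/\mathrm{increment}}$, encoding that a finer sector split
gives the optimizer more freedom to modulate; this is what makes
15°/15° plans measurably more complex than 30°/30° ones at equal
settings (a property the tests assert as a sign, not a magnitude —
absolute MCS values are optimizer-specific and are not matched).
Segment weights jitter lognormally with the same level; amplitudes
are capped at 0.85 of the half-width so opposing leaves never cross.

**Dose phantoms.** Doses are analytic fields, not beam transport: the
spherical PTV receives the prescription modulated by a smooth
three-axis sinusoidal ripple (relative amplitude 0.03, wavelengths
35–55 mm, phases drawn per patient so the three paired plans share
them), and outside the PTV the dose falls off exponentially in the
radial distance with a group-specific length $\lambda$: 33 mm (A),
30 mm (B), 23 mm (C). These defaults were fixed from sphere-geometry
arithmetic on the anatomy table: $\lambda_A$ puts the gradient index
near 3, and $\lambda_C$ sizes the mean group-C spinal-cord
$D_{0.03cc}$ reduction into the low-20% range for typical cord-edge
margins (the realized value varies with the anatomy draw, roughly
12–22% across seeds, since each patient contributes
$1-e^{-m\,\Delta}$ in its own margin $m$). Plan-level noise enters as
lognormal jitter on $\lambda$ (σ = 0.08) and on global output
(σ = 0.03). Organs that would overlap the PTV sphere are pushed to
tangency (distances resampled within the table range first). Phantoms
evaluate either on one full grid covering all structures (needed for
CN/GI, which integrate the whole dose field) or on per-structure
bounding boxes (sufficient for organ dose metrics and ~50× cheaper —
the 200-replicate recovery study uses this path with the PTV and
spinal cord only).

**What passing tests do and do not show.** The phantom family is
radially symmetric, noise is stationary and lognormal, apertures are
singly connected per control point, and dose is decoupled from the
MLC sequence (group effects are injected through $\lambda$, not
computed from apertures). Green tests therefore demonstrate that the
*metric pipeline* — parsing, geometry, DVH extraction, normalization,
exact testing, aggregation — is correct and that effects of known
size survive it undistorted; they say nothing about any optimizer's
actual dosimetric behavior, deliverability, or the absolute
complexity values real plans would score.

## Problem sizes and runtime

Defaults used by the shipped tests: full phantoms on ~4M-voxel grids
(2 mm spacing), cohort runs at 1–3 patients for end-to-end checks,
the oracle sweeps at 100 random 5³–9³ grids, the signed-rank
enumeration up to $n = 12$ (4096 patterns), and the recovery/power
study at 10 patients × 200 noise replicates on bounding-box grids.
The full suite runs in a couple of minutes on one core.

## Known limitations

* DICOM support is deliberately narrow: RT Plan only, explicit VR
  little endian, MLCX; no RT Dose / RT Structure Set import (dose
  grids and masks enter as arrays or via the generator).
* Binary voxel-center masks: no partial-volume weighting, so very
  small structures on coarse grids quantize (D$_{0.03cc}$ on a 2 mm
  grid reads a ~4-voxel tail).
* The fixed-width MLC model ignores leaf-end curvature, tongue-and-
  groove, interdigitation limits and jaw tracking.
* `percent_reduction()` presumes a positive reference mean; metrics
  that can legitimately be negative need the full-precision tables.
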