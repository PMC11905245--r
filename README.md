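# vmatmetrics

Plan-quality and MLC-complexity analysis for dual-arc VMAT treatment
plans, in R.

In volumetric-modulated arc therapy (VMAT) the optimizer splits each
360° gantry rotation into *arc sectors*; the multi-leaf collimator
(MLC) reverses its sweep direction at every sector boundary, so the
sector width (the *arc increment*) controls how much aperture
modulation a plan can carry. Medical physicists comparing increment
choices — e.g. dual arcs at 30°/30°, 15°/15° or a mixed 30°/15° for
head-and-neck treatments — need two families of numbers per plan:

* **dose-volumetric indices** from the 3-D dose and structure masks:
  near-maximum dose D<sub>0.03cc</sub>, mean dose D<sub>mean</sub>, and
  the PTV's conformity number, homogeneity index and gradient index

  CN = (V<sub>T,ref</sub>/V<sub>T</sub>) · (V<sub>T,ref</sub>/V<sub>ref</sub>),  HI = (D<sub>2%</sub> − D<sub>98%</sub>)/D<sub>50%</sub>,  GI = V<sub>50%</sub>/V<sub>100%</sub>

* **MU-weighted aperture-complexity metrics** from the control-point
  MLC sequence: the modulation complexity score

  MCS<sub>arc</sub> = Σ<sub>i</sub> (AAV<sub>i</sub>+AAV<sub>i+1</sub>)/2 · (LSV<sub>i</sub>+LSV<sub>i+1</sub>)/2 · MU<sub>i,i+1</sub>/MU<sub>arc</sub>,  MCS<sub>v</sub> = (1/K) Σ<sub>k</sub> MCS<sub>arc,k</sub>

  (leaf-sequence and aperture-area variability per control point), and
  the aperture-geometry family: aperture area AA, perimeter AP,
  irregularity AI = AP²/(4π·AA), aggregated with MU weights to
  beam level (BA, BI, BM = 1 − Σ MU·AA/(MU·U) against the union
  aperture U) and plan level (PA, PI, PM).

The package computes all of these, reads plans from DICOM-RT Plan
files or a documented JSON dialect, compares paired plan groups with
exact Wilcoxon signed-rank tests (mean ± SD tables, p-values, percent
reductions), and ships a fully seeded synthetic-cohort generator —
dual 360° arcs with sector-reversal leaf kinematics plus analytic dose
phantoms with PTV/spinal-cord/brain-stem/parotid masks — so the entire
pipeline is testable without any patient data.

## Worked example

Generate one synthetic dual-arc plan (30°/15°, the mixed-increment
configuration) and compute its complexity profile:

```r
library(vmatmetrics)

plan <- generate_plan(seed = 42, increments = c(30, 15),
                      group = "C", patient_id = "SYN001")
plan
#> <vmat_plan> SYN001 / group C: 2 arc(s), 1249.2 MU, 70 Gy / 35 fx
#> <vmat_arc> 121 control points, 563.2 MU, increment 30 deg (CW), 12 sectors
#> <vmat_arc> 121 control points, 686.0 MU, increment 15 deg (CCW), 24 sectors

plan_complexity(plan)
#> <plan_complexity>
#>   MCSv = 0.2583   MU = 1249.2
#>   PA = 7855.06 mm^2 (78.55 cm^2)   PI = 6.08   PM = 0.2671
#>   arc 1: MCS = 0.2675, BA = 7857.3 mm^2, BI = 5.32, BM = 0.2426, MU = 563.2
#>   arc 2: MCS = 0.2491, BA = 7853.2 mm^2, BI = 6.71, BM = 0.2872, MU = 686.0
```

MCS<sub>v</sub> runs from 1 (static, unmodulated aperture) toward 0
for heavy modulation; note the finer 15° arc is the more modulated one
(lower MCS, higher irregularity BI). PM is the MU-weighted fraction of
the union aperture that the individual apertures fail to cover.

An end-to-end cohort run — three paired plans per synthetic patient,
dose phantoms, DVH metrics, group tables and percent reductions:

```r
spec <- cohort_spec(n_patients = 3, seed = 1)
res <- run_pipeline(run_config("simulate", spec = spec,
                               output_dir = "run1"))
red <- res$reductions
red[red$metric %in% c("GI", "spinal_cord_D0.03cc_cGy",
                      "parotid_L_Dmean_cGy"), ]
#>                     metric vs_A vs_B
#> 4                       GI 19.3  8.9
#> 5  spinal_cord_D0.03cc_cGy 18.9  9.9
#> 10     parotid_L_Dmean_cGy 27.0 14.8
```

i.e. in this small simulated cohort the mixed-increment group C spares
the spinal cord's near-maximum dose by 18.9% relative to group A
(30°/30°) and steepens the dose gradient (lower GI) — the direction of
effect the generator injects via its group-specific dose falloff. The
output directory contains `plan_metrics.csv`, `dose_comparison.csv`,
`complexity_comparison.csv`, `reductions.csv` (rounded to report
precision, with `*_full.csv` companions) and a `manifest.yaml` of all
seeds; rerunning with the same spec reproduces every file byte for
byte.

Reference group means from a published 10-patient head-and-neck
comparison of these three increment groups ship with the package for
worked examples and cross-checks:

```r
ref <- reference_group_means("dose")
cord <- ref[ref$structure == "spinal_cord" & ref$metric == "D_0.03cc", ]
percent_reduction(cord$mean_A, cord$mean_C)
#> [1] 26
```

## Package layout

| file | contents |
| --- | --- |
| `R/plan-model.R` | control point / arc / plan types, validation, segment MU |
| `R/plan-json.R`, `R/dicom-rt.R` | JSON fixture dialect and DICOM-RT Plan reader/writer |
| `R/mlc-aperture.R`, `R/complexity.R` | aperture geometry and the LSV/AAV/MCS + BA/BI/BM/PA/PI/PM families |
| `R/dose-grid.R`, `R/dvh.R` | dose grids, masks, cumulative DVHs, CN/HI/GI, coverage normalization |
| `R/wilcoxon.R`, `R/group-comparison.R` | exact signed-rank test, paired group tables, percent reductions |
| `R/synthetic-cohort.R`, `R/pipeline.R` | seeded cohort/phantom generator, end-to-end runs, power study |

The methods vignette (`vignettes/vmat-plan-metrics.Rmd`) documents the
model assumptions, parameter choices and numerical conventions.
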