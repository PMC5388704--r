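# flowke

Ventricular kinetic-energy analysis for 4D phase-contrast MRI, in R.

## What this is for

4D phase-contrast (4D flow) MRI measures the three-directional velocity of
blood in every voxel of the heart across the cardiac cycle. Summing the
kinetic energy of the blood inside the ventricular segmentation,

> KE = ½ m v²,  m = V_voxel · ρ,  ρ = 1.05 g/cm³,

phase by phase yields a KE curve with a systolic (ejection) peak and one or
two diastolic (filling) peaks. In single-ventricle (Fontan) circulations —
where cardiac output is limited by ventricular filling — the shape and
magnitude of this curve track ventricular morphology and collateral flow:
short-outflow left ventricles show diastolic-dominant curves
(systole/diastole < 1), long-outflow and right-ventricular hearts
systolic-dominant ones, and significant aortopulmonary collateral (APC)
flow is associated with a diastolic KE plateau.

`flowke` is for researchers analyzing such data or prototyping such
analyses. It implements the full measurement chain:

* **Data model & I/O** — `velocity_field` / `mask_series` objects;
  NIfTI volumes + JSON sidecar reader/writer with bit-exact round trips.
* **Preprocessing** — venc-based temporal phase unwrapping, eddy-current
  compensation by first-order polynomial fits to auto-detected static
  tissue, periodic phase reconstruction (default 40 phases).
* **KE quantification** — `voxel_ke`, `roi_ke_curve`, volume-defined
  systole/diastole landmarks, systolic / early- / late-diastolic peak
  analysis with fusion and plateau detection, pattern classification, and
  indexing to stroke volume, BSA, cardiac index or vessel volume.
* **Hemodynamics** — EDV/ESV/SV/EF, plane-flow effective stroke volume,
  CO/CI, APC flow by aortic−caval or pulmonary−caval subtraction with the
  strict >25%-of-SV significance rule, vessel cross-sectional area.
* **Statistics** — exact (enumerated) Mann-Whitney U, Pearson r, Cohen's
  kappa, interobserver variability, cohort summary tables with
  small-subgroup suppression.
* **Synthetic phantoms** — uniform-flow and Poiseuille oracles with
  closed-form KE, a parameterized single-ventricle phantom realizing
  prescribed KE curves exactly, eddy/aliasing corruption injectors, and a
  two-group cohort simulator — so every stage is testable without patient
  data.

## Worked example

Generate a diastolic-dominant single-ventricle phantom, run the
preprocessing chain, and analyze its KE curve:

```r
library(flowke)

ph <- make_ventricle_phantom("diastolic_dominant", edv_ml = 120, esv_ml = 65,
                             peak_systolic_mJ = 0.9, peak_diastolic_mJ = 1.4,
                             seed = 7)
res   <- preprocess_flow(ph$field)              # unwrap, eddy-correct, 40 phases
masks <- resample_mask_phases(ph$masks, res$field)

vc <- volume_curve(masks)
#> <volume_curve> EDV 120.5 ml, ESV 65.1 ml, SV 55.3 ml, EF 45.9%

curve <- roi_ke_curve(res$field, masks)
#> <ke_curve> roi ventricle, 40 phases; peak 1.401 mJ, mean 0.3413 mJ

peaks <- analyze_peaks(curve, find_cycle_landmarks(vc))
#> <ke_peaks> systolic 0.8988 mJ @9; diastolic 1.401 mJ @27; S/D ratio 0.641; E/A fused

classify_pattern(peaks)
#> [1] "diastolic_dominant"

index_ke(peaks$diastolic_peak$value, sv = vc$sv)$ke_per_sv
#> 0.0253 mJ/ml
```

Reading the numbers: the phantom was built to volumes EDV 120 / ESV 65 ml
and peak KE 0.9 mJ (systole) / 1.4 mJ (diastole); the pipeline recovers the
volumes from the masks (120.5/65.1 ml — voxelization accounts for the
0.5 ml), finds the systolic peak at phase 9 and the early diastolic peak at
phase 27 of 40, reports the early/atrial peaks as fused (no separate
late-diastolic bump was requested), and classifies the curve as
diastolic-dominant from its systole/diastole ratio of 0.64. The peak
diastolic KE indexed to stroke volume, 0.025 mJ/ml, is the unit in which
patient groups are compared.

A cohort-level run (simulate, measure, summarize, test):

```r
res <- run_cohort(list(cohort = list(n_per_group = c(fontan = 11, control = 8)),
                       seed = 1))
res$table                     # group x morphology means ± SD
res$tests$peak_diastolic_ke_sv  # Mann-Whitney, exact for these sizes
```

A thin command-line front end covering the same chain
(`synth`, `preprocess`, `ke`, `cohort`, `run-subject`) is installed at
`system.file("cli", "flowke.R", package = "flowke")`.

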