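---
title: "Quantifying ventricular kinetic energy from 4D phase-contrast MRI"
author: "flowke"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

In a Fontan circulation a single functional ventricle drives the entire
systemic circulation while venous blood reaches the lungs passively through
the caval pathway. Because the limiting step of this circulation is
ventricular *filling*, diastolic function matters as much as systolic
function, and a natural physiological readout is the kinetic energy (KE) of
the intraventricular blood pool over the cardiac cycle: high early-diastolic
KE reflects vigorous suction-driven filling, a blunted or flattened
diastolic KE curve reflects impaired filling or competing inflow (for
example from aortopulmonary collaterals).

4D phase-contrast MRI measures the three-directional blood velocity in every
voxel of a volume covering the heart, at 14–22 acquired cardiac phases
typically reconstructed to 40. Given a segmentation of the ventricle (and of
the Fontan pathway vessels), the KE of a voxel is

$$ KE_v = \tfrac12\, m_v\, \lVert \mathbf{v} \rVert^2, \qquad
   m_v = V_{\mathrm{voxel}} \cdot \rho, $$

with $\rho = 1.05\ \mathrm{g/cm^3}$ the density of blood, and the regional
KE per phase is the sum over all voxels inside the delineation. `flowke`
implements this measurement chain end to end: data model and I/O,
preprocessing corrections, KE quantification and curve analysis, global
hemodynamics, and cohort statistics — together with synthetic phantoms that
make every stage testable against known ground truth.

Units are kept in the acquisition's own conventions (velocities in cm/s,
spacings in mm, density in g/cm³); conversion to SI happens exactly once,
inside `voxel_ke()`, which reports millijoules. For one voxel of
$8\ \mathrm{mm^3}$ at $100\ \mathrm{cm/s}$:
$\tfrac12 \cdot 8.4\cdot10^{-6}\,\mathrm{kg} \cdot (1\,\mathrm{m/s})^2
= 4.2\cdot10^{-3}\ \mathrm{mJ}$.

## Data model

A study is a `velocity_field` (a 5-D array: phase, x, y, z, component, in
cm/s) with `phase_times` spanning exactly one RR interval and a
`flow_metadata` record (venc, voxel spacing, phase counts, RR/heart rate,
BSA, blood density). Masks are per-phase integer label volumes
(`mask_series`) over the vocabulary background / ventricle / SVC /
IVC tunnel / LPA / RPA / aorta plane; a voxel belongs to a region iff its
label matches (voxel-center semantics), so the physical volume of a region
is its voxel count times the voxel volume. On disk a study is three
NIfTI scalar volumes (one per component, written as doubles so round trips
are bit-exact) plus a JSON sidecar; masks are integer NIfTI with a JSON
label dictionary. The sidecar dialect is this package's own — scanner
export formats vary, and committing to one vendor dialect would not make
the analysis more faithful. Single-phase masks are broadcast to all phases
with a message rather than rejected, because time-averaged cine-derived
segmentations are a common input.

## Preprocessing

Three corrections run in a fixed order — unwrap, eddy-correct,
reconstruct — chosen so that the eddy fit sees wrap-free static tissue and
the temporal interpolation sees jump-free series.

**Phase unwrapping** (`unwrap_velocity`). Velocities beyond the encoding
limit venc alias by multiples of $2\,\mathrm{venc}$. Unwrapping is 1-D
temporal per voxel and component: phase 1 is trusted, and each step to the
next phase is shifted by the multiple of $2\,\mathrm{venc}$ that minimizes
it. This equals the total-variation-minimizing assignment (each step's
shift is independent in the difference domain) and recovers injected wraps
exactly whenever the true inter-phase steps stay below venc — in practice,
speeds up to roughly $1.8\times$ venc at ordinary temporal resolutions.
Spatial unwrapping is not attempted; with a volumetric time series the
temporal criterion is the simplest method consistent with the physics, and
the tests state its recoverability condition explicitly.

**Eddy-current compensation** (`correct_eddy_currents`). Residual eddy
currents leave spatially smooth, nearly static velocity offsets. Following
common practice, a first-order polynomial (offset + linear terms in x, y,
z, gradients per mm so that fits are spacing-invariant) is least-squares
fitted per component to the *time-averaged* velocity over static tissue and
subtracted from every phase. One fit per component — rather than per-phase
fits — is the noise-robust reading of a "first-order polynomial fit to
stationary tissue". Static tissue is auto-detected
(`detect_static_tissue`): a voxel qualifies when each component's temporal
SD is below 5% of venc and its temporal-mean speed is below 10% of venc;
the thresholds scale with venc because both noise and flow signals do.
Least squares is exact on data in its model class, so injected planes on
noise-free fields are recovered to numerical precision; on real data the
residual RMS over static voxels is reported. Degenerate (coplanar) static
sets raise a rank-deficiency error rather than returning an unstable fit.

**Phase reconstruction** (`reconstruct_phases`). Retrospectively gated
acquisitions are conventionally reconstructed to 40 phases. The package
uses periodic linear interpolation in cycle time; whether a scanner used
linear, sliding-window or view-shared reconstruction is generally not
recoverable from the data, and linear interpolation is the choice made
here. Its error is the classical $h^2 f''/8$ bound — about 1.2% of
amplitude for a sinusoid sampled at 20 phases — and aligned output grids
reproduce the input exactly. Masks are categorical and are resampled by
cyclic nearest-phase lookup (`resample_mask_phases`).

## KE curve analysis

The systole/diastole split comes from the ventricular *volume* curve, not
from KE morphology: end-diastole is the volume maximum (cycle start),
end-systole the minimum, ties to the earliest phase. This is the
physiological standard and keeps the split independent of the quantity
being analyzed.

`analyze_peaks` reports, over the volume-defined windows:

* the **systolic peak** — the KE maximum over the ejection window;
* the **early diastolic (E-type) peak** — the first interior local maximum
  of the filling window;
* a **late diastolic (atrial, A-type) peak** — a second local maximum in
  the final 30% of diastole, separated from the early peak by a trough at
  least 10% below the smaller of the two; if no such peak exists the E and
  A waves are reported as *fused*, which is the expected state at high
  heart rates;
* a **diastolic plateau** flag — KE range over the central 50% of diastole
  below 15% of the diastolic peak, the curve shape associated with
  significant aortopulmonary collateral inflow;
* the **systole/diastole ratio**, on which `classify_pattern` divides
  curves into systolic-dominant (ratio > 1, the right-ventricular,
  long-outflow type) and diastolic-dominant (ratio < 1, the short-outflow
  left-ventricular type).

The published descriptions of fusion and plateau are qualitative; the
quantitative stand-ins above (final-30% window, 10% trough, 15% flatness
band, and a 5% minimum peak height that keeps boundary tails and numerical
ripples from counting as peaks) are this package's own calibration. All are
explicit arguments and are recorded in the returned object.

Indexing (`index_ke`) divides peak or mean KE by stroke volume (the
primary, body-size-robust denominator), body surface area, cardiac index,
or — for vessel segments — the time-averaged segment volume, which is the
stable reading of "volume of the vessel part" when masks are traced per
phase. The CI indexing is implemented as the printed quotient
mJ/(l/min/m²); dimensional interpretation of that ratio is left to the
reader, as it is in the clinical literature.

## Hemodynamics

`volume_curve` derives EDV/ESV/SV/EF (and EDVI/ESVI given BSA) from the
masks; `plane_flow` integrates through-plane velocity times pixel area over
a closed cycle (trapezoidal rule) for effective stroke volume — the caller
must declare the positive flow direction explicitly, since a silent sign
convention is the classic source of reversed flows. `cardiac_indices` gives
CO and CI. `apc_flow` quantifies aortopulmonary collateral flow per beat by
subtraction — aortic SV minus caval volume, or pulmonary venous minus caval
volume when aortic flow is unavailable — with the fraction expressed
relative to the minuend and a *strict* >25% significance rule. Negative
differences are floored at zero with a warning: they arise from measurement
noise, and an error would make routine batch processing brittle. The
pulmonary-venous method mirrors the aortic method's denominator convention;
the source description does not state which denominator was used in that
arm, and using the minuend keeps the two methods exactly consistent under
flow conservation.

## Statistics

Group differences use the Mann-Whitney U test (`mann_whitney`). For
tie-free samples with $\min(n) \le 8$ (or $n_1 n_2 \le 200$) the two-sided
p is exact: twice the smaller tail of the enumerated U null distribution,
capped at 1. Larger or tied samples use the normal approximation with tie
correction and continuity correction, and exact mode refuses tied data
outright — enumeration without ties is the only well-defined case. The test
suite checks the exact branch against brute-force enumeration over all
$\binom{N}{n_1}$ rank assignments for every split with $N \le 12$.
Correlations are Pearson's r with the t-transform p
(`pearson_correlation`); agreement between categorical ratings uses
unweighted Cohen's kappa (`cohens_kappa`); interobserver agreement is
summarized as mean ± SD of paired percent differences
(`interobserver_variability`). Subgroup comparisons below a minimum n
(default 5 per group) are suppressed with a notice instead of a p-value —
underpowered subgroup p-values invite overinterpretation.

## Synthetic phantoms and what they do (and do not) show

Because clinical 4D flow studies are not redistributable, the package ships
generators whose ground truth is known by construction:

* `make_uniform_phantom` — identical velocity in every ROI voxel;
  KE $= \tfrac12 \rho V v^2$ in closed form. The oracle for the
  voxel-summation chain and unit conversions.
* `make_poiseuille_vessel` — steady parabolic profile in a cylinder;
  continuum KE $= \tfrac12 \rho (v_{max}^2/3) \pi R^2 L$. The oracle for
  vessel-segment KE and discretization behaviour: at 1 mm spacing the
  voxelized sum sits within 3% of the continuum value and the error
  shrinks monotonically under refinement.
* `make_ventricle_phantom` — an ellipsoidal ventricle whose volume follows
  a single-minimum filling/ejection curve and whose voxel velocities are a
  fixed cross-axis Gaussian jet profile rescaled each phase so the
  ROI-summed KE *equals* a prescribed two-peak or plateau template. The
  template's peak centers snap to the sampled phase grid, so target peak
  amplitudes are attained exactly. This realizes KE-level ground truth
  without solving flow physics: the jet is kinematic, not divergence-free,
  and no pressure field exists. The plateau template holds mid-diastolic
  KE within ±7.5% of the early peak for over a quarter of diastole.
* `inject_eddy_offset` / `inject_aliasing` — corruption injectors that are
  exact inverses of the corrections (same coordinate convention, same wrap
  arithmetic), enabling recovery tests.
* `cohort_spec` / `cohort_params` / `simulate_cohort` — a two-group study
  simulator drawing per-subject peak KE/SV targets, morphology, heart
  rate, body size, volumes and APC fraction from group distributions. The
  defaults mirror a Fontan-vs-control design (11 vs 8 subjects; Fontan
  KE/SV 0.036 ± 0.018 systolic / 0.028 ± 0.010 diastolic, control LV
  0.048 ± 0.012 / 0.058 ± 0.010 mJ/ml; venc 100 cm/s; 2–3 mm voxels;
  14–22 acquired phases reconstructed to 40). KE/SV draws are realized
  against the discretized stroke volume of the generated masks, so the
  measured index equals the drawn truth without discretization bias.

Passing tests on these phantoms demonstrate that the measurement chain is
*correct as software*: unit conversions, summation, windowing, peak logic,
statistics. They do not demonstrate robustness to what real data add —
partial-volume and segmentation error at the endocardial border, spatially
correlated velocity noise, background phase errors beyond first order,
intra-voxel dephasing, or motion between the cine segmentation and the 4D
flow acquisition. Conclusions about those effects require real
acquisitions.

## Numerical and design choices

* Velocities stay in cm/s in memory; SI conversion happens only inside
  `voxel_ke`. Gradients of the eddy fit are per mm; both injector and fit
  use voxel-center coordinates (0-based index × spacing), so recovery is
  exact rather than merely close.
* Aliasing injection maps into $[-\mathrm{venc}, \mathrm{venc})$ via the
  modulo form, which is the wrap arithmetic with a well-defined boundary;
  it is idempotent on its output range.
* Tie-breaks: volume extrema to the earliest phase; equal-valued plateau
  runs count once, at their first sample; a systole/diastole ratio within
  $10^{-6}$ of 1 is an explicit indeterminate error, not a silent class.
* Degenerate inputs error early and name the offending axis, phase, label
  code or denominator: component volumes with mismatched extents, masks
  with out-of-vocabulary codes, empty static-tissue sets, constant volume
  curves, nonpositive indexing denominators.
* All generators are deterministic under a seed, and `run_subject` /
  `run_cohort` reproduce byte-identical numeric outputs from the same
  config and seed. Cohort-scale simulation synthesizes, measures and
  discards subjects one at a time so memory stays flat in n.
* Desk-scale problem sizes: phantom grids default to 32³ voxels with 20
  acquired phases (24³ for cohort simulation), which keeps a 100-per-group
  cohort — the size used for the parameter-recovery validation — in the
  minutes range on one core while leaving every stage's behaviour
  unchanged.

## Known limitations

* The eddy fit is first-order; higher-order background phase errors pass
  through uncorrected (scanner-side Maxwell-term compensation is assumed
  upstream).
* Temporal unwrapping cannot recover wraps when the true velocity jumps by
  more than venc between consecutive phases, and it trusts phase 1.
* The ventricle phantom prescribes KE, volume and pattern, not fluid
  dynamics; it cannot validate flow-pattern claims (vortices, flow
  components), only the measurement chain.
* Effective stroke volume from aortic plane flow and volumetric SV from
  masks are both available, but the pipeline indexes KE to the volumetric
  SV; with real (leaky or shunted) circulations the two differ and the
  choice should be made per study.
* Statistical helpers implement the small-cohort toolbox
  (rank tests, kappa, Pearson r) only; no modeling.
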