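---
title: "Quantitative CVR from dual-echo ASL/BOLD and phase-contrast MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative CVR from dual-echo ASL/BOLD and phase-contrast MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvrquant)
```

## The measurement model

Cerebrovascular reactivity (CVR) is the fractional change of a
hemodynamic signal per mmHg of end-tidal CO2 (EtCO2). The experiment
this package models is a step hypercapnia protocol: a 10-min dual-echo
pCASL acquisition (TR 4.006 s, 150 volumes, alternating control/label)
with the inspired gas switched from room air to 5% CO2 at 4 min, plus a
30-s phase-contrast (PC) scan of the superior sagittal sinus (SSS)
before and after, and a continuous capnograph recording throughout.

Three CVR readouts are computed from the same quotient

$$\mathrm{CVR} = 100\,
  \frac{(S_\mathrm{HC}-S_\mathrm{RA})/S_\mathrm{RA}}
       {\mathrm{EtCO2}_\mathrm{HC}-\mathrm{EtCO2}_\mathrm{RA}}
  \quad [\%/\mathrm{mmHg}],$$

where $S$ is, respectively, the perfusion-weighted (ASL) signal, the
BOLD signal, or the SSS blood flux, and the room-air (RA) and
hypercapnic (HC) epochs are the first and last 4 min of the scan — the
middle 2 min are discarded because the physiology is not at steady
state during the transition. Epoch windows are half-open $[t_0, t_1)$
and a volume's acquisition time is its start time (index × TR); both
conventions are arbitrary but fixed, so they are testable.

Basal cerebral blood flow follows from the normocapnic flux:

$$\mathrm{CBF} = \frac{\mathrm{Flux}_\mathrm{RA}}
  {V_\mathrm{brain}\cdot 1.06}\cdot 100 \cdot \frac{1}{0.46}
  \quad [\mathrm{ml}/100\mathrm{g}/\mathrm{min}],$$

with 0.46 the fraction of whole-brain flow drained by the SSS and
1.06 g/ml the mass density of brain tissue. Both constants are fields of
`quant_constants()` and can be overridden.

## Time-series processing

The dual-echo series is split into its echoes. Echo 1 (TE 13 ms) is
ASL-weighted; echo 2 (TE 30 ms) is BOLD-weighted. After a
motion-correction hook (`motion_correct()`, deliberately a pass-through:
synthetic subjects are motion-free, and in vivo realignment belongs to a
registration tool upstream) and volume-wise Gaussian smoothing
(FWHM 4 mm, per-axis in mm so anisotropic voxels are handled correctly),
two surround operators resolve the control/label alternation at full
temporal resolution:

- `surround_subtract()`:
  $\Delta M_i = \pm\left(s_i - \tfrac{1}{2}(s_{i-1}+s_{i+1})\right)$,
  signed so that control − label is positive. The symmetric two-neighbor
  form was chosen over pairwise subtraction because any purely linear
  drift cancels exactly at interior time points and the output keeps all
  150 samples; endpoints fall back to the single available neighbor and
  are the only drift-sensitive samples.
- `surround_add()`:
  $B_i = \tfrac{1}{2}\left(s_i + \tfrac{1}{2}(s_{i-1}+s_{i+1})\right)$,
  which cancels the labeling contamination of the BOLD echo exactly on
  alternating input while blurring a step by at most one sample.

ROI summaries (whole brain, GM, WM) are unweighted mask means of the
smoothed series; the whole-brain analysis mask is segmented from the
smoothed mean echo-1 image (threshold 0.25 × 98th percentile, largest
6-connected component). Whether segmentation should precede or follow
smoothing is genuinely open; we segment on the smoothed image and expose
`wb_from_data = FALSE` to use a supplied mask instead.

The canonical ROI CVR is *time-course first*: mask-mean series → epoch
means → quotient. Under noise this differs from averaging a voxelwise
CVR map over the ROI (the quotient is nonlinear, and low-SNR ASL voxels
can even have non-positive baselines); both orders are available
(`roi_cvr()`, `make_cvr_map()` + `map_roi_mean()`) and agree in the
noiseless linear case. Map voxels with non-positive room-air baseline
are masked out and counted, never clipped — CVR is undefined there.

## EtCO2 extraction and alignment

End-tidal values are per-breath summaries of the capnograph waveform.
Breaths are segmented as runs of samples above 50% of the trace's
robust maximum (98th percentile, rejecting inspiratory troughs and
cardiogenic ripple); within each breath the end-tidal value is the mean
over the alveolar plateau (samples within 98% of the breath maximum)
and the breath time is the plateau centroid. Averaging the plateau
rather than taking the single maximum sample matters: the maximum of a
noisy plateau is upward-biased and jittery, and that jitter propagates
directly into the lag search.

Alignment models the brain as following the lung with a nonnegative
delay: for each candidate lag $L \in \{0, 1, \dots, 60\}$ s the
breath-wise series is linearly interpolated onto the BOLD time grid at
$t - L$ (nearest-value extension at the edges) and Pearson-correlated
with the whole-brain BOLD time course; the maximizing lag wins, ties
going to the smallest lag. The one-sided search reflects lung-to-brain
transit physiology; both the range and step are configurable. The
aligned series then supplies epoch EtCO2 for the 4-min ASL/BOLD windows
and the two 30-s PC scan windows with the same half-open-window
averaging.

## Phase-contrast flow

The SSS cross-section is segmented on the complex-difference magnitude
image by seeded region growing (default seed: the brightest voxel;
inclusion at ≥ 50% of seed intensity; 4-connectivity), standing in for
a manually drawn ROI — an externally drawn mask is accepted verbatim as
an escape hatch. RA and HC ROIs are grown independently (whether they
should share geometry is not determined; a shared mask can be passed to
both). Flux is ROI area × mean through-plane velocity × 60 (ml/min);
velocity is in cm/s with venous through-plane flow positive, area in
cm². Because the velocity profile is approximately parabolic, dilating
the ROI into stationary background leaves the area × mean-velocity
product nearly unchanged — flux is robust to modest over-segmentation,
which is the property that makes the manual-ROI replacement safe.

## The synthetic-subject generator

`simulate_subject()` produces the full dataset the pipeline consumes,
with every generative quantity recorded in `ground_truth_params()`:

- **Phantom**: nested ellipsoids (WB, GM shell, WM core) on a
  32 × 32 × 16 grid of 3.4 × 3.4 × 6 mm voxels — the acquisition's
  in-plane resolution, at reduced matrix size so a full subject
  simulates in seconds. The brain volume (~0.36 L) is accordingly a
  scaled-down brain. Tissue between the canonical ROIs is split into
  peri-GM/peri-WM bands carrying the reactivity of the neighboring ROI
  (at low signal amplitude), so that 4-mm smoothing cannot mix
  different CVR ratios into the GM or WM means — without this, ROI
  recovery carries a percent-level partial-volume bias by construction.
- **Physiology**: a rounded-sawtooth capnograph waveform with a flat
  alveolar plateau; the end-tidal envelope steps from `etco2_baseline`
  (40 mmHg) by `etco2_step` at the gas switch with a 20-s smoothstep
  transition. The step default of +9 mmHg is a typical 5% CO2 response;
  it is configurable, not asserted. The *trace* steps at the switch;
  the *brain* responds `lung_to_brain_lag` (default 12 s) later — this
  asymmetry is exactly the alignment problem the lag search must solve,
  with a known answer.
- **Dual echo**: echo-1 control volumes carry M0 (GM 1000, WM 750 a.u.);
  label volumes carry M0 − ΔM(t) with ΔM tissue-dependent (GM 12, WM 5
  a.u.) scaling through the true ASL CVR, multiplied by
  `labeling_efficiency_hc` once hypercapnia is established. Echo 2
  carries a fractional BOLD step through the true BOLD CVR with GM
  amplitude > WM (standing in for venous blood volume differences) plus
  a 0.5% control/label alternation for surround addition to cancel.
  Defaults inject ASL CVR 5.6 (GM) / 5.1 (WM) %/mmHg — near-equal, as
  fractional CBF reactivity shows no appreciable GM–WM contrast — and
  BOLD CVR 0.33 / 0.19 %/mmHg. Optional shared linear drift and seeded
  Gaussian noise (ASL 2, BOLD 12 a.u., i.e. single-voxel tSNR ~500 and
  ~75) come last.
- **PC pair**: an elliptical vessel (~0.57 cm²) with a parabolic
  velocity profile, discretely normalized so integrated flux equals
  `basal_flux_sss` exactly at RA and
  `basal_flux_sss (1 + PC CVR · ΔEtCO2/100)` at HC; fluxes implying
  peak velocities at or above V_enc = 80 cm/s are rejected. The default
  flux of 120 ml/min is scaled to the phantom volume to give a
  physiological basal CBF (~68 ml/100g/min).
- **Cohorts**: `make_cohort()` draws per-subject parameters from
  young/old group distributions (`cohort_effects()`: PC CVR 6.59/5.46,
  ASL GM 5.74/5.31, WM 5.27/4.86, BOLD GM 0.33/0.33, WM 0.19/0.21
  %/mmHg, basal CBF 68.2/51.5 ml/100g/min, with between-subject SDs
  recovered as SE·√n for n = 32/17), assigns balanced deterministic
  sex/site labels, and returns the truth table plus per-subject
  parameter objects; image data are simulated per subject on demand to
  bound memory. Every draw flows through one explicit seed.

What the generator does *not* emulate — head motion, cardiac and
respiratory quasi-periodic noise, bolus-arrival-time changes, velocity
aliasing, slice-profile and vendor effects, true anatomical geometry —
bounds what passing tests show: they demonstrate that the estimators
recover the assumed generative structure at realistic SNR, not that the
pipeline is robust to every artifact of in vivo data.

## Statistics

Group contrasts are OLS of the per-subject outcome on group + sex +
site indicators, reporting the group coefficient, its t statistic on
n − rank degrees of freedom, and a two-sided p. With 49 subjects and
the full covariate set the residual df is 45; constant covariates
(e.g. a single-site cohort) are dropped with a message, while genuine
collinearity is an error naming the offending column. Sex and site
enter as indicator columns (one per non-reference level). Pearson
correlation and paired t tests follow the textbook formulas (via
`stats::cor.test` / `stats::t.test`), with explicit degenerate
handling: all-zero paired differences give t = 0, p = 1; constant
nonzero differences give a signed infinite t with p = 0. Two-sided
p-values throughout, no multiple-testing correction (per-comparison
α = 0.05); group SEs are sd/√n. `summarize_cohort()` assembles the
per-modality × compartment group table and the paired PC-vs-ASL and
GM-vs-WM contrasts.

## Numerical choices and degenerate inputs

- Smoothing uses a separable truncated Gaussian (radius 3σ) with edge
  renormalization, so constants are preserved exactly; FWHM 0 is the
  identity.
- The reactivity quotient is undefined for ΔEtCO2 = 0 (error) and for
  non-positive baselines (voxels masked and tallied; ROI courses error
  only if the ROI-mean baseline itself is non-positive).
- The lag search breaks correlation ties toward the smallest lag, and
  errors when either signal is constant (undefined correlation).
- Region growing rejects seeds whose intensity is far below the vessel
  signal (< 50% of the image's robust maximum) instead of flooding the
  background; ROIs touching the image border warn.
- `epoch_etco2()` warns (not errors) when EtCO2 does not rise under the
  nominal hypercapnic window — a failed gas challenge is a data problem
  the user must see, not a crash.
- All simulation randomness passes through integer seeds; identical
  seeds give byte-identical outputs.

## Problem sizes used in the tests

The shipped tests run the full pipeline at the default 32 × 32 × 16
phantom where recovery accuracy is asserted, and at a 16 × 16 × 8
phantom for replicate sweeps (20-seed confound sweeps, 100-replicate
lag recovery); the small grid cannot geometrically resolve the
peri-tissue bands around the WM core, so tissue-recovery tolerances are
asserted only at the default geometry. Statistical calibration
(type-I error of the adjusted contrast) uses 1,000 draws of a
49-subject null cohort at the truth-table level. These sizes were
chosen so the whole suite runs in about a minute while every assertion
still measures the property it names.

## Known limitations

- The no-op motion hook and mask-as-input design mean real data must be
  realigned and segmented upstream.
- The BOLD stream inherits the step paradigm's vulnerability to scanner
  drift; the surround operators remove only what their stencils can see
  (linear drift, for the ASL stream's interior points). No nonlinear
  CO2–BOLD response model is fitted.
- PC quantification addresses the SSS only; arterial inflow, aliasing
  correction and background phase offsets are out of scope.
- Site enters as a covariate; no scanner harmonization beyond that.
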