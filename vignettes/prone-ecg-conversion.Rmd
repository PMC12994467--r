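---
title: "Converting prone-position ECGs to standard supine ECGs: methods and design"
author: "pronecg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Converting prone-position ECGs to standard supine ECGs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pronecg)
```

## The problem

Patients ventilated in the prone position (common in severe ARDS) cannot be
turned for a conventional 12-lead ECG. The practical workaround places the
precordial electrodes on the back, mirrored around the spine. Limb leads are
essentially unaffected, but the mirrored precordial leads V1–V5 see the
cardiac dipole from the opposite side of the torso: waveforms invert,
amplitudes shrink, and anterior ST-segment elevation — the signature of
anterior STEMI — can disappear from view.

The physical fact that rescues the situation is that every ECG lead is a
projection of the *vectorcardiogram* (VCG): the cardiac electrical dipole
traced as a 3-D loop. The loop is a property of the heart, not of the
electrodes, so a prone recording and a supine recording of the same heart
are two different linear projections of one underlying trajectory
$\mathbf{v}(t) = (X(t), Y(t), Z(t))$:

$$\ell_i(t) = \mathbf{a}_i^\top \mathbf{v}(t), $$

where $\mathbf{a}_i$ is the lead vector of lead $i$ in the given posture.
Reconstructing the supine ECG from the prone one is therefore, to first
order, a change of linear basis — possibly confounded by torso geometry,
which is why the toolkit also carries covariates (sex, age, height, weight,
chest and waist circumference) and a nonlinear, tree-based route.

## The three conversion routes and the hybrid

**Route 1 — direct inverse-lead regression** (`fit_direct()`,
`convert_direct()`). The mirrored geometry makes specific lead pairs
(approximately) inverse images of each other: standard V1 pairs with prone
V4, standard V4 with prone V1, standard V2 with prone V2. Each target is an
ordinary least-squares regression on its paired prone lead plus age and sex,
fitted on pooled time samples of healthy subjects. V3 and V5 are derived as
arithmetic midpoints of their anatomical neighbours
($V3 = (V2 + V4)/2$, $V5 = (V4 + V6)/2$), V6 and the limb leads pass
through unchanged (those electrodes sit at standard sites).

**Route 2 — prone ECG → VCG → standard ECG** (`fit_prone_to_vcg()`,
`convert_approach2()`). A 16-predictor linear regression (12 prone leads +
male/age/height/weight) estimates $X, Y, Z$ per sample; fixed
VCG-to-ECG transform matrices then produce the 8 independent standard leads,
and the remaining limb leads follow exactly from the Einthoven/Goldberger
identities ($III = II - I$, $aVR = -(I+II)/2$, …). Two transforms are
packaged: Dower's classic lead-vector matrix (published values) and a
regression-style alternative in the "Uijen" slot. Per-lead selection uses
Dower for V3 and the Uijen slot elsewhere, the combination with the best
morphological agreement; the rule is overridable
(`matrix_rule = "dower"`/`"uijen"`).

**Route 3 — segment-wise tree ensembles** (`build_cohort_tables()`,
`train_segment_models()`). Each cardiac cycle is delineated and split into
three windows — P-R `[p_onset, qrs_onset)`, QRS `[qrs_onset, qrs_offset)`,
ST-T `[qrs_offset, t_offset)` — and each window is piecewise-linearly
time-normalized to a fixed length (50 / 60 / 200 points at 500 Hz). One row
of the feature table is one normalized time point: 12 prone-lead amplitudes
plus the 6 covariates (18 features) predicting the standard-lead amplitude
at the matched point. One model is fitted per target lead (V1–V5) and
segment — 15 per bundle — as either a random forest (500 trees, `mtry = 6`,
the regression default $p/3$ for 18 features) or gradient-boosted trees
(`eta = 0.1`, `max_depth = 2`, `gamma = 0.001`, `colsample_bytree = 0.4`;
`nrounds` is configuration, default 500). Splitting is *participant-level*
(all cycles of a subject on one side; `participant_split()` with an
explicit leakage guard) and cross-validation is grouped by subject.

**Hybrid** (`rescale_to_reference()`, `convert_hybrid()`). The tree route
produces the best waveform morphology and the VCG route the best
amplitudes, so the hybrid rescales each lead and segment of the tree-route
beat by $s = \mathrm{ptp}_{\text{ref}} / \mathrm{ptp}_{\text{tree}}$
(peak-to-peak ratio against the VCG-route beat). The source study does not
define its "scaled combination"; per-segment peak-to-peak affine scaling was
chosen here because a positive gain provably preserves the QRS pattern
string (its case rules are amplitude-ratio based) and, away from the
absolute flat/ST thresholds, every other descriptor too, while transferring
the reference amplitude. $s$ is clamped to $[0.2, 5]$ and forced to 1
whenever either segment's peak-to-peak is below 0.05 mV; the scale profile
ramps linearly over 10 ms at segment boundaries so identical inputs pass
through untouched and no amplitude step is introduced.

## Delineation

R peaks: Pan–Tompkins-style energy detection (5–25 Hz band-pass, squared
derivative, 150 ms integration, adaptive threshold at 20% of the peak
envelope, 200 ms refractory), snapped to the band-passed extremum.
Fiducials are located on lead II (fallback V2) and applied to all leads:
QRS onset/offset where the slope magnitude stays below 5% of the beat's
maximum slope for ≥ 12 ms within ±120 ms of R; T offset by the tangent
method on the ≤ 15 Hz low-passed ST-T (for a Gaussian T lobe this lands at
centre + 2 widths, which is also how the synthetic generator defines its
ground truth); the P wave is sought in `[R − 300 ms, QRS onset)` and called
absent below a 0.05 mV deflection threshold, in which case the P-R window
falls back to a fixed 120 ms span. Amplitudes are referenced to the mean of
the P-R window; the ST level is read at J + 60 ms (clinical convention; the
source study states the measurement but not the offset). Measurements are
per cycle, not on averaged beats — how the original 590 cycles were
measured is not stated, so the per-cycle choice is the package's own.

## The synthetic cohort generator

`simulate_cohort()` is the test substrate for every downstream stage, not a
fixture: it emulates the study conditions end to end. Each subject gets one
dipole loop built from Gaussian kernels (P, Q, R, S, T; per-wave amplitude,
width, centre, and a fixed 3-D direction), and that *identical* loop is
projected through a supine and a prone lead field — the generator's core
physical premise, and the recovery oracle for the linear routes: with
`noise_sd = 0` every lead is an exact linear function of $(X, Y, Z)$.

* The supine field is the Dower/Uijen composite the VCG route assumes, so
  route 2 is exactly consistent by construction.
* The prone field keeps limb rows identical and replaces precordial rows
  with a stylized mirrored-back geometry: prone V1/V4 are attenuated
  (× 0.8), sign-flipped images of supine V4/V1; prone V2 a sign-flipped,
  attenuated (× 0.85) image of supine V2; prone V3 the midpoint of prone V2
  and V4; prone V5 an attenuated lateral mix; prone V6 unchanged. No
  quantitative prone lead-field geometry has been published; this matrix is
  a clearly-labelled stylized stand-in, and nothing downstream depends on
  its exact values — only on its structure (sign flips, attenuation,
  posture-invariant limb rows).
* Defaults reproduce the development-cohort conditions: 70 subjects, 590
  cycles in total (7–10 beats per subject, adjusted to the total), 10 s
  records at 500 Hz, a diagnosis mix matching the development-cohort class
  counts (24 Normal, 7 ST-elevation, 8 old MI, 11 ST-depression, 4 CLBBB,
  11 CRBBB/RBBB, 5 LAH), and covariates drawn from truncated normals
  centred on the cohort medians (height 168 cm, weight 67 kg, chest
  90.3 cm, waist 86.4 cm, 58.6% male).
* Disease classes modify the kernel table: ST elevation/depression add a
  ±ST-offset kernel between QRS and T; old MI suppresses the initial R
  forces and deepens Q (QS-type patterns); CLBBB/CRBBB widen the QRS and
  add a delayed terminal kernel (leftward or rightward-anterior — rSR′-type
  right precordial patterns); LAH rotates the QRS loop in the frontal
  plane.
* `noise_sd` (default 0.02 mV, a realistic baseline-noise scale for resting
  ECG) adds independent Gaussian noise per lead; between-subject lognormal
  variation (sd 0.12) scales kernel amplitudes, and per-beat jitter
  (sd 0.03) varies beat size without changing loop shape.

What the generator does *not* emulate: respiration and motion artefacts,
electrode-placement variability, beat-to-beat fiducial jitter, non-sinus
rhythm, and any real torso volume-conductor effects. Passing tests
therefore demonstrate internal consistency and exact-recovery behaviour
under the model's own physics, not clinical-grade accuracy on real prone
recordings — the clinical cohort of the source study is not redistributable,
so its headline external-validation figures are used only as *floors* that
the noise-free synthetic refits must meet or exceed.

```{r cohort-example}
cohort <- simulate_cohort(cohort_config(n_subjects = 6, total_beats = 48,
                                        noise_sd = 0, seed = 42))
cohort
model <- fit_direct(cohort)
model$models$V4$r2   # exact linear recovery on noise-free data
```

## Numerical choices

* **Units and rate.** Millivolts and 500 Hz are canonical; readers convert
  (µV → mV, header gain for WFDB) and `resample_record()` harmonizes rates
  by FFT band-limited resampling (ringing confined to record edges; the
  packaged tests hold it to < 1e-3 mV mid-record on band-limited content).
* **Rank deficiency.** With `noise_sd = 0` the 12 prone leads span only the
  3-dimensional dipole space, so the 16-predictor design of route 2 is
  rank deficient by construction. Fits use the SVD pseudoinverse
  (minimum-norm solution) and warn; predictions and $R^2$ are unaffected.
* **Time normalization lengths** (50/60/200) are artifact choices roughly
  matching typical segment durations at 500 Hz (100 ms / 120 ms / 400 ms);
  the source study does not state how samples were aligned between the
  non-simultaneous prone and standard beats.
* **Beat pairing.** Prone and reference recordings are sequential, so beats
  are paired by index after R-peak synchronization; route 3 pairs each
  prone beat with the subject's representative (middle) standard beat.
* **QRS case rule.** A lobe is upper case iff it is the dominant lobe or
  strictly exceeds half the dominant amplitude — the strict inequality
  makes the boundary case (exactly half) lower case, matching the worked
  nomenclature examples (0.5/−0.3/0.6 → "RsR′").
* **Hard-label AUC.** Expert diagnoses are categorical, so the ROC has a
  single operating point and the AUC is the trapezoid
  $(\text{sens} + \text{spec})/2$; numeric scores use the Mann–Whitney rank
  statistic. Bootstrap CIs resample *subjects* (percentile method, the CI
  method in the source being unstated), respecting within-subject
  correlation.
* **Seeds.** Every stochastic step (simulation, noise, splits, tree
  training, bootstrap) takes an explicit seed and restores the caller's RNG
  state; `ranger` and `xgboost` run single-threaded for bit
  reproducibility.

## Known limitations

* The Uijen transform slot ships a synthetic stand-in (pseudoinverse of the
  Kors ECG→VCG regression matrix) because the genuine Uijen coefficients
  are not redistributable here; replace via `transform_matrix(values = )`
  for production use.
* The packaged clinical coefficient table (`table2_model()`) has unknown
  predictor scaling and no intercepts; it is flagged `scale_unknown` and
  excluded from amplitude-accuracy claims. Freshly fitted models are the
  validated path.
* Morphology preservation under hybrid rescaling is exact for the QRS
  pattern (ratio-based rules) but threshold-based wave classes can change
  if a deflection crosses the 0.05 mV flat threshold or the ST thresholds
  during amplitude transfer; the clamp and floor keep this rare.
* The delineator is a conventional rule-based design adequate for sinus
  rhythm; ectopy and arrhythmia are out of scope (the study design excludes
  non-sinus rhythm).

## Problem sizes used by the packaged checks

Unit and property tests run on cohorts of 4–12 subjects (32–100 cycles).
The acceptance script and the corresponding test block refit on full-size
noise-free cohorts (70 subjects, 590 cycles — about 2 × 10^5 pooled samples
for the linear routes and ~2.8 × 10^4 QRS rows for the tree route), sizes
chosen to mirror the development-cohort conditions while remaining
desk-scale.
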