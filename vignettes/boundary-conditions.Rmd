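---
title: "From in vivo implant kinematics to joint-simulator boundary conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From in vivo implant kinematics to joint-simulator boundary conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneebc)
```

## The problem

Six degree-of-freedom knee joint simulators evaluate total knee
arthroplasty (TKA) components by driving an implanted (cadaveric or
fixtured) knee through activities of daily living. Historically the
command profiles came from standardized sources measured on healthy,
non-implanted knees. A more faithful alternative is to derive the
profiles from in vivo measurements of the *same* implant system:
fluoroscopically measured femoral condylar low-point kinematics,
telemetric tibiofemoral (TF) compression, and musculoskeletal-model
quadriceps forces. Because displacement control is brittle when specimen
alignment and compliance vary, the displacement profiles must be
converted into *load-controlled* profiles that reproduce the same
low-point kinematics. `kneebc` implements that conversion pipeline, the
kinematic machinery underneath it, and the statistics used to verify
the resulting knee kinematics, exercised end-to-end on synthetic data.

## Coordinate and sign conventions

Everything assumes a right knee; left knees are mirrored at ingestion
(the source data do not state handedness conventions, so the package
fixes its own and documents them). Anatomical frames are x anterior,
y superior, z lateral. The Grood–Suntay joint coordinate system uses
the femoral medial–lateral axis as the fixed flexion axis, the tibial
long axis as the fixed internal–external axis, and their normalized
cross product as the floating anterior axis. Angles: flexion positive,
adduction positive, internal tibial rotation positive. Translations are
the components of the tibial origin in the (non-orthogonal) JCS basis,
which makes `jcs_from_poses()` and `poses_from_jcs()` *exact* mutual
inverses away from gimbal lock (|Ad–Ab| → 90°; flagged above 80°,
rejected at 90°). Condylar low points are reported in the tibial tray
frame with anterior and medial positive.

## Low points and the transverse-plane transform

The condylar low point is the point of each femoral condyle closest to
the tibial tray plane; its anterior–posterior (A-P) excursion
summarizes condylar sliding. `low_points()` extracts it from a posed
component mesh by a per-condyle vertex minimum over signed height,
split at a sagittal plane placed at the medial–lateral midpoint of the
component (the split location is a parameter; the source workflows do
not define it). The pair of condylar A-P translations maps to the joint
I-E rotation and A-P translation as

* `ie = atan2(medial_ap - lateral_ap, intercondylar_distance)`
* `ap = (medial_ap + lateral_ap) / 2`

The unweighted midpoint was chosen for the A-P definition because it
makes the pair (I-E, A-P) exactly invertible (`ie_ap_to_lowpoints()`),
which the tuning loop relies on. Whether a published "A-P translation"
refers to the JCS origin or the low-point midpoint is generally
ambiguous; both are available here, and the midpoint is the default for
low-point-derived profiles. The intercondylar distance is an explicit
parameter (default 49 mm) since commercial implant dimensions are
proprietary.

## Waveforms and cohort averaging

A `waveform` is a unit-tagged quantity on a 0–100 % activity-cycle
grid; 101 nodes is the package default (a field convention — sampling
density is rarely reported). `average_cohort()` implements the
averaging rule used for fluoroscopic cohorts: trial mean per subject,
implant-size normalization (multiplication by `mean_size /
subject_size`, applied to translational quantities only — rotations and
loads are dimensionally size-free), then an unweighted mean across
subjects with a pointwise SD band. Loads are body-weight normalized and
rescaled to a 66 kg reference person by the mass ratio
(`scale_to_body_weight()`; a weight ratio would be numerically
identical). Stand-to-sit and sit-to-stand movements are concatenated
into one sit–stand cycle with the halves at 0–50 % and 50–100 % and the
junction set to the mean of the two endpoint values — the junction
treatment and proportions are a package choice, as sources state only
that the movements were concatenated. Gait-like cycles split into
stance and swing at toe-off, 60 % of the cycle; sit–stand splits at
50 %; the boundary node belongs to the earlier phase.

## Synthetic data: what it emulates and what it does not

The generators produce every input the pipeline needs, with the
statistical structure the analysis assumes:

* **Low-point trajectories** (`gen_lowpoint_trajectories()`): a smooth
  low-order Fourier mean shape per activity plus a per-subject smooth
  periodic deviation (random offset plus three harmonics) whose
  pointwise SD equals the requested between-subject SD — defaults
  1.2 mm medial and 1.9 mm lateral, reflecting the consistently tighter
  medial-condyle variability reported for fluoroscopic TKA cohorts.
  Half the deviation variance sits in the constant offset, the rest
  decays over harmonics.
* **Load waveforms** (`gen_load_waveforms()`): built through named
  control peaks — gait quadriceps 651 N in early stance and 271 N at
  swing initiation; stair-descent quadriceps 645/582/251 N; sit–stand
  quadriceps 660 N at peak flexion. The interpolant is a C1
  piecewise-cubic Hermite with zero slope at every control point: an
  interpolating cubic spline overshoots its control values, so a named
  peak would no longer be the waveform maximum; the zero-slope Hermite
  attains every peak exactly and never overshoots, at the cost of flat
  tangents at control points.
* **Geometry** (`gen_implant_geometry()`): spherical condyles and
  spherically dished insert troughs, returned both as watertight
  triangle meshes and as analytic parameters, so every mesh operation
  can be checked against a closed form. These are idealized carriers,
  not reproductions of any commercial geometry.
* **Tray readings and marker data**: a pseudo-inverse gain model of a
  known calibration matrix, and posed fiducials plus isotropic noise.

A single master seed fans out into per-generator substreams keyed by
subject and generator name (`substream_seed()`), so outputs are
bit-identical under a fixed seed and adding a subject does not perturb
the others. The generators do **not** emulate fluoroscopic imaging
physics, soft-tissue artifact, gap-filling of dropped frames, or real
implant surface morphology — so passing tests demonstrate the
correctness and stability of the *pipeline*, not claims about any
clinical cohort.

## Tray calibration

An instrumented tibial tray with four quadrant load cells reports S-I
force and Ad-Ab/F-E moments about the tray centroid. Calibration loads
the tray through 13 beads at known tray-plane locations with a known
axial force (default 1000 N), giving known loads per bead
(`expected_loads()`; Ad-Ab moment about the tray A-P axis = force × y,
F-E moment about the M-L axis = force × x — the axis/sign assignment is
a documented package convention). `solve_calibration()` is a
minimum-norm least squares (SVD pseudo-inverse). The minimum-norm
choice matters: axial-only bead sweeps excite only the 3-dimensional
load space, so the 4-channel regression is rank-3, and within that row
space the minimum-norm solution coincides with the true full-row-rank
gain matrix — noiseless sweeps therefore recover it to machine
precision, which the tests assert. Channel data spanning fewer than 3
dimensions is an error. No intercept is modeled (cells are zeroed
before loading); thermal drift and crosstalk nonlinearity are out of
scope.

## The virtual knee

Physical profile tuning runs against a fixtured implant in the
simulator. The package substitutes a quasi-static *virtual knee*
(`virtual_knee_params()`), an intentionally simple surrogate that is
clearly labeled as invented plumbing:

| parameter | units | default | role |
|---|---|---|---|
| `baseline_ap_stiffness` | N/mm | 15 | articular A-P restoring stiffness at zero compression |
| `ap_stiffness_per_compression` | N/mm per kN | 30 | constraint–load coupling |
| `baseline_ie_stiffness` | Nmm/deg | 400 | articular I-E stiffness |
| `ie_stiffness_per_compression` | Nmm/deg per kN | 1500 | constraint–load coupling |
| `fixture_compliance_ap` | mm/N | 0.004 | series fixture spring |
| `fixture_compliance_ie` | deg/Nmm | 2e-5 | series fixture spring |
| `dwell_ap_of_flexion` | mm (poly in deg) | (0, −0.04) | dwell line vs flexion |
| `quad_to_compression_gain_of_flexion` | – (poly in deg) | (0.30, 0.004) | extensor → TF compression |
| `pf_wrap_coefs` | rad, rad/rad | (0.15, 1.0) | tendon wrap angle vs flexion |

The articulation applies a restoring force linear in the offset from a
flexion-dependent dwell line, with stiffness increasing linearly in the
articular compression (applied S-I plus the extensor contribution
`gain(flexion) × quad`): low TF compression means low articular
constraint, the coupling that makes displacement-to-load conversion
non-trivial. The patellofemoral resultant follows a two-force-member
wrap model, `2 · quad · sin(wrap/2)`, zero at zero quadriceps force and
homogeneous in it. Defaults were chosen once so that peak articular
compression for the default activity profiles lands in the 1.5–2.5 kN
range typical of gait/stair/sit–stand — plausibility anchoring, not
reproduction of any measurement. No source publishes specimen
stiffness or compliance values, so these parameters are free and
exposed, and the tests are recovery-style rather than value claims.

Because the model is linear in the transverse displacements at fixed
compression, the per-node equilibrium has a closed form (series-spring
balance in displacement control, direct solve in load control); an
iterative per-node solver would converge to the same numbers in one
step, so the package solves directly and reports the equilibrium
residual, required below 1e-6 of the characteristic load. Quasi-statics
(no inertia) is appropriate because activities of daily living are slow
relative to the articular dynamics and simulator control is
profile-tracking. Ligament bundles, wear, viscoelasticity, post-cam
engagement, and servo-hydraulic control dynamics are out of scope.

## The displacement-to-load tuning loop

`derive_load_profiles()` reproduces the iterative conversion:

1. Run the displacement-controlled profile set; record the A-P force
   and I-E torque the tibial actuator applied.
2. Replay the recorded loads in load control; compute achieved condylar
   low points and per-condyle RMSE against the target over the full
   cycle (both condyles must individually pass; tolerance 2.0 mm).
3. While above tolerance: correct each load waveform node by
   `gain × error × stiffness`, with the stiffness estimated per node by
   a secant from the last two iterates (a probe simulation with a small
   load offset seeds the first estimate), and replay.

The physical procedure is manual iterative modification; the published
descriptions give no update algorithm, so the proportional-secant rule
(default gain 0.7, maximum 50 iterations) is this package's
reproducible formalization, and the per-iteration RMSE history is
recorded for transparency. If the worst-condyle RMSE increases, the
gain is halved once before the loop returns `converged = FALSE` (never
an exception). With zero fixture compliance the initial replay is
already a fixed point and the loop exits after one iteration — the
structural property that makes the conversion well-posed.

## Evaluation statistics

`rmse_report()` produces phase-partitioned RMSE tables (full cycle,
stance/swing or stand–sit/sit–stand) for each paired quantity.
`spm_ttest2_1d()` implements two-sample 1D statistical parametric
mapping: a node-wise pooled-variance t statistic, residual smoothness
(FWHM) estimated by the standard normalized-residual-gradient
estimator, and a two-tailed critical threshold from the 1D
random-field-theory expected Euler characteristic at the
Bonferroni-adjusted level `alpha / n_comparisons`. Choices made where
the methods literature leaves room:

* **Unpaired** two-sample tests: the in vivo and in vitro cohorts are
  different individuals.
* **Bonferroni family size is an explicit parameter** (the pipeline
  default is 4, the number of kinematic quantities compared per
  activity); published descriptions rarely enumerate the family.
* **Variance floor** 1e-12 at degenerate zero-variance nodes, flagged
  in the result.
* Clusters are maximal runs of `|t|` above the threshold;
  `percent_significant` is the fraction of suprathreshold nodes.

`permutation_maxt()` provides a distribution-free cross-check: the
max-|t| permutation threshold converges to the RFT threshold on smooth
Gaussian nulls, and the acceptance suite verifies the family-wise
false-positive rate of the RFT test on 1000 simulated null repetitions
(two groups of 10 and 15 smooth curves, FWHM ≈ 15 nodes) against
`alpha` plus two binomial standard errors.

## The pipeline and problem sizes

`run_pipeline()` chains generate → assemble (implant-specific
displacement) → tune (implant-specific load) → derive a
high-conformity-style "CAMS-like" alternative (loads tuned to a
deliberately distorted target with exaggerated anterior excursion) →
evaluate → report, writing CSV/YAML artifacts and a manifest of output
hashes for exact reruns. The demo scale is 15 synthetic in vivo
subjects × 3 trials, 10 synthetic specimens (virtual knees with
log-normal parameter jitter), 101 cycle nodes, and 3 activities —
chosen as a representative desk-scale configuration; all sizes are
config fields. By construction the implant-specific loads track the
synthetic truth better than the distorted CAMS-like variant, and the
pipeline regression test asserts exactly that, not any clinical claim.

## Numerical notes and limitations

* Rotation matrices are validated to 1e-9 (orthogonality and unit
  determinant); JCS round trips hold to 1e-9 over random states.
* ICP uses point-to-point nearest-vertex correspondence without
  trimming, suitable for the small clean clouds generated here; its
  residual history is provably non-increasing, and convergence is only
  guaranteed within the usual local capture range.
* Kabsch rejects collinear model points (rotation unidentifiable).
* The virtual knee is linear about its dwell line: it cannot express
  dwell bistability, edge loading, or post-cam engagement, so tuning
  convergence rates on real hardware will differ; the loop's contract
  (monotone RMSE, recorded history, explicit non-convergence) is the
  transferable part.
* Waveform resampling is linear; interpolation error enters RMSE
  comparisons only through the shared grid.
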