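---
title: "Methods: mitral annular geometry, kinematics, and the synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitral annular geometry, kinematics, and the synthetic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annulokin)
```

This vignette records the mathematical definitions, parameter choices, and
numerical decisions behind `annulokin`, in enough detail to re-derive every
quantity the package computes.

## 1. From crystals to a closed annular curve

Sonomicrometry arrays measure either 3D crystal positions directly or the
pairwise inter-crystal distances. For distances,
`coordinates_from_distances()` embeds each frame's symmetric zero-diagonal
matrix by classical (Torgerson) multidimensional scaling
(`stats::cmdscale`, k = 3) and requires an embedding rank of 3; each frame is
then rotated onto the previous one by orthogonal Procrustes (Kabsch SVD,
reflection permitted) so the arbitrary orientation of the embedding cannot
flip between frames. Translation is unrecoverable from distances, so every
frame is centred on its centroid — all geometry metrics below are
translation-invariant, so this loses nothing.

The eight annular points, in circular anatomical order, are interpolated by a
**closed periodic cubic spline** (`fit_closed_spline()`):

- chord-length parameterization: knot `i` sits at parameter
  `t_i = (sum of chord lengths up to i) / (total perimeter)`, which makes the
  curve independent of crystal numbering and far less prone to overshooting
  than uniform parameterization;
- per-coordinate periodic interpolation with `stats::spline(method =
  "periodic")`, giving a C²-continuous closed curve through every knot;
- M = 360 equally spaced parameter samples per frame (configurable, minimum
  64). At M = 360 the discretization error of the shoelace area of an
  ellipse is below 0.01%, far below the spline-vs-truth error of the
  8-knot fit itself (~0.02% in area, ~0.01 mm radially for a circle).

Consecutive knots closer than 0.01 mm abort the fit: coincident neighbours
make the chord-length parameterization degenerate.

## 2. Per-frame geometry

**Annular plane.** `fit_plane_and_project()` fits the total-least-squares
plane of the 360 samples (SVD of the centred sample matrix; the normal is the
right singular vector of the smallest singular value). The sign of a plane
normal is arbitrary, so it is chosen to align with the previous frame's
normal (+z for the first frame), keeping the saddle's "up" stable through the
cycle. Samples are orthogonally projected and expressed in an in-plane
right-handed basis.

**Area.** `spline_area()` is the shoelace formula on the closed, densely
sampled projected polygon. A self-intersecting projection (possible for
pathological inputs) is detected by the total-turning-angle test — a simple
closed curve turns by ±2π, a figure-eight by ≈ 0 — and flagged with a
warning rather than silently returning a meaningless signed area.

**Axes, diameters, shape indices.** `principal_axes()` eigen-decomposes the
covariance of the projected samples; the major axis is the intercommissural
(ICW) direction, the minor the septolateral (SL). Signs follow a
deterministic convention (first component of axis 1 non-negative, axis 2
completing a right-handed pair), and near-circular frames (relative
eigenvalue gap below 1e-6) are flagged degenerate and re-use the previous
frame's axes for temporal continuity. `axis_intersections()` finds the two
crossings of each axis line with the projected curve by sign change of the
perpendicular coordinate with linear interpolation, and maps them back to 3D.
ICW and SL are the **3D** Euclidean distances between those annular points
(not their planar projections); ACI = SL / ICW.

**Non-planarity angle.** NPA is the angle subtended at the axis juncture by
the anterior and posterior horns: 180° for a flat annulus, smaller as the
saddle deepens. The two diameters (horn-to-horn and
commissure-to-commissure) intersect exactly only when the annulus is planar;
on a saddle they are skew. `axis_juncture()` therefore takes the **midpoint
of their common perpendicular** (the mutually closest point of the two
chords). This choice, rather than the projected sample centroid, is
deliberate: with chord-length parameterization the uniform-parameter samples
concentrate arc length near the high horns, biasing the centroid ~0.2 mm
above the saddle mid-plane and the NPA by ~2°, while the closest-approach
midpoint reproduces the analytic saddle value `NPA = 2·atan(b/h)` to machine
precision and reduces to the chord intersection in the planar limit.

## 3. Beat segmentation and deformational kinematics

**ED/ES detection** (`detect_ed_es()`): end-diastole is the onset of the
rapid pressure rise. The pressure is smoothed (5-sample moving average), its
central-difference derivative smoothed again, and candidate EDs taken where
dP/dt crosses 10% of its maximum, with a refractory merge at half the median
beat length. Each candidate is re-thresholded within its own beat (so a
globally weak beat is not missed) and refined to the local maximum of the
volume trace within ±15% of a beat length — the lower-right corner of the PV
loop. The window is symmetric because smoothing shifts the dP/dt crossing
slightly *before* the true ED. End-systole is the volume minimum within each
ED-to-ED window; peak systole the pressure maximum. A crossing-vs-corner
disagreement above 5 samples sets a per-beat flag. On simulated records the
detector is within ±1 sample of truth across heart rates 80–160 min⁻¹ and
pressure noise up to 1 mmHg.

**Cyclical reduction** (Δr): `100·(max − min)/max` within the beat for MAA
and NPA (percent), `max − min` for ACI (absolute).

**Deformation velocity** (v̄): the mean magnitude of the time derivative over
the *descending* segments of the cycle. Descending runs (≥ 3 samples) are
located on the smoothed derivative, then anchored to the enclosing raw local
extrema. Since the mean derivative over a segment is its net drop over its
duration, v̄ = Σ(drops)/Σ(durations). The end points are refined to
sub-sample accuracy by a **kinked-parabola / V fit** (`refine_vertex`): two
one-sided quadratic branches sharing the vertex, and alternatively two
straight branches (for slope-discontinuous extrema), scanned over ±0.6
samples, choosing the model with the lower residual; a plain line fitting
equally well means no resolvable extremum and the raw sample is kept. At
117 Hz and 135 bpm a systolic descent spans only ~16 samples, so a
half-sample error in either end point is ~3% of the duration — naive
discrete extrema are not accurate enough, and a single symmetric parabola
mislocates the vertex where the waveform's curvature changes abruptly.
With this estimator the sinusoid oracle `v̄ = 2Aω/π` is matched to <0.1% and
the full simulated beat to within ~1.5% at every sampling phase.

**Normalization and aggregation**: beats are resampled to K = 100 points of
normalized time by linear interpolation (`normalize_beat()`); per-beat
scalars and curves are averaged over 3 consecutive beats with standard
errors (`aggregate_beats()`). Fractional change is relative to the previous
beat's end-systolic value; the first beat has none and gets `NA`.

## 4. Hemodynamics and contractility

Body surface area uses the porcine Kelley formula `BSA = 734·BW^0.656`,
evaluated in cm² and converted to m² (58 kg → 1.053 m²). LV volume from two
epicardial dimensions uses the ellipsoid of revolution `V = (π/6)·D²·L`
(mm³ → mL), with `correct_for_wall_thickness()` removing twice the
(phase-interpolated) equatorial wall thickness from the short axis and the
apical thickness from the long axis. Per-beat indices obey the identities
SV = EDV − ESV, EF = 100·SV/EDV, CI = HR·SV/(1000·BSA).

Contractility is the ESPVR slope over up to 10 beats of a
caval-constriction run: OLS of end-systolic pressure on end-systolic volume
(`estimate_ees()`), with V0 the volume-axis intercept. The measurement beat
for interventions (`select_state_beat()`) is the first beat with a 20% EDP
drop (ICC) or the first beat on the peak-pressure plateau (AO, consecutive
change < 2%).

Study-level inference is ordinary least squares of one kinematic metric per
subject on E_es (`regress_kinematics_on_ees()`), with r² equal to the squared
Pearson correlation and a 95% CI for the slope from the t-distribution with
n − 2 df. Repeated-measures ANOVA across states is deliberately out of scope:
the package ships descriptive state summaries and the regression only.

## 5. The synthetic ground truth

### Annulus

The generator (`simulate_annulus()`) places `n_crystals = 8` crystals at
fixed angles θ on the saddle

x = a·cosθ, y = b·sinθ, z = −h·cos2θ,

so the horns (θ = ±π/2, the SL axis) sit **high** and the commissures low.
Closed forms: MAA = πab, ACI = b/a, NPA = 2·atan2(b, h). Prescribed periodic
waveforms drive (MAA, ACI, NPA) between their end-diastolic maxima and
end-systolic minima through a C¹ piecewise-sin² beat shape `w(φ)` (rise on
[0, es_frac], recovery on [es_frac, 1]); the semi-axes follow as
`a = √(MAA/(π·ACI))`, `b = a·ACI`, `h = b·cot(NPA·π/360)`.

Defaults follow measured porcine annular dynamics: maximal MAA = 607 mm²/m²
× BSA(58 kg) ≈ 639 mm² with a 21.2% cyclical reduction; maximal ACI 0.71
with an absolute reduction of 0.12; maximal NPA 169° with a 10.3% reduction;
HR 135 bpm, sampling interval 0.00853 s (117 Hz), end-systole at 30% of the
beat. Acquisition imperfections are optional and off in the oracle tests:
slow rigid-body drift (5° rotation, 2 mm translation over a 3 s period) and
i.i.d. Gaussian positional noise (SD 0.05 mm).

### Ventricle

`simulate_pv()` is a time-varying elastance model: P(t) = E(t)·(V(t) − V0)
with a raised-cosine activation from E_min to E_max over the first
`act_frac = 0.6` of the beat. Volume follows the same `w(φ)` shape between
EDV and ESV with end-systole at `act_frac/2`, and the stroke volume is
coupled to afterload through SV = E_max(EDV − V0)/(Ea + E_max), which makes
ESP = E_max(ESV − V0) hold **exactly** — the simulated ESPVR is exactly
linear, so contractility recovery can be tested to machine precision.
Defaults: E_max = 2.66 mmHg/mL, V0 = 15 mL, EDV = 120 mL, SV = 44 mL
(EF 36.7%), EDP = 9.8 mmHg.

### Protocols

`simulate_protocol()` couples both generators on one clock
(`es_frac = act_frac/2`) and implements:

- **baseline** — constant parameters;
- **icc** (caval constriction) — EDV decays by 5% per beat; the annular area
  scales with volume^(2/3), so annular and ventricular preload responses are
  consistent; E_max is fixed, so the ESPVR stays one line;
- **ao** (aortic occlusion) — arterial elastance ramps to 2.2× baseline with
  rate 0.7 per beat (plateau within ~10 beats); the annulus dilates by up to
  10% in area and its saddle height falls by up to 30% (flattening under
  pressure load).

`simulate_study()` adds between-animal variation: per-subject E_es ~
N(2.66, 0.85²) truncated at 0.8, with the prescribed area reduction linked
linearly to E_es (slope 7.39 %-points per mmHg/mL, residual SD 3.72 —
population r² ≈ 0.74), so the study-level regression has a known recoverable
structure.

### What the generator does and does not emulate

It emulates: saddle-shaped annular geometry and its cyclical deformation,
preload/afterload intervention physiology, shared annulus-ventricle timing,
rigid-body motion, and positional measurement noise. It does **not** emulate
leaflet or subvalvular mechanics, regional (non-affine) annular deformation,
translational annular excursion relative to the ventricle, respiratory
variation, arrhythmia, or transit-time measurement error models (noise is
applied to coordinates, not distances).

## 6. Problem sizes and cost

A 12-beat recording at 117 Hz is 625 frames; per frame the chain is one
spline fit (3 × periodic spline on 9 knots), one 360×3 SVD, one 2×2
eigen-decomposition and two axis searches — about 4 ms, so a recording takes
~2.5 s and a 10-subject, 2-state study under a minute. The acceptance script
(`scripts/acceptance.R`) runs in well under two minutes.

## 7. Limitations

- Geometry assumes the crystal ordering is circular and correct; a shuffled
  ordering produces a self-intersecting projection, which is flagged but not
  repaired.
- The ED detector requires a pressure upstroke; it is not designed for
  non-ejecting or severely arrhythmic records (non-ejecting beats are
  flagged downstream).
- v̄ is defined on descending segments only; a beat without one (monotone
  rise) yields `NA` with a warning.
- The ellipsoid volume model and wall-thickness correction are geometric
  approximations; they are provided for completeness and tested as formulas,
  not validated against imaging.
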