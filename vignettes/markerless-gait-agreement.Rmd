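---
title: "Markerless gait kinematics and two-system agreement: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markerless gait kinematics and two-system agreement: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitmark)
library(dplyr)
```

`gaitmark` validates a markerless (video + pose-estimation) gait pipeline
against a reference system at the level of per-subject kinematic
summaries. This vignette is the package's account of the underlying
model: what is computed, which conventions and defaults were chosen where
several were defensible, and what the synthetic data can and cannot show.

## Joint angles from pose landmarks

The input is a time series of 2D landmarks in the 33-point BlazePose
topology, with a per-landmark visibility score. Only eight landmarks are
used: hips, knees, ankles and toes (foot index). The knee angle of one
limb is the angle at the knee between the hip→knee and knee→ankle
segment vectors,

$$\theta_1 = \arccos\frac{\vec{AB}\cdot\vec{BC}}{|\vec{AB}|\,|\vec{BC}|},$$

and the ankle angle $\theta_2$ is defined analogously on knee→ankle and
ankle→toe. Both are computed per frame by `joint_angle_series()` and are
invariant under translation, rotation, reflection and uniform scaling of
the image — which is why an orthographic sagittal projection suffices and
no metric calibration is needed for the angles themselves. The arccos
argument is clamped to $[-1, 1]$ to absorb floating-point rounding at
perfectly straight or folded configurations.

**Anatomical convention.** Knee flexion is $\theta_1$ itself (0° = full
extension). The ankle is split about a neutral fixed at
$\theta_2 = 90°$: the anatomical angle is $90° - \theta_2$, positive for
dorsiflexion. The neutral is a convention, not a measurement; any
constant offset in it cancels exactly in range of motion, and the
additive structure dorsiflexion + plantarflexion = ankle ROM holds by
construction. The "extension" parameter reported for the knee is the
*minimum* of $\theta_1$ over a cycle (residual flexion), not a signed
hyperextension; this keeps all parameters positive and preserves
ROM = flexion − extension.

**Side conventions.** The published BlazePose topology assigns landmark
23 to the *left* hip. Processing pipelines in the field sometimes use the
mirrored mapping (23 = right hip), and a lateral camera view cannot
disambiguate sides anyway. Both mappings are supported via
`joint_spec(side_convention =)`; the mirrored `"paper"` mapping is the
default. Neither is declared "correct": with a symmetric synthetic walker
the choice only relabels sides.

**Tracking gaps.** Landmarks with visibility below 0.5 are treated as
missing and linearly interpolated across gaps of at most 5 frames
(~0.17 s at 30 fps); longer gaps raise an error naming the frame ranges
rather than silently inventing geometry. Smoothing (centered moving
average, `smooth_angles()`) exists but is **off by default**: the
extraction stage is defined without filtering, and the moving average
attenuates genuine peak flexion (the attenuation follows the Dirichlet
kernel gain, which the tests verify analytically).

## Lens distortion

Consumer cameras add radial distortion that bends the walkway's straight
lines and therefore biases angles computed far from the image center.
`camera_model()` carries intrinsics in the form produced by standard
checkerboard calibration; only the two radial terms are modelled
(`1 + k_1 r^2 + k_2 r^4` in normalized coordinates), since that is the
standard minimal output of such calibrations and tangential terms are
rarely reported for phone cameras. Undistortion inverts the model by
damped fixed-point iteration to 1e-9 normalized units (≤ 100 iterations;
divergence is an error). The correction is applied to landmark
*coordinates*, not to images — the only option in a landmark-level
package; with zero coefficients the stage is an exact identity.
Extrinsic parameters in a config file are accepted but inert: a
summary-level comparison needs no metric reconstruction.

## Cycles and aggregation

Gait cycles are delimited peak-to-peak on the knee-flexion curve. The
swing-phase flexion maximum is the most prominent recurring event in the
sagittal knee angle, so `segment_cycles()` takes local maxima with
topographic prominence ≥ 15° separated by ≥ 0.6 s and forms half-open
peak-to-peak intervals; $k$ peaks give $k-1$ cycles, and leading/trailing
partial cycles are discarded. The defaults are deliberately conservative
for healthy adult gait (swing flexion excursion far exceeds 15°; stride
time far exceeds 0.6 s) and both are exposed. Ankle parameters are
computed over the knee-defined cycles of the same limb so that a single
temporal partition yields every parameter of a walk. How a given study
identified its cycles by hand cannot be known; the peak-to-peak rule is a
documented, reproducible stand-in.

Aggregation is a chain of unweighted means: per-cycle max, min and ROM →
session mean (`mean1`, `mean2`, …) → subject overall mean (`meantot`).
Because every step is linear, mean ROM = mean max − mean min holds
*exactly* at every level, and the tests assert it to 1e-12. Sessions
with fewer than three detected cycles are flagged, three being the
smallest cycle count the averaging is intended for. A caveat that
follows from this linearity: when a published table prints max, min and
ROM means rounded independently to two decimals, the identity can appear
violated by up to ~0.8° in print; it is a rounding artifact of the table,
not of the aggregation, and only rows whose printed arithmetic is exact
are usable as cross-checks.

## The agreement battery

For each parameter (knee flexion, knee extension, ankle dorsiflexion,
ankle plantarflexion, and both ROMs, per side), `compare_systems()`
pairs the two systems' subject-level values and reports:

* **Location**: Shapiro–Wilk on the paired differences at α = 0.05
  gates between a two-sided paired *t*-test and a Wilcoxon signed-rank
  test. The Wilcoxon branch drops zero differences, uses mean ranks for
  ties, and is exact for n ≤ 25 without ties (verified against full
  2^n sign-pattern enumeration), else a continuity-corrected normal
  approximation. No multiplicity correction is applied; each parameter
  is tested at α = 0.05 on its own, as is conventional in this
  literature.
* **Correlation**: Spearman ρ (Pearson on average ranks), with the
  interpretation bands poor < 0.500, moderate 0.500–0.750, good
  0.750–0.900, excellent > 0.900.
* **Reliability**: ICC(2,1) — two-way random effects, absolute
  agreement, single measure — computed from the two-way ANOVA mean
  squares
  $\mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}$
  with $k = 2$. Reports of this kind rarely state the ICC form; the
  absolute-agreement single-measure form is the choice here (documented,
  not inferred) because a validation study asks whether the systems
  agree in value, not merely in ranking — a constant offset *should*
  depress the coefficient, and the tests verify it does relative to the
  consistency form.
* **Error and agreement**: MAE, and Bland–Altman bias with
  `bias ± 1.96·SD` limits of agreement and `bias ± 1.96·SD/√n` bias CI.
  The normal multiplier 1.96 (rather than $t_{n-1}$) is used for the
  bias CI because it is the form such comparison tables print; at
  n = 27 it gives ≈ 93.9% rather than 95% nominal coverage, a known
  slight undercoverage documented here rather than hidden.
* **Difference direction**: estimated − reference by default.
  Published tables are often ambiguous or internally inconsistent about
  the direction; it is configurable and always stated in the output.

## The synthetic gait generator

There is no public recording attached to this package, so the generator
is a first-class module, not a fixture. It emulates the acquisition
geometry of a single-phone validation study: lateral view of an ~8 m
walkway, 1920 × 1080 px, 30 fps, at least three gait cycles per walk,
two walks per subject, cohorts of 27 subjects.

* **Waveforms.** Knee and ankle angles over the cycle are piecewise
  raised-cosine templates: a stance bump (default 18°) and a swing peak
  (default 50°) on a 6° flexion baseline for the knee; a +15°
  dorsiflexion lobe and a −17° plantarflexion lobe for the ankle, on a
  1.1 s cycle. The lobes are placed so they never overlap within a
  cycle, which makes the configured peaks the *exact* closed-form
  extrema — the property everything downstream is tested against. The
  lobe widths keep peak curvature low enough that 30 fps sampling stays
  within 0.5° of the true extrema (and 120 fps within 0.1°), which is
  the package's stated recovery bound. Defaults sit at the scale of
  healthy-adult values reported by inertial systems (knee ≈ 47–51°
  flexion, 6–7° extension; ankle ≈ 12–20° dorsi, 17–20° plantar).
* **Walker.** Segment lengths default to standard anthropometric
  fractions of a 1.68 m stature (thigh 0.245, shank 0.246, foot 0.152,
  hip height 0.530), walking at 1.25 m/s; the left limb is the right
  waveform shifted by half a cycle (symmetric healthy gait). The thigh
  swings as a plain sinusoid — it cancels out of all relative joint
  angles, so its exact shape is immaterial. Forward kinematics places
  hip/knee/ankle/toe so that the landmark-level angle formulas recover
  the waveforms exactly (segment lengths conserved to 1e-9 m).
* **Projection and noise.** Orthographic scale (200 px/m) plus offset
  maps the walking plane to the image; the lateral-view-at-distance
  geometry makes perspective a second-order effect and it is out of
  scope. Optional forward distortion of a `camera_model()` gives the
  correction stage something to undo. Noise is isotropic Gaussian per
  landmark per frame, visibility dropout is Bernoulli, and all
  randomness flows from a mandatory seed (same seed → bit-identical
  output; no hidden global state).
* **Cohorts.** `simulate_cohort()` works at the summary level: subject
  true values are drawn from per-parameter normal populations (defaults
  in `default_population()`, at inertial-reference scale), sessions add
  Gaussian variability (SD 2°), and the estimated system adds a
  constant offset plus homoscedastic Gaussian error (SD 3.5°, chosen so
  the subject-level SD of between-system differences lands near the
  2.5° scale typical of knee-parameter validation studies). ROM rows
  are derived, never drawn, so the aggregation identity is exact;
  draws violating physical constraints are rejected and redrawn.

**What passing tests do and do not show.** The generator demonstrates
that the pipeline recovers known kinematics, that injected biases
reappear in the Bland–Altman output (an injected 3° offset falls inside
its own bias CI in ≈ 95% of seeded replicates), and that the statistics
match independent oracles. It does *not* demonstrate curve-level
fidelity to any real subject's waveforms, robustness to pose-estimator
failure modes (identity switches, occlusion, foot-landmark jitter), or
performance on pathological gait — raised-cosine lobes are a stand-in
with analytic extrema, not a normative gait curve, so only
statistical-scale agreement with published cohort values is ever
claimed.

## Problem sizes and numerical choices

The test suite and acceptance script run, by design, at the study's own
scale: 27-subject × 2-session cohorts (20 replicates for coverage
checks), single-subject renders of 5 cycles at 30 and 120 fps, 200
random matrices for the ICC oracle, and full 2^6 and 2^8 Wilcoxon
enumerations. Tolerances: 1e-12 for algebraic identities, 1e-10 for
ANOVA-oracle agreement, 1e-9° for similarity invariance, 1e-6 px for
distortion round trips, 0.1°/0.5° for 120/30 fps extrema recovery.
Report CSVs round to two decimals half-away-from-zero (the convention of
printed comparison tables); all internal computation keeps full
precision.

## Known limitations

* Sagittal plane only; no hip kinematics, no frontal/transverse angles,
  no spatio-temporal parameters (speed, cadence, stance/swing phases).
* Orthographic projection; strong perspective or out-of-plane walking
  is not modelled.
* The normality gate inherits Shapiro–Wilk's small-sample behaviour;
  with n < 4 paired subjects the location test is reported as
  unavailable rather than guessed.
* The 1.96-multiplier bias CI slightly undercovers (see above).
* Repeated-measures and regression-based (proportional-bias)
  Bland–Altman variants are out of scope.
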