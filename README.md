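# gaitmark

Markerless, video-based gait analysis extracts joint kinematics from 2D
pose landmarks instead of optical markers or wearable sensors. Before such
a system can be used clinically it must be validated against an accepted
reference — typically a wearable inertial (IMU) system — by comparing the
kinematic summaries both systems produce for the same walks. `gaitmark`
implements that whole workflow for the sagittal plane, for researchers in
human movement biomechanics:

* **Kinematics** — per-frame knee and ankle angles from landmark triples in
  the 33-point BlazePose topology. The knee angle is
  `theta1 = arccos( AB·BC / (|AB||BC|) )` with `AB` the hip→knee and `BC`
  the knee→ankle vector; the ankle angle `theta2` uses knee→ankle and
  ankle→toe. Anatomically, knee flexion = `theta1` and the ankle angle is
  split about a neutral at `theta2 = 90°` (positive = dorsiflexion).
* **Camera stage** — two-term radial lens-distortion model
  (`1 + k1 r² + k2 r⁴`) applied or inverted on landmark coordinates, with
  intrinsics from a standard checkerboard calibration.
* **Cycles and parameters** — gait cycles delimited peak-to-peak on the
  knee-flexion curve; per-cycle maxima, minima and range of motion
  (ROM = max − min), averaged over the cycles of a walk (`mean1`,
  `mean2`, …) and then over walks into a subject overall mean (`meantot`).
* **Agreement** — for each parameter, a normality-gated paired test
  (Shapiro–Wilk deciding between paired *t* and exact Wilcoxon
  signed-rank), Spearman ρ, ICC(2,1) (two-way random effects, absolute
  agreement, single measure), mean absolute error
  `MAE = (1/N) Σ |x_i − x̂_i|`, and Bland–Altman bias with 95% limits of
  agreement `bias ± 1.96·SD` and bias CI `bias ± 1.96·SD/√n`.
* **Synthetic gait generator** — a planar walker built from raised-cosine
  joint-angle templates with closed-form extrema, projected to a
  1920 × 1080 / 30 fps lateral view with configurable pixel noise,
  visibility dropout, lens distortion and inter-system bias. Because the
  true extrema are known analytically, every downstream stage is testable
  without recorded data.

## Worked example

Render one noiseless synthetic walk and recover its kinematic parameters:

```r
library(gaitmark)

wf <- gait_waveforms(gait_waveform_config())   # knee 6-50 deg, ankle +15/-17
trial <- render_landmark_series(wf, anthropometry(), duration = 5.5, fps = 120)
analyze_session(trial$series)
#> # A tibble: 12 × 5
#>   joint side  parameter      value_deg n_cycles
#>   <chr> <chr> <chr>              <dbl>    <int>
#> 1 knee  right flexion_max        50.0         4
#> 2 knee  right extension_min       6.00        4
#> 3 knee  right rom                44.0         4
#> 4 ankle right dorsiflexion       15.0         4
#> 5 ankle right plantarflexion     17.0         4
#> 6 ankle right rom                32.0         4
#> # i 6 more rows
```

The recovered flexion maximum (50.0°), residual flexion (6.0°) and ROM
(44.0°) match the configured waveform extrema; at 120 fps the sampling
error is below 0.1°.

Simulate a 27-subject, two-session validation study with a 3° systematic
offset between the estimated and the reference system, and compare them:

```r
cohort <- simulate_cohort(n_subjects = 27, n_sessions = 2,
                          angle_offset = 3, seed = 42)
report <- compare_systems(cohort$reference, cohort$estimated)
glance(report)
#> # A tibble: 1 × 6
#>   n_parameters n_subjects mean_mae mean_abs_bias n_icc_good_or_better
#>          <int>      <int>    <dbl>         <dbl>                <int>
#> 1           12         27     3.59          2.94                    7
```

`tidy(report)` returns the full one-row-per-parameter table (means ± SD
per system, p-value and test used, ρ and ICC with their interpretation
bands — poor < 0.500, moderate 0.500–0.750, good 0.750–0.900,
excellent > 0.900 — MAE, bias, CI and limits of agreement); the injected
3° offset reappears in the bias column and drags the absolute-agreement
ICC down, exactly as a real inter-system bias would.
`autoplot(report)` draws the Bland–Altman panels.

File-based workflows use `pipeline_simulate()`, `pipeline_analyze()` and
`pipeline_compare()` driven by a YAML config (see `inst/cli/gaitmark.R`
for a shell front end); landmark streams travel as long-format CSV with a
JSON metadata sidecar, summaries as tidy CSV.

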