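# Shared fixtures: small, fast synthetic trials built in code.

default_wf <- function(...) gait_waveforms(gait_waveform_config(...))

quick_trial <- function(fps = 60, n_cycles = 5, noise = noise_model(),
                        camera = NULL, ...) {
  cfg <- gait_waveform_config(...)
  wf <- gait_waveforms(cfg)
  render_landmark_series(wf, anthropometry(),
                         duration = n_cycles * cfg$cycle_duration,
                         fps = fps, noise = noise, camera = camera)
}

# A tiny hand-built landmark series: one landmark triple held fixed over
# `n` frames, for geometry-level tests.
static_series <- function(points, n = 10, ids = c(23L, 25L, 27L),
                          visibility = 1, fps = 30) {
  frames <- tidyr::crossing(frame = 0:(n - 1), k = seq_along(ids)) |>
    dplyr::mutate(landmark_id = ids[k],
                  x = points[k, 1], y = points[k, 2],
                  visibility = visibility) |>
    dplyr::select(frame, landmark_id, x, y, visibility)
  landmark_series(frames, fps = fps, coordinate_mode = "pixel")
}

# Subject-level summary table with a single parameter, for agreement tests.
summary_table <- function(values, parameter = "flexion_max",
                          joint = "knee", side = "right") {
  tibble::tibble(
    subject = sprintf("S%02d", seq_along(values)), session = 1L,
    joint = joint, side = side, parameter = parameter, value_deg = values)
}

# ANOVA mean-squares oracle for ICC(2,1), via stats::aov
icc_oracle <- function(x, y) {
  n <- length(x)
  d <- data.frame(value = c(x, y),
                  subject = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- summary(aov(value ~ subject + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + 2 / n * (msc - mse))
}

# Full enumeration of the signed-rank null: all 2^n sign assignments of the
# fixed magnitudes, two-sided p by tail symmetry.
wilcoxon_enum_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  mean_v <- n * (n + 1) / 4
  p <- mean(abs(v_all - mean_v) >= abs(v_obs - mean_v) - 1e-12)
  min(1, p)
}

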