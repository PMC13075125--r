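#' Configure the parametric gait waveforms
#'
#' Defines the joint-angle targets of the synthetic planar gait model. The
#' knee curve is built from two raised-cosine lobes on a flexion baseline
#' (an early-stance bump and the swing-phase peak); the ankle curve from a
#' positive dorsiflexion lobe and a negative plantarflexion lobe around the
#' neutral shank-foot configuration. Because the lobes do not overlap within
#' a cycle, the configured peaks are the exact extrema of the continuous
#' waveforms, which is what makes the generator usable as ground truth.
#'
#' Defaults are scaled to healthy-adult sagittal gait (knee flexion peak
#' near 50 degrees, residual flexion near 6 degrees, ankle excursion roughly
#' +15/-17 degrees).
#'
#' @param cycle_duration Gait-cycle duration in seconds (> 0).
#' @param knee_swing_peak Swing-phase knee flexion maximum, degrees.
#' @param knee_stance_peak Early-stance knee flexion bump, degrees; must be
#'   strictly below `knee_swing_peak` and at least `knee_min`.
#' @param knee_min Minimum knee flexion over the cycle (the "extension"
#'   parameter), degrees, >= 0.
#' @param ankle_dorsi_peak Peak dorsiflexion, degrees (>= 0, positive up).
#' @param ankle_plantar_peak Peak plantarflexion magnitude, degrees (>= 0).
#' @param left_phase_offset Left-limb phase lag as a fraction of the cycle
#'   in `[0, 1)`; 0.5 models symmetric alternating gait.
#' @return An object of class `gait_waveform_config` (a named list).
#' @export
#' @examples
#' cfg <- gait_waveform_config(knee_swing_peak = 50, knee_min = 6)
#' wf <- gait_waveforms(cfg)
#' wf$extrema
gait_waveform_config <- function(cycle_duration = 1.1,
                                 knee_swing_peak = 50,
                                 knee_stance_peak = 18,
                                 knee_min = 6,
                                 ankle_dorsi_peak = 15,
                                 ankle_plantar_peak = 17,
                                 left_phase_offset = 0.5) {
  check_number(cycle_duration, "cycle_duration", lower = 0, strict_lower = TRUE)
  check_number(knee_swing_peak, "knee_swing_peak")
  check_number(knee_stance_peak, "knee_stance_peak")
  check_number(knee_min, "knee_min", lower = 0)
  check_number(ankle_dorsi_peak, "ankle_dorsi_peak", lower = 0)
  check_number(ankle_plantar_peak, "ankle_plantar_peak", lower = 0)
  check_number(left_phase_offset, "left_phase_offset",
               lower = 0, upper = 1, strict_upper = TRUE)
  if (!(knee_swing_peak > knee_stance_peak)) {
    stop_validation(
      "`knee_swing_peak` must be strictly greater than `knee_stance_peak`.")
  }
  if (!(knee_stance_peak >= knee_min)) {
    stop_validation("`knee_stance_peak` must be at least `knee_min`.")
  }
  structure(
    list(
      cycle_duration = cycle_duration,
      knee_swing_peak = knee_swing_peak,
      knee_stance_peak = knee_stance_peak,
      knee_min = knee_min,
      ankle_dorsi_peak = ankle_dorsi_peak,
      ankle_plantar_peak = ankle_plantar_peak,
      left_phase_offset = left_phase_offset
    ),
    class = "gait_waveform_config"
  )
}

# Raised-cosine lobe on the unit circle of gait phase: value 1 at `center`,
# 0 outside [center - width/2, center + width/2] (wrapped), C1-continuous.
raised_cosine_lobe <- function(phase, center, width) {
  d <- ((phase - center + 0.5) %% 1) - 0.5
  out <- numeric(length(phase))
  inside <- abs(d) <= width / 2
  out[inside] <- cos(pi * d[inside] / width)^2
  out
}

# Lobe placement (gait-phase fractions). Chosen so lobes never overlap and
# the knee baseline is attained on an open interval between them; the widths
# keep peak curvature low enough that 30 fps sampling stays within half a
# degree of the true extrema.
.knee_lobes <- list(stance = c(center = 0.17, width = 0.30),
                    swing  = c(center = 0.74, width = 0.48))
.ankle_lobes <- list(dorsi   = c(center = 0.38, width = 0.36),
                     plantar = c(center = 0.78, width = 0.40))

#' Build continuous joint-angle waveforms with closed-form extrema
#'
#' Turns a [gait_waveform_config()] into periodic joint-angle functions of
#' time (anatomical convention: knee flexion in degrees, >= 0; ankle signed,
#' positive = dorsiflexion) and tabulates their exact extrema per joint and
#' side. Left-side curves are the right-side curves shifted by
#' `left_phase_offset` of a cycle, so extrema are side-independent.
#'
#' @param config A [gait_waveform_config()].
#' @return An object of class `gait_waveforms`: a list with
#'   * `config`: the input configuration;
#'   * `angle`: `function(t, joint, side)` returning degrees at time `t`
#'     (seconds, vectorised);
#'   * `extrema`: tibble with columns `joint`, `side`, `true_max`,
#'     `true_min`, `true_rom`.
#' @export
gait_waveforms <- function(config) {
  if (!inherits(config, "gait_waveform_config")) {
    stop_validation("`config` must be created by `gait_waveform_config()`.")
  }
  cfg <- config

  phase_of <- function(t, side) {
    off <- if (side == "left") cfg$left_phase_offset else 0
    (t / cfg$cycle_duration + off) %% 1
  }

  knee_fun <- function(phase) {
    cfg$knee_min +
      (cfg$knee_stance_peak - cfg$knee_min) *
        raised_cosine_lobe(phase, .knee_lobes$stance["center"],
                           .knee_lobes$stance["width"]) +
      (cfg$knee_swing_peak - cfg$knee_min) *
        raised_cosine_lobe(phase, .knee_lobes$swing["center"],
                           .knee_lobes$swing["width"])
  }
  ankle_fun <- function(phase) {
    cfg$ankle_dorsi_peak *
      raised_cosine_lobe(phase, .ankle_lobes$dorsi["center"],
                         .ankle_lobes$dorsi["width"]) -
      cfg$ankle_plantar_peak *
        raised_cosine_lobe(phase, .ankle_lobes$plantar["center"],
                           .ankle_lobes$plantar["width"])
  }

  angle <- function(t, joint = c("knee", "ankle"),
                    side = c("right", "left")) {
    joint <- match.arg(joint)
    side <- match.arg(side)
    ph <- phase_of(t, side)
    if (joint == "knee") knee_fun(ph) else ankle_fun(ph)
  }

  per_joint <- tibble(
    joint = c("knee", "ankle"),
    true_max = c(cfg$knee_swing_peak, cfg$ankle_dorsi_peak),
    true_min = c(cfg$knee_min, -cfg$ankle_plantar_peak)
  )
  extrema <- tidyr::crossing(side = c("right", "left"), per_joint) |>
    mutate(true_rom = .data$true_max - .data$true_min) |>
    select("joint", "side", "true_max", "true_min", "true_rom") |>
    arrange(.data$joint, .data$side)

  structure(list(config = cfg, angle = angle, extrema = extrema),
            class = "gait_waveforms")
}

#' Ground-truth kinematic parameters of a waveform set
#'
#' Expresses the exact waveform extrema in the pipeline's parameter naming:
#' `flexion_max`, `extension_min` and `rom` for the knee; `dorsiflexion`,
#' `plantarflexion` (both positive magnitudes) and `rom` for the ankle.
#'
#' @param waveforms A [gait_waveforms()] object.
#' @param angle_offset Systematic offset (degrees) added to max/min
#'   parameters, mirroring an inter-system bias injected downstream; `rom`
#'   is offset-free because a common offset cancels in max - min.
#' @return Tibble with columns `joint`, `side`, `parameter`, `true_value`.
#' @export
ground_truth_parameters <- function(waveforms, angle_offset = 0) {
  if (!inherits(waveforms, "gait_waveforms")) {
    stop_validation("`waveforms` must be created by `gait_waveforms()`.")
  }
  check_number(angle_offset, "angle_offset")
  waveforms$extrema |>
    purrr::pmap(function(joint, side, true_max, true_min, true_rom) {
      if (joint == "knee") {
        tibble(joint = joint, side = side,
               parameter = c("flexion_max", "extension_min", "rom"),
               true_value = c(true_max + angle_offset,
                              true_min + angle_offset, true_rom))
      } else {
        tibble(joint = joint, side = side,
               parameter = c("dorsiflexion", "plantarflexion", "rom"),
               true_value = c(true_max + angle_offset,
                              -(true_min + angle_offset), true_rom))
      }
    }) |>
    bind_rows()
}
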