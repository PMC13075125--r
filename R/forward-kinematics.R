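#' Body-segment dimensions for the planar gait model
#'
#' Segment lengths default to standard anthropometric fractions of stature
#' (thigh 0.245, shank 0.246, foot 0.152; greater-trochanter height 0.530),
#' so a single stature argument yields a plausible planar skeleton. Segment
#' values may also be given explicitly.
#'
#' @param stature Body height in metres.
#' @param thigh_length,shank_length,foot_length,hip_height Segment lengths
#'   and hip height in metres; all strictly positive.
#' @param walking_speed Forward progression speed in m/s.
#' @return An object of class `anthropometry` (named list, metres and m/s).
#' @export
anthropometry <- function(stature = 1.68,
                          thigh_length = 0.245 * stature,
                          shank_length = 0.246 * stature,
                          foot_length = 0.152 * stature,
                          hip_height = 0.530 * stature,
                          walking_speed = 1.25) {
  for (nm in c("stature", "thigh_length", "shank_length", "foot_length",
               "hip_height", "walking_speed")) {
    check_number(get(nm), nm, lower = 0, strict_lower = TRUE)
  }
  structure(
    list(thigh_length = thigh_length, shank_length = shank_length,
         foot_length = foot_length, hip_height = hip_height,
         walking_speed = walking_speed),
    class = "anthropometry"
  )
}

# Rotate 2D row-pairs (x, y) counter-clockwise by `deg` degrees.
rotate2d <- function(x, y, deg) {
  th <- deg * pi / 180
  list(x = x * cos(th) - y * sin(th), y = x * sin(th) + y * cos(th))
}

# Thigh elevation from vertical (degrees, positive = hip flexion). A plain
# sinusoid peaking in late swing; it cancels out of all relative joint
# angles and only shapes the absolute limb orientation.
thigh_angle <- function(phase, amplitude = 20) {
  amplitude * cos(2 * pi * (phase - 0.80))
}

#' Planar forward kinematics of the synthetic walker
#'
#' Places hip, knee, ankle and toe for both limbs at the requested times.
#' The hip advances at `walking_speed` at a constant height; the thigh swings
#' about the hip; the shank is the thigh direction rotated by the knee angle
#' theta1, so the hip-knee-ankle angle equals the knee waveform exactly; the
#' foot is the shank direction rotated by theta2 = 90 - ankle angle, so the
#' knee-ankle-toe angle equals 90 degrees minus the ankle waveform. World
#' coordinates are metres, x forward, y up.
#'
#' @param waveforms A [gait_waveforms()] object.
#' @param anthropometry An [anthropometry()] object.
#' @param t Time(s) in seconds (finite, vectorised).
#' @param start_x Hip x position at `t = 0`, metres.
#' @return Tibble with columns `time`, `side`, `landmark`
#'   (`hip`/`knee`/`ankle`/`toe`), `x`, `y`.
#' @export
#' @examples
#' wf <- gait_waveforms(gait_waveform_config())
#' forward_kinematics(wf, anthropometry(), t = c(0, 0.25))
forward_kinematics <- function(waveforms, anthropometry, t, start_x = 0) {
  if (!inherits(waveforms, "gait_waveforms")) {
    stop_validation("`waveforms` must be created by `gait_waveforms()`.")
  }
  if (!inherits(anthropometry, "anthropometry")) {
    stop_validation("`anthropometry` must be created by `anthropometry()`.")
  }
  if (!is.numeric(t) || !all(is.finite(t))) {
    stop_validation("`t` must be finite numeric time(s) in seconds.")
  }
  check_number(start_x, "start_x")
  an <- anthropometry
  cyc <- waveforms$config$cycle_duration

  one_side <- function(side) {
    phase <- (t / cyc + if (side == "left")
      waveforms$config$left_phase_offset else 0) %% 1
    theta1 <- waveforms$angle(t, "knee", side)
    theta2 <- 90 - waveforms$angle(t, "ankle", side)
    phi <- thigh_angle(phase)

    hip_x <- start_x + an$walking_speed * t
    hip_y <- rep(an$hip_height, length(t))
    # unit vectors: thigh from vertical-down, shank = thigh rotated by
    # -theta1 (flexion folds the shank backward), foot = shank rotated by
    # +theta2 (theta2 = 90 at neutral ankle).
    thigh <- list(x = sin(phi * pi / 180), y = -cos(phi * pi / 180))
    shank <- rotate2d(thigh$x, thigh$y, -theta1)
    foot <- rotate2d(shank$x, shank$y, theta2)

    knee_x <- hip_x + an$thigh_length * thigh$x
    knee_y <- hip_y + an$thigh_length * thigh$y
    ankle_x <- knee_x + an$shank_length * shank$x
    ankle_y <- knee_y + an$shank_length * shank$y
    toe_x <- ankle_x + an$foot_length * foot$x
    toe_y <- ankle_y + an$foot_length * foot$y

    tibble(
      time = rep(t, 4L),
      side = side,
      landmark = rep(c("hip", "knee", "ankle", "toe"), each = length(t)),
      x = c(hip_x, knee_x, ankle_x, toe_x),
      y = c(hip_y, knee_y, ankle_y, toe_y)
    )
  }

  bind_rows(one_side("right"), one_side("left")) |>
    arrange(.data$time, .data$side, match(.data$landmark,
                                          c("hip", "knee", "ankle", "toe")))
}
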