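#' Locate local maxima with a prominence threshold
#'
#' A peak's prominence is its height above the highest of the two bases
#' found by descending on each side until a higher point (or the series
#' edge) is met — the standard topographic definition. Peaks below
#' `min_prominence` are dropped; remaining peaks closer than `min_distance`
#' samples are thinned greedily, keeping the higher peak.
#'
#' @param v Numeric vector.
#' @param min_prominence Minimum prominence (same units as `v`).
#' @param min_distance Minimum separation between kept peaks, samples.
#' @return Integer vector of peak positions (1-based), increasing.
#' @export
find_peaks <- function(v, min_prominence = 0, min_distance = 1) {
  n <- length(v)
  if (n < 3) return(integer(0))
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  if (length(cand) == 0) return(integer(0))

  prominence <- vapply(cand, function(i) {
    left <- v[seq_len(i - 1)]
    higher_l <- which(left > v[i])
    lbase <- min(v[(if (length(higher_l)) max(higher_l) else 1):i])
    right <- v[i:n]
    higher_r <- which(right > v[i])
    rbase <- min(v[i:(if (length(higher_r)) i + min(higher_r) - 1 else n)])
    v[i] - max(lbase, rbase)
  }, numeric(1))
  keep <- cand[prominence >= min_prominence]
  if (length(keep) <= 1) return(keep)

  ord <- keep[order(v[keep], decreasing = TRUE)]
  chosen <- integer(0)
  for (p in ord) {
    if (all(abs(p - chosen) >= min_distance)) chosen <- c(chosen, p)
  }
  sort(chosen)
}

#' Segment an angle series into gait cycles
#'
#' Gait cycles are delimited peak-to-peak on the knee-flexion curve: the
#' swing-phase flexion maximum is the most prominent recurring event in the
#' sagittal knee angle, so consecutive qualifying maxima bound one cycle
#' each (k peaks give k - 1 half-open cycles; leading and trailing partial
#' cycles are discarded). Ankle parameters are computed over the
#' knee-defined cycles of the same limb, so one temporal partition serves
#' all parameters.
#'
#' @param series An `angle_series` (knee, anatomical convention).
#' @param min_prominence Minimum peak prominence in degrees (default 15, a
#'   conservative floor for healthy-gait swing flexion).
#' @param min_period Minimum time between peaks in seconds (default 0.6,
#'   below any plausible healthy adult stride time).
#' @return Tibble of cycles: `start_frame`, `end_frame` (half-open
#'   `[start, end)`), `anchor_peak_frame`.
#' @export
segment_cycles <- function(series, min_prominence = 15, min_period = 0.6) {
  m <- angle_series_meta(series)
  check_number(min_prominence, "min_prominence", lower = 0)
  check_number(min_period, "min_period", lower = 0)
  peaks <- find_peaks(series$value_deg, min_prominence,
                      min_distance = min_period * m$fps)
  if (length(peaks) < 2) {
    stop_computation(sprintf(
      "Found %d qualifying flexion peak(s); at least 2 are needed to delimit a gait cycle.",
      length(peaks)))
  }
  tibble(
    start_frame = series$frame[peaks[-length(peaks)]],
    end_frame = series$frame[peaks[-1]],
    anchor_peak_frame = series$frame[peaks[-length(peaks)]]
  )
}

#' Kinematic parameters of one gait cycle
#'
#' The absolute maximum, absolute minimum and their difference (range of
#' motion) of the angle over the frames in `[start_frame, end_frame)`.
#'
#' @param series An `angle_series`.
#' @param cycle One row of the tibble returned by [segment_cycles()] (or
#'   any list with `start_frame` and `end_frame`).
#' @return Tibble with one row: `max_deg`, `min_deg`, `rom_deg`.
#' @export
cycle_parameters <- function(series, cycle) {
  idx <- series$frame >= cycle$start_frame & series$frame < cycle$end_frame
  if (!any(idx)) {
    stop_validation("Cycle interval contains no frames of the series.")
  }
  v <- series$value_deg[idx]
  tibble(max_deg = max(v), min_deg = min(v), rom_deg = max(v) - min(v))
}

#' Session-level averages of per-cycle parameters
#'
#' Unweighted mean of each parameter across the cycles of one walking
#' session (the per-walk mean of the per-cycle maxima, minima and ROM). The
#' mean ROM equals mean max minus mean min exactly, by linearity. Sessions
#' with fewer than three cycles are flagged, since three is the smallest
#' cycle count the averaging is intended for.
#'
#' @param params Tibble of per-cycle rows (`max_deg`, `min_deg`, `rom_deg`).
#' @return Tibble with one row: `max_deg`, `min_deg`, `rom_deg`,
#'   `n_cycles`, `few_cycles` (logical flag).
#' @export
session_summary <- function(params) {
  if (is.null(nrow(params)) || nrow(params) == 0) {
    stop_validation("At least one cycle is required for a session summary.")
  }
  if (nrow(params) < 3) {
    warn("Session has fewer than 3 gait cycles; summary flagged.",
         class = "gaitmark_few_cycles")
  }
  tibble(
    max_deg = mean(params$max_deg),
    min_deg = mean(params$min_deg),
    rom_deg = mean(params$rom_deg),
    n_cycles = nrow(params),
    few_cycles = nrow(params) < 3
  )
}

#' Subject-level overall means across sessions
#'
#' The overall mean of each parameter is the unweighted mean of the
#' session means (mean of mean1 and mean2 for a two-session protocol).
#'
#' @param sessions Tibble of session rows (`max_deg`, `min_deg`,
#'   `rom_deg`, optionally `n_cycles`).
#' @return Tibble with one row: `max_deg`, `min_deg`, `rom_deg`,
#'   `n_sessions`.
#' @export
subject_summary <- function(sessions) {
  if (is.null(nrow(sessions)) || nrow(sessions) == 0) {
    stop_validation("At least one session is required for a subject summary.")
  }
  tibble(
    max_deg = mean(sessions$max_deg),
    min_deg = mean(sessions$min_deg),
    rom_deg = mean(sessions$rom_deg),
    n_sessions = nrow(sessions)
  )
}

# Map a (joint-specific) summary row to the named-parameter long format:
# knee max/min are flexion/extension; ankle max is dorsiflexion and the
# minimum's magnitude is plantarflexion (anatomical sign convention).
summary_to_parameters <- function(row, joint, side) {
  if (joint == "knee") {
    tibble(joint = joint, side = side,
           parameter = c("flexion_max", "extension_min", "rom"),
           value_deg = c(row$max_deg, row$min_deg, row$rom_deg))
  } else {
    tibble(joint = joint, side = side,
           parameter = c("dorsiflexion", "plantarflexion", "rom"),
           value_deg = c(row$max_deg, -row$min_deg, row$rom_deg))
  }
}

#' Full single-session kinematic analysis of a landmark series
#'
#' Runs the per-session pipeline: optional lens-distortion correction,
#' joint-angle extraction for knee and ankle on both sides, conversion to
#' the anatomical convention, knee-anchored cycle segmentation per limb,
#' per-cycle parameters and their session means.
#'
#' @param series A [landmark_series()].
#' @param camera Optional [camera_model()] used to undistort first.
#' @param min_prominence,min_period Segmentation settings, see
#'   [segment_cycles()].
#' @param smooth_window Odd moving-average window in frames; 1 (default)
#'   disables smoothing.
#' @return Tibble with columns `joint`, `side`, `parameter`, `value_deg`,
#'   `n_cycles`.
#' @export
analyze_session <- function(series, camera = NULL,
                            min_prominence = 15, min_period = 0.6,
                            smooth_window = 1) {
  m <- series_meta(series)
  if (m$coordinate_mode == "normalized") series <- to_pixels(series)
  if (!is.null(camera)) series <- undistort_series(camera, series)

  purrr::map(c("right", "left"), function(side) {
    angle_of <- function(joint) {
      s <- joint_angle_series(
        series, joint_spec(joint, side, m$side_convention)) |>
        to_anatomical()
      if (smooth_window > 1) s <- smooth_angles(s, smooth_window)
      s
    }
    knee <- angle_of("knee")
    ankle <- angle_of("ankle")
    cycles <- segment_cycles(knee, min_prominence, min_period)

    params_for <- function(angle_series) {
      purrr::map(seq_len(nrow(cycles)),
                 ~cycle_parameters(angle_series, cycles[.x, ])) |>
        bind_rows() |>
        session_summary()
    }
    bind_rows(
      summary_to_parameters(params_for(knee), "knee", side),
      summary_to_parameters(params_for(ankle), "ankle", side)
    ) |>
      mutate(n_cycles = nrow(cycles))
  }) |>
    bind_rows()
}

#' Aggregate session parameter tables into subject overall means
#'
#' @param session_tables A list of tibbles as returned by
#'   [analyze_session()], one per session, or a single long tibble with a
#'   `session` column.
#' @param subject Subject identifier recorded in the output.
#' @return Tibble with `subject`, `joint`, `side`, `parameter`,
#'   `value_deg` (the overall mean), `n_sessions`.
#' @export
analyze_subject <- function(session_tables, subject = "S01") {
  if (is.data.frame(session_tables)) {
    long <- session_tables
    if (!"session" %in% names(long)) long$session <- 1L
  } else {
    long <- purrr::imap(session_tables,
                        ~mutate(.x, session = .y)) |> bind_rows()
  }
  long |>
    group_by(.data$joint, .data$side, .data$parameter) |>
    summarise(value_deg = mean(.data$value_deg),
              n_sessions = dplyr::n_distinct(.data$session),
              .groups = "drop") |>
    mutate(subject = subject) |>
    select("subject", "joint", "side", "parameter", "value_deg",
           "n_sessions")
}
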