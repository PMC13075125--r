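#' Measurement-noise model for the synthetic acquisition
#'
#' @param pixel_sd Isotropic Gaussian noise per landmark per frame, pixels
#'   (>= 0).
#' @param angle_offset Systematic bias in degrees added to the estimated
#'   system's summaries (inter-system offset), default 0.
#' @param visibility_dropout_rate Fraction of landmark records flagged
#'   low-visibility, in `[0, 1)`.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(pixel_sd = 0, angle_offset = 0,
                        visibility_dropout_rate = 0, seed = 1L) {
  check_number(pixel_sd, "pixel_sd", lower = 0)
  check_number(angle_offset, "angle_offset")
  check_number(visibility_dropout_rate, "visibility_dropout_rate",
               lower = 0, upper = 1, strict_upper = TRUE)
  check_number(seed, "seed")
  structure(list(pixel_sd = pixel_sd, angle_offset = angle_offset,
                 visibility_dropout_rate = visibility_dropout_rate,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Orthographic projection of the sagittal view
#'
#' The camera views the walkway laterally from a few metres, so the mapping
#' from the walking plane to the image is modelled as an orthographic scale
#' plus offset: `u = u0 + px_per_m * x`, `v = v0 - px_per_m * y` (image y
#' points down). Defaults place a 1.7 m walker walking 7 m inside a
#' 1920 x 1080 frame.
#'
#' @param px_per_m Pixels per metre.
#' @param u0 Horizontal pixel offset of the world origin.
#' @param v0 Vertical pixel coordinate of the ground line.
#' @return An object of class `sagittal_projection`.
#' @export
sagittal_projection <- function(px_per_m = 200, u0 = 60, v0 = 1000) {
  check_number(px_per_m, "px_per_m", lower = 0, strict_lower = TRUE)
  check_number(u0, "u0"); check_number(v0, "v0")
  structure(list(px_per_m = px_per_m, u0 = u0, v0 = v0),
            class = "sagittal_projection")
}

#' Render a synthetic walking trial as a landmark series
#'
#' Samples the planar forward kinematics at `fps` for `duration` seconds,
#' projects the joints into the image, optionally applies the forward
#' radial-distortion model of a [camera_model()] (so the downstream
#' correction stage has something to undo), adds pixel noise and visibility
#' dropout, and returns the stream together with its exact ground truth.
#' At least three gait cycles must fit in `duration`, matching the shortest
#' trial the per-session averaging is defined for.
#'
#' @param waveforms A [gait_waveforms()] object.
#' @param anthropometry An [anthropometry()] object.
#' @param duration Trial length, seconds (>= 3 cycles).
#' @param fps Frame rate, Hz (> 0); frames are `floor(duration * fps)`.
#' @param noise A [noise_model()].
#' @param camera Optional [camera_model()] whose distortion is applied.
#' @param projection A [sagittal_projection()].
#' @param start_x Hip x position at `t = 0`, metres.
#' @param side_convention Landmark-id convention for the output series.
#' @return List with `series` (a [landmark_series()]) and `truth` (tibble
#'   from [ground_truth_parameters()]).
#' @export
render_landmark_series <- function(waveforms, anthropometry,
                                   duration, fps = 30,
                                   noise = noise_model(),
                                   camera = NULL,
                                   projection = sagittal_projection(),
                                   start_x = 0.3,
                                   side_convention = c("paper", "official")) {
  side_convention <- match.arg(side_convention)
  stopifnot(inherits(waveforms, "gait_waveforms"),
            inherits(noise, "noise_model"))
  check_number(fps, "fps", lower = 0, strict_lower = TRUE)
  min_dur <- 3 * waveforms$config$cycle_duration
  if (!is.numeric(duration) || duration < min_dur) {
    stop_validation(sprintf(
      "`duration` must cover at least three gait cycles (>= %.3f s here).",
      min_dur))
  }

  n_frames <- floor(duration * fps)
  t <- (seq_len(n_frames) - 1) / fps
  pos <- forward_kinematics(waveforms, anthropometry, t, start_x = start_x)

  ids <- landmark_id_table(side_convention)
  pos <- left_join(pos, ids, by = c("landmark", "side"))

  u <- projection$u0 + projection$px_per_m * pos$x
  v <- projection$v0 - projection$px_per_m * pos$y
  if (!is.null(camera)) {
    stopifnot(inherits(camera, "camera_model"))
    d <- distort_point(camera, u, v)
    u <- d$x
    v <- d$y
  }

  frames <- tibble(
    frame = as.integer(round(pos$time * fps)),
    timestamp = pos$time,
    landmark_id = pos$landmark_id,
    x = u, y = v, visibility = 1
  )

  frames <- withr::with_seed(noise$seed, {
    nrec <- nrow(frames)
    if (noise$pixel_sd > 0) {
      frames$x <- frames$x + rnorm(nrec, 0, noise$pixel_sd)
      frames$y <- frames$y + rnorm(nrec, 0, noise$pixel_sd)
    }
    if (noise$visibility_dropout_rate > 0) {
      drop <- runif(nrec) < noise$visibility_dropout_rate
      frames$visibility[drop] <- runif(sum(drop), 0, 0.4)
    }
    frames
  })

  series <- landmark_series(frames, fps = fps, coordinate_mode = "pixel",
                            image_width = 1920, image_height = 1080,
                            side_convention = side_convention)
  list(series = series,
       truth = ground_truth_parameters(waveforms))
}
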