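#' Angle at the middle point of an ordered landmark triple
#'
#' The joint angle used throughout the pipeline: the angle between the
#' segment vector entering the joint (`b - a`) and the one leaving it
#' (`c - b`), `arccos` of their normalized dot product, in degrees within
#' `[0, 180]`. For the knee the triple is hip-knee-ankle (angle theta1);
#' for the ankle it is knee-ankle-toe (theta2). The value is invariant
#' under translation, rotation, reflection and uniform scaling.
#'
#' @param a,b,c Numeric length-2 points `(x, y)`, or equal-length vectors
#'   via `ax/ay/...` in [angle_between_xy()].
#' @return Angle in degrees.
#' @export
#' @examples
#' angle_between(c(0, 0), c(0, 1), c(0, 2))  # 0, straight leg
#' angle_between(c(0, 0), c(1, 0), c(1, 1))  # 90
angle_between <- function(a, b, c) {
  stopifnot(length(a) == 2, length(b) == 2, length(c) == 2)
  angle_between_xy(a[1], a[2], b[1], b[2], c[1], c[2])
}

#' @rdname angle_between
#' @param ax,ay,bx,by,cx,cy Coordinate vectors (equal length).
#' @export
angle_between_xy <- function(ax, ay, bx, by, cx, cy) {
  ux <- bx - ax
  uy <- by - ay
  vx <- cx - bx
  vy <- cy - by
  nu <- sqrt(ux^2 + uy^2)
  nv <- sqrt(vx^2 + vy^2)
  if (any(nu == 0)) {
    stop_computation("Degenerate geometry: first segment (a-b) has zero length.")
  }
  if (any(nv == 0)) {
    stop_computation("Degenerate geometry: second segment (b-c) has zero length.")
  }
  # clamp absorbs floating-point rounding at exactly 0 or 180 degrees
  cosang <- pmin(1, pmax(-1, (ux * vx + uy * vy) / (nu * nv)))
  acos(cosang) * 180 / pi
}

new_angle_series <- function(values, timestamp, frame, joint, side, fps,
                             convention = c("raw_theta", "anatomical")) {
  convention <- match.arg(convention)
  if (convention == "raw_theta" &&
      any(values < -1e-9 | values > 180 + 1e-9)) {
    stop_validation("Raw joint angles must lie in [0, 180] degrees.")
  }
  structure(
    tibble(frame = as.integer(frame), timestamp = timestamp,
           value_deg = as.numeric(values)),
    joint = joint, side = side, fps = fps, convention = convention,
    class = c("angle_series", class(tibble()))
  )
}

angle_series_meta <- function(series) {
  list(joint = attr(series, "joint"), side = attr(series, "side"),
       fps = attr(series, "fps"), convention = attr(series, "convention"))
}

#' Per-frame joint angle from a landmark series
#'
#' Extracts the three landmarks named by a [joint_spec()], repairs brief
#' tracking losses, and evaluates [angle_between_xy()] frame by frame.
#' Landmarks with visibility below `visibility_threshold` are treated as
#' missing and linearly interpolated across gaps of at most `max_gap`
#' frames (edge gaps take the nearest reliable value); longer gaps raise an
#' error that reports the offending frame ranges.
#'
#' @param series A [landmark_series()].
#' @param spec A [joint_spec()].
#' @param visibility_threshold Visibility below this flags a landmark as
#'   missing (default 0.5).
#' @param max_gap Longest run of missing frames that may be interpolated.
#' @return An `angle_series` tibble (`frame`, `timestamp`, `value_deg`)
#'   with attributes `joint`, `side`, `fps`, `convention = "raw_theta"`.
#' @export
joint_angle_series <- function(series, spec, visibility_threshold = 0.5,
                               max_gap = 5) {
  stopifnot(inherits(spec, "joint_spec"))
  m <- series_meta(series)
  dat <- as_tibble(series) |> filter(.data$landmark_id %in% spec$ids)
  frames <- sort(unique(as_tibble(series)$frame))

  coord <- function(id) {
    one <- dat |> filter(.data$landmark_id == id)
    if (nrow(one) == 0) {
      stop_validation(sprintf(
        "Landmark %d required for the %s %s angle is absent from the series.",
        id, spec$side, spec$joint))
    }
    one <- one[match(frames, one$frame), ]
    miss <- is.na(one$frame) | one$visibility < visibility_threshold
    x <- ifelse(miss, NA_real_, one$x)
    y <- ifelse(miss, NA_real_, one$y)
    filled_x <- fill_gaps(x, max_gap, id, frames)
    filled_y <- fill_gaps(y, max_gap, id, frames)
    list(x = filled_x, y = filled_y)
  }

  p1 <- coord(spec$ids[1])
  p2 <- coord(spec$ids[2])
  p3 <- coord(spec$ids[3])
  values <- angle_between_xy(p1$x, p1$y, p2$x, p2$y, p3$x, p3$y)

  ts <- as_tibble(series)$timestamp[match(frames, as_tibble(series)$frame)]
  new_angle_series(values, ts, frames, spec$joint, spec$side, m$fps,
                   convention = "raw_theta")
}

# Linear interpolation across short low-visibility gaps; long gaps error.
fill_gaps <- function(v, max_gap, landmark_id, frames) {
  if (!anyNA(v)) return(v)
  runs <- rle(is.na(v))
  long <- which(runs$values & runs$lengths > max_gap)
  if (length(long) > 0) {
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    ranges <- paste(sprintf("%d-%d", frames[starts[long]], frames[ends[long]]),
                    collapse = ", ")
    stop_computation(sprintf(
      "Landmark %d has low-visibility gap(s) longer than %d frames (frames %s).",
      landmark_id, max_gap, ranges))
  }
  out <- zoo::na.approx(v, na.rm = FALSE)
  if (!all(is.na(out))) out <- zoo::na.fill(out, "extend")  # edge gaps
  if (anyNA(out)) {
    stop_computation(sprintf(
      "Landmark %d has no reliable frames to interpolate from.", landmark_id))
  }
  as.numeric(out)
}

#' Convert a raw-theta angle series to the anatomical convention
#'
#' Knee: anatomical flexion equals theta1 unchanged (0 = full extension,
#' larger = more flexion). Ankle: anatomical angle is `90 - theta2` about a
#' neutral at theta2 = 90 degrees, so positive values are dorsiflexion and
#' negative values plantarflexion. The neutral offset cancels in any range
#' of motion, which is why ankle ROM is convention-independent.
#'
#' @param series An `angle_series` in `raw_theta` convention.
#' @return The series in `anatomical` convention.
#' @export
#' @examples
#' # theta2 = 75 degrees -> +15 (dorsiflexion); 110 -> -20 (plantarflexion)
to_anatomical <- function(series) {
  m <- angle_series_meta(series)
  if (m$convention != "raw_theta") {
    stop_validation("Series is already in anatomical convention.")
  }
  values <- if (m$joint == "ankle") 90 - series$value_deg else series$value_deg
  new_angle_series(values, series$timestamp, series$frame,
                   m$joint, m$side, m$fps, convention = "anatomical")
}

#' Centered moving-average smoothing of an angle series
#'
#' Optional noise suppression (off by default in the pipeline). The window
#' shrinks symmetrically near the edges, so the output never extends beyond
#' the input's range and `window = 1` is the identity.
#'
#' @param series An `angle_series`.
#' @param window Odd window length in frames (>= 1).
#' @return The smoothed `angle_series`.
#' @export
smooth_angles <- function(series, window) {
  if (!is.numeric(window) || length(window) != 1 || window < 1 ||
      window != round(window) || window %% 2 == 0) {
    stop_validation("`window` must be an odd integer >= 1.")
  }
  m <- angle_series_meta(series)
  v <- series$value_deg
  n <- length(v)
  half <- (window - 1) / 2
  cs <- cumsum(c(0, v))
  out <- vapply(seq_len(n), function(i) {
    k <- min(half, i - 1, n - i)
    (cs[i + k + 1] - cs[i - k]) / (2 * k + 1)
  }, numeric(1))
  new_angle_series(out, series$timestamp, series$frame, m$joint, m$side,
                   m$fps, convention = m$convention)
}

#' Export an angle series as a tidy tibble
#'
#' @param x An `angle_series`.
#' @param ... Unused.
#' @return Tibble with `frame`, `timestamp`, `joint`, `side`, `convention`,
#'   `value_deg`.
#' @method tidy angle_series
#' @export
tidy.angle_series <- function(x, ...) {
  m <- angle_series_meta(x)
  tibble(frame = x$frame, timestamp = x$timestamp, joint = m$joint,
         side = m$side, convention = m$convention, value_deg = x$value_deg)
}
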