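#' Pinhole camera with two-term radial distortion
#'
#' Intrinsics and radial distortion coefficients in the form produced by a
#' standard checkerboard calibration. Only the radial terms `k1`, `k2` are
#' modelled (no tangential distortion). Extrinsics, if present in a config
#' file, are accepted but inert: landmark correction needs no metric
#' reconstruction.
#'
#' @param fx,fy Focal lengths, pixels (> 0).
#' @param cx,cy Principal point, pixels.
#' @param k1,k2 Radial distortion coefficients (dimensionless).
#' @param image_width,image_height Image size, pixels (> 0).
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(fx = 1500, fy = 1500, cx = 960, cy = 540,
                         k1 = 0, k2 = 0,
                         image_width = 1920, image_height = 1080) {
  check_number(fx, "fx", lower = 0, strict_lower = TRUE)
  check_number(fy, "fy", lower = 0, strict_lower = TRUE)
  check_number(cx, "cx"); check_number(cy, "cy")
  check_number(k1, "k1"); check_number(k2, "k2")
  check_number(image_width, "image_width", lower = 0, strict_lower = TRUE)
  check_number(image_height, "image_height", lower = 0, strict_lower = TRUE)
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy, k1 = k1, k2 = k2,
                 image_width = image_width, image_height = image_height),
            class = "camera_model")
}

#' Apply the radial distortion model to pixel points
#'
#' Normalizes about the principal point with the focal lengths, applies the
#' radial factor `1 + k1 r^2 + k2 r^4`, and maps back to pixels. With
#' `k1 = k2 = 0` this is the identity.
#'
#' @param camera A [camera_model()].
#' @param x,y Pixel coordinates (vectorised, finite).
#' @return A list with distorted `x` and `y`.
#' @export
#' @examples
#' cam <- camera_model(fx = 1000, fy = 1000, cx = 0, cy = 0, k1 = 0.1)
#' distort_point(cam, 100, 0)  # r^2 = 0.01 -> factor 1.001 -> x = 100.1
distort_point <- function(camera, x, y) {
  stopifnot(inherits(camera, "camera_model"))
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop_validation("Points to distort must be finite.")
  }
  if (camera$k1 == 0 && camera$k2 == 0) return(list(x = x, y = y))
  xn <- (x - camera$cx) / camera$fx
  yn <- (y - camera$cy) / camera$fy
  r2 <- xn^2 + yn^2
  f <- 1 + camera$k1 * r2 + camera$k2 * r2^2
  list(x = camera$cx + camera$fx * xn * f,
       y = camera$cy + camera$fy * yn * f)
}

#' Invert the radial distortion model
#'
#' Damped fixed-point iteration in normalized coordinates:
#' `x_{n+1} = x_d / (1 + k1 r_n^2 + k2 r_n^4)` starting from the distorted
#' point, to a tolerance of 1e-9 normalized units. Valid for moderate
#' distortion (|k1| r^2 well below 1 over the field of view).
#'
#' @inheritParams distort_point
#' @param max_iter Iteration cap; non-convergence raises an error.
#' @return A list with undistorted `x` and `y`.
#' @export
undistort_point <- function(camera, x, y, max_iter = 100) {
  stopifnot(inherits(camera, "camera_model"))
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop_validation("Points to undistort must be finite.")
  }
  if (camera$k1 == 0 && camera$k2 == 0) return(list(x = x, y = y))
  xd <- (x - camera$cx) / camera$fx
  yd <- (y - camera$cy) / camera$fy
  xu <- xd
  yu <- yd
  tol <- 1e-9
  for (i in seq_len(max_iter)) {
    r2 <- xu^2 + yu^2
    f <- 1 + camera$k1 * r2 + camera$k2 * r2^2
    x_new <- xd / f
    y_new <- yd / f
    step <- max(abs(x_new - xu), abs(y_new - yu), 0)
    xu <- x_new
    yu <- y_new
    if (step < tol) {
      return(list(x = camera$cx + camera$fx * xu,
                  y = camera$cy + camera$fy * yu))
    }
  }
  stop_computation(sprintf(
    "Undistortion failed to converge in %d iterations (distortion too strong?).",
    max_iter))
}

#' Undistort every landmark of a series
#'
#' Applies [undistort_point()] to all landmark coordinates; timestamps and
#' visibility are untouched. The series must be in pixel mode — convert
#' normalized input with [to_pixels()] first.
#'
#' @param camera A [camera_model()].
#' @param series A [landmark_series()] in pixel mode.
#' @return The corrected [landmark_series()].
#' @export
undistort_series <- function(camera, series) {
  m <- series_meta(series)
  if (m$coordinate_mode != "pixel") {
    stop_validation(
      "Series is in normalized mode; convert with `to_pixels()` before undistorting.")
  }
  und <- undistort_point(camera, series$x, series$y)
  out <- as_tibble(series)
  out$x <- und$x
  out$y <- und$y
  landmark_series(out, fps = m$fps, coordinate_mode = "pixel",
                  image_width = m$image_width, image_height = m$image_height,
                  side_convention = m$side_convention)
}
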