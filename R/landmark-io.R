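#' @name landmark_series
#' @title Landmark time series in the 33-point pose topology
#'
#' @description
#' A `landmark_series` is a tibble in long format — one row per frame per
#' landmark — with columns `frame` (0-based integer), `timestamp` (seconds),
#' `landmark_id` (0-32, the BlazePose topology), `x`, `y` (pixels or
#' normalized units) and `visibility` in `[0, 1]`. Acquisition metadata
#' travel as attributes: `fps`, `coordinate_mode` (`"pixel"` or
#' `"normalized"`), `image_width`, `image_height` and `side_convention`
#' (`"paper"` or `"official"`, see [joint_spec()]).
NULL

#' Construct and validate a landmark series
#'
#' @param frames Data frame with columns `frame`, `landmark_id`, `x`, `y`,
#'   and optionally `timestamp` (derived as `frame / fps` when absent) and
#'   `visibility` (defaults to 1).
#' @param fps Frame rate, Hz (> 0).
#' @param coordinate_mode `"pixel"` or `"normalized"`.
#' @param image_width,image_height Image size in pixels.
#' @param side_convention `"paper"` (right hip = 23) or `"official"`
#'   (left hip = 23); see [joint_spec()].
#' @return A validated `landmark_series` tibble.
#' @export
landmark_series <- function(frames, fps = 30,
                            coordinate_mode = c("pixel", "normalized"),
                            image_width = 1920, image_height = 1080,
                            side_convention = c("paper", "official")) {
  coordinate_mode <- match.arg(coordinate_mode)
  side_convention <- match.arg(side_convention)
  check_number(fps, "fps", lower = 0, strict_lower = TRUE)
  check_number(image_width, "image_width", lower = 0, strict_lower = TRUE)
  check_number(image_height, "image_height", lower = 0, strict_lower = TRUE)

  frames <- as_tibble(frames)
  required <- c("frame", "landmark_id", "x", "y")
  missing_cols <- setdiff(required, names(frames))
  if (length(missing_cols) > 0) {
    stop_validation(sprintf("Missing required column(s): %s.",
                            paste(missing_cols, collapse = ", ")))
  }
  if (!"visibility" %in% names(frames)) frames$visibility <- 1
  if (!"timestamp" %in% names(frames)) frames$timestamp <- frames$frame / fps

  frames <- frames |>
    mutate(frame = as.integer(.data$frame),
           landmark_id = as.integer(.data$landmark_id)) |>
    select("frame", "timestamp", "landmark_id", "x", "y", "visibility") |>
    arrange(.data$frame, .data$landmark_id)

  out <- structure(frames,
                   fps = fps, coordinate_mode = coordinate_mode,
                   image_width = image_width, image_height = image_height,
                   side_convention = side_convention,
                   class = c("landmark_series", class(frames)))
  validate_landmark_series(out)
}

validate_landmark_series <- function(series) {
  s <- series
  bad_ids <- unique(s$landmark_id[s$landmark_id < 0L | s$landmark_id > 32L])
  if (length(bad_ids) > 0) {
    stop_validation(sprintf(
      "landmark_id outside the 0-32 topology: %s.",
      paste(sort(bad_ids), collapse = ", ")))
  }
  if (anyNA(s$x) || anyNA(s$y) || !all(is.finite(s$x)) || !all(is.finite(s$y))) {
    stop_validation("Landmark coordinates must be finite and non-missing.")
  }
  if (any(s$visibility < 0 | s$visibility > 1, na.rm = TRUE) ||
      anyNA(s$visibility)) {
    stop_validation("`visibility` must lie in [0, 1].")
  }
  if (any(s$frame < 0L)) stop_validation("`frame` indices must be >= 0.")
  if (anyDuplicated(s[, c("frame", "landmark_id")])) {
    stop_validation("Duplicate (frame, landmark_id) records.")
  }
  frames_sorted <- unique(s$frame)
  if (is.unsorted(frames_sorted, strictly = TRUE)) {
    stop_validation("Frame indices must be strictly increasing.")
  }
  if (attr(s, "coordinate_mode") == "normalized" &&
      (any(s$x < 0 | s$x > 1) || any(s$y < 0 | s$y > 1))) {
    stop_validation("Normalized coordinates must lie in [0, 1].")
  }
  s
}

series_meta <- function(series) {
  list(fps = attr(series, "fps"),
       coordinate_mode = attr(series, "coordinate_mode"),
       image_width = attr(series, "image_width"),
       image_height = attr(series, "image_height"),
       side_convention = attr(series, "side_convention"))
}

#' Convert a normalized-coordinate series to pixels
#'
#' Multiplies normalized `x` by `image_width` and `y` by `image_height`.
#' Pixel-mode input is returned unchanged.
#'
#' @param series A [landmark_series()].
#' @return The series in pixel mode.
#' @export
to_pixels <- function(series) {
  m <- series_meta(series)
  if (m$coordinate_mode == "pixel") return(series)
  landmark_series(
    mutate(as_tibble(series),
           x = .data$x * m$image_width, y = .data$y * m$image_height),
    fps = m$fps, coordinate_mode = "pixel",
    image_width = m$image_width, image_height = m$image_height,
    side_convention = m$side_convention
  )
}

# Landmark id tables. In the published 33-point topology landmark 23 is the
# LEFT hip; the "paper" convention mirrors the sides (23 = right hip) and is
# kept as the default because it reproduces the source pipeline's mapping.
landmark_id_table <- function(side_convention = c("paper", "official")) {
  side_convention <- match.arg(side_convention)
  paper <- tibble(
    landmark = rep(c("hip", "knee", "ankle", "toe"), each = 2),
    side = rep(c("right", "left"), times = 4),
    landmark_id = c(23L, 24L, 25L, 26L, 27L, 28L, 31L, 32L)
  )
  if (side_convention == "paper") {
    paper
  } else {
    mutate(paper, side = ifelse(.data$side == "right", "left", "right"))
  }
}

#' Landmark triple defining a joint angle
#'
#' Returns the ordered landmark ids whose two segment vectors define a joint
#' angle: hip-knee-ankle for the knee, knee-ankle-toe for the ankle. Under
#' the `"paper"` convention the right hip/knee/ankle/toe are landmarks
#' 23/25/27/31 and the left 24/26/28/32; `"official"` follows the published
#' topology, in which those ids belong to the left side (mirrored).
#'
#' @param joint `"knee"` or `"ankle"`.
#' @param side `"right"` or `"left"`.
#' @param side_convention `"paper"` or `"official"`.
#' @return An object of class `joint_spec`: list with `joint`, `side`, and
#'   `ids` (ordered integer triple).
#' @export
#' @examples
#' joint_spec("knee", "right")           # 23, 25, 27
#' joint_spec("ankle", "right")          # 25, 27, 31
#' joint_spec("knee", "right", "official")
joint_spec <- function(joint = c("knee", "ankle"),
                       side = c("right", "left"),
                       side_convention = c("paper", "official")) {
  joint <- check_flag_choice(joint[1], "joint", c("knee", "ankle"))
  side <- check_flag_choice(side[1], "side", c("right", "left"))
  side_convention <- check_flag_choice(side_convention[1], "side_convention",
                                       c("paper", "official"))
  tab <- landmark_id_table(side_convention)
  pick <- function(lm) {
    tab$landmark_id[tab$landmark == lm & tab$side == side]
  }
  ids <- if (joint == "knee") {
    c(pick("hip"), pick("knee"), pick("ankle"))
  } else {
    c(pick("knee"), pick("ankle"), pick("toe"))
  }
  structure(list(joint = joint, side = side, ids = as.integer(ids)),
            class = "joint_spec")
}

#' Read a landmark series from disk
#'
#' Two dialects are supported. `"csv"` is a long-format table
#' (`frame,timestamp,landmark_id,x,y,visibility`) with a JSON metadata
#' sidecar at `<path>.json` carrying `fps`, `coordinate_mode`,
#' `image_width`, `image_height` and `side_convention`. `"json"` is a single
#' JSON document with a `meta` object and a `frames` record array.
#'
#' @param path File path.
#' @param dialect `"csv"` or `"json"`.
#' @return A [landmark_series()].
#' @export
read_landmark_series <- function(path, dialect = c("csv", "json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop_validation(sprintf("File does not exist: %s", path))
  }
  if (dialect == "csv") {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) {
      stop_validation(sprintf("Metadata sidecar missing: %s", sidecar))
    }
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    frames <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!all(c("meta", "frames") %in% names(doc))) {
      stop_validation("JSON dialect requires top-level `meta` and `frames`.")
    }
    meta <- doc$meta
    frames <- as_tibble(doc$frames)
    if (nrow(frames) == 0) {
      frames <- tibble(frame = integer(), timestamp = double(),
                       landmark_id = integer(), x = double(), y = double(),
                       visibility = double())
    }
  }
  need <- c("fps", "coordinate_mode", "image_width", "image_height",
            "side_convention")
  missing_meta <- setdiff(need, names(meta))
  if (length(missing_meta) > 0) {
    stop_validation(sprintf("Metadata missing field(s): %s.",
                            paste(missing_meta, collapse = ", ")))
  }
  landmark_series(frames, fps = meta$fps,
                  coordinate_mode = meta$coordinate_mode,
                  image_width = meta$image_width,
                  image_height = meta$image_height,
                  side_convention = meta$side_convention)
}

#' Write a landmark series to disk
#'
#' Inverse of [read_landmark_series()]; numeric values are written with
#' enough digits (15 significant) for a lossless round trip at double
#' precision read-back.
#'
#' @param series A [landmark_series()].
#' @param path Output file path.
#' @param dialect `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_landmark_series <- function(series, path, dialect = c("csv", "json")) {
  dialect <- match.arg(dialect)
  series <- validate_landmark_series(series)
  meta <- series_meta(series)
  frames <- as_tibble(series)
  if (dialect == "csv") {
    readr::write_csv(frames, path, progress = FALSE)
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(list(meta = meta, frames = frames), path,
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(path)
}

#' Write / read subject kinematic-parameter summaries
#'
#' Summary tables use one row per subject x session x joint x side x
#' parameter with a `value_deg` column; `session = NA` (or the string
#' `"meantot"`) marks subject-level overall means.
#'
#' @param summaries Tibble with columns `subject`, `session`, `joint`,
#'   `side`, `parameter`, `value_deg`.
#' @param path CSV file path.
#' @return `path` (write) or the tibble (read).
#' @export
write_summary_csv <- function(summaries, path) {
  need <- c("subject", "session", "joint", "side", "parameter", "value_deg")
  missing_cols <- setdiff(need, names(summaries))
  if (length(missing_cols) > 0) {
    stop_validation(sprintf("Summary table missing column(s): %s.",
                            paste(missing_cols, collapse = ", ")))
  }
  readr::write_csv(summaries[, need], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_summary_csv
#' @export
read_summary_csv <- function(path) {
  if (!file.exists(path)) {
    stop_validation(sprintf("File does not exist: %s", path))
  }
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("subject", "session", "joint", "side", "parameter", "value_deg")
  missing_cols <- setdiff(need, names(out))
  if (length(missing_cols) > 0) {
    stop_validation(sprintf("Summary table missing column(s): %s.",
                            paste(missing_cols, collapse = ", ")))
  }
  out
}
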