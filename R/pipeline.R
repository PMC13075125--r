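#' Pipeline configuration
#'
#' A plain named list, readable from YAML, that drives the three pipeline
#' stages. Recognized fields: `seed` (integer, mandatory for simulation),
#' `output_dir`, `fps`, `duration`, `n_subjects`, `n_sessions`,
#' `angle_offset`, `error_sd`, `session_sd`, `pixel_sd`,
#' `visibility_dropout_rate`, `side_convention`, `direction`,
#' `min_prominence`, `min_period`, `smooth_window`, and an optional
#' `camera` block with [camera_model()] fields (extra fields such as
#' extrinsics are accepted and ignored).
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop_validation(sprintf("Config file does not exist: %s", path))
  }
  yaml::read_yaml(path)
}

config_camera <- function(config) {
  if (is.null(config$camera)) return(NULL)
  cam <- config$camera
  known <- c("fx", "fy", "cx", "cy", "k1", "k2", "image_width",
             "image_height")
  do.call(camera_model, cam[intersect(names(cam), known)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a full two-system study to disk
#'
#' Renders one landmark-series file per subject and session from the
#' configured waveforms, and writes the paired reference/estimated
#' summary tables plus the exact ground truth. Every random draw descends
#' from `config$seed`; rerunning with the same config reproduces the files
#' byte for byte.
#'
#' @param config Named list, see [read_pipeline_config()]. `seed` and
#'   `output_dir` are required.
#' @return Invisibly, a list of the written file paths.
#' @export
pipeline_simulate <- function(config) {
  if (is.null(config$seed)) {
    stop_validation("`seed` is required in the simulation config.")
  }
  if (is.null(config$output_dir)) {
    stop_validation("`output_dir` is required.")
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  n_subjects <- config$n_subjects %||% 27
  n_sessions <- config$n_sessions %||% 2
  fps <- config$fps %||% 30
  wf_cfg <- do.call(gait_waveform_config, config$waveforms %||% list())
  duration <- config$duration %||% (5 * wf_cfg$cycle_duration)
  camera <- config_camera(config)

  wf <- gait_waveforms(wf_cfg)
  anthro <- do.call(anthropometry, config$anthropometry %||% list())

  paths <- list()
  for (s in seq_len(n_subjects)) {
    for (ses in seq_len(n_sessions)) {
      nm <- noise_model(
        pixel_sd = config$pixel_sd %||% 0,
        visibility_dropout_rate = config$visibility_dropout_rate %||% 0,
        seed = as.integer(config$seed) + s * 1000L + ses
      )
      rendered <- render_landmark_series(
        wf, anthro, duration = duration, fps = fps, noise = nm,
        camera = camera,
        side_convention = config$side_convention %||% "paper")
      p <- file.path(config$output_dir,
                     sprintf("landmarks_S%02d_session%d.csv", s, ses))
      write_landmark_series(rendered$series, p, dialect = "csv")
      paths <- c(paths, p)
    }
  }

  cohort <- simulate_cohort(
    n_subjects = n_subjects, n_sessions = n_sessions,
    angle_offset = config$angle_offset %||% 0,
    error_sd = config$error_sd %||% 3.5,
    session_sd = config$session_sd %||% 2,
    seed = as.integer(config$seed))
  ref_path <- file.path(config$output_dir, "reference_summaries.csv")
  est_path <- file.path(config$output_dir, "estimated_summaries.csv")
  write_summary_csv(cohort$reference, ref_path)
  write_summary_csv(cohort$estimated, est_path)
  truth_path <- file.path(config$output_dir, "ground_truth.csv")
  readr::write_csv(ground_truth_parameters(gait_waveforms(wf_cfg)),
                   truth_path, progress = FALSE)

  invisible(list(landmarks = paths, reference = ref_path,
                 estimated = est_path, truth = truth_path))
}

#' Analyze landmark files into subject summaries
#'
#' Reads every landmark file, runs the per-session kinematic pipeline
#' (undistortion if a camera is configured, joint angles, anatomical
#' conversion, cycle segmentation, per-cycle parameters, session means)
#' and averages sessions into subject overall means.
#'
#' @param config Named list with `landmark_files` (a tibble or data frame
#'   with columns `subject`, `session`, `path`, or a directory
#'   `landmark_dir` of files named `landmarks_<subject>_session<k>.csv`),
#'   optional `camera`, and segmentation settings.
#' @return Subject-level summary tibble (`subject`, `joint`, `side`,
#'   `parameter`, `value_deg`, `n_sessions`).
#' @export
pipeline_analyze <- function(config) {
  files <- config$landmark_files
  if (is.null(files)) {
    if (is.null(config$landmark_dir)) {
      stop_validation("Provide `landmark_files` or `landmark_dir`.")
    }
    paths <- list.files(config$landmark_dir,
                        pattern = "^landmarks_.*\\.csv$", full.names = TRUE)
    if (length(paths) == 0) {
      stop_validation(sprintf("No landmark CSV files found in %s.",
                              config$landmark_dir))
    }
    info <- regmatches(basename(paths),
                       regexec("^landmarks_(.+)_session(\\d+)\\.csv$",
                               basename(paths)))
    files <- tibble(
      subject = vapply(info, function(x) x[2], character(1)),
      session = as.integer(vapply(info, function(x) x[3], character(1))),
      path = paths
    )
  }
  camera <- config_camera(config)

  files |>
    group_by(.data$subject) |>
    dplyr::group_modify(function(g, key) {
      per_session <- purrr::map2(g$path, g$session, function(p, ses) {
        analyze_session(
          read_landmark_series(p, dialect = "csv"), camera = camera,
          min_prominence = config$min_prominence %||% 15,
          min_period = config$min_period %||% 0.6,
          smooth_window = config$smooth_window %||% 1) |>
          mutate(session = ses)
      }) |> bind_rows()
      analyze_subject(per_session, subject = key$subject) |>
        select(-"subject")
    }) |>
    ungroup() |>
    select("subject", "joint", "side", "parameter", "value_deg",
           "n_sessions")
}

#' Compare two summary files and write report tables
#'
#' Runs [compare_systems()] on two summary CSVs and, if `output_dir` is
#' set, writes `agreement.csv` (the statistical battery), `bland_altman.csv`
#' (bias and limits of agreement) and `ba_plot_data.csv` (per-subject mean
#' vs difference). Report CSVs round to two decimals, half-up, as
#' comparison tables are conventionally printed; the returned object keeps
#' full precision.
#'
#' @param config Named list with `reference_path`, `estimated_path`,
#'   optional `output_dir`, `direction`, `alpha`.
#' @return The `agreement_report`, invisibly if files were written.
#' @export
pipeline_compare <- function(config) {
  ref <- read_summary_csv(config$reference_path)
  est <- read_summary_csv(config$estimated_path)
  report <- compare_systems(
    ref, est,
    direction = config$direction %||% "estimated-reference",
    alpha = config$alpha %||% 0.05)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    round2 <- function(x) round_half_up(x, 2)
    agr <- report$agreement |>
      mutate(across(dplyr::where(is.numeric) & !dplyr::matches("^n$"),
                    round2))
    ba <- report$bland_altman |>
      mutate(across(dplyr::where(is.numeric) & !dplyr::matches("^n$"),
                    round2))
    readr::write_csv(agr, file.path(config$output_dir, "agreement.csv"),
                     progress = FALSE)
    readr::write_csv(ba, file.path(config$output_dir, "bland_altman.csv"),
                     progress = FALSE)
    readr::write_csv(report$plot_data,
                     file.path(config$output_dir, "ba_plot_data.csv"),
                     progress = FALSE)
    return(invisible(report))
  }
  report
}

# Round half away from zero at `digits` decimals (the convention of the
# printed comparison tables), unlike base R's round-half-even.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
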