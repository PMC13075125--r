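#' Population distribution of kinematic parameters
#'
#' Default per-parameter normal distributions for the reference system,
#' scaled to inertial-sensor summaries of healthy adult gait (knee flexion
#' near 47-50 degrees, residual flexion 7, ankle dorsiflexion 12-15 and
#' plantarflexion 17-20). Range of motion is not drawn: it is derived from
#' the max/min parameters so the ROM = max - min identity holds by
#' construction.
#'
#' @return Tibble with columns `joint`, `side`, `parameter`, `mean`, `sd`.
#' @export
default_population <- function() {
  tibble::tribble(
    ~joint,  ~side,   ~parameter,        ~mean,  ~sd,
    "knee",  "right", "flexion_max",     49.18, 14.47,
    "knee",  "right", "extension_min",    7.26,  4.31,
    "knee",  "left",  "flexion_max",     47.45, 10.31,
    "knee",  "left",  "extension_min",    6.80,  3.40,
    "ankle", "right", "dorsiflexion",    14.86,  3.93,
    "ankle", "right", "plantarflexion",  16.92,  7.92,
    "ankle", "left",  "dorsiflexion",    12.48,  3.19,
    "ankle", "left",  "plantarflexion",  20.17,  7.32
  )
}

#' Simulate a paired two-system cohort of subject summaries
#'
#' Draws per-subject true kinematic parameters from the population
#' distributions, adds session-level variability to the reference system's
#' sessions, and produces the estimated system's sessions as the reference
#' values plus a constant inter-system offset plus homoscedastic Gaussian
#' error. Draws violating physical constraints (knee max below min, a
#' negative ankle magnitude) are redrawn. ROM rows are derived, never drawn,
#' so every summary satisfies ROM = max - min (knee) or dorsi + plantar
#' (ankle) exactly.
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param n_sessions Sessions per subject (>= 1).
#' @param population Tibble as from [default_population()].
#' @param angle_offset Constant estimated-minus-reference offset, degrees.
#' @param error_sd SD of the estimated system's extra error per session,
#'   degrees (>= 0).
#' @param session_sd SD of session-to-session variability, degrees (>= 0).
#' @param seed Integer seed (mandatory for reproducibility).
#' @return List of session-level summary tibbles `reference` and
#'   `estimated` (columns `subject`, `session`, `joint`, `side`,
#'   `parameter`, `value_deg`), plus `truth` (subject-level true values).
#' @export
simulate_cohort <- function(n_subjects = 27, n_sessions = 2,
                            population = default_population(),
                            angle_offset = 0, error_sd = 3.5,
                            session_sd = 2, seed) {
  if (missing(seed)) stop_validation("`seed` is required.")
  check_number(seed, "seed")
  if (!is.numeric(n_subjects) || n_subjects < 3) {
    stop_validation("`n_subjects` must be at least 3.")
  }
  check_number(n_sessions, "n_sessions", lower = 1)
  check_number(angle_offset, "angle_offset")
  check_number(error_sd, "error_sd", lower = 0)
  check_number(session_sd, "session_sd", lower = 0)
  if (any(population$sd < 0)) stop_validation("Population SDs must be >= 0.")

  withr::with_seed(as.integer(seed), {
    subjects <- sprintf("S%02d", seq_len(n_subjects))

    # subject-level true values, constrained draws
    truth <- population |>
      tidyr::crossing(subject = subjects) |>
      group_by(.data$subject, .data$joint, .data$side) |>
      dplyr::group_modify(function(p, key) {
        repeat {
          p$true_value <- rnorm(nrow(p), p$mean, p$sd)
          ok <- if (key$joint == "knee") {
            p$true_value[p$parameter == "flexion_max"] >
              p$true_value[p$parameter == "extension_min"]
          } else {
            all(p$true_value >= 0)
          }
          if (ok) break
        }
        p[, c("parameter", "true_value")]
      }) |>
      ungroup() |>
      select("subject", "joint", "side", "parameter", "true_value")

    sessions <- truth |>
      tidyr::crossing(session = seq_len(n_sessions)) |>
      mutate(
        reference = .data$true_value + rnorm(n(), 0, session_sd),
        estimated = .data$reference + angle_offset + rnorm(n(), 0, error_sd)
      )

    finish <- function(col) {
      base <- sessions |>
        select("subject", "session", "joint", "side", "parameter",
               value_deg = all_of(col))
      rom <- base |>
        tidyr::pivot_wider(names_from = "parameter",
                           values_from = "value_deg") |>
        mutate(value_deg = ifelse(
          .data$joint == "knee",
          .data$flexion_max - .data$extension_min,
          .data$dorsiflexion + .data$plantarflexion),
          parameter = "rom") |>
        select("subject", "session", "joint", "side", "parameter",
               "value_deg")
      bind_rows(base, rom) |>
        arrange(.data$subject, .data$session, .data$joint, .data$side,
                .data$parameter)
    }

    list(reference = finish("reference"),
         estimated = finish("estimated"),
         truth = truth)
  })
}
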