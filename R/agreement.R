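#' Interpretation bands for correlation and reliability coefficients
#'
#' Categorizes a coefficient as `"poor"` (< 0.500), `"moderate"`
#' (0.500-0.750), `"good"` (0.750-0.900) or `"excellent"` (> 0.900).
#' Negative values are poor; values outside `[-1, 1]` are an error.
#'
#' @param value Coefficient(s) in `[-1, 1]`.
#' @return Character vector of band labels.
#' @export
#' @examples
#' classify_band(c(0.916, 0.798, 0.499))  # excellent, good, poor
classify_band <- function(value) {
  if (any(!is.finite(value) | value < -1 | value > 1)) {
    stop_validation("Coefficients must lie in [-1, 1].")
  }
  dplyr::case_when(
    value > 0.9 ~ "excellent",
    value > 0.75 ~ "good",
    value >= 0.5 ~ "moderate",
    TRUE ~ "poor"
  )
}

check_paired <- function(reference, estimated, min_n = 3) {
  if (length(reference) != length(estimated)) {
    stop_validation("`reference` and `estimated` must have equal length.")
  }
  if (length(reference) < min_n) {
    stop_validation(sprintf("At least %d paired observations are required.",
                            min_n))
  }
  if (!all(is.finite(reference)) || !all(is.finite(estimated))) {
    stop_validation("Paired values must be finite.")
  }
  invisible(NULL)
}

#' Mean absolute error between two systems
#'
#' `MAE = mean(|reference - estimated|)`; zero iff the systems agree
#' exactly, and symmetric in the two systems.
#'
#' @param reference,estimated Paired numeric vectors (degrees).
#' @return MAE in degrees.
#' @export
mae <- function(reference, estimated) {
  check_paired(reference, estimated, min_n = 1)
  mean(abs(reference - estimated))
}

#' Bland-Altman agreement analysis
#'
#' Differences are `estimated - reference` by default (configurable via
#' `direction`). Reports the bias (mean difference), the sample SD of the
#' differences (n - 1 denominator), the 95% limits of agreement
#' `bias +/- 1.96 * SD`, and the bias confidence bounds
#' `bias +/- 1.96 * SD / sqrt(n)` (normal multiplier, matching the common
#' reporting convention for two-system gait comparisons).
#'
#' @param reference,estimated Paired numeric vectors (degrees).
#' @param direction `"estimated-reference"` (default) or
#'   `"reference-estimated"`.
#' @return An object of class `ba_result`: a one-row tibble with `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `ci_low`, `ci_high`, `n`.
#' @export
#' @examples
#' bland_altman(reference = c(0, 0, 0), estimated = c(1, 2, 3))
bland_altman <- function(reference, estimated,
                         direction = c("estimated-reference",
                                       "reference-estimated")) {
  direction <- match.arg(direction)
  check_paired(reference, estimated, min_n = 3)
  d <- if (direction == "estimated-reference") estimated - reference
       else reference - estimated
  n <- length(d)
  bias <- mean(d)
  sd_diff <- sd(d)
  out <- tibble(
    bias = bias, sd_diff = sd_diff,
    loa_low = bias - 1.96 * sd_diff, loa_high = bias + 1.96 * sd_diff,
    ci_low = bias - 1.96 * sd_diff / sqrt(n),
    ci_high = bias + 1.96 * sd_diff / sqrt(n),
    n = n
  )
  class(out) <- c("ba_result", class(out))
  out
}

#' Spearman rank correlation between the two systems
#'
#' Pearson correlation of average-ranked values (ties share mean ranks).
#'
#' @param reference,estimated Paired numeric vectors.
#' @return rho in `[-1, 1]`.
#' @export
spearman_rho <- function(reference, estimated) {
  check_paired(reference, estimated, min_n = 3)
  if (length(unique(reference)) < 2 || length(unique(estimated)) < 2) {
    stop_computation(
      "Spearman correlation undefined: a system has zero rank variance.")
  }
  cor(reference, estimated, method = "spearman")
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measure, from the
#' two-way ANOVA mean squares of the subjects x systems table:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))`, here with k = 2
#' systems. Absolute agreement (unlike the consistency form) penalizes a
#' constant offset between systems.
#'
#' @param reference,estimated Paired numeric vectors (one row per subject).
#' @return ICC value.
#' @export
icc21 <- function(reference, estimated) {
  check_paired(reference, estimated, min_n = 3)
  n <- length(reference)
  k <- 2
  m <- cbind(reference, estimated)
  grand <- mean(m)
  if (all(m == m[1])) {
    stop_computation("ICC undefined: zero total variance.")
  }
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

#' Normality-gated paired location test
#'
#' Shapiro-Wilk on the paired differences decides the branch: if normality
#' is not rejected at `alpha`, a two-sided paired t-test; otherwise a
#' two-sided Wilcoxon signed-rank test (zero differences dropped, mean
#' ranks for ties, exact null distribution for n <= 25 without ties and a
#' continuity-corrected normal approximation otherwise).
#'
#' @param reference,estimated Paired numeric vectors (n >= 4).
#' @param alpha Significance level for the normality gate.
#' @param branch `"auto"` (normality-gated, the default), or `"wilcoxon"` /
#'   `"paired_t"` to force a branch.
#' @return List with `p_value`, `test_used` (`"paired_t"` or
#'   `"wilcoxon"`), and `shapiro_p`.
#' @export
paired_location_test <- function(reference, estimated, alpha = 0.05,
                                 branch = c("auto", "wilcoxon", "paired_t")) {
  branch <- match.arg(branch)
  check_paired(reference, estimated, min_n = 4)
  d <- estimated - reference
  if (all(d == 0)) {
    stop_computation(
      "Degenerate paired test: all differences are exactly zero.")
  }
  shapiro_p <- if (length(unique(d)) < 2) 0 else shapiro.test(d)$p.value
  use_t <- switch(branch, auto = shapiro_p >= alpha,
                  paired_t = TRUE, wilcoxon = FALSE)
  if (use_t) {
    p <- t.test(estimated, reference, paired = TRUE)$p.value
    list(p_value = p, test_used = "paired_t", shapiro_p = shapiro_p)
  } else {
    nz <- d[d != 0]
    exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
    p <- suppressWarnings(
      wilcox.test(estimated, reference, paired = TRUE,
                  exact = exact, correct = TRUE)$p.value)
    list(p_value = p, test_used = "wilcoxon", shapiro_p = shapiro_p)
  }
}

#' Compare two systems' subject summaries parameter by parameter
#'
#' Aligns the two subject-level summary tables on subject id, and for every
#' joint x side x parameter produces the full agreement battery: per-system
#' mean and SD, normality-gated paired test, Spearman rho, ICC(2,1), mean
#' absolute error, interpretation bands, and a Bland-Altman row, plus the
#' per-subject plot data (mean vs difference) needed to draw BA plots.
#'
#' @param reference,estimated Subject-level summary tibbles with columns
#'   `subject`, `joint`, `side`, `parameter`, `value_deg` (session-level
#'   tables are first averaged per subject).
#' @param direction Difference direction for the Bland-Altman analysis,
#'   see [bland_altman()].
#' @param alpha Significance level for the normality gate.
#' @return An object of class `agreement_report`: list with tibbles
#'   `agreement` (one row per parameter), `bland_altman`, and `plot_data`.
#' @export
compare_systems <- function(reference, estimated,
                            direction = c("estimated-reference",
                                          "reference-estimated"),
                            alpha = 0.05) {
  direction <- match.arg(direction)
  ref <- collapse_to_subject(reference)
  est <- collapse_to_subject(estimated)

  ref_ids <- unique(ref$subject)
  est_ids <- unique(est$subject)
  if (!setequal(ref_ids, est_ids)) {
    stop_validation(sprintf(
      "Subject sets differ between systems (only in reference: %s; only in estimated: %s).",
      paste(setdiff(ref_ids, est_ids), collapse = ", "),
      paste(setdiff(est_ids, ref_ids), collapse = ", ")))
  }

  paired <- dplyr::inner_join(
    ref |> dplyr::rename(reference = "value_deg"),
    est |> dplyr::rename(estimated = "value_deg"),
    by = c("subject", "joint", "side", "parameter"))

  groups <- paired |>
    group_by(.data$joint, .data$side, .data$parameter) |>
    dplyr::group_split()

  rows <- purrr::map(groups, function(g) {
    r <- g$reference
    e <- g$estimated
    ident <- all(r == e)
    test <- if (ident) {
      list(p_value = NA_real_, test_used = "degenerate")
    } else {
      # too few subjects for the normality gate (or all-zero diffs after
      # rounding) degrade to an NA p-value rather than aborting the report
      tryCatch(paired_location_test(r, e, alpha = alpha),
               gaitmark_error = function(c) {
                 list(p_value = NA_real_, test_used = "unavailable")
               })
    }
    rho <- tryCatch(spearman_rho(r, e), gaitmark_error = function(c) NA_real_)
    icc <- tryCatch(icc21(r, e), gaitmark_error = function(c) NA_real_)
    ba <- bland_altman(r, e, direction = direction)
    agreement <- tibble(
      joint = g$joint[1], side = g$side[1], parameter = g$parameter[1],
      n = length(r),
      mean_est = mean(e), sd_est = sd(e),
      mean_ref = mean(r), sd_ref = sd(r),
      p_value = test$p_value, test_used = test$test_used,
      rho = rho,
      rho_band = if (is.na(rho)) NA_character_ else classify_band(rho),
      icc = icc,
      icc_band = if (is.na(icc)) NA_character_ else classify_band(icc),
      mae = mae(r, e)
    )
    ba_row <- dplyr::bind_cols(
      tibble(joint = g$joint[1], side = g$side[1],
             parameter = g$parameter[1]), ba)
    plot_data <- tibble(
      joint = g$joint[1], side = g$side[1], parameter = g$parameter[1],
      subject = g$subject,
      mean_value = (r + e) / 2,
      difference = if (direction == "estimated-reference") e - r else r - e
    )
    list(agreement = agreement, ba = ba_row, plot_data = plot_data)
  })

  out <- list(
    agreement = bind_rows(purrr::map(rows, "agreement")),
    bland_altman = bind_rows(purrr::map(rows, "ba")),
    plot_data = bind_rows(purrr::map(rows, "plot_data")),
    direction = direction, alpha = alpha
  )
  class(out) <- "agreement_report"
  out
}

# Session-level summary tables are averaged to subject level (overall mean
# across sessions) before pairing.
collapse_to_subject <- function(tbl) {
  need <- c("subject", "joint", "side", "parameter", "value_deg")
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols) > 0) {
    stop_validation(sprintf("Summary table missing column(s): %s.",
                            paste(missing_cols, collapse = ", ")))
  }
  tbl |>
    group_by(.data$subject, .data$joint, .data$side, .data$parameter) |>
    summarise(value_deg = mean(.data$value_deg), .groups = "drop")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "Two-system agreement report (%d parameters, n = %d subjects, differences = %s)\n",
    nrow(x$agreement), x$agreement$n[1], x$direction))
  print(x$agreement, ...)
  cat("\nBland-Altman:\n")
  print(x$bland_altman, ...)
  invisible(x)
}
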