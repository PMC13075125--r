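#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_hline geom_line
#'   facet_wrap labs theme_minimal
#' @export
ggplot2::autoplot

#' Tidy an agreement report into one row per parameter
#'
#' Joins the statistical battery with the Bland-Altman columns, giving the
#' familiar comparison-table layout (per-system mean +/- SD, p, rho, ICC,
#' MAE, bias and limits of agreement).
#'
#' @param x An `agreement_report` from [compare_systems()].
#' @param ... Unused.
#' @return A tibble with one row per joint x side x parameter.
#' @method tidy agreement_report
#' @export
tidy.agreement_report <- function(x, ...) {
  dplyr::left_join(x$agreement,
                   dplyr::select(x$bland_altman, -dplyr::any_of("n")),
                   by = c("joint", "side", "parameter"))
}

#' One-line summary of an agreement report
#'
#' @param x An `agreement_report`.
#' @param ... Unused.
#' @return A one-row tibble: number of parameters, subjects, mean MAE,
#'   mean absolute bias, and counts of parameters in each ICC band.
#' @method glance agreement_report
#' @export
glance.agreement_report <- function(x, ...) {
  tibble(
    n_parameters = nrow(x$agreement),
    n_subjects = x$agreement$n[1],
    mean_mae = mean(x$agreement$mae),
    mean_abs_bias = mean(abs(x$bland_altman$bias)),
    n_icc_good_or_better = sum(x$agreement$icc_band %in%
                                 c("good", "excellent"), na.rm = TRUE),
    n_significant = sum(x$agreement$p_value < x$alpha, na.rm = TRUE)
  )
}

#' @rdname tidy.agreement_report
#' @method tidy ba_result
#' @export
tidy.ba_result <- function(x, ...) as_tibble(x)

#' Bland-Altman plot of an agreement report
#'
#' One panel per parameter: per-subject between-system differences against
#' the pairwise means, with the bias (solid) and 95% limits of agreement
#' (dashed) as horizontal references.
#'
#' @param object An `agreement_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot agreement_report
#' @export
autoplot.agreement_report <- function(object, ...) {
  lines <- object$bland_altman |>
    tidyr::pivot_longer(c("bias", "loa_low", "loa_high"),
                        names_to = "line", values_to = "y") |>
    mutate(linetype = ifelse(.data$line == "bias", "solid", "dashed"),
           panel = paste(.data$side, .data$joint, .data$parameter))
  pts <- object$plot_data |>
    mutate(panel = paste(.data$side, .data$joint, .data$parameter))
  ggplot(pts, aes(x = .data$mean_value, y = .data$difference)) +
    geom_point(alpha = 0.7) +
    geom_hline(data = lines,
               aes(yintercept = .data$y, linetype = .data$linetype)) +
    facet_wrap(~panel, scales = "free") +
    ggplot2::scale_linetype_identity() +
    labs(x = "Mean of the two systems (deg)",
         y = sprintf("Difference (%s, deg)", object$direction)) +
    theme_minimal()
}

#' Plot an angle series
#'
#' @param object An `angle_series`.
#' @param ... Unused.
#' @return A ggplot object of angle against time.
#' @method autoplot angle_series
#' @export
autoplot.angle_series <- function(object, ...) {
  m <- angle_series_meta(object)
  ggplot(tidy(object), aes(x = .data$timestamp, y = .data$value_deg)) +
    geom_line() +
    labs(x = "Time (s)",
         y = sprintf("%s %s angle (deg, %s)", m$side, m$joint,
                     m$convention)) +
    theme_minimal()
}
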