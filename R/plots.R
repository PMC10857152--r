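#' Plot per-case landmark error magnitudes
#'
#' Grouped bars of mean FLE, TRE and FRE per case, the standard at-a-glance
#' view of a navigation accuracy experiment.
#'
#' @param landmark_summary Per-case summary tibble from [run_pipeline()]
#'   or `dplyr::bind_rows(lapply(cohort, summarize_case))`.
#' @return A ggplot object.
#' @export
plot_landmark_errors <- function(landmark_summary) {
  long <- tidyr::pivot_longer(
    landmark_summary,
    cols = c("mean_fle", "mean_tre", "mean_fre"),
    names_to = "metric", values_to = "mm")
  long$metric <- factor(toupper(sub("mean_", "", long$metric)),
                        levels = c("FLE", "TRE", "FRE"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$case_id, y = .data$mm,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "mean error magnitude [mm]",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot lesion overlap against lesion volume
#'
#' Scatter of the Dice coefficient against lesion volume, coloured by
#' surgical position group -- the relationship that drives the
#' volume-accuracy correlation in the cohort analysis.
#'
#' @param lesions Per-lesion metrics tibble from [run_pipeline()] or
#'   [evaluate_lesions()].
#' @return A ggplot object.
#' @export
plot_dsc_volume <- function(lesions) {
  colour <- if ("group" %in% names(lesions)) "group" else "position"
  ggplot2::ggplot(lesions,
                  ggplot2::aes(x = .data$volume_cm3, y = .data$dsc,
                               colour = .data[[colour]])) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression("lesion volume [" * cm^3 * "]"),
                  y = "Dice similarity coefficient", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Residual plot for a rigid registration fit
#'
#' Per-marker residual (fiducial registration error) magnitudes.
#'
#' @param object A [fit_rigid()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rigid_fit
#' @export
autoplot.rigid_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$label),
                                   y = .data$magnitude)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$rms_residual,
                        linetype = "dashed") +
    ggplot2::labs(x = "marker", y = "residual magnitude [mm]",
                  subtitle = sprintf("RMS residual %.2f mm",
                                     object$rms_residual)) +
    ggplot2::theme_minimal()
}
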