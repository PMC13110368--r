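#' Plot a cohort's per-embryo measurements by genotype
#'
#' Jittered per-embryo points with group mean and SD bars - the standard
#' presentation of primordium cell-count comparisons.
#'
#' @param cohort a [run_cohort()] tibble (rows with `status != "ok"` are
#'   dropped).
#' @param value bare column to plot (default `cell_count`).
#' @return A ggplot object.
#' @export
plot_cohort <- function(cohort, value = cell_count) {
  ok <- cohort[cohort$status == "ok", , drop = FALSE]
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$genotype, y = {{ value }})) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.4) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_sdl,
                          fun.args = list(mult = 1), geom = "errorbar",
                          width = 0.2, linewidth = 0.4) +
    ggplot2::labs(x = NULL) +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a line-profile curve
#'
#' Normalized mean gray value per channel against relative distance.
#'
#' @param object a [line_profile()] tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.profile_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              -"relative_distance",
                              names_to = "channel", values_to = "intensity")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$relative_distance,
                                     y = .data$intensity,
                                     colour = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "relative distance", y = "normalized mean gray value") +
    ggplot2::theme_classic()
}

#' Plot a deposition pattern along the anteroposterior axis
#'
#' @param object a [deposition_pattern()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.deposition_pattern <- function(object, ...) {
  df <- tibble::tibble(
    position_um = object$positions_um,
    what = c("ganglion", rep("neuromast", length(object$positions_um) - 1)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position_um, y = 0,
                                   shape = .data$what)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_y_continuous(NULL, breaks = NULL) +
    ggplot2::labs(x = "position along AP axis (um, ganglion = 0)") +
    ggplot2::theme_classic()
}
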