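#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a depth profile
#'
#' Mean value versus normalized depth (0 = articulating surface, 1 =
#' cartilage-bone interface) with a +/- 1 SD ribbon.
#'
#' @param object a `depth_profile`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.depth_profile <- function(object, ...) {
  kind <- attr(object, "kind")
  ylab <- switch(kind,
                 partition_pct = "Ioxaglate partition (%)",
                 od = "Optical density",
                 "Attenuation (HU)")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$depth, y = .data$value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$value - .data$sd,
                                      ymax = .data$value + .data$sd),
                         alpha = 0.2) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Normalized depth (0 = surface, 1 = bone interface)",
                  y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot cohort VOI results by location
#'
#' Boxplots of the full-thickness partition (or OD) per location, mirroring
#' the study's summary figure.
#'
#' @param voi_results tibble from [simulate_cohort()] / [run_pipeline()].
#' @param value column to plot (tidy-eval; default `mean_partition_pct`).
#' @return A ggplot.
#' @export
plot_voi_summary <- function(voi_results, value = mean_partition_pct) {
  value <- rlang::enquo(value)
  df <- dplyr::mutate(
    voi_results,
    role = factor(.data$role, c("lesion", "away_3mm", "contralateral"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$role, y = !!value)) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5, size = 1) +
    ggplot2::labs(x = NULL, y = rlang::as_label(value)) +
    ggplot2::theme_minimal()
}

#' Plot profiles of all three locations of a joint
#'
#' @param results tibble with `role` and `profile` list-column (one joint).
#' @return A ggplot of the three mean profiles.
#' @export
plot_joint_profiles <- function(results) {
  df <- tidyr::unnest(
    dplyr::mutate(results[, c("role", "profile")],
                  profile = purrr::map(.data$profile, tibble::as_tibble)),
    "profile"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth, y = .data$value,
                                   colour = .data$role)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Normalized depth", y = "Value", colour = "Location") +
    ggplot2::theme_minimal()
}
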