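#' Pseudotime versus real sampling time
#'
#' Boxplots of normalized pseudotime per sampling time, the standard view of
#' a lagged modality response.
#'
#' @param object an oriented `pseudotime_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pseudotime_result <- function(object, ...) {
  stopifnot(isTRUE(object$oriented))
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$time_point_h), .data$u)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "time of hypoxia (h)", y = "normalized pseudotime") +
    ggplot2::theme_minimal()
}

#' Joint transcription-translation profiles
#'
#' Ribbon plot of standardized abundance (windowed mean with 95% confidence
#' band) against the common pseudotemporal axis, colored by modality and
#' faceted by feature.
#'
#' @param object a `joint_profile` tibble from [feature_profile()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.joint_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$u, .data$mean,
                                       color = .data$modality,
                                       fill = .data$modality)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25, color = NA) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~feature) +
    ggplot2::labs(x = "common pseudotemporal axis",
                  y = "standardized abundance") +
    ggplot2::theme_minimal()
}

#' Detection completeness versus abundance
#'
#' Scatter of per-feature detection rate against mean observed log abundance
#' for a protein matrix, the diagnostic of DDA-like acquisition bias.
#'
#' @param x a raw or normalized protein `scm` with a missing mask.
#' @return a ggplot object.
#' @export
plot_completeness <- function(x) {
  stopifnot(inherits(x, "scm"), x$modality == "protein")
  v <- scm_values(x)
  d <- tibble::tibble(
    feature = colnames(v),
    detection_rate = colMeans(!is.na(v)),
    mean_log_abundance = suppressWarnings(log(colMeans(v, na.rm = TRUE)))
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$mean_log_abundance, .data$detection_rate)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "mean log abundance (observed)",
                  y = "fraction of cells detected") +
    ggplot2::theme_minimal()
}
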