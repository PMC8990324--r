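#' Plot an estimated valence trajectory with its confidence band
#'
#' @param object A `valence_em` object from [fit_valence_model()].
#' @param ... Unused.
#' @return A ggplot of the smoothed state with its 95% band, over the
#'   continuous feature.
#' @method autoplot valence_em
#' @export
autoplot.valence_em <- function(object, ...) {
  tr <- object$trajectory
  ggplot2::ggplot(tr, ggplot2::aes(.data$k)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         fill = "darkgreen", alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$x_sm), colour = "darkgreen") +
    ggplot2::labs(x = "bin", y = "estimated valence state") +
    ggplot2::theme_minimal()
}

#' Plot extracted EMG features
#'
#' @param features A tibble from [extract_features()].
#' @return A ggplot with the binary spikes and the continuous log-bandpower
#'   feature in stacked facets.
#' @export
plot_features <- function(features) {
  d <- dplyr::bind_rows(
    tibble(t_s = features$t_start_s, value = as.numeric(features$n),
           panel = "binary feature n"),
    tibble(t_s = features$t_start_s, value = features$z,
           panel = "continuous feature z")
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$t_s, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "firebrick") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}
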