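#' Plot trophic-position estimates by species and framework
#'
#' Points with propagated-SD error bars, one panel per framework, plus the
#' stomach-content TP as a reference mark when available.
#'
#' @param object A `tp_estimates` tibble from [estimate_tp()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tp_estimates
#' @export
autoplot.tp_estimates <- function(object, ...) {
  est <- tibble::as_tibble(object)
  est <- est[!is.na(est$tp), , drop = FALSE]
  p <- ggplot2::ggplot(
    est,
    ggplot2::aes(x = .data$species, y = .data$tp, colour = .data$tissue)
  ) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$tp - .data$tp_sd, ymax = .data$tp + .data$tp_sd),
      position = ggplot2::position_jitter(width = 0.15, height = 0),
      fatten = 1.5, alpha = 0.8
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$framework)) +
    ggplot2::labs(
      x = NULL, y = "Trophic position",
      colour = "Tissue"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if ("tp_sc" %in% names(est)) {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(y = .data$tp_sc),
      shape = 4, size = 3, colour = "black", na.rm = TRUE
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Glx-Phe difference against stomach-content trophic position
#'
#' The diagnostic scatter for whether the Glx-Phe delta-15N difference works
#' as an index of relative trophic position: under the standard model it
#' should increase monotonically with TP.
#'
#' @param deltas A per-specimen table with `delta_glx_phe`, `tp_sc`,
#'   `species` (e.g. `study_fixture()$deltas` or [glx_phe_difference()]
#'   output joined to diet-derived TPs).
#' @return A ggplot object.
#' @export
plot_delta_vs_tp <- function(deltas) {
  ggplot2::ggplot(
    tibble::as_tibble(deltas),
    ggplot2::aes(
      x = .data$tp_sc, y = .data$delta_glx_phe, colour = .data$species
    )
  ) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = "Stomach-content trophic position",
      y = expression(delta^15 * N[Glx - Phe] ~ "(‰)"),
      colour = "Species"
    ) +
    ggplot2::theme_minimal()
}
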