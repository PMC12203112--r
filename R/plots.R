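#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the balancing-factor sensitivity curve
#'
#' Objective value against lambda with the selected transition point marked.
#'
#' @param object A `lambda_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lambda_scan
#' @export
autoplot.lambda_scan <- function(object, ...) {
  p <- object$path
  ycol <- if ("z" %in% names(p)) "z" else "mean_cor"
  ggplot2::ggplot(p, ggplot2::aes(x = .data$lambda, y = .data[[ycol]])) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$selected, colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(x = expression(lambda),
                  y = if (ycol == "z") "objective z*" else "mean Spearman correlation",
                  title = paste0("Balancing-factor selection (", object$method, ")"),
                  subtitle = paste("selected lambda =", format(object$selected))) +
    ggplot2::theme_minimal()
}

#' Plot predicted growth rates
#'
#' @param object An `imic_fit`.
#' @param ... Unused.
#' @return A ggplot bar chart of member growth rates.
#' @method autoplot imic_fit
#' @export
autoplot.imic_fit <- function(object, ...) {
  ggplot2::ggplot(object$growth,
                  ggplot2::aes(x = stats::reorder(.data$member, -.data$mu),
                               y = .data$mu)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "member", y = expression(mu ~ (h^-1)),
                  title = paste0("Predicted growth rates (sample ",
                                 object$sample_id, ", lambda = ",
                                 format(object$lambda), ")")) +
    ggplot2::theme_minimal()
}

#' Plot top exchanged metabolites by minimum flux sum
#'
#' @param fluxsum Result of [essential_imports()].
#' @param top_k Number of metabolites to show, ranked by their maximum
#'   flux sum over samples.
#' @return A ggplot.
#' @export
plot_flux_sum <- function(fluxsum, top_k = 20) {
  rank <- dplyr::summarise(dplyr::group_by(fluxsum, .data$metabolite),
                           phi = max(.data$phi_min), .groups = "drop")
  keep <- rank$metabolite[order(-rank$phi)][seq_len(min(top_k, nrow(rank)))]
  d <- fluxsum[fluxsum$metabolite %in% keep, ]
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$metabolite, .data$phi_min),
                                  y = .data$phi_min, fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~sample_id) +
    ggplot2::labs(x = NULL, y = "minimum flux sum (mmol/gDW/h)", fill = "class") +
    ggplot2::theme_minimal()
}
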