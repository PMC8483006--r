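# ggplot2 figure helpers. Latitude axes run poleward to the right
# (degrees South as positive values), matching the transect convention.

#' Plot the latitudinal richness gradient
#'
#' Regional range-through richness as a line, with mean rarefied local
#' richness overlaid as points (secondary-axis-free: rarefied values are
#' drawn on their own scale only when `rescale_local = TRUE`).
#'
#' @param bin_table A bin table with `bin_mid`, `richness` and optionally
#'   `mean_rarefied_richness`.
#' @param rescale_local Multiply local richness onto the regional scale for
#'   display (regional max / local max), default `TRUE`.
#' @return A ggplot object.
#' @export
plot_gradient <- function(bin_table, rescale_local = TRUE) {
  p <- ggplot2::ggplot(bin_table, ggplot2::aes(x = .data$bin_mid)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$richness), linewidth = 0.6) +
    ggplot2::labs(x = "Latitude (degrees S)", y = "Species richness") +
    ggplot2::theme_minimal()
  if ("mean_rarefied_richness" %in% names(bin_table) &&
      any(!is.na(bin_table$mean_rarefied_richness))) {
    scale <- if (rescale_local) {
      max(bin_table$richness, na.rm = TRUE) /
        max(bin_table$mean_rarefied_richness, na.rm = TRUE)
    } else 1
    p <- p + ggplot2::geom_point(
      data = dplyr::filter(bin_table, !is.na(.data$mean_rarefied_richness)),
      ggplot2::aes(y = .data$mean_rarefied_richness * scale),
      colour = "steelblue", size = 1.6
    )
  }
  p
}

#' @method autoplot ldg_forest
#' @export
autoplot.ldg_forest <- function(object, ...) {
  df <- tibble::tibble(observed = object$data[[object$response]],
                       predicted = object$oob_predictions)
  ggplot2::ggplot(df, ggplot2::aes(.data$observed, .data$predicted)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Observed richness", y = "OOB predicted richness",
                  subtitle = sprintf("pseudo-r2 = %.2f", object$pseudo_r2)) +
    ggplot2::theme_minimal()
}

#' @method autoplot ldg_pd
#' @export
autoplot.ldg_pd <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$value, .data$yhat)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$predictor), scales = "free_x") +
    ggplot2::labs(x = "Predictor value", y = "Partial predicted richness") +
    ggplot2::theme_minimal()
}

#' @method autoplot ldg_correlogram
#' @export
autoplot.ldg_correlogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$mean_distance, .data$moran_i)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$null_lo,
                                      ymax = .data$null_hi),
                         fill = "grey80") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Latitudinal distance (degrees)", y = "Moran's I") +
    ggplot2::theme_minimal()
}

#' @method autoplot ldg_phylo
#' @export
autoplot.ldg_phylo <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::mutate(object, bin_index = dplyr::row_number()),
    cols = c("pd_ses", "mpd_ses", "vpd_obs"),
    names_to = "index", values_to = "value"
  )
  ggplot2::ggplot(dplyr::filter(long, !is.na(.data$value)),
                  ggplot2::aes(.data$bin_index, .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$index), scales = "free_y",
                        ncol = 1) +
    ggplot2::labs(x = "Latitudinal bin (equator to pole)", y = "Index value") +
    ggplot2::theme_minimal()
}
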