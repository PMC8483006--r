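#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the richness forest: per-predictor importance
#'
#' @param x An `ldg_forest`.
#' @param ... Unused.
#' @return A tibble with `predictor` and the forest's built-in
#'   (unconditional) permutation `importance`, sorted decreasing.
#' @export
tidy.ldg_forest <- function(x, ...) {
  imp <- x$model$variable.importance
  dplyr::arrange(tibble::tibble(predictor = names(imp),
                                importance = unname(imp)),
                 dplyr::desc(.data$importance))
}

#' @rdname tidy.ldg_forest
#' @return `glance()`: a one-row tibble with `pseudo_r2`, `n_bins`,
#'   `n_trees`, `mtry`, `min_node_size`.
#' @export
glance.ldg_forest <- function(x, ...) {
  tibble::tibble(pseudo_r2 = x$pseudo_r2, n_bins = nrow(x$data),
                 n_trees = x$config$n_trees, mtry = x$mtry,
                 min_node_size = x$config$min_node_size)
}

#' Tidy the local-regional saturation fit
#'
#' @param x An `ldg_saturation`.
#' @param ... Unused.
#' @return The polynomial coefficient table (`term`, `estimate`, `p_value`).
#' @export
tidy.ldg_saturation <- function(x, ...) x$fit

#' @rdname tidy.ldg_saturation
#' @export
glance.ldg_saturation <- function(x, ...) {
  tibble::tibble(pearson_r = x$pearson_r, p_value = x$p_value,
                 n_bins = x$n_bins, r2 = x$r2,
                 p_linear = x$fit$p_value[2], p_quadratic = x$fit$p_value[3])
}

#' Tidy Blomberg's K result
#'
#' @param x An `ldg_physig`.
#' @param ... Unused.
#' @return A one-row tibble with `k`, `p_value`, `n_tips`, `n_perm`.
#' @export
tidy.ldg_physig <- function(x, ...) {
  tibble::tibble(k = x$k, p_value = x$p_value, n_tips = x$n_tips,
                 n_perm = x$n_perm)
}

#' Tidy a full pipeline run: driver attribution summary
#'
#' @param x An `ldg_pipeline`.
#' @param ... Unused.
#' @return A tibble, one row per predictor: VIF, conditional importance,
#'   importance p-value and (where tested) Blomberg's K with its p-value —
#'   the package's analogue of a drivers summary table.
#' @export
tidy.ldg_pipeline <- function(x, ...) {
  x$vif |>
    dplyr::select("predictor", "vif") |>
    dplyr::left_join(dplyr::select(x$importance, "predictor", "importance"),
                     by = "predictor") |>
    dplyr::left_join(dplyr::select(x$importance_p, "predictor",
                                   importance_p = "p_value"),
                     by = "predictor") |>
    dplyr::left_join(dplyr::select(x$signal, predictor = "proxy", "k",
                                   k_p = "p_value"),
                     by = "predictor") |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @rdname tidy.ldg_pipeline
#' @export
glance.ldg_pipeline <- function(x, ...) {
  peak <- which.max(x$bin_table$richness)
  tibble::tibble(
    n_species = x$manifest$n_species,
    n_bins = nrow(x$bin_table),
    max_richness = x$bin_table$richness[peak],
    peak_latitude = x$bin_table$bin_mid[peak],
    local_regional_r = if (is.null(x$saturation)) NA_real_ else
      x$saturation$pearson_r,
    pseudo_r2 = x$forest$pseudo_r2
  )
}
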