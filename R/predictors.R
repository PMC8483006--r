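#' Aggregate environmental pixels to latitudinal bins
#'
#' Averages pixel-level predictor values over each half-degree bin using
#' only shelf pixels (depth strictly below the cutoff). Shelf area is an
#' extensive quantity and is summed, not averaged; all other predictors are
#' intensive and take the arithmetic mean. Bins with no qualifying pixel
#' carry `NA`.
#'
#' @param pixels A data frame with `latitude` (degrees South), `depth`
#'   (metres, positive down) and any subset of the predictor columns
#'   (`sst`, `sst_range`, `salinity`, `salinity_range`, `prim_prod`,
#'   `shelf_area`).
#' @param domain,width Bin grid, as in [latitude_bins()].
#' @param depth_cutoff Shelf depth cutoff in metres, default 200; pixels at
#'   exactly the cutoff are excluded.
#' @return A tibble with `bin_lower`, `bin_upper`, `bin_mid` and one column
#'   per predictor present in `pixels`.
#' @export
aggregate_pixels <- function(pixels, domain = c(3, 56), width = 0.5,
                             depth_cutoff = 200) {
  require_columns(pixels, c("latitude", "depth"), "pixels")
  if (!is.numeric(depth_cutoff) || depth_cutoff <= 0) {
    stop("`depth_cutoff` must be positive.", call. = FALSE)
  }
  bins <- latitude_bins(domain, width)
  vars <- intersect(predictor_names(), names(pixels))
  if (length(vars) == 0L) {
    stop("pixel table holds no recognised predictor column.", call. = FALSE)
  }
  shelf <- dplyr::filter(tibble::as_tibble(pixels), .data$depth < depth_cutoff)
  if (nrow(shelf) == 0L) {
    stop(sprintf("no pixels shallower than %g m.", depth_cutoff),
         call. = FALSE)
  }
  agg <- shelf |>
    dplyr::mutate(bin = bin_of_latitude(.data$latitude, bins)) |>
    dplyr::filter(!is.na(.data$bin)) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(setdiff(vars, "shelf_area")), mean),
      dplyr::across(dplyr::any_of("shelf_area"), sum),
      .by = "bin"
    )
  bins |>
    dplyr::mutate(bin = dplyr::row_number()) |>
    dplyr::left_join(agg, by = "bin") |>
    dplyr::select(-"bin")
}

#' Median latitudinal range of the species in each bin
#'
#' For every bin, the median of `lat_max - lat_min` over the species whose
#' ranges intersect the bin (range-through membership). Extents are the FULL,
#' unclipped ranges — species limits estimated beyond the study domain count
#' at their actual value — while membership itself uses the domain-clipped
#' intersection rule. Empty bins carry `NA`.
#'
#' @inheritParams range_through_richness
#' @return A tibble with `bin_lower`, `bin_upper`, `bin_mid`,
#'   `median_lat_range`.
#' @export
median_lat_range_by_bin <- function(ranges, domain = c(3, 56), width = 0.5) {
  ranges <- validate_ranges(ranges)
  bins <- latitude_bins(domain, width)
  member <- range_bin_membership(pmax(ranges$lat_min, domain[1]),
                                 pmin(ranges$lat_max, domain[2]),
                                 bins)
  outside <- ranges$lat_max < domain[1] | ranges$lat_min >= domain[2]
  member[outside, ] <- FALSE
  extent <- ranges$lat_max - ranges$lat_min
  med <- apply(member, 2, function(in_bin) {
    if (!any(in_bin)) NA_real_ else stats::median(extent[in_bin])
  })
  dplyr::mutate(bins, median_lat_range = med)
}

#' Variance inflation factors for a predictor matrix
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from an OLS of predictor `j`
#' on all other predictors with intercept. Rows with any missing value are
#' dropped listwise. Exact collinearity is reported as an infinite VIF with
#' an explicit flag rather than a numeric overflow.
#'
#' @param predictors A data frame of numeric predictor columns (non-predictor
#'   columns such as bin edges are ignored if named `bin_lower`, `bin_upper`,
#'   `bin_mid`).
#' @return A tibble with `predictor`, `vif`, `exact_collinear`.
#' @export
vif_diagnostics <- function(predictors) {
  x <- dplyr::select(tibble::as_tibble(predictors),
                     -dplyr::any_of(c("bin_lower", "bin_upper", "bin_mid")))
  x <- dplyr::select(x, dplyr::where(is.numeric))
  x <- x[stats::complete.cases(x), , drop = FALSE]
  p <- ncol(x)
  if (p < 2L) stop("need at least two predictor columns.", call. = FALSE)
  if (nrow(x) < p + 2L) {
    stop(sprintf("need at least p + 2 = %d complete rows, got %d.",
                 p + 2L, nrow(x)), call. = FALSE)
  }
  sds <- vapply(x, stats::sd, numeric(1))
  if (any(sds == 0)) {
    stop(sprintf("degenerate input: constant column %s.",
                 names(x)[sds == 0][1]), call. = FALSE)
  }
  xm <- as.matrix(x)
  res <- purrr::map(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, xm[, -j, drop = FALSE]), xm[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((xm[, j] - mean(xm[, j]))^2)
    r2 <- 1 - rss / tss
    exact <- rss <= tss * 1e-12
    list(vif = if (exact) Inf else 1 / (1 - r2), exact = exact)
  })
  tibble::tibble(
    predictor = colnames(xm),
    vif = purrr::map_dbl(res, "vif"),
    exact_collinear = purrr::map_lgl(res, "exact")
  )
}

#' Assemble the full per-bin analysis table
#'
#' Joins regional range-through richness, mean rarefied local richness, the
#' per-bin predictor table and the median latitudinal range into the single
#' bin table all downstream analyses consume.
#'
#' @param ranges Species range table.
#' @param assemblages Long assemblage table, or `NULL` to skip the
#'   rarefaction columns.
#' @param predictors Per-bin predictor table (see [validate_predictors()]),
#'   or a pixel table to be passed through [aggregate_pixels()] when it has
#'   a `depth` column.
#' @param domain,width Bin grid.
#' @param rarefaction_n Rarefaction size, default 20.
#' @param depth_cutoff Shelf cutoff for pixel tables, default 200 m.
#' @return A tibble with one row per bin: bin edges and midpoint,
#'   `richness`, `mean_rarefied_richness`, `n_sites`, the six predictors and
#'   `median_lat_range`.
#' @export
build_bin_table <- function(ranges, assemblages = NULL, predictors = NULL,
                            domain = c(3, 56), width = 0.5,
                            rarefaction_n = 20, depth_cutoff = 200) {
  out <- range_through_richness(ranges, domain, width)
  if (!is.null(assemblages)) {
    rar <- mean_rarefied_by_bin(assemblages, rarefaction_n, domain, width)
    out <- dplyr::left_join(
      out, dplyr::select(rar, "bin_lower", "mean_rarefied_richness", "n_sites"),
      by = "bin_lower"
    )
  }
  if (!is.null(predictors)) {
    if ("depth" %in% names(predictors)) {
      predictors <- aggregate_pixels(predictors, domain, width, depth_cutoff)
      predictors <- dplyr::select(predictors, -dplyr::any_of("bin_mid"))
    } else {
      predictors <- validate_predictors(predictors)
    }
    out <- dplyr::left_join(
      out, dplyr::select(predictors, -dplyr::any_of("bin_upper")),
      by = "bin_lower"
    )
  }
  mlr <- median_lat_range_by_bin(ranges, domain, width)
  dplyr::left_join(out,
                   dplyr::select(mlr, "bin_lower", "median_lat_range"),
                   by = "bin_lower")
}
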