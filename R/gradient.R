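#' Range-through species richness per latitudinal bin
#'
#' Scores every species present in each half-open bin `[lower, upper)` whose
#' interval intersects the species' closed latitudinal range (the
#' range-through assumption: a continuous distribution between the observed
#' range limits). Ranges are clipped to the domain for binning; species whose
#' full extent misses the domain contribute to no bin. Touching a bin's lower
#' edge counts as presence, touching its upper edge does not, so the tiling
#' never double-counts a range endpoint.
#'
#' @param ranges Species range table (see [validate_ranges()]).
#' @param domain Latitude interval in degrees South, default `c(3, 56)`.
#' @param width Bin width in degrees, default 0.5.
#' @return A tibble with `bin_lower`, `bin_upper`, `bin_mid`, `richness`.
#'   An empty range table gives zero richness everywhere.
#' @examples
#' rng <- tibble::tibble(species = c("a", "b"), family = "f", genus = "g",
#'                       lat_min = c(10, 11.4), lat_max = c(12, 11.6))
#' range_through_richness(rng, domain = c(3, 56))
#' @export
range_through_richness <- function(ranges, domain = c(3, 56), width = 0.5) {
  bins <- latitude_bins(domain, width)
  if (is.null(ranges) || nrow(ranges) == 0L) {
    return(dplyr::mutate(bins, richness = 0L))
  }
  ranges <- validate_ranges(ranges)
  member <- range_bin_membership(pmax(ranges$lat_min, domain[1]),
                                 pmin(ranges$lat_max, domain[2]),
                                 bins)
  # clipping can invert ranges that lie wholly outside the domain
  outside <- ranges$lat_max < domain[1] | ranges$lat_min >= domain[2]
  member[outside, ] <- FALSE
  dplyr::mutate(bins, richness = as.integer(colSums(member)))
}

#' Bin-by-species presence matrix (range-through)
#'
#' The binary community matrix underlying [range_through_richness()]: rows
#' are bins, columns species, entries presence under the range-through rule
#' after clipping to the domain.
#'
#' @inheritParams range_through_richness
#' @return A logical matrix, `length(bins)` x `nrow(ranges)`, with dimnames.
#' @export
range_through_membership <- function(ranges, domain = c(3, 56), width = 0.5) {
  ranges <- validate_ranges(ranges)
  bins <- latitude_bins(domain, width)
  member <- range_bin_membership(pmax(ranges$lat_min, domain[1]),
                                 pmin(ranges$lat_max, domain[2]),
                                 bins)
  outside <- ranges$lat_max < domain[1] | ranges$lat_min >= domain[2]
  member[outside, ] <- FALSE
  m <- t(member)
  dimnames(m) <- list(format_bin_labels(bins), ranges$species)
  m
}

format_bin_labels <- function(bins) {
  sprintf("[%g,%g)", bins$bin_lower, bins$bin_upper)
}

#' Individual-based (Hurlbert) rarefaction
#'
#' Expected species count in a uniform random subsample of `n` individuals
#' drawn without replacement from an abundance vector:
#' `E(S_n) = sum_i (1 - choose(N - N_i, n) / choose(N, n))`, evaluated with
#' log-scale combinatorics so large counts cannot overflow.
#'
#' @param counts Non-negative integer abundance vector (zeros are dropped).
#' @param n Subsample size (default 20 individuals, a typical minimum site
#'   total in soft-bottom surveys).
#' @return Expected species count, a number in `[1, S]`. Errors with
#'   "insufficient individuals" when the site total is below `n`; callers
#'   exclude such sites rather than zero-filling them.
#' @examples
#' rarefy_count(c(a = 5, b = 3, c = 2), n = 4)
#' @export
rarefy_count <- function(counts, n = 20) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("`n` must be a single positive integer.", call. = FALSE)
  }
  counts <- counts[counts > 0]
  if (any(counts != round(counts))) {
    stop("`counts` must be integers.", call. = FALSE)
  }
  N <- sum(counts)
  if (N < n) {
    stop(sprintf("insufficient individuals: site total %d < rarefaction size %d.",
                 N, as.integer(n)), call. = FALSE)
  }
  # P(species i absent from the subsample) = C(N - N_i, n) / C(N, n)
  p_absent <- exp(lchoose(N - counts, n) - lchoose(N, n))
  sum(1 - p_absent)
}

#' Mean rarefied richness per latitudinal bin
#'
#' Rarefies every eligible site to `n` individuals and averages within the
#' half-degree bin holding the site's latitude. Sites with fewer than `n`
#' individuals are excluded (with a message); bins without an eligible site
#' carry `NA`.
#'
#' @param assemblages Long assemblage table (see [validate_assemblages()]).
#' @param n Rarefaction size, default 20.
#' @inheritParams range_through_richness
#' @return A tibble with `bin_lower`, `bin_upper`, `bin_mid`,
#'   `mean_rarefied_richness`, `n_sites`.
#' @export
mean_rarefied_by_bin <- function(assemblages, n = 20, domain = c(3, 56),
                                 width = 0.5) {
  assemblages <- validate_assemblages(assemblages)
  bins <- latitude_bins(domain, width)

  per_site <- assemblages |>
    dplyr::summarise(latitude = dplyr::first(.data$latitude),
                     total = sum(.data$count),
                     .by = "site")
  short <- per_site$total < n
  if (any(short)) {
    message(sprintf("excluding %d site(s) with fewer than %d individuals.",
                    sum(short), as.integer(n)))
  }
  eligible <- per_site$site[!short]

  rarefied <- assemblages |>
    dplyr::filter(.data$site %in% eligible) |>
    dplyr::summarise(
      latitude = dplyr::first(.data$latitude),
      rarefied = rarefy_count(.data$count, n),
      .by = "site"
    ) |>
    dplyr::mutate(bin = bin_of_latitude(.data$latitude, bins)) |>
    dplyr::filter(!is.na(.data$bin)) |>
    dplyr::summarise(mean_rarefied_richness = mean(.data$rarefied),
                     n_sites = dplyr::n(), .by = "bin")

  bins |>
    dplyr::mutate(bin = dplyr::row_number()) |>
    dplyr::left_join(rarefied, by = "bin") |>
    dplyr::mutate(n_sites = dplyr::coalesce(.data$n_sites, 0L)) |>
    dplyr::select(-"bin")
}

#' Local-regional richness relationship and saturation test
#'
#' Correlates mean rarefied local richness with regional (range-through)
#' richness over the bins holding both, and fits a second-order polynomial
#' OLS of local on regional richness. A significant quadratic term supports
#' saturation of local assemblages; a significant linear term with a
#' non-significant quadratic term supports unsaturated, "open" assemblages.
#' The Pearson p-value uses the classical t transform with n - 2 degrees of
#' freedom.
#'
#' @param bins A bin table holding `richness` and `mean_rarefied_richness`
#'   columns (e.g. the output of [build_bin_table()]).
#' @return An object of class `ldg_saturation`: a list with `pearson_r`,
#'   `p_value`, `n_bins`, and a `fit` tibble of polynomial coefficients with
#'   p-values, plus `r2`.
#' @export
local_regional_test <- function(bins) {
  require_columns(bins, c("richness", "mean_rarefied_richness"), "bin")
  ok <- stats::complete.cases(bins$richness, bins$mean_rarefied_richness)
  x <- bins$richness[ok]
  y <- bins$mean_rarefied_richness[ok]
  n <- length(x)
  if (n < 4L) {
    stop(sprintf("insufficient data: %d bin(s) with both local and regional richness (need >= 4).",
                 n), call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: zero variance in local or regional richness.",
         call. = FALSE)
  }
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)

  fit <- stats::lm(y ~ x + I(x^2))
  cf <- summary(fit)$coefficients
  out <- list(
    pearson_r = r,
    p_value = p,
    n_bins = n,
    fit = tibble::tibble(
      term = c("intercept", "linear", "quadratic"),
      estimate = unname(cf[, 1]),
      p_value = unname(cf[, 4])
    ),
    r2 = summary(fit)$r.squared
  )
  class(out) <- "ldg_saturation"
  out
}

#' @export
print.ldg_saturation <- function(x, ...) {
  cat("<ldg_saturation>\n")
  cat(sprintf("  Pearson r = %.3f (p = %.4g, n = %d bins)\n",
              x$pearson_r, x$p_value, x$n_bins))
  cat(sprintf("  polynomial OLS: p(linear) = %.4g, p(quadratic) = %.4g, r2 = %.3f\n",
              x$fit$p_value[2], x$fit$p_value[3], x$r2))
  verdict <- if (x$fit$p_value[3] < 0.05) "saturated" else
    if (x$fit$p_value[2] < 0.05) "unsaturated (open assemblages)" else
      "inconclusive"
  cat(sprintf("  verdict: %s\n", verdict))
  invisible(x)
}
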