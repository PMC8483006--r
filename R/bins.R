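#' Latitudinal bin grid
#'
#' Tile a latitudinal domain into contiguous half-open bins
#' `[bin_lower, bin_upper)`. Latitudes are degrees South expressed as
#' positive reals throughout the package (3 means 3 degrees S), so "towards
#' the pole" is increasing latitude.
#'
#' @param domain Numeric length-2, lower and upper domain limit in degrees
#'   South. Default `c(3, 56)`, the Guayaquil Gulf to Cape Horn transect.
#' @param width Bin width in degrees, default 0.5.
#' @return A tibble with columns `bin_lower`, `bin_upper`, `bin_mid`, one row
#'   per bin, ordered from the equatorward edge.
#' @examples
#' latitude_bins()          # 106 half-degree bins over 3-56 degrees S
#' latitude_bins(c(0, 10), 1)
#' @export
latitude_bins <- function(domain = c(3, 56), width = 0.5) {
  check_domain(domain)
  if (!is.numeric(width) || length(width) != 1L || !is.finite(width) || width <= 0) {
    stop("`width` must be a single positive number.", call. = FALSE)
  }
  n <- ceiling((domain[2] - domain[1]) / width - 1e-9)
  lower <- domain[1] + width * (seq_len(n) - 1L)
  tibble::tibble(
    bin_lower = lower,
    bin_upper = pmin(lower + width, domain[2]),
    bin_mid = (lower + pmin(lower + width, domain[2])) / 2
  )
}

check_domain <- function(domain) {
  if (!is.numeric(domain) || length(domain) != 2L || anyNA(domain) ||
      !all(is.finite(domain)) || domain[1] >= domain[2]) {
    stop("`domain` must be two finite numbers with lower < upper.", call. = FALSE)
  }
  invisible(domain)
}

# Seed `seed` for the duration of the calling function, then restore the
# caller's RNG stream, so package functions are reproducible without
# perturbing user-level replication.
local_seed <- function(seed, env = parent.frame()) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  restore <- function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
  do.call(on.exit, list(as.call(list(restore)), add = TRUE), envir = env)
  set.seed(as.integer(seed))
  invisible()
}

# Half-open bin lookup: lower <= lat < upper; NA outside the grid.
bin_of_latitude <- function(lat, bins) {
  idx <- findInterval(lat, c(bins$bin_lower, bins$bin_upper[nrow(bins)]),
                      rightmost.closed = FALSE)
  idx[idx < 1L | idx > nrow(bins)] <- NA_integer_
  # points exactly on the top edge fall outside the half-open tiling
  idx[!is.na(lat) & lat >= bins$bin_upper[nrow(bins)]] <- NA_integer_
  idx
}

# Logical species x bin membership: closed species interval [lat_min, lat_max]
# intersects the half-open bin [lower, upper). Touching the lower edge counts,
# touching the upper edge does not.
range_bin_membership <- function(lat_min, lat_max, bins) {
  outer(lat_min, bins$bin_upper, `<`) & outer(lat_max, bins$bin_lower, `>=`)
}
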