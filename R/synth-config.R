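#' Configuration for the synthetic survey generator
#'
#' Bundles and validates every knob of the synthetic data generator. The
#' defaults emulate the structure of a Southeastern-Pacific-style benthic
#' survey: 643 species on a 3-56 degree S shelf transect, a hump-shaped
#' richness gradient peaking at 42 degrees S, taxonomically autocorrelated
#' range midpoints (niche conservatism), 57 soft-bottom assemblage sites
#' concentrated in a subset of bins, and six smooth-to-noisy environmental
#' predictors on the half-degree bin grid.
#'
#' @param n_species Number of species, default 643.
#' @param domain Latitude interval in degrees South, default `c(3, 56)`.
#' @param hump_center Latitude (degrees S) of the richness peak, default 42.
#' @param hump_sd Spread (degrees) of hump-component range midpoints,
#'   default 8.
#' @param conservatism Fraction in `[0, 1]` of midpoint variance shared
#'   within lineages (split evenly between the family and genus levels),
#'   default 0.5. At 1, congeners share a midpoint exactly; at 0 midpoints
#'   are independent of taxonomy.
#' @param n_genera,n_families Lineage counts, defaults 250 and 60
#'   (a few species per genus, as in diverse marine annelid faunas).
#' @param range_width_law Distribution of latitudinal range widths for
#'   hump-component species: a list with `dist = "lognormal"`
#'   (`meanlog`, `sdlog`) or `dist = "uniform"` (`min`, `max`). Default
#'   lognormal with median 12 degrees.
#' @param prop_widespread Fraction of species given very broad, loosely
#'   centred ranges (eurytopic taxa whose limits lie far beyond the study
#'   transect), default 0.25. Set 0 to disable the mixture.
#' @param widespread_width Width range (degrees) for widespread species,
#'   default `c(50, 120)`.
#' @param couple_width_to_center If `TRUE`, range width shrinks with
#'   midpoint distance from `hump_center` (a built-in Rapoport pattern).
#'   Default `FALSE`: widths independent of midpoints, so any
#'   range-size gradient in the output is emergent, not assumed.
#' @param n_sites Number of local assemblages, default 57.
#' @param n_occupied_bins Number of distinct bins the sites fall in, default
#'   29; sites beyond that count are assigned to already-occupied bins.
#' @param individuals_per_site Individuals sampled per site: a single count
#'   or one per site. Default 200.
#' @param evenness Abundance evenness in `(0, 1]`: multinomial weights follow
#'   a geometric rank-abundance series spanning the whole pool, with
#'   `evenness` the rarest-to-commonest weight ratio (1 = equal weights).
#'   Scaling the series to the pool keeps local richness responsive to pool
#'   size. Default 0.05.
#' @param sst_north,sst_south Noise-free SST (degrees C) at the equatorward and
#'   poleward domain edges, defaults 22 and 7; SST decreases monotonically
#'   polewards.
#' @param predictor_noise Multiplier on all predictor noise standard
#'   deviations, default 1; 0 gives noise-free smooth profiles.
#' @param seed Integer RNG seed, default 1.
#' @return An object of class `synth_config` (a validated list).
#' @seealso [simulate_survey()], [generate_ranges()],
#'   [generate_predictors()], [sample_assemblages()]
#' @export
synth_config <- function(n_species = 643,
                         domain = c(3, 56),
                         hump_center = 42,
                         hump_sd = 8,
                         conservatism = 0.5,
                         n_genera = 250,
                         n_families = 60,
                         range_width_law = list(dist = "lognormal",
                                                meanlog = log(12), sdlog = 0.6),
                         prop_widespread = 0.25,
                         widespread_width = c(50, 120),
                         couple_width_to_center = FALSE,
                         n_sites = 57,
                         n_occupied_bins = 29,
                         individuals_per_site = 200,
                         evenness = 0.05,
                         sst_north = 22,
                         sst_south = 7,
                         predictor_noise = 1,
                         seed = 1) {
  cfg <- list(
    n_species = n_species, domain = domain, hump_center = hump_center,
    hump_sd = hump_sd, conservatism = conservatism, n_genera = n_genera,
    n_families = n_families, range_width_law = range_width_law,
    prop_widespread = prop_widespread, widespread_width = widespread_width,
    couple_width_to_center = couple_width_to_center,
    n_sites = n_sites, n_occupied_bins = n_occupied_bins,
    individuals_per_site = individuals_per_site, evenness = evenness,
    sst_north = sst_north, sst_south = sst_south,
    predictor_noise = predictor_noise, seed = seed
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  bad <- function(field, msg) {
    stop(sprintf("Invalid synth_config field `%s`: %s", field, msg),
         call. = FALSE)
  }
  count1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x >= 1 && x == round(x)
  check_domain(cfg$domain)
  if (!count1(cfg$n_species)) bad("n_species", "must be a positive integer.")
  if (!count1(cfg$n_genera)) bad("n_genera", "must be a positive integer.")
  if (!count1(cfg$n_families)) bad("n_families", "must be a positive integer.")
  if (cfg$n_species < cfg$n_genera) {
    bad("n_genera", "cannot exceed n_species.")
  }
  if (cfg$n_genera < cfg$n_families) {
    bad("n_families", "cannot exceed n_genera.")
  }
  if (!is.numeric(cfg$hump_center) || length(cfg$hump_center) != 1L ||
      cfg$hump_center <= cfg$domain[1] || cfg$hump_center >= cfg$domain[2]) {
    bad("hump_center", "must lie strictly inside the domain.")
  }
  if (!is.numeric(cfg$hump_sd) || cfg$hump_sd <= 0) {
    bad("hump_sd", "must be positive.")
  }
  if (!is.numeric(cfg$conservatism) || length(cfg$conservatism) != 1L ||
      cfg$conservatism < 0 || cfg$conservatism > 1) {
    bad("conservatism", "must lie in [0, 1].")
  }
  law <- cfg$range_width_law
  if (!is.list(law) || is.null(law$dist) ||
      !law$dist %in% c("lognormal", "uniform")) {
    bad("range_width_law", "dist must be \"lognormal\" or \"uniform\".")
  }
  if (law$dist == "lognormal" && (is.null(law$meanlog) || is.null(law$sdlog))) {
    bad("range_width_law", "lognormal law needs meanlog and sdlog.")
  }
  if (law$dist == "uniform" &&
      (is.null(law$min) || is.null(law$max) || law$min <= 0 ||
       law$max < law$min)) {
    bad("range_width_law", "uniform law needs 0 < min <= max.")
  }
  if (!is.numeric(cfg$prop_widespread) || cfg$prop_widespread < 0 ||
      cfg$prop_widespread > 1) {
    bad("prop_widespread", "must lie in [0, 1].")
  }
  if (!count1(cfg$n_sites)) bad("n_sites", "must be a positive integer.")
  if (!count1(cfg$n_occupied_bins)) {
    bad("n_occupied_bins", "must be a positive integer.")
  }
  ips <- cfg$individuals_per_site
  if (!is.numeric(ips) || !length(ips) %in% c(1L, cfg$n_sites) ||
      any(ips < 1) || any(ips != round(ips))) {
    bad("individuals_per_site",
        "must be one positive integer or one per site.")
  }
  if (!is.numeric(cfg$evenness) || cfg$evenness <= 0 || cfg$evenness > 1) {
    bad("evenness", "must lie in (0, 1].")
  }
  if (!is.numeric(cfg$predictor_noise) || cfg$predictor_noise < 0) {
    bad("predictor_noise", "must be non-negative.")
  }
  if (!count1(abs(cfg$seed) + 1)) bad("seed", "must be a single integer.")
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  %d species in %d genera / %d families\n",
              x$n_species, x$n_genera, x$n_families))
  cat(sprintf("  domain %.1f-%.1f degrees S, hump at %.1f (sd %.1f), conservatism %.2f\n",
              x$domain[1], x$domain[2], x$hump_center, x$hump_sd,
              x$conservatism))
  cat(sprintf("  %d sites in %d bins, seed %d\n",
              x$n_sites, x$n_occupied_bins, as.integer(x$seed)))
  invisible(x)
}
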