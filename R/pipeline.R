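#' Run the full diversity-gradient pipeline
#'
#' Orchestrates every stage: bin-table construction (range-through richness,
#' rarefied local richness, predictors, median latitudinal range),
#' local-regional saturation test, collinearity diagnostics, the richness
#' random forest with conditional importance, permutation importance
#' p-values, partial dependence curves and residual correlogram, and the
#' taxonomy-proxy phylogenetic stage (per-bin PD/MPD/VPD with SES,
#' index-richness correlations, Blomberg's K of per-species proxy medians).
#' All randomness flows from one root seed, split per stage, so an identical
#' configuration and seed reproduces every number.
#'
#' @param survey An `ldg_survey` (from [simulate_survey()]) or a list with
#'   elements `ranges`, `assemblages` (optional), `predictors`.
#' @param domain,width Bin grid, defaults `c(3, 56)` and 0.5.
#' @param rarefaction_n Rarefaction size, default 20.
#' @param rf An [rf_config()]; its seed is overridden by the pipeline seed.
#' @param importance_trees Trees evaluated for conditional importance,
#'   default 500 (importance stabilises well below the ensemble size).
#' @param n_null Randomizations for SES of PD/MPD, default 999.
#' @param n_signal_perm Trait shuffles for Blomberg's K, default 999.
#' @param correlogram_runs Permutations for the Moran's I envelope,
#'   default 999.
#' @param signal_proxies Bin columns tested for phylogenetic signal; default
#'   every driver predictor except shelf area (an extensive bin property,
#'   not an ambient condition a species experiences).
#' @param seed Root RNG seed, default 1.
#' @param out_dir Optional directory: when given, writes `bin_table.tsv`,
#'   `driver_report.json`, `phylo_report.json`, `saturation_report.json` and
#'   `manifest.json` there (and removes partial outputs on failure).
#' @return An object of class `ldg_pipeline`: a list with `bin_table`,
#'   `vif`, `saturation`, `forest`, `importance`, `importance_p`,
#'   `partial_dependence`, `correlogram`, `phylo`, `phylo_correlations`,
#'   `signal`, and `manifest`.
#' @export
run_ldg_pipeline <- function(survey,
                             domain = c(3, 56), width = 0.5,
                             rarefaction_n = 20,
                             rf = rf_config(),
                             importance_trees = 500,
                             n_null = 999,
                             n_signal_perm = 999,
                             correlogram_runs = 999,
                             signal_proxies = setdiff(
                               default_driver_predictors(), "shelf_area"),
                             seed = 1,
                             out_dir = NULL) {
  ranges <- validate_ranges(survey$ranges)
  assemblages <- if (!is.null(survey$assemblages)) {
    validate_assemblages(survey$assemblages)
  }
  predictors <- survey$predictors
  if (is.null(predictors)) stop("survey has no predictor table.", call. = FALSE)

  local_seed(as.integer(seed))
  stage_seed <- sample.int(.Machine$integer.max, 6)

  bin_table <- build_bin_table(ranges, assemblages, predictors,
                               domain = domain, width = width,
                               rarefaction_n = rarefaction_n)

  saturation <- if (!is.null(assemblages)) local_regional_test(bin_table)
  vif <- vif_diagnostics(bin_table[default_driver_predictors()])

  rf$seed <- stage_seed[1]
  forest <- fit_richness_forest(bin_table, rf)
  importance <- conditional_importance(forest,
                                       n_trees = importance_trees,
                                       seed = stage_seed[2])
  importance_p <- importance_pvalues(bin_table, rf)
  pd_curves <- purrr::map_dfr(forest$predictors,
                              function(v) partial_dependence(forest, v))
  correlogram <- residual_correlogram(forest$residuals,
                                      forest$data$bin_mid,
                                      n_runs = correlogram_runs,
                                      seed = stage_seed[3])

  tree <- taxonomy_tree(ranges)
  membership <- range_through_membership(ranges, domain, width)
  phylo <- ses_phylodiv(membership, tree, n_null = n_null,
                        seed = stage_seed[4])
  phylo_cors <- phylo_richness_correlations(phylo, bin_table$richness)
  signal <- purrr::map_dfr(signal_proxies, function(px) {
    trait <- trait_medians(ranges, bin_table, px, domain, width)
    ps <- blomberg_k(ape::keep.tip(tree, names(trait)), trait,
                     n_perm = n_signal_perm, seed = stage_seed[5])
    tibble::tibble(proxy = px, k = ps$k, p_value = ps$p_value,
                   n_species = ps$n_tips)
  })

  manifest <- list(
    seed = as.integer(seed),
    domain = domain, width = width, rarefaction_n = rarefaction_n,
    rf = unclass(rf), importance_trees = importance_trees,
    n_null = n_null, n_signal_perm = n_signal_perm,
    correlogram_runs = correlogram_runs,
    n_species = nrow(ranges),
    n_sites = if (is.null(assemblages)) 0L else
      dplyr::n_distinct(assemblages$site),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("latdiv"))
  )

  out <- structure(list(
    bin_table = bin_table, vif = vif, saturation = saturation,
    forest = forest, importance = importance, importance_p = importance_p,
    partial_dependence = pd_curves, correlogram = correlogram,
    phylo = phylo, phylo_correlations = phylo_cors, signal = signal,
    tree = tree, manifest = manifest
  ), class = "ldg_pipeline")

  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  on_fail <- function(e) {
    file.remove(written[file.exists(written)])
    stop(e)
  }
  tryCatch({
    f <- file.path(out_dir, "bin_table.tsv")
    write_tsv_base(result$bin_table, f); written <- c(written, f)

    f <- file.path(out_dir, "driver_report.json")
    jsonlite::write_json(list(
      pseudo_r2 = result$forest$pseudo_r2,
      vif = result$vif,
      conditional_importance = result$importance,
      importance_p = result$importance_p,
      partial_dependence = result$partial_dependence,
      correlogram = result$correlogram,
      residuals = tibble::tibble(bin_mid = result$forest$data$bin_mid,
                                 residual = result$forest$residuals)
    ), f, auto_unbox = TRUE, digits = NA); written <- c(written, f)

    f <- file.path(out_dir, "phylo_report.json")
    jsonlite::write_json(list(
      per_bin = result$phylo,
      correlations = result$phylo_correlations,
      blomberg_k = result$signal
    ), f, auto_unbox = TRUE, digits = NA); written <- c(written, f)

    if (!is.null(result$saturation)) {
      f <- file.path(out_dir, "saturation_report.json")
      s <- result$saturation
      jsonlite::write_json(list(pearson_r = s$pearson_r, p_value = s$p_value,
                                n_bins = s$n_bins, fit = s$fit, r2 = s$r2),
                           f, auto_unbox = TRUE, digits = NA)
      written <- c(written, f)
    }

    f <- file.path(out_dir, "newick.tree")
    ape::write.tree(result$tree, f); written <- c(written, f)

    f <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(result$manifest, f, auto_unbox = TRUE, digits = NA)
    written <- c(written, f)
  }, error = on_fail)
  invisible(written)
}

#' @export
print.ldg_pipeline <- function(x, ...) {
  cat("<ldg_pipeline>\n")
  peak <- x$bin_table[which.max(x$bin_table$richness), ]
  cat(sprintf("  richness peak: %d species in bin [%g, %g) degrees S\n",
              peak$richness, peak$bin_lower, peak$bin_upper))
  if (!is.null(x$saturation)) {
    cat(sprintf("  local-regional r = %.3f (p = %.3g, n = %d bins)\n",
                x$saturation$pearson_r, x$saturation$p_value,
                x$saturation$n_bins))
  }
  cat(sprintf("  forest pseudo-r2 = %.3f; significant predictors: %s\n",
              x$forest$pseudo_r2,
              paste(x$importance_p$predictor[x$importance_p$p_value <= 0.05],
                    collapse = ", ")))
  cat(sprintf("  Blomberg's K significant for: %s\n",
              paste(x$signal$proxy[x$signal$p_value <= 0.05],
                    collapse = ", ")))
  invisible(x)
}
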