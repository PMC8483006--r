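# latdiv

Tools for building and explaining **latitudinal diversity gradients (LDGs)**
from species range tables, written for macroecologists working on coastal
transects where the gradient is *not* the canonical tropics-peak — the
motivating case is a hump-shaped gradient on a 3–56° S continental-shelf
transect with a richness maximum near 42° S. The package covers the whole
workflow:

1. **Gradient construction** — range-through binning of species latitudinal
   ranges into half-degree bands: a species is present in every bin between
   its range limits. Richness per bin is the regional diversity curve.
2. **Sampling-bias control** — individual-based (Hurlbert) rarefaction of
   local assemblage counts,
   `E(S_n) = Σ_i [1 − C(N−N_i, n)/C(N, n)]`,
   averaged per bin and tested against regional richness (Pearson r plus a
   second-order polynomial OLS saturation test).
3. **Driver attribution** — a random forest of richness on seven per-bin
   predictors (SST, SST range, salinity, salinity range, primary
   productivity, shelf area, median latitudinal range), with out-of-bag
   pseudo-r², **conditional permutation importance** (predictors permuted
   within strata of their correlated covariates, discretised at each tree's
   own split points), response-permutation importance p-values
   (`p = (1 + #{null ≥ obs})/(B + 1)`), partial dependence curves, and a
   Moran's I residual correlogram with a permutation envelope.
4. **Phylogenetic structure** — a taxonomy-proxy tree (root–family–genus–
   species, unit branch lengths), per-bin Faith's PD, MPD and VPD,
   standardized effect sizes `SES = (obs − null mean)/null SD` from a
   tip-shuffle null, and Blomberg's K phylogenetic signal of per-species
   proxy medians with permutation p-values.
5. **Synthetic data** — a generator that emulates the survey structure
   (hump-shaped midpoint density, taxonomically autocorrelated ranges,
   smooth environmental gradients, multinomial assemblage sampling), so the
   entire pipeline is testable with no external data.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` methods on fitted objects, `autoplot()` / `plot_gradient()` for
figures.

## Worked example

```r
library(latdiv)

survey <- simulate_survey(synth_config(seed = 2024))
result <- run_ldg_pipeline(
  survey,
  rf = rf_config(n_trees = 500, n_perm_importance = 199),
  n_null = 499, n_signal_perm = 499, correlogram_runs = 499,
  seed = 2024
)
result
#> <ldg_pipeline>
#>   richness peak: 451 species in bin [40, 40.5) degrees S
#>   local-regional r = 0.948 (p = 6.73e-15, n = 29 bins)
#>   forest pseudo-r2 = 0.981; significant predictors: sst, sst_range, salinity, median_lat_range
#>   Blomberg's K significant for: sst, sst_range, salinity

tidy(result)
#> # A tibble: 7 x 6
#>   predictor          vif importance importance_p      k    k_p
#>   <chr>            <dbl>      <dbl>        <dbl>  <dbl>  <dbl>
#> 1 median_lat_range  3.64    1094.          0.005  0.482  0.21
#> 2 sst              10.9      146.          0.005  0.589  0.002
#> 3 shelf_area        1.06      66.8         0.325 NA     NA
#> 4 salinity          4.01      58.9         0.01   0.587  0.002
#> 5 sst_range         4.18      30.5         0.01   0.590  0.002
#> 6 prim_prod         1.03      17.9         0.43   0.474  0.372
#> 7 salinity_range    1.02      -5.39        0.44   0.489  0.134

glance(result)
#> # A tibble: 1 x 6
#>   n_species n_bins max_richness peak_latitude local_regional_r pseudo_r2
#>       <int>  <int>        <int>         <dbl>            <dbl>     <dbl>
#> 1       643    106          451          40.2            0.948     0.981
```

Reading the output: the synthetic fauna of 643 species peaks at 451 species
near the configured 42° S hump (this seed realises it at 40.2° S); rarefied
local richness tracks the regional curve (r = 0.95 over the 29 bins with
assemblage data), so the hump is not a sampling artefact; the forest
explains the gradient (OOB pseudo-r² = 0.98) and attributes it to the four
structured predictors (median latitudinal range, SST, salinity, SST range
all at p ≤ 0.01) while the three noise controls (shelf area, primary
productivity, salinity range) stay non-significant; `importance` is the
conditional permutation importance in squared-richness units. The `k`
column is Blomberg's phylogenetic signal of each predictor's per-species
median (shelf area is excluded by design — it is a bin property, not an
ambient condition).

Figures:

```r
plot_gradient(result$bin_table)            # regional + rarefied local curve
autoplot(result$forest)                    # observed vs OOB-predicted
autoplot(result$correlogram)               # Moran's I vs distance + envelope
autoplot(result$phylo)                     # PD_SES / MPD_SES / VPD by bin
```

Single stages are available as plain functions when you bring your own
tables: `range_through_richness()`, `rarefy_count()`,
`mean_rarefied_by_bin()`, `local_regional_test()`, `aggregate_pixels()`,
`median_lat_range_by_bin()`, `vif_diagnostics()`, `fit_richness_forest()`,
`conditional_importance()`, `importance_pvalues()`, `partial_dependence()`,
`residual_correlogram()`, `taxonomy_tree()`, `faith_pd()`, `mpd_vpd()`,
`ses_phylodiv()`, `blomberg_k()`, `trait_medians()`. Input schemas are
documented in `?validate_ranges`, `?validate_assemblages`,
`?validate_predictors`; tables round-trip through tab-separated text with
`write_survey_tables()` / `read_ranges()` etc.

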