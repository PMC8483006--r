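---
title: "Methods: building and explaining a hump-shaped latitudinal diversity gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and explaining a hump-shaped latitudinal diversity gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`latdiv` implements a complete analysis pipeline for latitudinal diversity
gradients (LDGs) built from species range tables, with the Southeastern
Pacific shelf transect (3-56 degrees S, half-degree bins) as its default
geometry. This vignette documents the scientific choices behind each stage:
what is computed, under which assumptions, which knobs matter, and what the
synthetic-data generator does and does not emulate.

Throughout the package latitude is expressed in **degrees South as positive
numbers** (3 means 3 degrees S), so the transect is a single increasing axis
and no sign conventions enter the arithmetic.

```{r setup, message = FALSE}
library(latdiv)
```

## The regional gradient: range-through binning

The regional richness curve is built with the *range-through* rule: a species
is scored present in every latitudinal bin between its observed range limits,
assuming a continuous distribution in between. Bins are half-open intervals
`[lower, upper)` of width 0.5 degrees with lower edges at 3.0, 3.5, ..., 55.5
(106 bins); a species' closed interval intersects a bin when it overlaps it,
with the tie rule that touching a bin's *lower* edge counts and touching its
*upper* edge does not. The half-open tiling guarantees that a range endpoint
is never double-counted and that the bins partition the domain exactly.
Ranges are clipped to the domain for binning, but the **full** (unclipped)
extents are retained wherever range *size* is the quantity of interest
(see "Median latitudinal range" below) — species limits estimated outside
the study transect are real information about range size even when the
occurrences themselves fall outside the study area.

```{r}
sv <- simulate_survey(synth_config(seed = 1))
bt <- build_bin_table(sv$ranges, sv$assemblages, sv$predictors)
bt[which.max(bt$richness), c("bin_lower", "bin_upper", "richness")]
```

## Sampling-effort control: Hurlbert rarefaction

Range-through richness can be inflated where sampling has been intense. As a
control, local soft-bottom assemblages with per-species individual counts
are rarefied to a common number of individuals. The expected species count in
a uniform subsample of `n` individuals drawn without replacement is the
Hurlbert form

$$E(S_n) = \sum_i \left(1 - \binom{N - N_i}{n} \middle/ \binom{N}{n}\right),$$

evaluated with log-scale binomial coefficients (`lchoose`) so large counts
cannot overflow. The default subsample is `n = 20` individuals — the
smallest site total a survey of this kind typically retains — and is exposed
as a parameter. Sites with fewer than `n` individuals are *excluded with a
message*, never silently zero-filled, because a zero would masquerade as an
observed absence of diversity. Rarefied values are averaged within each bin
and correlated with regional richness; a second-order polynomial OLS of
local on regional richness provides the saturation test (significant
quadratic term: local assemblages saturate; significant linear term only:
assemblages are open to the regional pool). The Pearson p-value uses the
classical t transform with `n - 2` degrees of freedom.

## The predictor matrix

Seven per-bin covariates feed the driver analysis: sea-surface temperature
(SST), SST range, salinity, salinity range, primary productivity, shelf area,
and the median latitudinal range of the species present in the bin. When
predictors arrive as per-pixel values, `aggregate_pixels()` keeps only shelf
pixels (depth strictly less than 200 m; a pixel at exactly the cutoff is
excluded) and averages within bins — except shelf area, which is an
*extensive* quantity and is summed. Treating area as a mean would make a
bin's "shelf area" independent of how much shelf it holds, which is the
opposite of what the species-area hypothesis needs the predictor to measure;
this is the one place the package takes a position where either reading of
"averaged" was possible.

`median_lat_range_by_bin()` computes, per bin, the median of `lat_max -
lat_min` over the bin's range-through members using unclipped extents.
Collinearity is diagnosed with variance inflation factors,
`VIF_j = 1 / (1 - R^2_j)`, from an OLS of each predictor on all others with
intercept, listwise-deleting incomplete rows; exact collinearity is flagged
explicitly rather than surfacing as a numeric overflow.

## Driver attribution: random forest with conditional importance

Richness is regressed on the seven predictors with a random forest
(`ranger`), using `mtry = floor(p/3)` predictors per split, terminal nodes
of at least 5 observations and 2000 trees by default. Accuracy is an
out-of-bag pseudo-r², `1 - MSE_OOB / Var(richness)`, computed on OOB
predictions only, which is the standard accuracy notion for bagged ensembles
(no holdout is wasted, no training-set optimism).

Because several predictors are smooth functions of latitude, they are
mutually correlated, and plain permutation importance credits shared
information to every member of a correlated group. `conditional_importance()`
therefore permutes a predictor *within strata of its correlated covariates*:
the conditioning set for predictor `j` is every covariate with |Pearson r| >
0.2 to `j` (the threshold is exposed in `rf_config()`), and within each tree
the conditioning covariates are discretised at that tree's own split points.
Importance is the mean over trees of the out-of-bag MSE increase after
permutation; with an empty conditioning set the procedure reduces exactly to
unconditional permutation importance, which is tested.

Statistical significance of importance comes from response permutation: the
richness column is permuted `B` times, the forest refitted, and the
importance statistic recomputed, giving `p = (1 + \#\{null \ge observed\}) /
(B + 1)` with the add-one convention (smallest attainable p is `1/(B+1)`).
The unconditional statistic is the default for the p-values because the
scheme refits the forest `B` times; the conditional statistic is available
as an option. Reference analyses of this kind use B in the thousands, which
is a cluster-scale budget; desk runs here default to `B = 199` and the
choice is reported alongside every result.

Two diagnostics accompany the model. `partial_dependence()` sweeps one
predictor over a grid, sets it to each grid value in *all* rows, and
averages predictions — the marginal response shape isolated from the other
predictors. `residual_correlogram()` checks the spatial independence
assumption: pairwise bin distances (absolute latitudinal differences) are
cut into 10 equal-width classes and Moran's I computed per class with binary
within-class weights, against a 95% envelope from 999 random permutations of
the residuals across bins.

## Taxonomy-proxy phylogenetic diversity

Lacking a resolved molecular phylogeny, the taxonomic hierarchy serves as a
coarse proxy tree: root - family - genus - species, every edge of unit
length, so the tree is ultrametric with depth 3 and patristic distances
count unshared ranks (congeners 2, confamilials 4, different families 6).
Monotypic genera keep their internal node, so tree shape reflects the
classification, not its collapse. Unit branch lengths make the indices
interpretable as taxonomic-distinctness measures: MPD on this tree is
average taxonomic distinctness (AvTD / Delta+).

Three per-bin indices summarise complementary facets of relatedness:

* **Faith's PD** (richness-type): total branch length of the minimal subtree
  spanning the bin's species and the root;
* **MPD** (divergence-type): mean patristic distance over all species pairs,
  presence-based — regional bins carry no abundance structure;
* **VPD** (regularity-type): the variance of those pairwise distances, with
  the population divisor (number of pairs), reported raw.

PD and MPD depend strongly on richness, so they are standardised:
`SES = (observed - null mean) / null SD`, with the null built by shuffling
species identities across the tree's tips 999 times (default). Tip-shuffling
preserves each bin's richness and each species' occupancy pattern as a
block, which makes it the standard richness-controlled null for SES; an
independent-swap null (fixed row and column totals) is available as an
option. Negative SES indicates phylogenetic clustering, positive SES
overdispersion. VPD is not standardised — its raw latitudinal trend is the
quantity of interest. A calibration test confirms that SES has mean 0 and SD
1 when the data are drawn from the null itself.

## Phylogenetic signal: Blomberg's K

Niche conservatism is quantified per predictor by Blomberg's K of the
species-level trait "median of the bin-level proxy across the bins the
species occupies" (range-through occupancy). K is the observed ratio of
trait variance to phylogenetically-corrected variance, scaled by its
expectation under Brownian motion on the tree, so K near 1 matches Brownian
evolution, near 0 no signal, above 1 stronger-than-Brownian conservatism.
The p-value is one-sided from shuffling trait values across tips with the
add-one convention. The implementation is validated against an independent
reference implementation and calibrated: Brownian traits simulated on the
taxonomy tree give mean K within [0.9, 1.1], and shuffled traits reject at
the nominal 5% rate. Shelf area is excluded from signal testing — it is an
extensive property of a bin, not an ambient condition a species experiences,
so a species-level "median shelf area" has no niche interpretation.

## The synthetic-data generator

`simulate_survey()` produces the three tables the pipeline consumes, with
defaults emulating the structure of the motivating survey: 643 species, a
3-56 degree S domain, a richness peak at 42 degrees S, 57 assemblage sites
concentrated in 29 bins, rarefaction floor of 20 individuals.

* **Ranges.** Midpoints are hierarchical: `hump_center` + family effect +
  genus effect + species deviation. The `conservatism` parameter (default
  0.5) fixes the fraction of midpoint variance carried by the lineage
  levels; at 1 congeners coincide, at 0 taxonomy is uninformative. Lineage
  effects are centred on their species-weighted mean, so the generator
  emulates one fixed empirical gradient whose peak sits at the configured
  latitude rather than a superpopulation whose realised peak drifts between
  draws. The hump spread defaults to 8 degrees; range widths are lognormal
  (median 12 degrees) and independent of midpoints by default — any
  Rapoport-type range-size gradient in the output is *emergent* (edge bins
  can only be reached by wide-ranged species), not assumed; an explicit
  coupling switch exists but is off. A quarter of species are "widespread"
  (widths 50-120 degrees), mimicking eurytopic taxa whose limits lie far
  beyond the transect; this keeps edge-bin richness a substantial fraction
  of the peak, as in real shelf faunas. The taxonomy defaults to 250 genera
  in 60 families, a few species per genus, as in diverse marine annelid
  groups.
* **Predictors.** SST declines linearly polewards (22 to 7 degrees C) with
  noise; SST range declines with curvature (strong low-latitude interannual
  variability); salinity drops sigmoidally south of ~40 degrees S (fjord
  freshening). Salinity range, primary productivity and shelf area are noise
  around a constant — deliberate negative controls for driver attribution.
  Noise levels are chosen so the predictor set is correlated but not
  degenerate (all VIF well below the conventional threshold of 10);
  `predictor_noise = 0` gives the smooth profiles for exact tests.
* **Assemblages.** Sites are placed in 29 distinct bins (the bin coverage of
  the motivating survey is a parameter, not an assumption) and each draws a
  multinomial sample (default 200 individuals) from the species covering its
  latitude. Weights follow a geometric rank-abundance series whose
  rarest-to-commonest ratio (`evenness`, default 0.05) is fixed regardless
  of pool size; scaling the series to the pool keeps local richness
  responsive to regional richness, which is what the local-regional
  correlation is meant to detect.

What the generator does **not** emulate: real taxonomic name structure,
observational error in range limits, spatial aggregation of occurrences
within bins, raster-level environmental structure, or abundance dynamics.
Tests passing on synthetic data therefore demonstrate the *correctness and
calibration of the machinery* under the stated generative assumptions — not
that any particular empirical dataset satisfies those assumptions.

## Numerical and design choices

* Rarefaction uses log-combinatorics; the exact enumeration oracle bounds
  the error at 1e-10 on all small cases.
* Bins tie-break as described above; a point range on an interior edge
  belongs to the higher-latitude (poleward) bin.
* VIF infinities are flags, not overflows; constant columns are errors.
* Forest seeds propagate from one root seed split per stage, so a pipeline
  run is reproducible end to end from its manifest; package functions
  restore the caller's RNG stream on exit.
* MPD/VPD of a singleton assemblage are reported as undefined (`NA` with an
  explanation attribute), never as zero.
* SES is `NA` where the null SD is zero (degenerate bins).
* Conditional-importance conditioning threshold 0.2 is the conventional
  default of the conditional-importance literature; it is a parameter.
* `n_perm_importance`, `n_null`, `n_signal_perm` and `correlogram_runs`
  trade Monte-Carlo precision for time; defaults (199 / 999 / 999 / 999)
  keep a full default-size run in a few minutes on one core. The package's
  own test suite runs the calibration checks at these sizes (SES: 8
  replicates of 50 bins x 200 species; K: 200 replicates on 100 tips;
  importance: 20 replicate surveys at B = 199).

## Known limitations

* The taxonomy tree is a proxy; K and SES inherit its coarseness. Unit
  branch lengths are a convention, and K's magnitude is only comparable
  across traits on the same tree.
* Conditional importance with many fine-grained conditioning strata permutes
  within small cells and can shrink towards zero for heavily conditioned
  predictors; rankings of p-values are the robust output, not raw
  importance magnitudes.
* The importance p-values treat the forest's own refitting noise as part of
  the null, which is conservative at small B.
* Range-through binning assumes continuity between range limits; real
  ranges with gaps inflate mid-range richness, and nothing in the pipeline
  can detect that from a range table alone.
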