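Package: latdiv
Title: Latitudinal Diversity Gradients with Sampling Control, Machine-Learning
    Attribution and Taxonomy-Proxy Phylogenetic Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build and explain latitudinal diversity gradients from
    species range tables. Implements range-through richness binning on a
    half-degree latitudinal grid, individual-based (Hurlbert) rarefaction of
    local assemblages as a sampling-effort control, assembly of per-bin
    environmental predictor matrices with collinearity diagnostics, random
    forest attribution of richness drivers with conditional permutation
    importance, response-permutation importance p-values, partial dependence
    curves and Moran's I residual correlograms, and taxonomy-proxy
    phylogenetic diversity (Faith's PD, MPD, VPD) with randomization-based
    standardized effect sizes and Blomberg's K phylogenetic signal. A
    synthetic-data generator emulates a hump-shaped coastal gradient so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    picante,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
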