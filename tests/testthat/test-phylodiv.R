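small_tree_ranges <- function() {
  tibble::tibble(
    species = c("s1", "s2", "s3", "s4", "s5"),
    family = c("fA", "fA", "fA", "fB", "fB"),
    genus = c("g1", "g1", "g2", "g3", "g3"),
    lat_min = 1, lat_max = 2
  )
}

test_that("taxonomy trees have rank-ladder structure and unit depths", {
  tree <- taxonomy_tree(small_tree_ranges())
  expect_s3_class(tree, "phylo")
  d <- patristic_distances(tree)
  expect_equal(d["s1", "s2"], 2)   # congeners
  expect_equal(d["s1", "s3"], 4)   # same family, different genus
  expect_equal(d["s1", "s4"], 6)   # different families
  # ultrametric: all root-to-tip depths equal 3
  depths <- ape::dist.nodes(tree)[6, 1:5]
  expect_true(all(depths == 3))
  bad <- small_tree_ranges()
  bad$family[3] <- "fB"            # genus g2 stays in fA? no - reassign g1
  bad$family[2] <- "fB"            # genus g1 now claims two families
  expect_error(taxonomy_tree(bad), "g1")
})

test_that("patristic distances equal brute-force root-path sums", {
  r <- generate_ranges(synth_config(n_species = 10, n_genera = 5,
                                    n_families = 3, seed = 33))
  tree <- taxonomy_tree(r)
  d <- patristic_distances(tree)
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(d[i, j], patristic_oracle(tree, i, j),
                 info = sprintf("pair %d-%d", i, j))
  }
})

test_that("Faith's PD matches hand counts and the edge-set oracle", {
  tree <- taxonomy_tree(small_tree_ranges())
  expect_equal(faith_pd(tree, "s1"), 3)              # one root-to-tip path
  expect_equal(faith_pd(tree, c("s1", "s2")), 4)     # shared family+genus
  expect_error(faith_pd(tree, "nope"), "unknown tip")

  r <- generate_ranges(synth_config(n_species = 40, n_genera = 12,
                                    n_families = 4, seed = 34))
  big <- taxonomy_tree(r)
  set.seed(35)
  for (k in c(1, 3, 10, 40)) {
    tips <- sample(40, k)
    expect_equal(faith_pd(big, tips), pd_oracle(big, tips))
  }
  skip_if_not_installed("picante")
  # two families so the collapsed tree is binary-rooted at the top
  r2 <- generate_ranges(synth_config(n_species = 30, n_genera = 10,
                                     n_families = 2, seed = 77))
  t2 <- taxonomy_tree(r2)
  comm <- matrix(0, 1, 30, dimnames = list("b1", t2$tip.label))
  comm[1, sample(30, 12)] <- 1
  expect_equal(faith_pd(t2, colnames(comm)[comm[1, ] > 0]),
               picante::pd(comm, ape::collapse.singles(t2),
                           include.root = TRUE)$PD)
})

test_that("PD is monotone under tip addition", {
  r <- generate_ranges(synth_config(n_species = 30, n_genera = 10,
                                    n_families = 3, seed = 36))
  tree <- taxonomy_tree(r)
  set.seed(37)
  tips <- sample(30, 5)
  pd0 <- faith_pd(tree, tips)
  for (extra in setdiff(sample(30, 10), tips)) {
    expect_gte(faith_pd(tree, c(tips, extra)), pd0)
  }
})

test_that("MPD and VPD match trivial cases and pairwise enumeration", {
  tree <- taxonomy_tree(small_tree_ranges())
  two <- mpd_vpd(tree, c("s1", "s4"))
  expect_equal(two$mpd, 6)
  expect_equal(two$vpd, 0)
  equi <- mpd_vpd(tree, c("s3", "s4", "s1"))  # not equidistant
  one <- mpd_vpd(tree, "s1")
  expect_true(is.na(one$mpd))
  expect_match(attr(one, "undefined"), "fewer than two")

  # three mutually-equidistant tips: zero variance
  r3 <- tibble::tibble(species = c("a", "b", "c"), family = "f",
                       genus = c("g1", "g2", "g3"), lat_min = 1, lat_max = 2)
  t3 <- taxonomy_tree(r3)
  expect_equal(mpd_vpd(t3, c("a", "b", "c"))$vpd, 0)

  big <- taxonomy_tree(generate_ranges(synth_config(
    n_species = 25, n_genera = 8, n_families = 3, seed = 38)))
  d <- patristic_distances(big)
  set.seed(39)
  tips <- sample(25, 9)
  got <- mpd_vpd(big, tips)
  pairs <- utils::combn(tips, 2)
  dd <- apply(pairs, 2, function(p) d[p[1], p[2]])
  expect_equal(got$mpd, mean(dd), tolerance = 1e-12)
  expect_equal(got$vpd, mean((dd - mean(dd))^2), tolerance = 1e-12)
  # unit-branch taxonomy bounds: MPD of any multi-species set lies in [2, 6]
  expect_gte(got$mpd, 2); expect_lte(got$mpd, 6)
})

test_that("SES fields satisfy the standardisation identity", {
  r <- generate_ranges(synth_config(n_species = 60, n_genera = 20,
                                    n_families = 6, seed = 40))
  tree <- taxonomy_tree(r)
  m <- range_through_membership(r)[40:60, ]
  ph <- ses_phylodiv(m, tree, n_null = 99, seed = 4)
  ok <- !is.na(ph$pd_ses)
  expect_equal(ph$pd_ses[ok],
               (ph$pd_obs[ok] - ph$pd_null_mean[ok]) / ph$pd_null_sd[ok],
               tolerance = 1e-12)
  # the stated formula: observed 2, null mean 1, null SD 0.5 gives SES 2
  expect_equal((2 - 1) / 0.5, 2)
  expect_true(all(ph$richness == rowSums(m)))
  # determinism
  ph2 <- ses_phylodiv(m, tree, n_null = 99, seed = 4)
  expect_identical(ph$pd_ses, ph2$pd_ses)
})

test_that("Blomberg's K obeys its invariances and matches picante", {
  r <- generate_ranges(synth_config(n_species = 50, n_genera = 15,
                                    n_families = 5, seed = 41))
  tree <- taxonomy_tree(r)
  trait <- (r$lat_min + r$lat_max) / 2
  names(trait) <- r$species
  k1 <- blomberg_k(tree, trait, n_perm = 99, seed = 1)

  scaled <- tree; scaled$edge.length <- tree$edge.length * 7.3
  k2 <- blomberg_k(scaled, trait, n_perm = 99, seed = 1)
  expect_equal(k1$k, k2$k, tolerance = 1e-10)

  k3 <- blomberg_k(tree, trait + 100, n_perm = 99, seed = 1)
  expect_equal(k1$k, k3$k, tolerance = 1e-10)

  expect_error(blomberg_k(tree, setNames(rep(1, 50), r$species)), "constant")

  skip_if_not_installed("picante")
  expect_equal(k1$k,
               as.numeric(picante::Kcalc(trait, ape::collapse.singles(tree))),
               tolerance = 1e-8)
})

test_that("K permutation p-values use the add-one formula", {
  # strong signal: trait equals family index, so observed K beats all nulls
  r <- generate_ranges(synth_config(n_species = 60, n_genera = 20,
                                    n_families = 6, conservatism = 1,
                                    prop_widespread = 0, seed = 43))
  tree <- taxonomy_tree(r)
  trait <- as.numeric(factor(r$family)) + 0.001 * seq_len(60)
  names(trait) <- r$species
  ps <- blomberg_k(tree, trait, n_perm = 199, seed = 2)
  expect_equal(ps$p_value, 1 / 200)
})

test_that("stronger niche conservatism raises the K of range midpoints", {
  ks <- sapply(c(0, 0.9), function(cv) {
    r <- generate_ranges(synth_config(n_species = 150, n_genera = 40,
                                      n_families = 10, conservatism = cv,
                                      seed = 44))
    tree <- taxonomy_tree(r)
    mid <- (r$lat_min + r$lat_max) / 2
    names(mid) <- r$species
    blomberg_k(tree, mid, n_perm = 99, seed = 3)$k
  })
  expect_gt(ks[2], ks[1])
})

test_that("trait medians follow range-through occupancy", {
  r <- tibble::tibble(
    species = c("one_bin", "three_bins"),
    family = "f", genus = c("g1", "g2"),
    lat_min = c(10.1, 20.0), lat_max = c(10.2, 21.4)
  )
  bins <- latitude_bins()
  bt <- dplyr::mutate(bins, sst = seq(30, 30 - 0.2 * 105, by = -0.2))
  tm <- trait_medians(r, bt, "sst")
  expect_equal(unname(tm["one_bin"]), bt$sst[bt$bin_lower == 10.0])
  occ <- which(bins$bin_upper > 20.0 & bins$bin_lower <= 21.4)
  expect_equal(unname(tm["three_bins"]), median(bt$sst[occ]))

  outside <- dplyr::bind_rows(r, tibble::tibble(
    species = "gone", family = "f", genus = "g3",
    lat_min = 80, lat_max = 90))
  expect_warning(tm2 <- trait_medians(outside, bt, "sst"), "occupy no bin")
  expect_false("gone" %in% names(tm2))
})

test_that("index-richness correlations match the direct covariance formula", {
  set.seed(45)
  n <- 30
  ph <- tibble::tibble(
    richness = rpois(n, 50),
    pd_ses = rnorm(n), mpd_ses = rnorm(n), vpd_obs = runif(n)
  )
  ph$pd_ses <- ph$richness * 0.05 + rnorm(n, sd = 0.5)
  out <- phylo_richness_correlations(ph)
  for (ix in out$index) {
    x <- ph[[ix]]; y <- ph$richness
    r_hand <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(out$r[out$index == ix], r_hand, tolerance = 1e-12)
  }
  ident <- dplyr::mutate(ph, pd_ses = richness)
  expect_equal(phylo_richness_correlations(ident)$r[1], 1, tolerance = 1e-12)
})
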