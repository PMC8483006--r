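# Independent oracles and small fixtures used across test files. Oracles are
# deliberately naive (enumeration / double loops) so they share no code with
# the implementation they check.

# Expected species count over ALL n-subsets of individuals, by enumeration.
rarefy_oracle <- function(counts, n) {
  inds <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(inds), n)
  mean(apply(subs, 2, function(ix) length(unique(inds[ix]))))
}

# Per-bin richness by a double loop over (species, bin) intersection tests.
richness_oracle <- function(ranges, domain = c(3, 56), width = 0.5) {
  lowers <- seq(domain[1], domain[2] - width / 2, by = width)
  sapply(lowers, function(lo) {
    hi <- min(lo + width, domain[2])
    n <- 0L
    for (i in seq_len(nrow(ranges))) {
      a <- max(ranges$lat_min[i], domain[1])
      b <- min(ranges$lat_max[i], domain[2])
      if (a > b) next            # range wholly outside the domain
      if (a < hi && b >= lo) n <- n + 1L
    }
    n
  })
}

# Patristic distance by explicit root-path symmetric difference.
patristic_oracle <- function(tree, i, j) {
  root_path <- function(tip) {
    node <- tip
    path <- integer(0)
    repeat {
      row <- which(tree$edge[, 2] == node)
      if (length(row) == 0L) break
      path <- c(path, row)
      node <- tree$edge[row, 1]
    }
    path
  }
  pi <- root_path(i); pj <- root_path(j)
  shared <- intersect(pi, pj)
  sum(tree$edge.length[setdiff(c(pi, pj), shared)])
}

# Faith's PD by brute-force union of root-path edge sets.
pd_oracle <- function(tree, tips_idx) {
  edges <- integer(0)
  for (tip in tips_idx) {
    node <- tip
    repeat {
      row <- which(tree$edge[, 2] == node)
      if (length(row) == 0L) break
      edges <- union(edges, row)
      node <- tree$edge[row, 1]
    }
  }
  sum(tree$edge.length[edges])
}

# A small survey configuration that keeps unit tests fast.
small_config <- function(seed = 1, ...) {
  synth_config(n_species = 120, n_genera = 30, n_families = 8,
               n_sites = 12, n_occupied_bins = 10, seed = seed, ...)
}

# Random range table with uniform midpoints/widths (no hump structure).
random_ranges <- function(n, seed, domain = c(3, 56)) {
  set.seed(seed)
  mid <- runif(n, domain[1] - 5, domain[2] + 5)
  w <- runif(n, 0.1, 30)
  tibble::tibble(
    species = sprintf("s%03d", seq_len(n)),
    family = sprintf("f%02d", sample.int(5, n, replace = TRUE)),
    genus = sprintf("g%02d", sample.int(20, n, replace = TRUE)),
    lat_min = mid - w / 2,
    lat_max = mid + w / 2
  ) |>
    dplyr::mutate(family = family[match(genus, genus)])  # one family per genus
}
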