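#' Taxonomy-proxy phylogenetic tree
#'
#' Builds a rooted tree from the taxonomic ranks of a range table
#' (root - family - genus - species), the standard coarse proxy for
#' phylogenetic relationships in groups lacking a resolved molecular
#' phylogeny. Every edge gets the same branch length (default 1), so the
#' tree is ultrametric with root-to-tip depth 3 and patristic distances
#' count unshared ranks: congeners are 2 apart, confamilial species 4,
#' species in different families 6. Monotypic genera and families keep
#' their internal node.
#'
#' @param ranges Species range table with `species`, `genus`, `family`.
#' @param branch_length Length of every edge, default 1.
#' @return An `ape` "phylo" object with species as tip labels and genus /
#'   family / "root" labels on internal nodes. Exportable with
#'   [ape::write.tree()].
#' @export
taxonomy_tree <- function(ranges, branch_length = 1) {
  ranges <- validate_ranges(ranges)
  if (!is.numeric(branch_length) || branch_length <= 0) {
    stop("`branch_length` must be positive.", call. = FALSE)
  }
  n <- nrow(ranges)
  genera <- unique(ranges$genus)
  families <- unique(ranges$family)
  genus_family <- ranges$family[match(genera, ranges$genus)]

  root <- n + 1L
  fam_id <- stats::setNames(root + seq_along(families), families)
  gen_id <- stats::setNames(root + length(families) + seq_along(genera),
                            genera)
  edge <- rbind(
    cbind(root, unname(fam_id)),
    cbind(unname(fam_id[genus_family]), unname(gen_id)),
    cbind(unname(gen_id[ranges$genus]), seq_len(n))
  )
  tree <- structure(list(
    edge = edge,
    edge.length = rep(branch_length, nrow(edge)),
    Nnode = 1L + length(families) + length(genera),
    tip.label = ranges$species,
    node.label = c("root", families, genera)
  ), class = "phylo", order = "cladewise")
  tree
}

#' Patristic distance matrix
#'
#' @param tree A "phylo" tree.
#' @return Symmetric matrix of tip-to-tip branch-length distances, with tip
#'   labels as dimnames.
#' @export
patristic_distances <- function(tree) {
  n <- length(tree$tip.label)
  d <- ape::dist.nodes(tree)[seq_len(n), seq_len(n)]
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

# For each tip, the edge indices on its path to the root.
tip_edge_paths <- function(tree) {
  parent_edge <- integer(max(tree$edge))
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  root <- length(tree$tip.label) + 1L
  lapply(seq_along(tree$tip.label), function(tip) {
    path <- integer(0)
    node <- tip
    while (node != root) {
      e <- parent_edge[node]
      path <- c(path, e)
      node <- tree$edge[e, 1]
    }
    path
  })
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the minimal subtree spanning a set of tips and
#' the root — a richness-type phylogenetic index (the total evolutionary
#' history summed by the set).
#'
#' @param tree A "phylo" tree.
#' @param tips Character vector of tip labels (or integer tip indices).
#' @return Faith's PD as a single number.
#' @export
faith_pd <- function(tree, tips) {
  idx <- resolve_tips(tree, tips)
  if (length(idx) == 0L) stop("`tips` is empty.", call. = FALSE)
  paths <- tip_edge_paths(tree)
  sum(tree$edge.length[unique(unlist(paths[idx], use.names = FALSE))])
}

resolve_tips <- function(tree, tips) {
  if (is.numeric(tips)) {
    if (any(tips < 1 | tips > length(tree$tip.label))) {
      stop("tip index out of range.", call. = FALSE)
    }
    return(as.integer(tips))
  }
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) {
    stop(sprintf("unknown tip(s): %s",
                 paste(tips[is.na(idx)][1:min(3, sum(is.na(idx)))],
                       collapse = ", ")), call. = FALSE)
  }
  idx
}

#' Mean and variance of pairwise phylogenetic distances
#'
#' MPD (equivalently average taxonomic distinctness on a unit-branch
#' taxonomy tree) is the mean patristic distance over all unordered tip
#' pairs, presence-based; VPD is the population variance of the same
#' distances (divisor = number of pairs), a regularity-type index.
#'
#' @param tree A "phylo" tree, or a precomputed patristic distance matrix.
#' @param tips Tip labels or indices; at least 2.
#' @return A list with `mpd` and `vpd`. With fewer than two tips both are
#'   `NA` and attribute `"undefined"` is set (a singleton assemblage has no
#'   pairwise structure; this is reported, not silently zeroed).
#' @export
mpd_vpd <- function(tree, tips) {
  d <- if (is.matrix(tree)) tree else patristic_distances(tree)
  idx <- if (is.numeric(tips)) as.integer(tips) else {
    i <- match(tips, colnames(d))
    if (anyNA(i)) stop("unknown tip in `tips`.", call. = FALSE)
    i
  }
  if (length(idx) < 2L) {
    out <- list(mpd = NA_real_, vpd = NA_real_)
    attr(out, "undefined") <- "fewer than two tips"
    return(out)
  }
  sub <- d[idx, idx]
  pairs <- sub[upper.tri(sub)]
  list(mpd = mean(pairs), vpd = mean((pairs - mean(pairs))^2))
}

#' Standardized effect sizes of per-bin phylogenetic diversity
#'
#' Computes Faith's PD, MPD and VPD for every bin of a binary bin-by-species
#' membership matrix and standardises PD and MPD against a randomization
#' null: `SES = (observed - null mean) / null SD`. The default null shuffles
#' species identities across the tree's tips, preserving each bin's richness
#' and each species' occupancy pattern as a block — the standard
#' richness-controlled null. SES below zero indicates phylogenetic
#' clustering, above zero overdispersion. VPD is reported raw (observed
#' only). An independent-swap null (preserving row and column totals of the
#' matrix with checkerboard swaps) is available when the picante package is
#' installed.
#'
#' @param membership Logical or 0/1 matrix, bins x species; column names
#'   must match tree tips (see [range_through_membership()]).
#' @param tree A "phylo" tree containing every species column.
#' @param n_null Number of randomizations (at least 99), default 999.
#' @param seed RNG seed.
#' @param null_model `"tipshuffle"` (default) or `"independentswap"`.
#' @return A tibble of class `ldg_phylo`, one row per bin: `richness`,
#'   `pd_obs`, `pd_null_mean`, `pd_null_sd`, `pd_ses`, the same for MPD,
#'   `vpd_obs` and `n_null`. SES is `NA` where the null SD is zero or the
#'   index is undefined.
#' @export
ses_phylodiv <- function(membership, tree, n_null = 999, seed = 1,
                         null_model = c("tipshuffle", "independentswap")) {
  null_model <- match.arg(null_model)
  if (n_null < 99) stop("`n_null` must be at least 99.", call. = FALSE)
  membership <- membership > 0
  sp <- colnames(membership)
  idx_map <- resolve_tips(tree, sp)
  local_seed(seed)

  paths <- tip_edge_paths(tree)
  el <- tree$edge.length
  d <- patristic_distances(tree)
  pd_of <- function(tips) {
    if (length(tips) == 0L) return(NA_real_)
    sum(el[unique(unlist(paths[tips], use.names = FALSE))])
  }
  mpd_of <- function(tips) {
    k <- length(tips)
    if (k < 2L) return(NA_real_)
    sub <- d[tips, tips]
    sum(sub) / (k * (k - 1))
  }
  vpd_of <- function(tips) {
    k <- length(tips)
    if (k < 2L) return(NA_real_)
    pairs <- d[tips, tips][upper.tri(diag(k))]
    mean((pairs - mean(pairs))^2)
  }

  bin_tips <- apply(membership, 1, function(row) idx_map[row],
                    simplify = FALSE)
  nb <- length(bin_tips)
  pd_obs <- vapply(bin_tips, pd_of, numeric(1))
  mpd_obs <- vapply(bin_tips, mpd_of, numeric(1))
  vpd_obs <- vapply(bin_tips, vpd_of, numeric(1))

  pd_null <- matrix(NA_real_, n_null, nb)
  mpd_null <- matrix(NA_real_, n_null, nb)
  if (null_model == "tipshuffle") {
    for (r in seq_len(n_null)) {
      relabel <- sample(idx_map)
      names(relabel) <- NULL
      shuffled <- stats::setNames(relabel, as.character(idx_map))
      for (b in seq_len(nb)) {
        t_null <- shuffled[as.character(bin_tips[[b]])]
        pd_null[r, b] <- pd_of(t_null)
        mpd_null[r, b] <- mpd_of(t_null)
      }
    }
  } else {
    if (!requireNamespace("picante", quietly = TRUE)) {
      stop("the independent-swap null requires the picante package.",
           call. = FALSE)
    }
    m01 <- membership * 1
    for (r in seq_len(n_null)) {
      mr <- picante::randomizeMatrix(m01, null.model = "independentswap")
      for (b in seq_len(nb)) {
        t_null <- idx_map[mr[b, ] > 0]
        pd_null[r, b] <- pd_of(t_null)
        mpd_null[r, b] <- mpd_of(t_null)
      }
    }
  }

  ses_of <- function(obs, null) {
    mu <- colMeans(null)
    sdv <- apply(null, 2, stats::sd)
    ses <- (obs - mu) / sdv
    ses[!is.finite(ses)] <- NA_real_
    list(mean = mu, sd = sdv, ses = ses)
  }
  pd_s <- ses_of(pd_obs, pd_null)
  mpd_s <- ses_of(mpd_obs, mpd_null)

  structure(tibble::tibble(
    bin = rownames(membership) %||% as.character(seq_len(nb)),
    richness = as.integer(rowSums(membership)),
    pd_obs = pd_obs, pd_null_mean = pd_s$mean, pd_null_sd = pd_s$sd,
    pd_ses = pd_s$ses,
    mpd_obs = mpd_obs, mpd_null_mean = mpd_s$mean, mpd_null_sd = mpd_s$sd,
    mpd_ses = mpd_s$ses,
    vpd_obs = vpd_obs,
    n_null = n_null
  ), class = c("ldg_phylo", "tbl_df", "tbl", "data.frame"))
}

#' Blomberg's K phylogenetic signal
#'
#' K compares the observed ratio of trait variance to
#' phylogenetically-corrected variance against its expectation under
#' Brownian motion on the tree: K near 1 matches Brownian evolution, K near
#' 0 means no signal, K above 1 stronger-than-Brownian conservatism. The
#' p-value is one-sided, from shuffling trait values across tips:
#' `p = (1 + #\{K_null >= K_obs\}) / (n_perm + 1)`.
#'
#' @param tree A "phylo" tree with positive branch lengths and >= 4 tips.
#' @param trait Named numeric vector over all tips (names matched to tip
#'   labels; an unnamed vector is taken in tip order).
#' @param n_perm Number of trait shuffles (at least 99), default 999.
#' @param seed RNG seed.
#' @return An object of class `ldg_physig`: list with `k`, `p_value`,
#'   `n_perm`, `n_tips`, and the `trait` used.
#' @export
blomberg_k <- function(tree, trait, n_perm = 999, seed = 1) {
  n <- length(tree$tip.label)
  if (n < 4L) stop("need at least 4 tips.", call. = FALSE)
  if (any(tree$edge.length <= 0)) {
    stop("branch lengths must be positive.", call. = FALSE)
  }
  if (!is.null(names(trait))) {
    idx <- match(tree$tip.label, names(trait))
    if (anyNA(idx)) stop("trait missing for some tips.", call. = FALSE)
    trait <- trait[idx]
  }
  if (length(trait) != n) stop("need one trait value per tip.", call. = FALSE)
  if (anyNA(trait)) stop("trait must be defined for all tips.", call. = FALSE)
  if (stats::sd(trait) == 0) {
    stop("degenerate input: trait is constant.", call. = FALSE)
  }
  if (n_perm < 99) stop("`n_perm` must be at least 99.", call. = FALSE)
  local_seed(seed)

  V <- phylo_vcv(tree)
  Vinv <- solve(V)
  s <- sum(Vinv)
  expected_ratio <- (sum(diag(V)) - n / s) / (n - 1)

  k_of <- function(X) {
    # X: n x m matrix of traits, one column per evaluation
    ahat <- colSums(Vinv %*% X) / s
    Xc <- sweep(X, 2, ahat)
    mse0 <- colSums(Xc^2) / (n - 1)
    mse <- colSums(Xc * (Vinv %*% Xc)) / (n - 1)
    (mse0 / mse) / expected_ratio
  }

  k_obs <- k_of(matrix(trait, ncol = 1))
  perms <- matrix(trait[as.vector(replicate(n_perm, sample.int(n)))],
                  nrow = n)
  k_null <- k_of(perms)
  structure(list(
    k = unname(k_obs),
    p_value = (1 + sum(k_null >= k_obs)) / (n_perm + 1),
    n_perm = n_perm,
    n_tips = n,
    trait = trait
  ), class = "ldg_physig")
}

# Brownian-motion variance-covariance matrix: V[i, j] = shared root-to-MRCA
# path length. Computed from node distances so rank-ladder trees with
# single-child internal nodes are handled.
phylo_vcv <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  dd <- ape::dist.nodes(tree)
  depth <- dd[root, seq_len(n)]
  V <- (outer(depth, depth, `+`) - dd[seq_len(n), seq_len(n)]) / 2
  dimnames(V) <- list(tree$tip.label, tree$tip.label)
  V
}

#' @export
print.ldg_physig <- function(x, ...) {
  cat(sprintf("<ldg_physig> Blomberg's K = %.3f (p = %.4g, %d tips, %d permutations)\n",
              x$k, x$p_value, x$n_tips, x$n_perm))
  invisible(x)
}

#' Per-species median of a per-bin proxy
#'
#' For each species, the median of a bin-level proxy (e.g. SST) over the
#' bins the species occupies under the range-through rule — the species-level
#' trait used for phylogenetic-signal testing. Species occupying no bin are
#' dropped with a warning.
#'
#' @param ranges Species range table.
#' @param bins Bin table holding the proxy column (bins aligned with
#'   `domain`/`width`).
#' @param proxy Proxy column name.
#' @inheritParams range_through_richness
#' @return A named numeric vector: per-species median proxy values.
#' @export
trait_medians <- function(ranges, bins, proxy, domain = c(3, 56),
                          width = 0.5) {
  require_columns(bins, proxy, "bin")
  member <- range_through_membership(ranges, domain, width)
  if (nrow(member) != nrow(bins)) {
    stop("`bins` does not match the bin grid implied by domain/width.",
         call. = FALSE)
  }
  vals <- bins[[proxy]]
  out <- apply(member, 2, function(occ) {
    occ <- occ & !is.na(vals)
    if (!any(occ)) NA_real_ else stats::median(vals[occ])
  })
  if (anyNA(out)) {
    warning(sprintf("%d species occupy no bin with a %s value; excluded.",
                    sum(is.na(out)), proxy), call. = FALSE)
    out <- out[!is.na(out)]
  }
  out
}

#' Correlations of phylogenetic diversity indices with richness
#'
#' Pearson correlation (with classical t-transform p-values) of `pd_ses`,
#' `mpd_ses` and `vpd_obs` against per-bin species richness.
#'
#' @param phylo An [ses_phylodiv()] result.
#' @param richness Optional per-bin richness; defaults to the `richness`
#'   column of `phylo`.
#' @return A tibble with `index`, `r`, `p_value`, `n`.
#' @export
phylo_richness_correlations <- function(phylo, richness = NULL) {
  if (is.null(richness)) richness <- phylo$richness
  purrr::map_dfr(c("pd_ses", "mpd_ses", "vpd_obs"), function(ix) {
    ok <- stats::complete.cases(phylo[[ix]], richness)
    x <- phylo[[ix]][ok]; y <- richness[ok]
    if (sum(ok) < 4L) {
      stop(sprintf("fewer than 4 complete bins for %s.", ix), call. = FALSE)
    }
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      stop(sprintf("degenerate variance for %s.", ix), call. = FALSE)
    }
    r <- stats::cor(x, y)
    n <- sum(ok)
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    tibble::tibble(index = ix, r = r,
                   p_value = 2 * stats::pt(-abs(tstat), df = n - 2), n = n)
  })
}
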