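#' Random forest configuration
#'
#' Hyperparameters for the richness-versus-predictors random forest and its
#' importance machinery. Defaults follow common regression-forest practice:
#' `mtry = floor(p / 3)` (at least 1) predictors tried per split and terminal
#' nodes of at least 5 observations; 2000 trees.
#'
#' @param n_trees Number of trees, default 2000.
#' @param mtry Predictors per split; `NULL` (default) means `floor(p / 3)`,
#'   minimum 1.
#' @param min_node_size Minimal terminal node size, default 5.
#' @param cond_threshold Absolute Pearson correlation above which a covariate
#'   joins a predictor's conditioning set for conditional permutation
#'   importance, default 0.2.
#' @param n_perm_importance Response permutations for importance p-values
#'   (at least 99), default 199. Large studies use thousands; that many
#'   forest refits is cluster-scale, so desk analyses keep B in the
#'   99-499 range and report it.
#' @param seed Integer RNG seed, default 1.
#' @return An object of class `rf_config`.
#' @export
rf_config <- function(n_trees = 2000, mtry = NULL, min_node_size = 5,
                      cond_threshold = 0.2, n_perm_importance = 199,
                      seed = 1) {
  if (n_trees < 1 || n_trees != round(n_trees)) {
    stop("`n_trees` must be a positive integer.", call. = FALSE)
  }
  if (!is.null(mtry) && (mtry < 1 || mtry != round(mtry))) {
    stop("`mtry` must be a positive integer or NULL.", call. = FALSE)
  }
  if (min_node_size < 1) stop("`min_node_size` must be >= 1.", call. = FALSE)
  if (n_perm_importance < 99) {
    stop("`n_perm_importance` must be at least 99.", call. = FALSE)
  }
  structure(list(n_trees = n_trees, mtry = mtry,
                 min_node_size = min_node_size,
                 cond_threshold = cond_threshold,
                 n_perm_importance = n_perm_importance,
                 seed = as.integer(seed)),
            class = "rf_config")
}

default_driver_predictors <- function() {
  c(predictor_names(), "median_lat_range")
}

#' Fit the richness random forest
#'
#' Regresses per-bin richness on the predictor columns with a random forest
#' (bootstrap-aggregated regression trees, via ranger). Rows with any
#' missing predictor or response are dropped listwise. Accuracy is an
#' out-of-bag pseudo-r2, `1 - MSE_OOB / Var(richness)`, computed on OOB
#' predictions only.
#'
#' @param bins A bin table (see [build_bin_table()]) holding the response
#'   and predictor columns.
#' @param config An [rf_config()].
#' @param response Response column name, default `"richness"`.
#' @param predictors Character vector of predictor column names; default the
#'   six environmental predictors plus `median_lat_range`.
#' @return An object of class `ldg_forest`: the ranger model plus the
#'   training data, OOB predictions, residuals (observed minus OOB
#'   predicted), `pseudo_r2` and the configuration.
#' @export
fit_richness_forest <- function(bins, config = rf_config(),
                                response = "richness",
                                predictors = default_driver_predictors()) {
  require_columns(bins, c(response, predictors), "bin")
  all_missing <- predictors[vapply(bins[predictors],
                                   function(x) all(is.na(x)), logical(1))]
  if (length(all_missing) > 0L) {
    stop(sprintf("predictor(s) entirely missing: %s",
                 paste(all_missing, collapse = ", ")), call. = FALSE)
  }
  dat <- dplyr::select(tibble::as_tibble(bins),
                       dplyr::any_of(c("bin_mid", response, predictors)))
  keep <- stats::complete.cases(dat[c(response, predictors)])
  dat <- dat[keep, , drop = FALSE]
  if (nrow(dat) < 2L * config$min_node_size) {
    stop(sprintf("only %d complete rows; need at least 2 x min_node_size = %d.",
                 nrow(dat), 2L * config$min_node_size), call. = FALSE)
  }
  y <- dat[[response]]
  if (stats::var(y) == 0) {
    stop("degenerate input: response has zero variance, pseudo-r2 undefined.",
         call. = FALSE)
  }
  p <- length(predictors)
  mtry <- if (is.null(config$mtry)) max(1L, floor(p / 3)) else min(config$mtry, p)

  model <- ranger::ranger(
    x = as.data.frame(dat[predictors]), y = y,
    num.trees = config$n_trees, mtry = mtry,
    min.node.size = config$min_node_size,
    importance = "permutation", keep.inbag = TRUE,
    seed = config$seed, num.threads = 1
  )
  oob <- model$predictions
  pseudo_r2 <- 1 - mean((y - oob)^2) / stats::var(y)

  structure(list(
    model = model,
    data = dat,
    response = response,
    predictors = predictors,
    mtry = mtry,
    oob_predictions = oob,
    residuals = y - oob,
    pseudo_r2 = pseudo_r2,
    config = config
  ), class = "ldg_forest")
}

#' @export
print.ldg_forest <- function(x, ...) {
  cat("<ldg_forest>\n")
  cat(sprintf("  %d trees, mtry %d, node size %d, %d rows, %d predictors\n",
              x$config$n_trees, x$mtry, x$config$min_node_size,
              nrow(x$data), length(x$predictors)))
  cat(sprintf("  OOB pseudo-r2 = %.3f\n", x$pseudo_r2))
  invisible(x)
}

#' Predict from a fitted richness forest
#'
#' @param object An `ldg_forest`.
#' @param newdata Data frame with the predictor columns; default the
#'   training rows.
#' @param ... Unused.
#' @return Numeric vector of ensemble predictions.
#' @export
predict.ldg_forest <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  stats::predict(object$model,
                 data = as.data.frame(newdata[object$predictors]),
                 num.threads = 1)$predictions
}

# Per-tree predictions (n x n_trees) for the first `n_trees` trees.
predict_per_tree <- function(forest, newdata, n_trees) {
  stats::predict(forest$model,
                 data = as.data.frame(newdata[forest$predictors]),
                 predict.all = TRUE, num.trees = n_trees,
                 num.threads = 1)$predictions
}

#' Conditional permutation importance
#'
#' Per-tree permutation importance in which a predictor is permuted within
#' strata of its correlated covariates, so that importance measures the
#' information a predictor adds beyond what its collinear partners already
#' carry. For predictor `j`, the conditioning set is every covariate with
#' absolute Pearson correlation to `j` above `cond_threshold`; within each
#' tree those covariates are discretised at that tree's own split points and
#' `j` is permuted within the resulting strata among the tree's out-of-bag
#' rows. Importance is the mean over trees of the OOB mean-squared-error
#' increase. With an empty conditioning set (e.g. a threshold above 1) this
#' reduces exactly to unconditional per-tree permutation importance.
#'
#' @param forest An [fit_richness_forest()] result.
#' @param cond_threshold Correlation threshold; default taken from the
#'   forest's configuration.
#' @param n_trees Number of trees to evaluate (the first `n_trees` of the
#'   ensemble); default all. Importance stabilises well below the ensemble
#'   size, so large forests can be evaluated on a subset.
#' @param seed RNG seed for the within-stratum permutations.
#' @return A tibble with `predictor`, `importance` (mean OOB MSE increase,
#'   raw response-squared units) and `n_conditioning` (conditioning-set
#'   size).
#' @export
conditional_importance <- function(forest, cond_threshold = NULL,
                                   n_trees = NULL, seed = 1) {
  stopifnot(inherits(forest, "ldg_forest"))
  if (is.null(cond_threshold)) cond_threshold <- forest$config$cond_threshold
  model <- forest$model
  n_use <- if (is.null(n_trees)) model$num.trees else
    min(n_trees, model$num.trees)
  xm <- as.data.frame(forest$data[forest$predictors])
  y <- forest$data[[forest$response]]
  n <- nrow(xm)
  p <- length(forest$predictors)
  local_seed(seed)

  inbag <- matrix(unlist(model$inbag.counts, use.names = FALSE), nrow = n)
  preds_all <- predict_per_tree(forest, forest$data, n_use)

  cors <- suppressWarnings(stats::cor(as.matrix(xm)))
  cond_sets <- lapply(seq_len(p), function(j) {
    which(abs(cors[j, ]) > cond_threshold & seq_len(p) != j)
  })

  delta <- matrix(0, nrow = n_use, ncol = p)
  for (t in seq_len(n_use)) {
    oob <- which(inbag[, t] == 0L)
    if (length(oob) < 2L) next
    base_mse <- mean((y[oob] - preds_all[oob, t])^2)
    ti <- ranger::treeInfo(model, t)
    split_vals <- split(ti$splitval[!ti$terminal],
                        ti$splitvarName[!ti$terminal])
    for (j in seq_len(p)) {
      strata <- tree_strata(xm, oob, cond_sets[[j]], split_vals,
                            forest$predictors)
      newx <- xm[oob, , drop = FALSE]
      newx[[j]] <- permute_within(newx[[j]], strata)
      perm_pred <- predict_per_tree(forest, newx, n_use)[, t]
      delta[t, j] <- mean((y[oob] - perm_pred)^2) - base_mse
    }
  }
  tibble::tibble(
    predictor = forest$predictors,
    importance = colMeans(delta),
    n_conditioning = lengths(cond_sets)
  )
}

# Stratum labels for OOB rows: interaction of each conditioning covariate cut
# at this tree's split points for that covariate.
tree_strata <- function(xm, oob, cond_set, split_vals, predictor_names) {
  if (length(cond_set) == 0L) return(rep(1L, length(oob)))
  labels <- lapply(cond_set, function(k) {
    cuts <- split_vals[[predictor_names[k]]]
    if (is.null(cuts) || length(cuts) == 0L) return(rep(1L, length(oob)))
    findInterval(xm[oob, k], sort(unique(cuts)))
  })
  as.integer(interaction(as.data.frame(labels), drop = TRUE))
}

permute_within <- function(x, strata) {
  for (s in unique(strata)) {
    idx <- which(strata == s)
    if (length(idx) > 1L) x[idx] <- x[sample(idx)]
  }
  x
}

#' Permutation p-values for predictor importance
#'
#' Response-permutation importance testing: the response column is permuted
#' `B` times, the forest refitted on each permuted dataset and the
#' importance statistic recomputed, giving each predictor a null importance
#' distribution. `p_j = (1 + #\{null >= observed\}) / (B + 1)`, so the
#' smallest attainable p is `1 / (B + 1)`.
#'
#' @param bins Bin table, as for [fit_richness_forest()].
#' @param config An [rf_config()]; `n_perm_importance` sets `B`.
#' @param response,predictors As in [fit_richness_forest()].
#' @param statistic `"unconditional"` (the forest's OOB permutation
#'   importance; fast, default) or `"conditional"`
#'   ([conditional_importance()], much slower under refitting).
#' @return A tibble with `predictor`, `importance` (observed), `p_value`;
#'   the null matrix is attached as attribute `"null"`.
#' @export
importance_pvalues <- function(bins, config = rf_config(),
                               response = "richness",
                               predictors = default_driver_predictors(),
                               statistic = c("unconditional", "conditional")) {
  statistic <- match.arg(statistic)
  B <- config$n_perm_importance

  imp_of <- function(cfg, data) {
    f <- fit_richness_forest(data, cfg, response, predictors)
    if (statistic == "conditional") {
      conditional_importance(f, seed = cfg$seed)$importance
    } else {
      unname(f$model$variable.importance[predictors])
    }
  }

  observed <- imp_of(config, bins)
  local_seed(config$seed)
  null <- matrix(NA_real_, nrow = B, ncol = length(predictors))
  dat <- bins
  perm_seeds <- sample.int(.Machine$integer.max, B)
  for (b in seq_len(B)) {
    dat[[response]] <- sample(bins[[response]])
    cfg_b <- config
    cfg_b$seed <- perm_seeds[b]
    null[b, ] <- imp_of(cfg_b, dat)
  }
  p <- (1 + colSums(sweep(null, 2, observed, `>=`))) / (B + 1)
  out <- tibble::tibble(predictor = predictors, importance = observed,
                        p_value = p)
  attr(out, "null") <- null
  out
}

#' Partial dependence of predicted richness on one predictor
#'
#' For each grid value `v` over the predictor's observed range, sets the
#' predictor to `v` in every training row (other columns untouched) and
#' averages the model predictions — the functional relationship between the
#' response and one predictor, isolated from the others.
#'
#' @param forest An `ldg_forest`.
#' @param predictor Predictor column name.
#' @param grid_size Number of evenly spaced grid values, default 25.
#' @param grid Optional explicit grid (overrides `grid_size`).
#' @return A tibble of class `ldg_pd` with columns `predictor`, `value`,
#'   `yhat`, ordered in the predictor.
#' @export
partial_dependence <- function(forest, predictor, grid_size = 25,
                               grid = NULL) {
  stopifnot(inherits(forest, "ldg_forest"))
  if (!predictor %in% forest$predictors) {
    stop(sprintf("unknown predictor: %s", predictor), call. = FALSE)
  }
  obs <- forest$data[[predictor]]
  if (is.null(grid)) {
    grid <- if (grid_size == 1L) stats::median(obs) else
      seq(min(obs), max(obs), length.out = grid_size)
  }
  grid <- sort(grid)
  yhat <- vapply(grid, function(v) {
    newx <- forest$data
    newx[[predictor]] <- v
    mean(predict(forest, newx))
  }, numeric(1))
  structure(tibble::tibble(predictor = predictor, value = grid, yhat = yhat),
            class = c("ldg_pd", "tbl_df", "tbl", "data.frame"))
}

#' Moran's I residual correlogram with a permutation envelope
#'
#' Splits all bin pairs into equal-width latitudinal distance classes and
#' computes Moran's I per class with binary within-class weights:
#' `I = (n / W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`.
#' The null envelope is the 2.5/97.5 percentile band of I under random
#' permutation of the residuals across bins.
#'
#' @param residuals Per-bin residuals.
#' @param positions Bin positions (degrees South, e.g. bin midpoints);
#'   pairwise distance is the absolute latitudinal difference.
#' @param n_classes Number of equal-width distance classes, default 10.
#' @param n_runs Number of permutation runs for the envelope (at least 99),
#'   default 999.
#' @param seed RNG seed.
#' @return A tibble of class `ldg_correlogram` with one row per class:
#'   `mean_distance`, `moran_i`, `null_lo`, `null_hi`, `n_pairs`. Pair
#'   counts over classes sum to `n(n-1)/2`.
#' @export
residual_correlogram <- function(residuals, positions, n_classes = 10,
                                 n_runs = 999, seed = 1) {
  n <- length(residuals)
  if (n < 5L) stop("need at least 5 bins.", call. = FALSE)
  if (length(positions) != n) {
    stop("`residuals` and `positions` lengths differ.", call. = FALSE)
  }
  if (stats::sd(residuals) == 0) {
    stop("degenerate input: residuals are constant.", call. = FALSE)
  }
  if (n_runs < 99) stop("`n_runs` must be at least 99.", call. = FALSE)
  local_seed(seed)

  pair <- utils::combn(n, 2)
  i1 <- pair[1, ]; i2 <- pair[2, ]
  d <- abs(positions[i1] - positions[i2])
  breaks <- seq(0, max(d), length.out = n_classes + 1)
  cls <- cut(d, breaks, include.lowest = TRUE, labels = FALSE)

  moran_by_class <- function(x) {
    xc <- x - mean(x)
    ss <- sum(xc^2)
    num <- rowsum(xc[i1] * xc[i2], cls, reorder = TRUE)
    m <- as.vector(rowsum(rep(1, length(cls)), cls, reorder = TRUE))
    # binary symmetric weights: W = 2m, numerator doubles too
    as.vector(num) * n / (m * ss)
  }

  obs <- moran_by_class(residuals)
  null <- replicate(n_runs, moran_by_class(sample(residuals)))
  lo <- apply(null, 1, stats::quantile, probs = 0.025)
  hi <- apply(null, 1, stats::quantile, probs = 0.975)

  structure(tibble::tibble(
    class = sort(unique(cls)),
    mean_distance = as.vector(tapply(d, cls, mean)),
    moran_i = obs,
    null_lo = lo,
    null_hi = hi,
    n_pairs = as.vector(table(cls))
  ), class = c("ldg_correlogram", "tbl_df", "tbl", "data.frame"))
}
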