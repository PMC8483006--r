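# Shared small fixture: a bin table with a strong structured response.
driver_fixture <- function(seed = 1, n = 106) {
  set.seed(seed)
  lat <- seq(3.25, by = 0.5, length.out = n)
  tibble::tibble(
    bin_mid = lat,
    x1 = seq(0, 1, length.out = n) + rnorm(n, sd = 0.05),
    x2 = rnorm(n),
    x3 = rnorm(n),
    richness = round(100 * exp(-(lat - 42)^2 / 60) + rnorm(n, sd = 2)) + 20
  )
}

test_that("forest fitting is reproducible and guards degenerate input", {
  bt <- driver_fixture(seed = 2)
  cfg <- rf_config(n_trees = 150, seed = 5)
  f1 <- fit_richness_forest(bt, cfg, predictors = c("x1", "x2", "x3"))
  f2 <- fit_richness_forest(bt, cfg, predictors = c("x1", "x2", "x3"))
  expect_identical(f1$oob_predictions, f2$oob_predictions)
  expect_lte(f1$pseudo_r2, 1)

  const <- dplyr::mutate(bt, richness = 7)
  expect_error(fit_richness_forest(const, cfg,
                                   predictors = c("x1", "x2", "x3")),
               "zero variance")
  allna <- dplyr::mutate(bt, x2 = NA_real_)
  expect_error(fit_richness_forest(allna, cfg,
                                   predictors = c("x1", "x2", "x3")),
               "entirely missing")
})

test_that("a step-function signal is learned almost perfectly", {
  set.seed(9)
  n <- 200
  bt <- tibble::tibble(
    x1 = runif(n), x2 = rnorm(n),
    richness = ifelse(x1 > 0.5, 100, 10)
  )
  f <- fit_richness_forest(bt, rf_config(n_trees = 500, seed = 1),
                           predictors = c("x1", "x2"))
  expect_gt(f$pseudo_r2, 0.9)
})

test_that("pseudo-r2 is near zero when the response is independent noise", {
  set.seed(10)
  r2s <- sapply(1:5, function(s) {
    bt <- tibble::tibble(x1 = rnorm(80), x2 = rnorm(80),
                         richness = rnorm(80))
    fit_richness_forest(bt, rf_config(n_trees = 300, seed = s),
                        predictors = c("x1", "x2"))$pseudo_r2
  })
  expect_lt(abs(mean(r2s)), 0.25)
  expect_true(all(r2s <= 1))
})

test_that("conditional importance reduces to unconditional with no conditioning", {
  bt <- driver_fixture(seed = 3)
  f <- fit_richness_forest(bt, rf_config(n_trees = 100, seed = 2),
                           predictors = c("x1", "x2", "x3"))
  ci_over1 <- conditional_importance(f, cond_threshold = 1.5, seed = 7)
  expect_true(all(ci_over1$n_conditioning == 0))

  # independent hand-coded unconditional per-tree permutation importance,
  # replaying the same RNG stream
  xm <- as.data.frame(f$data[f$predictors])
  y <- f$data$richness
  inbag <- matrix(unlist(f$model$inbag.counts), nrow = nrow(xm))
  base <- predict(f$model, data = xm, predict.all = TRUE,
                  num.threads = 1)$predictions
  set.seed(7)
  delta <- matrix(0, f$model$num.trees, 3)
  for (t in seq_len(f$model$num.trees)) {
    oob <- which(inbag[, t] == 0)
    mse0 <- mean((y[oob] - base[oob, t])^2)
    for (j in 1:3) {
      nd <- xm[oob, ]
      nd[[j]] <- nd[[j]][sample(seq_along(oob))]
      pp <- predict(f$model, data = nd, predict.all = TRUE,
                    num.threads = 1)$predictions[, t]
      delta[t, j] <- mean((y[oob] - pp)^2) - mse0
    }
  }
  expect_equal(ci_over1$importance, colMeans(delta), tolerance = 1e-10)
  expect_gt(ci_over1$importance[1], 10 * abs(ci_over1$importance[2]))
})

test_that("a duplicated informative predictor shares (and loses) importance", {
  set.seed(12)
  n <- 150
  x <- runif(n)
  bt <- tibble::tibble(x1 = x, x1copy = x + rnorm(n, sd = 0.01),
                       z = rnorm(n),
                       richness = 50 * x + rnorm(n, sd = 1))
  f_dup <- fit_richness_forest(bt, rf_config(n_trees = 300, seed = 3),
                               predictors = c("x1", "x1copy", "z"))
  ci_dup <- conditional_importance(f_dup, cond_threshold = 0.2, seed = 4)
  f_solo <- fit_richness_forest(bt, rf_config(n_trees = 300, seed = 3),
                                predictors = c("x1", "z"))
  ci_solo <- conditional_importance(f_solo, cond_threshold = 1.5, seed = 4)
  solo_imp <- ci_solo$importance[ci_solo$predictor == "x1"]
  expect_lt(ci_dup$importance[ci_dup$predictor == "x1"], solo_imp)
  expect_lt(ci_dup$importance[ci_dup$predictor == "x1copy"], solo_imp)
})

test_that("a pure-noise predictor has conditional importance near zero", {
  imps <- sapply(1:20, function(s) {
    set.seed(100 + s)
    n <- 100
    bt <- tibble::tibble(x = runif(n), noise = rnorm(n))
    bt$richness <- 10 * bt$x + rnorm(n, sd = 0.5)
    f <- fit_richness_forest(bt, rf_config(n_trees = 150, seed = s),
                             predictors = c("x", "noise"))
    conditional_importance(f, seed = s)$importance[2]
  })
  mc_se <- sd(imps) / sqrt(length(imps))
  expect_lt(abs(mean(imps)), 2 * mc_se + 0.01)
})

test_that("importance p-values follow the add-one permutation formula", {
  bt <- driver_fixture(seed = 4)
  cfg <- rf_config(n_trees = 100, n_perm_importance = 199, seed = 6)
  ip <- importance_pvalues(bt, cfg, predictors = c("x1", "x2", "x3"))
  null <- attr(ip, "null")
  expect_equal(dim(null), c(199, 3))
  for (j in 1:3) {
    expect_equal(ip$p_value[j],
                 (1 + sum(null[, j] >= ip$importance[j])) / 200,
                 tolerance = 1e-12)
  }
  # x1 drives the response strongly: observed importance beats every null
  expect_equal(ip$p_value[ip$predictor == "x1"], 1 / 200)
  expect_gte(min(ip$p_value), 1 / 200)
})

test_that("partial dependence is flat for an ignored predictor and exact for grids", {
  set.seed(15)
  n <- 120
  bt <- tibble::tibble(x = runif(n), ignored = rnorm(n),
                       richness = 40 * x)
  # mtry = 2 lets every split see the informative predictor, so the tree
  # never needs the irrelevant one
  f <- fit_richness_forest(bt, rf_config(n_trees = 200, mtry = 2, seed = 2),
                           predictors = c("x", "ignored"))
  flat <- partial_dependence(f, "ignored", grid_size = 15)
  expect_lt(diff(range(flat$yhat)), 2)

  one <- partial_dependence(f, "x", grid_size = 1)
  expect_equal(nrow(one), 1)
  newx <- f$data; newx$x <- one$value
  expect_equal(one$yhat, mean(predict(f, newx)), tolerance = 1e-10)
  expect_error(partial_dependence(f, "nope"), "unknown predictor")
})

test_that("partial dependence at observed values equals the brute-force double average", {
  bt <- driver_fixture(seed = 6, n = 40)
  f <- fit_richness_forest(bt, rf_config(n_trees = 100, seed = 3),
                           predictors = c("x1", "x2", "x3"))
  grid <- sort(f$data$x1)
  pd <- partial_dependence(f, "x1", grid = grid)
  brute <- sapply(grid, function(v) {
    nd <- f$data; nd$x1 <- v
    mean(predict(f, nd))
  })
  expect_equal(pd$yhat, brute, tolerance = 1e-8)
})

test_that("an additive component is recovered by partial dependence", {
  set.seed(16)
  n <- 300
  x <- runif(n, -2, 2); z <- runif(n, -2, 2)
  bt <- tibble::tibble(x = x, z = z, richness = x^2 + 3 * z)
  f <- fit_richness_forest(bt, rf_config(n_trees = 400, seed = 4),
                           predictors = c("x", "z"))
  pd <- partial_dependence(f, "x", grid_size = 21)
  truth <- pd$value^2
  # match up to an additive constant
  rmse <- sqrt(mean((pd$yhat - mean(pd$yhat) - (truth - mean(truth)))^2))
  expect_lt(rmse, 0.5)
})

test_that("Moran's I per class equals a hand-expanded double sum", {
  x <- c(1.2, -0.7, 0.3, 2.1, -1.5, 0.6)
  pos <- c(1, 2, 3, 5, 8, 13)
  cg <- residual_correlogram(x, pos, n_classes = 3, n_runs = 99, seed = 2)
  n <- 6
  xc <- x - mean(x)
  d <- abs(outer(pos, pos, `-`))
  breaks <- seq(0, max(d), length.out = 4)
  for (k in seq_len(nrow(cg))) {
    lo <- breaks[cg$class[k]]; hi <- breaks[cg$class[k] + 1]
    w <- d > lo & d <= hi & row(d) != col(d)
    I_hand <- (n / sum(w)) * sum(w * outer(xc, xc)) / sum(xc^2)
    expect_equal(cg$moran_i[k], I_hand, tolerance = 1e-12)
  }
  expect_equal(sum(cg$n_pairs), n * (n - 1) / 2)
})

test_that("checkerboard residuals give negative short-range autocorrelation", {
  x <- rep(c(1, -1), length.out = 20)
  pos <- seq(3.25, by = 0.5, length.out = 20)
  cg <- residual_correlogram(x, pos, n_classes = 5, n_runs = 99, seed = 3)
  expect_lt(cg$moran_i[1], 0)
  expect_true(all(cg$null_lo <= cg$null_hi))
  expect_error(residual_correlogram(rep(1, 10), 1:10), "constant")
})

test_that("permuted residuals fall inside the 95% envelope about 95% of the time", {
  set.seed(18)
  pos <- seq(3.25, by = 0.5, length.out = 40)
  inside <- replicate(40, {
    x <- rnorm(40)
    cg <- residual_correlogram(x, pos, n_classes = 5, n_runs = 199,
                               seed = sample.int(1e6, 1))
    mean(cg$moran_i >= cg$null_lo & cg$moran_i <= cg$null_hi)
  })
  expect_gt(mean(inside), 0.88)
})
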