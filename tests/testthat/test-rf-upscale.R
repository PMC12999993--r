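# small regression fixture with one dominant predictor
rf_fixture <- function(n = 200, seed = 1, noise = 0.05) {
  set.seed(seed)
  d <- data.frame(x1 = runif(n, 0, 10), x2 = rnorm(n), x3 = rnorm(n),
                  x4 = rnorm(n))
  d$y <- d$x1 / (d$x1 + 2) + rnorm(n, 0, noise)
  d
}

test_that("seeded forest fits are deterministic and refuse bad input", {
  d <- rf_fixture()
  m1 <- fit_rf(d, "y", c("x1", "x2", "x3", "x4"), n_trees = 100, seed = 7)
  m2 <- fit_rf(d, "y", c("x1", "x2", "x3", "x4"), n_trees = 100, seed = 7)
  expect_identical(m1$oob_mse, m2$oob_mse)
  expect_identical(m1$oob_predictions, m2$oob_predictions)
  const <- d; const$y <- 1
  expect_error(fit_rf(const, "y", "x1"), "constant response")
  expect_error(fit_rf(d[1:30, ], "y", "x1"), "at least 50")
  expect_error(fit_rf(d, "y", c("x1", "zz")), "zz")
})

test_that("OOB variance explained brackets signal and noise regimes", {
  covs <- c("map", "mat", "pet", "humidity", "soc", "ph", "silt", "clay",
            "cec", "bsat", "depth", "ndvi")
  sim <- generate_observations(sim_config(n_per_biome = 182, seed = 13,
                                          noise_sd = 0))
  d <- sim$observations
  # response generated noiselessly from one covariate
  d$y <- d$soc / (d$soc + 15)
  m <- fit_rf(d, "y", covs, n_trees = 200, seed = 13)
  expect_gte(m$var_explained, 90)
  # pure-noise response
  set.seed(13)
  d$y <- rnorm(nrow(d))
  m <- fit_rf(d, "y", covs, n_trees = 200, seed = 13)
  expect_lte(m$var_explained, 10)
})

test_that("permutation importance isolates the dominant predictor", {
  d <- rf_fixture(250, seed = 5)
  m <- fit_rf(d, "y", c("x1", "x2", "x3", "x4"), n_trees = 150, seed = 5)
  imp <- importance_incmse(m, n_perm = 5, seed = 5)
  expect_equal(imp$predictor[1], "x1")
  expect_gt(imp$inc_mse[1], 10 * max(abs(imp$inc_mse[-1])))
  expect_true(all(is.na(imp$p_value)))
  expect_error(importance_incmse(m, predictors = "x9"), "x9")
})

test_that("the add-one permutation p-value follows its formula", {
  d <- rf_fixture(60, seed = 2, noise = 0.01)
  m <- fit_rf(d, "y", c("x1", "x2", "x3", "x4"), n_trees = 40, seed = 2)
  imp <- importance_incmse(m, n_perm = 2, seed = 2, n_null = 20)
  null <- attr(imp, "null")
  expect_identical(dim(null), c(20L, 4L))
  x1 <- imp[imp$predictor == "x1", ]
  # the dominant predictor exceeds every null draw -> p = 1 / (B + 1)
  expect_true(all(null[, "x1"] < x1$inc_mse))
  expect_equal(x1$p_value, 1 / 21)
  expect_true(all(imp$p_value > 0 & imp$p_value <= 1))
  # recomputing the p-values from the retained nulls reproduces them
  for (j in seq_len(nrow(imp))) {
    p <- imp$predictor[j]
    expect_equal(imp$p_value[j],
                 (1 + sum(null[, p] >= imp$inc_mse[j])) / 21)
  }
})

test_that("duplicating an informative predictor splits its importance", {
  d <- rf_fixture(250, seed = 9, noise = 0.02)
  m1 <- fit_rf(d, "y", c("x1", "x2"), n_trees = 150, seed = 9)
  i1 <- importance_incmse(m1, n_perm = 5, seed = 9)
  d$x1b <- d$x1
  m2 <- fit_rf(d, "y", c("x1", "x2", "x1b"), n_trees = 150, seed = 9)
  i2 <- importance_incmse(m2, n_perm = 5, seed = 9)
  single <- i1$inc_mse[i1$predictor == "x1"]
  dup <- i2$inc_mse[i2$predictor == "x1"]
  expect_lt(dup, single)
})

test_that("partial dependence reflects the marginal shape of the driver", {
  d <- rf_fixture(400, seed = 3, noise = 0.01)
  m <- fit_rf(d, "y", c("x1", "x2", "x3", "x4"), n_trees = 200, seed = 3)
  pd <- partial_dependence(m, "x1", n_grid = 40)
  expect_equal(nrow(pd), 40)
  expect_true(all(diff(pd$value) > 0))
  rng <- max(pd$yhat) - min(pd$yhat)
  # monotone-saturating within tolerance: no sizeable decreasing step,
  # most of the rise in the lower half of the range
  expect_true(all(diff(pd$yhat) > -0.05 * rng))
  first_half <- pd$yhat[20] - pd$yhat[1]
  expect_gt(first_half, 0.6 * rng)

  # a predictor the response ignores gives a near-flat curve
  pd2 <- partial_dependence(m, "x3", n_grid = 20)
  expect_lt(max(pd2$yhat) - min(pd2$yhat), 0.1 * rng)

  # row order of the training data does not matter
  set.seed(4)
  d2 <- d[sample(nrow(d)), ]
  m2 <- fit_rf(d2, "y", c("x1", "x2", "x3", "x4"), n_trees = 200, seed = 3)
  pd3 <- partial_dependence(m2, "x1", n_grid = 40)
  expect_equal(pd3$value, pd$value, tolerance = 1e-12)

  expect_error(partial_dependence(m, "x1", n_grid = 1), "at least 2")
  expect_error(partial_dependence(m, "nope"), "nope")
})

test_that("grid prediction matches per-tree brute force and propagates nodata", {
  d <- rf_fixture(120, seed = 6)
  covs <- c("x1", "x2", "x3", "x4")
  m <- fit_rf(d, "y", covs, n_trees = 60, seed = 6)

  set.seed(6)
  layers <- lapply(setNames(covs, covs), function(v)
    matrix(runif(48, min(d[[v]]), max(d[[v]])), 6, 8))
  layers$x2[2, 3] <- NA
  g <- covariate_grid(layers, extent = c(0, 8, 0, 6))
  pg <- predict_grid(m, g)

  # brute force: loop over cells and trees
  for (cell in list(c(1, 1), c(4, 5), c(6, 8))) {
    row <- cell[1]; col <- cell[2]
    nd <- as.data.frame(lapply(layers, function(l) l[row, col]))
    tp <- drop(tree_predictions(m, nd))
    expect_equal(pg$layers$prediction[row, col], mean(tp),
                 tolerance = 1e-10)
    expect_equal(pg$layers$sd[row, col], sd(tp), tolerance = 1e-10)
    # ensemble prediction equals the mean over trees (averaging forest)
    expect_equal(predict(m$forest, data = nd,
                         num.threads = 1)$predictions,
                 mean(tp), tolerance = 1e-10)
  }
  # nodata in any covariate propagates to all outputs
  expect_true(is.na(pg$layers$prediction[2, 3]))
  expect_true(is.na(pg$layers$sd[2, 3]))
  expect_true(is.na(pg$layers$rel_uncertainty[2, 3]))
  # outputs independent of tile size
  pg2 <- predict_grid(m, g, tile_size = 7)
  expect_identical(pg$layers, pg2$layers)

  # uniform grid: every cell equals one training row -> uniform raster
  # equal to the tabular point prediction
  row1 <- d[17, covs]
  layers_u <- lapply(setNames(covs, covs), function(v)
    matrix(row1[[v]], 3, 3))
  pgu <- predict_grid(m, covariate_grid(layers_u, c(0, 3, 0, 3)))
  tab <- predict(m$forest, data = row1, num.threads = 1)$predictions
  expect_true(all(abs(pgu$layers$prediction - tab) < 1e-12))

  # all-nodata input -> all-nodata output
  layers_na <- lapply(layers, function(l) { l[] <- NA_real_; l })
  pgn <- predict_grid(m, covariate_grid(layers_na, c(0, 8, 0, 6)))
  expect_true(all(is.na(pgn$layers$prediction)))

  expect_error(predict_grid(m, covariate_grid(layers[1:3], c(0, 8, 0, 6))),
               "x4")
})

test_that("relative uncertainty is the SD as a percentage of the global mean", {
  expect_equal(relative_uncertainty(0.06, 0.60), 10)
  expect_equal(relative_uncertainty(c(0, 0.3), 0.6), c(0, 50))
})
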