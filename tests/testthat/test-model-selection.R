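# noiseless linear data
linear_data <- function(n = 100, seed = 2) {
  set.seed(seed)
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  d$y <- 1.5 + 2 * d$x1 - d$x2 + 0.5 * d$x3
  d
}

test_that("splits have the exact sizes and are seed-reproducible", {
  s1 <- make_cv_splits(100, n_iter = 25, train_frac = 0.8, seed = 9)
  s2 <- make_cv_splits(100, n_iter = 25, train_frac = 0.8, seed = 9)
  expect_identical(s1, s2)
  expect_true(all(vapply(s1, length, 0L) == 80L))
  for (tr in s1) {
    expect_equal(length(unique(tr)), 80)      # no repeats: 20 held out
    expect_true(all(tr %in% 1:100))
  }
  s3 <- make_cv_splits(100, n_iter = 25, train_frac = 0.8, seed = 10)
  expect_false(identical(s1, s3))
})

test_that("validation scoring never sees training rows", {
  # a memorizing "model" that can only answer for rows it saw in training
  d <- linear_data(80)
  d$.row <- seq_len(nrow(d))
  memorizer <- model_spec(
    "memorizer",
    fit = function(data, response)
      list(seen = data$.row, y = data[[response]]),
    predict = function(model, newdata) {
      hit <- match(newdata$.row, model$seen)
      out <- model$y[hit]
      out[is.na(hit)] <- 0
      out
    })
  res <- monte_carlo_cv(d, "y", memorizer, n_iter = 20, seed = 4)
  # if any validation row had been in training, it would be predicted
  # perfectly; an honest harness leaves the memorizer useless
  expect_lt(res$mean_r2, 0.05)
})

test_that("noiseless linear data is fit perfectly by the linear specs", {
  d <- linear_data(100)
  specs <- default_model_specs()
  for (name in c("mlr", "stepwise", "elastic_net", "lar")) {
    # step() warns about model selection on a perfect fit; that is the point
    res <- suppressWarnings(
      monte_carlo_cv(d, "y", specs[[name]], n_iter = 10, seed = 1))
    expect_gte(res$mean_r2, 0.999)
  }
})

test_that("summary metrics are the arithmetic means of the iterations", {
  d <- linear_data(60)
  d$y <- d$y + rnorm(60, 0, 0.5)
  res <- monte_carlo_cv(d, "y", default_model_specs()$mlr, n_iter = 15,
                        seed = 3)
  expect_equal(res$mean_r2, mean(res$r2), tolerance = 1e-12)
  expect_equal(res$mean_rmse, mean(res$rmse), tolerance = 1e-12)
  expect_length(res$r2, 15)
})

test_that("identical specs on a shared seed give identical results", {
  d <- linear_data(80)
  d$y <- d$y + rnorm(80, 0, 0.3)
  specs <- list(a = default_model_specs()$mlr, b = default_model_specs()$mlr)
  cmp <- compare_models(d, "y", specs, n_iter = 8, seed = 6)
  expect_identical(cmp$results$a$r2, cmp$results$b$r2)
  expect_identical(cmp$results$a$rmse, cmp$results$b$rmse)
})

test_that("a spec failing every iteration is ranked last with a status", {
  d <- linear_data(60)
  broken <- model_spec("broken",
                       fit = function(data, response) stop("boom"),
                       predict = function(model, newdata) 0)
  specs <- list(mlr = default_model_specs()$mlr, broken = broken)
  suppressWarnings(cmp <- compare_models(d, "y", specs, n_iter = 5, seed = 1))
  expect_equal(cmp$table$model[nrow(cmp$table)], "broken")
  expect_equal(cmp$table$status[nrow(cmp$table)], "all_failed")
  expect_equal(cmp$table$n_failed[cmp$table$model == "broken"], 5L)
})

test_that("the forest outranks linear regression on an interaction surface", {
  specs <- default_model_specs(n_trees = 100)
  wins <- 0L
  for (seed in 1:5) {
    set.seed(seed)
    n <- 150
    d <- data.frame(x1 = runif(n, -2, 2), x2 = runif(n, -2, 2),
                    x3 = rnorm(n))
    d$y <- sin(2 * d$x1) * d$x2 + 0.5 * d$x2^2 + rnorm(n, 0, 0.1)
    cmp <- compare_models(d, "y", specs[c("mlr", "random_forest")],
                          n_iter = 10, seed = seed)
    if (cmp$table$model[1] == "random_forest") wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("failed iterations are excluded from the means with a warning", {
  d <- linear_data(60)
  flaky_counter <- new.env()
  flaky_counter$i <- 0L
  flaky <- model_spec(
    "flaky",
    fit = function(data, response) {
      flaky_counter$i <- flaky_counter$i + 1L
      if (flaky_counter$i == 2L) stop("transient")
      stats::lm(y ~ ., data = data)
    },
    predict = function(model, newdata) unname(predict(model, newdata)))
  expect_warning(res <- monte_carlo_cv(d, "y", flaky, n_iter = 4, seed = 2),
                 "transient")
  expect_equal(res$n_failed, 1L)
  expect_equal(res$mean_r2, mean(res$r2[!res$failed]))
})
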