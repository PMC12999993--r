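#' Fit the final random-forest model
#'
#' A 500-tree regression forest over the VIF-retained covariates, keeping
#' in-bag counts so that per-tree and out-of-bag (OOB) predictions are
#' retrievable for the permutation-importance and per-cell uncertainty
#' stages.
#'
#' @param data data frame holding the response and covariates.
#' @param response response column name.
#' @param covariates covariate column names (the VIF-retained set).
#' @param n_trees ensemble size (default 500).
#' @param seed forest seed; identical seeds give identical OOB statistics.
#' @param min_node_size minimal terminal node size.
#' @return object of class `forest_model` with elements `forest`,
#'   `covariates`, `response`, `data` (the complete training rows),
#'   `oob_predictions`, `oob_mse` (mean squared residual) and
#'   `var_explained` (percent OOB variance explained).
#' @export
fit_rf <- function(data, response, covariates, n_trees = 500, seed = 1,
                   min_node_size = 5) {
  stopifnot(response %in% names(data))
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov))
    stop("covariate(s) not in data: ", paste(missing_cov, collapse = ", "))
  d <- data[c(response, covariates)]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 50) stop("need at least 50 complete rows")
  if (stats::sd(d[[response]]) == 0)
    stop("constant response: a forest cannot be fit")
  forest <- ranger::ranger(stats::reformulate(covariates, response),
                           data = d, num.trees = n_trees, seed = seed,
                           keep.inbag = TRUE, num.threads = 1,
                           min.node.size = min_node_size)
  structure(list(forest = forest, covariates = covariates,
                 response = response, data = d, n_trees = n_trees,
                 seed = seed,
                 oob_predictions = forest$predictions,
                 oob_mse = forest$prediction.error,
                 var_explained = 100 * forest$r.squared),
            class = "forest_model")
}

#' @export
print.forest_model <- function(x, ...) {
  cat(sprintf("Random forest: %d trees, %d training rows, %d covariates\n",
              x$n_trees, nrow(x$data), length(x$covariates)))
  cat(sprintf("  OOB mean squared residual: %.4g\n", x$oob_mse))
  cat(sprintf("  OOB variance explained: %.2f%%\n", x$var_explained))
  invisible(x)
}

#' Per-tree predictions
#'
#' @param model a [fit_rf()] model.
#' @param newdata data frame with the training covariates.
#' @return numeric matrix, rows = observations, columns = trees.
#' @export
tree_predictions <- function(model, newdata) {
  stopifnot(inherits(model, "forest_model"))
  predict(model$forest, data = newdata, predict.all = TRUE,
          num.threads = 1)$predictions
}

inbag_matrix <- function(model) {
  matrix(unlist(model$forest$inbag.counts), nrow = nrow(model$data),
         ncol = model$n_trees)
}

# Forest-level OOB MSE for (possibly permuted) versions of the training
# covariates: each row is predicted by the trees for which it was out of bag.
oob_mse_for <- function(model, data_x, oob_mask = inbag_matrix(model) == 0) {
  preds <- tree_predictions(model, data_x)
  n_oob <- rowSums(oob_mask)
  oob_pred <- rowSums(preds * oob_mask) / n_oob
  keep <- n_oob > 0
  mean((model$data[[model$response]][keep] - oob_pred[keep])^2)
}

perm_pvalue <- function(observed, null) (1 + sum(null >= observed)) /
  (1 + length(null))

#' Permutation importance (%IncMSE) with one-sided significance
#'
#' `%IncMSE_j = 100 * (OOB MSE with predictor j permuted - baseline OOB MSE)
#' / baseline OOB MSE`, averaged over `n_perm` independent permutations, with
#' both MSEs computed at the forest level from out-of-bag predictions.
#' One-sided p-values come from a null distribution of the same statistic
#' under `n_null` forests refit to a permuted response (so the null carries
#' no predictor-response association), with the add-one rule
#' `p = (1 + #\{null >= observed\}) / (1 + n_null)`, which keeps p > 0.
#' p-values are not corrected for multiple comparisons.  The null draws are
#' retained in the `"null"` attribute.
#'
#' @param model a [fit_rf()] model.
#' @param n_perm permutations averaged per predictor (default 500).
#' @param seed permutation seed.
#' @param n_null null forests for the significance test; `0` (default)
#'   skips p-values.  The study-scale setting is `n_null = n_perm = 500`.
#' @param predictors predictors to evaluate (default: all training
#'   covariates); unknown names raise an error.
#' @return object of class `importance_result`: data frame `predictor`,
#'   `inc_mse`, `p_value`, ordered by decreasing `inc_mse`; attributes
#'   `baseline_mse`, `null` (matrix of null draws), `seed`.
#' @export
importance_incmse <- function(model, n_perm = 500, seed = 1, n_null = 0,
                              predictors = model$covariates) {
  stopifnot(inherits(model, "forest_model"), n_perm >= 1)
  unknown <- setdiff(predictors, model$covariates)
  if (length(unknown))
    stop("unknown predictor(s): ", paste(unknown, collapse = ", "))
  set.seed(seed)
  oob_mask <- inbag_matrix(model) == 0
  x <- model$data

  observed_for <- function(m, dat, mask) {
    base <- oob_mse_for(m, dat, mask)
    vapply(predictors, function(p) {
      incs <- vapply(seq_len(n_perm), function(b) {
        perm <- dat
        perm[[p]] <- sample(perm[[p]])
        100 * (oob_mse_for(m, perm, mask) - base) / base
      }, 0)
      mean(incs)
    }, 0)
  }

  baseline <- oob_mse_for(model, x, oob_mask)
  observed <- observed_for(model, x, oob_mask)

  null <- NULL
  pvals <- rep(NA_real_, length(predictors))
  if (n_null > 0) {
    null <- matrix(NA_real_, n_null, length(predictors),
                   dimnames = list(NULL, predictors))
    for (b in seq_len(n_null)) {
      yb <- sample(model$data[[model$response]])
      db <- model$data
      db[[model$response]] <- yb
      mb <- fit_rf(db, model$response, model$covariates,
                   n_trees = model$n_trees, seed = model$seed + b)
      null[b, ] <- observed_for(mb, mb$data, inbag_matrix(mb) == 0)
    }
    pvals <- vapply(seq_along(predictors), function(j)
      perm_pvalue(observed[j], null[, j]), 0)
  }

  tab <- data.frame(predictor = predictors, inc_mse = unname(observed),
                    p_value = pvals, stringsAsFactors = FALSE)
  tab <- tab[order(-tab$inc_mse), ]
  rownames(tab) <- NULL
  structure(tab, class = c("importance_result", "data.frame"),
            baseline_mse = baseline, null = null, seed = seed,
            n_perm = n_perm, n_null = n_null)
}

#' Partial-dependence curve of one predictor
#'
#' The marginal effect of a predictor on the forest prediction: at each grid
#' point g (an even grid spanning the 1st-99th percentiles of the training
#' values, trimming extrapolated tails), the curve value is the mean ensemble
#' prediction over all training rows with the predictor set to g.
#'
#' @param model a [fit_rf()] model.
#' @param predictor training covariate name.
#' @param n_grid number of grid points (>= 2).
#' @return object of class `pdp_curve`: data frame `value`, `yhat`;
#'   attribute `predictor`.
#' @export
partial_dependence <- function(model, predictor, n_grid = 100) {
  stopifnot(inherits(model, "forest_model"))
  if (!predictor %in% model$covariates)
    stop("unknown predictor: ", predictor)
  if (n_grid < 2) stop("n_grid must be at least 2")
  v <- model$data[[predictor]]
  q <- stats::quantile(v, c(0.01, 0.99), names = FALSE, type = 7)
  grid <- seq(q[1], q[2], length.out = n_grid)
  yhat <- vapply(grid, function(g) {
    d <- model$data
    d[[predictor]] <- g
    mean(predict(model$forest, data = d, num.threads = 1)$predictions)
  }, 0)
  structure(data.frame(value = grid, yhat = yhat),
            class = c("pdp_curve", "data.frame"), predictor = predictor)
}

#' Relative prediction uncertainty
#'
#' Per-cell ensemble SD expressed as a percentage of the global mean
#' prediction: `SD / global_mean * 100`.
#'
#' @param sd per-cell SD of the per-tree predictions.
#' @param global_mean global (masked) mean prediction.
#' @return numeric, percent.
#' @export
relative_uncertainty <- function(sd, global_mean) 100 * sd / global_mean

#' Predict over a covariate grid with per-cell uncertainty
#'
#' Applies the forest to every grid cell, streaming cells in fixed-size tiles
#' so memory stays bounded; outputs are independent of the tile size.  The
#' per-cell prediction is the ensemble mean over the trees; the per-cell SD
#' is the standard deviation of the per-tree predictions; relative
#' uncertainty normalizes that SD by the global (masked) mean prediction.
#' Nodata in any covariate propagates to all outputs.
#'
#' @param model a [fit_rf()] model.
#' @param grids a [covariate_grid()] containing a layer for every training
#'   covariate (a missing layer raises an error naming it).
#' @param tile_size cells per tile.
#' @return object of class `prediction_grid` (a [covariate_grid()] with
#'   layers `prediction`, `sd`, `rel_uncertainty`); attributes
#'   `global_mean`, `n_trees`.
#' @export
predict_grid <- function(model, grids, tile_size = 10000) {
  stopifnot(inherits(model, "forest_model"),
            inherits(grids, "covariate_grid"), tile_size >= 1)
  missing_layers <- setdiff(model$covariates, names(grids$layers))
  if (length(missing_layers))
    stop("missing covariate layer(s): ",
         paste(missing_layers, collapse = ", "))
  d <- grid_dim(grids)
  n_cells <- prod(d)
  cells <- as.data.frame(lapply(grids$layers[model$covariates], as.vector))
  valid <- which(stats::complete.cases(cells))
  pred <- sd <- rep(NA_real_, n_cells)
  for (start in seq(1, length(valid) + 1, by = tile_size)) {
    if (start > length(valid)) break
    idx <- valid[seq(start, min(start + tile_size - 1, length(valid)))]
    tp <- tree_predictions(model, cells[idx, , drop = FALSE])
    pred[idx] <- rowMeans(tp)
    sd[idx] <- sqrt(rowSums((tp - rowMeans(tp))^2) / (ncol(tp) - 1))
  }
  global_mean <- mean(pred[valid])
  rel <- relative_uncertainty(sd, global_mean)
  out <- covariate_grid(list(prediction = matrix(pred, d[1], d[2]),
                             sd = matrix(sd, d[1], d[2]),
                             rel_uncertainty = matrix(rel, d[1], d[2])),
                        grids$extent)
  class(out) <- c("prediction_grid", class(out))
  attr(out, "global_mean") <- global_mean
  attr(out, "n_trees") <- model$n_trees
  out
}

#' @export
print.prediction_grid <- function(x, ...) {
  d <- grid_dim(x)
  valid <- sum(!is.na(x$layers$prediction))
  cat(sprintf("prediction_grid: %d x %d cells (%d valid)\n",
              d[1], d[2], valid))
  cat(sprintf("  global mean prediction: %.4g\n", attr(x, "global_mean")))
  cat(sprintf("  mean relative uncertainty: %.2f%%\n",
              mean(x$layers$rel_uncertainty, na.rm = TRUE)))
  invisible(x)
}
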