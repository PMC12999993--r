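#' Candidate model specification
#'
#' A serializable spec wrapping a fit and a predict closure, used by the
#' Monte-Carlo cross-validation harness.  `fit(data, response)` receives the
#' training fold only, so any tuning or standardization a model performs
#' (inner cross-validation for the penalized models, for instance) never sees
#' validation rows.
#'
#' @param name short identifier.
#' @param fit function `(data, response) -> model`.
#' @param predict function `(model, newdata) -> numeric`.
#' @param hyper named list of hyperparameters, recorded for logging.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(name, fit, predict, hyper = list()) {
  stopifnot(is.character(name), is.function(fit), is.function(predict))
  structure(list(name = name, fit = fit, predict = predict, hyper = hyper),
            class = "model_spec")
}

predictor_names <- function(data, response) setdiff(names(data), response)

xy <- function(data, response) {
  list(x = as.matrix(data[predictor_names(data, response)]),
       y = data[[response]])
}

# ---- least-angle regression (LAR path + inner-CV step selection) ---------

# Classic equiangular LAR path on standardized predictors.  Returns the
# coefficient matrix (steps + 1 rows, original scale pieces kept separate)
# for prediction at any step.
lar_path <- function(x, y, max_steps = ncol(x)) {
  n <- nrow(x); p <- ncol(x)
  mx <- colMeans(x)
  xc <- sweep(x, 2, mx)
  nrm <- sqrt(colSums(xc^2))
  nrm[nrm == 0] <- 1
  xs <- sweep(xc, 2, nrm, "/")
  my <- mean(y)
  yc <- y - my
  beta <- matrix(0, max_steps + 1L, p)
  mu <- rep(0, n)
  active <- integer()
  for (k in seq_len(max_steps)) {
    cvec <- drop(crossprod(xs, yc - mu))
    inactive <- setdiff(seq_len(p), active)
    if (!length(inactive)) break
    cmax <- max(abs(cvec[inactive]))
    if (cmax < 1e-10) { beta[(k + 1L):(max_steps + 1L), ] <-
      matrix(beta[k, ], max_steps + 1L - k, p, byrow = TRUE); break }
    j <- inactive[which.max(abs(cvec[inactive]))]
    active <- c(active, j)
    s <- sign(cvec[active])
    xa <- sweep(xs[, active, drop = FALSE], 2, s, "*")
    g <- crossprod(xa)
    ginv1 <- tryCatch(solve(g, rep(1, length(active))),
                      error = function(e) NULL)
    if (is.null(ginv1)) { active <- active[-length(active)]
      beta[(k + 1L):(max_steps + 1L), ] <-
        matrix(beta[k, ], max_steps + 1L - k, p, byrow = TRUE); break }
    aa <- 1 / sqrt(sum(ginv1))
    w <- aa * ginv1
    u <- drop(xa %*% w)
    if (length(active) == p) {
      gamma <- cmax / aa
    } else {
      a <- drop(crossprod(xs, u))
      rest <- setdiff(seq_len(p), active)
      cand <- c((cmax - cvec[rest]) / (aa - a[rest]),
                (cmax + cvec[rest]) / (aa + a[rest]))
      cand <- cand[is.finite(cand) & cand > 1e-12]
      gamma <- if (length(cand)) min(cand) else cmax / aa
    }
    beta[k + 1L, ] <- beta[k, ]
    beta[k + 1L, active] <- beta[k + 1L, active] + gamma * w * s
    mu <- mu + gamma * u
  }
  list(beta = beta, mx = mx, nrm = nrm, my = my)
}

lar_predict_step <- function(path, x, step) {
  b <- path$beta[step + 1L, ] / path$nrm
  drop(sweep(x, 2, path$mx) %*% b) + path$my
}

lar_fit <- function(data, response, nfolds = 5) {
  d <- xy(data, response)
  p <- ncol(d$x)
  max_steps <- min(p, nrow(d$x) - 2L)
  folds <- sample(rep_len(seq_len(nfolds), nrow(d$x)))
  err <- matrix(NA_real_, nfolds, max_steps + 1L)
  for (f in seq_len(nfolds)) {
    tr <- folds != f
    pf <- lar_path(d$x[tr, , drop = FALSE], d$y[tr], max_steps)
    for (k in 0:max_steps) {
      pred <- lar_predict_step(pf, d$x[!tr, , drop = FALSE], k)
      err[f, k + 1L] <- mean((d$y[!tr] - pred)^2)
    }
  }
  best <- which.min(colMeans(err)) - 1L
  list(path = lar_path(d$x, d$y, max_steps), step = best,
       response = response)
}

# ---- rule-based model-tree ensemble (piecewise-linear, residual-boosted) --

model_tree_fit <- function(data, response, target, minsize = 20) {
  d <- data
  d$.target <- target
  d[[response]] <- NULL
  ctl <- tree::tree.control(nobs = nrow(d), mincut = max(5, minsize %/% 2),
                            minsize = minsize, mindev = 0.005)
  fit <- tree::tree(.target ~ ., data = d, control = ctl)
  leaf_of <- fit$where
  split_vars <- setdiff(as.character(fit$frame$var), "<leaf>")
  leaves <- lapply(split(seq_len(nrow(d)), leaf_of), function(rows) {
    if (length(split_vars) && length(rows) >= length(split_vars) + 5) {
      f <- stats::reformulate(split_vars, ".target")
      stats::lm(f, data = d[rows, , drop = FALSE])
    } else {
      mean(target[rows])
    }
  })
  list(tree = fit, leaves = leaves)
}

model_tree_predict <- function(model, newdata) {
  where <- predict(model$tree, newdata, type = "where")
  out <- rep(NA_real_, nrow(newdata))
  for (leaf in names(model$leaves)) {
    rows <- which(as.character(where) == leaf)
    if (!length(rows)) next
    lmod <- model$leaves[[leaf]]
    out[rows] <- if (is.numeric(lmod)) lmod else
      predict(lmod, newdata[rows, , drop = FALSE])
  }
  # rows routed to a leaf unseen at fit time fall back to the tree mean
  out[is.na(out)] <- predict(model$tree, newdata[is.na(out), ,
                                                 drop = FALSE])
  out
}

rule_ensemble_fit <- function(data, response, committees = 5, shrink = 0.5) {
  y <- data[[response]]
  members <- vector("list", committees)
  fitted <- rep(0, nrow(data))
  for (m in seq_len(committees)) {
    target <- if (m == 1) y else y - fitted
    members[[m]] <- model_tree_fit(data, response, target)
    pred <- model_tree_predict(members[[m]], data)
    fitted <- if (m == 1) pred else fitted + shrink * pred
  }
  list(members = members, shrink = shrink, response = response)
}

rule_ensemble_predict <- function(model, newdata) {
  out <- model_tree_predict(model$members[[1]], newdata)
  for (m in seq_along(model$members)[-1])
    out <- out + model$shrink * model_tree_predict(model$members[[m]],
                                                   newdata)
  out
}

# ---- the eight-model panel ------------------------------------------------

#' Default panel of eight candidate models
#'
#' Four linear specs (multiple linear regression, bidirectional AIC stepwise
#' regression, elastic net, least-angle regression) and four nonlinear specs
#' (rule-based model-tree ensemble, bagged trees, boosted trees, random
#' forest).  Penalty strength for the elastic net and the LAR step are tuned
#' by 5-fold cross-validation inside the training fold; tree ensembles use
#' `n_trees` learners, boosted trees depth-3 learners at learning rate 0.1.
#'
#' @param n_trees learners in the bagged-tree and random-forest ensembles.
#' @param n_rounds boosting rounds.
#' @param committees members of the rule-based ensemble.
#' @return named list of [model_spec()] objects.
#' @export
default_model_specs <- function(n_trees = 500, n_rounds = 500,
                                committees = 5) {
  list(
    mlr = model_spec(
      "mlr",
      fit = function(data, response)
        stats::lm(stats::reformulate(".", response), data = data),
      predict = function(model, newdata)
        unname(predict(model, newdata))),
    stepwise = model_spec(
      "stepwise",
      fit = function(data, response)
        stats::step(stats::lm(stats::reformulate(".", response),
                              data = data),
                    direction = "both", trace = 0),
      predict = function(model, newdata)
        unname(predict(model, newdata)),
      hyper = list(criterion = "AIC", direction = "both")),
    elastic_net = model_spec(
      "elastic_net",
      fit = function(data, response) {
        d <- xy(data, response)
        # explicit lambda path down to ~0 so a near-noiseless signal can
        # reach the unpenalized fit (glmnet's own path stops early)
        sx <- scale(d$x)
        lmax <- max(abs(crossprod(sx, d$y - mean(d$y)))) /
          (nrow(d$x) * 0.5)
        lambda <- lmax * 10^seq(0, -8, length.out = 100)
        fit <- glmnet::cv.glmnet(d$x, d$y, alpha = 0.5, nfolds = 5,
                                 lambda = lambda)
        list(fit = fit, response = response)
      },
      predict = function(model, newdata) {
        x <- as.matrix(newdata[predictor_names(newdata, model$response)])
        drop(predict(model$fit, newx = x, s = "lambda.min"))
      },
      hyper = list(alpha = 0.5, lambda = "5-fold CV")),
    lar = model_spec(
      "lar",
      fit = function(data, response) lar_fit(data, response),
      predict = function(model, newdata) {
        x <- as.matrix(newdata[predictor_names(newdata, model$response)])
        lar_predict_step(model$path, x, model$step)
      },
      hyper = list(step = "5-fold CV")),
    cubist = model_spec(
      "cubist",
      fit = function(data, response)
        rule_ensemble_fit(data, response, committees = committees),
      predict = rule_ensemble_predict,
      hyper = list(committees = committees)),
    bagged_tree = model_spec(
      "bagged_tree",
      fit = function(data, response) {
        f <- stats::reformulate(".", response)
        trees <- lapply(seq_len(n_trees), function(i) {
          rows <- sample(nrow(data), replace = TRUE)
          rpart::rpart(f, data = data[rows, , drop = FALSE],
                       control = rpart::rpart.control(cp = 0.005,
                                                      minbucket = 5))
        })
        list(trees = trees)
      },
      predict = function(model, newdata)
        rowMeans(sapply(model$trees, predict, newdata = newdata)),
      hyper = list(n_trees = n_trees)),
    boosted_tree = model_spec(
      "boosted_tree",
      fit = function(data, response) {
        d <- xy(data, response)
        fit <- xgboost::xgboost(data = d$x, label = d$y,
                                max_depth = 3, eta = 0.1,
                                nrounds = n_rounds, nthread = 1,
                                objective = "reg:squarederror", verbose = 0)
        list(fit = fit, response = response)
      },
      predict = function(model, newdata) {
        x <- as.matrix(newdata[predictor_names(newdata, model$response)])
        predict(model$fit, x)
      },
      hyper = list(max_depth = 3, eta = 0.1, n_rounds = n_rounds)),
    random_forest = model_spec(
      "random_forest",
      fit = function(data, response) {
        fit <- ranger::ranger(stats::reformulate(".", response),
                              data = data, num.trees = n_trees,
                              num.threads = 1)
        list(fit = fit)
      },
      predict = function(model, newdata)
        predict(model$fit, data = newdata,
                num.threads = 1)$predictions,
      hyper = list(n_trees = n_trees))
  )
}

#' Reproducible Monte-Carlo train/validation splits
#'
#' @param n number of rows.
#' @param n_iter number of resampling iterations.
#' @param train_frac fraction of rows in the training fold.
#' @param seed split seed; the same seed yields identical splits.
#' @return list of integer vectors of training-row indices.
#' @export
make_cv_splits <- function(n, n_iter = 100, train_frac = 0.8, seed = 1) {
  stopifnot(train_frac > 0, train_frac < 1, n >= 2)
  set.seed(seed)
  n_train <- round(train_frac * n)
  lapply(seq_len(n_iter), function(i) sort(sample.int(n, n_train)))
}

iter_seed <- function(seed, i) (seed %% 1000000L) + 7919L * i

#' Monte-Carlo cross-validation of one candidate model
#'
#' For each iteration the data are randomly partitioned into a training
#' fraction and a held-out validation fraction (default 80/20); the model is
#' fit on the training fold and scored on validation with
#' `R2 = 1 - SSE/SST` (SST about the validation-fold mean) and RMSE.  A fit
#' failure on an iteration is recorded, warned about and excluded from the
#' means.
#'
#' @param data complete-case data frame of response + predictors.
#' @param response response column name.
#' @param spec a [model_spec()].
#' @param n_iter iterations (default 100).
#' @param train_frac training fraction (default 0.8).
#' @param seed root seed for splits and per-iteration fit randomness.
#' @param splits optional precomputed splits ([make_cv_splits()]), shared
#'   across specs for paired comparison.
#' @return object of class `cv_result`: per-iteration `r2` and `rmse`,
#'   `mean_r2`, `mean_rmse`, `n_failed`, `seed`, `train_frac`.
#' @export
monte_carlo_cv <- function(data, response, spec, n_iter = 100,
                           train_frac = 0.8, seed = 1, splits = NULL) {
  stopifnot(inherits(spec, "model_spec"), response %in% names(data))
  data <- data[stats::complete.cases(data), , drop = FALSE]
  if (nrow(data) < 25) stop("need at least 25 complete rows")
  if (is.null(splits))
    splits <- make_cv_splits(nrow(data), n_iter, train_frac, seed)
  n_iter <- length(splits)
  r2 <- rmse <- rep(NA_real_, n_iter)
  failed <- rep(FALSE, n_iter)
  for (i in seq_len(n_iter)) {
    tr <- splits[[i]]
    train <- data[tr, , drop = FALSE]
    valid <- data[-tr, , drop = FALSE]
    set.seed(iter_seed(seed, i))
    pred <- tryCatch({
      model <- spec$fit(train, response)
      spec$predict(model, valid)
    }, error = function(e) e)
    if (inherits(pred, "error")) {
      failed[i] <- TRUE
      warning(sprintf("%s: iteration %d failed (%s)", spec$name, i,
                      conditionMessage(pred)))
      next
    }
    y <- valid[[response]]
    sse <- sum((y - pred)^2)
    sst <- sum((y - mean(y))^2)
    r2[i] <- 1 - sse / sst
    rmse[i] <- sqrt(mean((y - pred)^2))
  }
  structure(list(model = spec$name, r2 = r2, rmse = rmse, failed = failed,
                 mean_r2 = mean(r2[!failed]), mean_rmse = mean(rmse[!failed]),
                 n_failed = sum(failed), seed = seed,
                 train_frac = train_frac, hyper = spec$hyper),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Monte-Carlo CV: %s, %d iterations (%d failed)\n",
              x$model, length(x$r2), x$n_failed))
  cat(sprintf("  mean R2 = %.4f, mean RMSE = %.4g\n",
              x$mean_r2, x$mean_rmse))
  invisible(x)
}

#' Compare candidate models on identical Monte-Carlo splits
#'
#' Runs [monte_carlo_cv()] for every spec over one shared split sequence
#' (so the comparison is paired) and ranks by mean validation R2
#' (descending), breaking ties by mean RMSE (ascending).  A spec failing all
#' iterations is ranked last with a failure status.
#'
#' @inheritParams monte_carlo_cv
#' @param specs named list of [model_spec()] objects (>= 2).
#' @return list with `table` (the ranked summary data frame) and `results`
#'   (the per-spec `cv_result` objects).
#' @export
compare_models <- function(data, response, specs = default_model_specs(),
                           n_iter = 100, train_frac = 0.8, seed = 1) {
  stopifnot(length(specs) >= 2)
  data <- data[stats::complete.cases(data), , drop = FALSE]
  splits <- make_cv_splits(nrow(data), n_iter, train_frac, seed)
  results <- lapply(specs, function(spec)
    monte_carlo_cv(data, response, spec, seed = seed, splits = splits,
                   train_frac = train_frac))
  tab <- data.frame(
    model = vapply(results, `[[`, "", "model"),
    mean_r2 = vapply(results, `[[`, 0, "mean_r2"),
    mean_rmse = vapply(results, `[[`, 0, "mean_rmse"),
    n_failed = vapply(results, `[[`, 0L, "n_failed"),
    stringsAsFactors = FALSE)
  tab$status <- ifelse(tab$n_failed == length(splits), "all_failed", "ok")
  key <- ifelse(is.na(tab$mean_r2), -Inf, tab$mean_r2)
  tab <- tab[order(-key, tab$mean_rmse, na.last = TRUE), ]
  rownames(tab) <- NULL
  list(table = tab, results = results)
}
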