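#' Completeness screening of the enzyme set
#'
#' An observation enters efficiency estimation only if it carries all four
#' enzyme activities (BG, NAG, LAP, AP) together; rows failing the criterion
#' are excluded with a per-row reason.
#'
#' @param obs observation table.
#' @param required columns that must all be present and non-missing.
#' @return list with `retained` (the passing rows), `excluded` (the failing
#'   rows) and `log` (data frame `row`, `site_id`, `reason`).
#' @export
check_completeness <- function(obs,
                               required = c("bg", "nag", "lap", "ap")) {
  if (!is.data.frame(obs) || nrow(obs) == 0L)
    stop("empty observation table")
  missing_cols <- setdiff(required, names(obs))
  if (length(missing_cols))
    stop("observation table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  miss <- sapply(required, function(f) is.na(obs[[f]]))
  miss <- matrix(miss, nrow = nrow(obs))
  bad <- rowSums(miss) > 0
  reason <- apply(miss, 1, function(r)
    paste0("missing:", paste(required[r], collapse = ",")))
  log <- data.frame(row = which(bad),
                    site_id = if ("site_id" %in% names(obs))
                      obs$site_id[bad] else NA_character_,
                    reason = reason[bad],
                    stringsAsFactors = FALSE)
  list(retained = obs[!bad, , drop = FALSE],
       excluded = obs[bad, , drop = FALSE],
       log = log)
}

#' Interquartile-range outlier flagging
#'
#' Flags values outside `[Q1 - factor * IQR, Q3 + factor * IQR]`, with
#' quartiles by linear interpolation of order statistics (the type-7
#' convention, the dominant default).  Flagging only reports; exclusion is a
#' separate, explicit decision by the caller.
#'
#' @param values numeric vector (at least 4 finite values required for a
#'   meaningful fence; otherwise a warning is raised and nothing is flagged).
#' @param factor fence multiplier (default 1.5).
#' @return object of class `outlier_report`: `q1`, `q3`, `lower`, `upper`,
#'   logical `flags`, `n_flagged`, `status`.
#' @export
#' @examples
#' flag_outliers_iqr(c(1:10, 100))
flag_outliers_iqr <- function(values, factor = 1.5) {
  stopifnot(is.numeric(values), factor >= 0)
  finite <- is.finite(values)
  if (sum(finite) < 4L) {
    warning("fewer than 4 finite values; no outliers flagged")
    return(structure(list(q1 = NA_real_, q3 = NA_real_,
                          lower = NA_real_, upper = NA_real_,
                          factor = factor,
                          flags = rep(FALSE, length(values)),
                          n_flagged = 0L, status = "insufficient_data"),
                     class = "outlier_report"))
  }
  q <- stats::quantile(values[finite], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lower <- q[1] - factor * iqr
  upper <- q[2] + factor * iqr
  flags <- finite & (values < lower | values > upper)
  structure(list(q1 = q[1], q3 = q[2], lower = lower, upper = upper,
                 factor = factor, flags = flags,
                 n_flagged = sum(flags), status = "ok"),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("IQR outlier report (factor %g): %d flagged\n",
              x$factor, x$n_flagged))
  cat(sprintf("  Q1 = %g, Q3 = %g, fences [%g, %g]\n",
              x$q1, x$q3, x$lower, x$upper))
  invisible(x)
}

# VIFs of every column of a numeric matrix: diagonal of the inverse
# correlation matrix, with a per-column regression fallback when the
# correlation matrix is computationally singular (perfect collinearity ->
# infinite VIF).
vif_values <- function(x) {
  r <- stats::cor(x)
  inv <- tryCatch(solve(r), error = function(e) NULL)
  if (!is.null(inv) && all(diag(inv) > 0)) return(diag(inv))
  sapply(seq_len(ncol(x)), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    sse <- sum(fit$residuals^2)
    sst <- sum((x[, j] - mean(x[, j]))^2)
    r2 <- 1 - sse / sst
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  })
}

#' Iterative variance-inflation-factor screening
#'
#' Repeatedly removes the predictor with the largest VIF
#' (`VIF_j = 1 / (1 - R2_j)`, with `R2_j` from regressing predictor j on all
#' other retained predictors) until every retained predictor has VIF below
#' the threshold.  Perfectly collinear predictors carry infinite VIF and are
#' removed first; constant columns are dropped with a warning.  On equal
#' maximal VIFs the later column in schema order is removed, giving seed-free
#' determinism.
#'
#' @param predictors data frame (or matrix) of numeric predictors; rows with
#'   any missing value are dropped.
#' @param threshold retention threshold (default 5).
#' @return object of class `vif_report`: `removed` (data frame `variable`,
#'   `vif`, in removal order), `retained` (named vector of final VIFs),
#'   `threshold`, `n_rows`.
#' @export
#' @examples
#' x <- data.frame(a = rnorm(50), b = rnorm(50))
#' screen_vif(x)
screen_vif <- function(predictors, threshold = 5) {
  x <- as.matrix(as.data.frame(predictors))
  if (!is.numeric(x)) stop("predictors must be numeric")
  if (ncol(x) < 2L) stop("need at least 2 predictors")
  x <- x[stats::complete.cases(x), , drop = FALSE]
  removed <- data.frame(variable = character(), vif = numeric(),
                        stringsAsFactors = FALSE)
  constant <- apply(x, 2, function(v) stats::sd(v) == 0)
  if (any(constant)) {
    warning("constant column(s) removed: ",
            paste(colnames(x)[constant], collapse = ", "))
    removed <- rbind(removed,
                     data.frame(variable = colnames(x)[constant],
                                vif = NA_real_))
    x <- x[, !constant, drop = FALSE]
  }
  if (nrow(x) < ncol(x) + 2L)
    stop("need at least p + 2 complete rows for VIF screening")
  repeat {
    if (ncol(x) < 2L) {
      vifs <- stats::setNames(rep(1, ncol(x)), colnames(x))
      break
    }
    vifs <- stats::setNames(vif_values(x), colnames(x))
    if (max(vifs) < threshold) break
    # remove the largest VIF; ties go to the later column in schema order
    worst <- max(vifs)
    j <- max(which(vifs >= worst - 1e-10 | (is.infinite(vifs) &
                                              is.infinite(worst))))
    removed <- rbind(removed,
                     data.frame(variable = colnames(x)[j], vif = vifs[[j]]))
    x <- x[, -j, drop = FALSE]
  }
  structure(list(removed = removed, retained = vifs,
                 threshold = threshold, n_rows = nrow(x)),
            class = "vif_report")
}

#' @export
print.vif_report <- function(x, ...) {
  cat(sprintf("VIF screening (threshold %g): %d removed, %d retained\n",
              x$threshold, nrow(x$removed), length(x$retained)))
  if (nrow(x$removed)) {
    cat("  removal trace:\n")
    for (i in seq_len(nrow(x$removed)))
      cat(sprintf("    %s (VIF %.3g)\n", x$removed$variable[i],
                  x$removed$vif[i]))
  }
  cat("  retained:",
      paste(sprintf("%s=%.3g", names(x$retained), x$retained),
            collapse = ", "), "\n")
  invisible(x)
}
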