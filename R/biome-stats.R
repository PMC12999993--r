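#' Per-biome mean and standard deviation
#'
#' Arithmetic mean and sample SD of an efficiency per biome, the machine
#' analogue of a biome summary table.  Unclassified records (missing biome)
#' and missing values are excluded; empty biomes are omitted with a warning.
#'
#' @param values numeric efficiency values.
#' @param biomes biome labels, same length.
#' @return data frame `biome`, `n`, `mean`, `sd`, ordered by biome;
#'   attribute `global_mean` holds the mean over all included values.
#' @export
summarize_by_biome <- function(values, biomes) {
  stopifnot(length(values) == length(biomes))
  keep <- !is.na(values) & !is.na(biomes)
  all_biomes <- unique(as.character(biomes[!is.na(biomes)]))
  values <- values[keep]
  biomes <- as.character(biomes[keep])
  if (!length(values)) stop("no classified, non-missing values")
  dropped <- setdiff(all_biomes, biomes)
  if (length(dropped))
    warning("empty biome(s) omitted: ", paste(dropped, collapse = ", "))
  out <- do.call(rbind, lapply(split(values, biomes), function(v)
    data.frame(n = length(v), mean = mean(v), sd = stats::sd(v))))
  out <- data.frame(biome = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "global_mean") <- mean(values)
  out
}

# Compact letter display by insert-and-absorb: start from one letter shared
# by all groups; for each significantly different pair, split every letter
# column containing both; absorb columns that became subsets of others.
# Groups are processed in order of decreasing mean (ties alphabetically),
# so the lettering is deterministic.
compact_letters <- function(signif_pairs, groups) {
  # drop any column contained in (or duplicating) another
  absorb <- function(cols) {
    drop <- rep(FALSE, length(cols))
    for (i in seq_along(cols)) {
      for (j in seq_along(cols)) {
        if (i == j || drop[j]) next
        if (all(cols[[i]] %in% cols[[j]]) &&
            (length(cols[[i]]) < length(cols[[j]]) || j < i)) {
          drop[i] <- TRUE
          break
        }
      }
    }
    cols[!drop]
  }
  cols <- list(groups)
  for (k in seq_len(nrow(signif_pairs))) {
    a <- signif_pairs$a[k]; b <- signif_pairs$b[k]
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (a %in% col && b %in% col) {
        cols[[ci]] <- setdiff(col, a)
        cols[[length(cols) + 1L]] <- setdiff(col, b)
      }
    }
    cols <- absorb(cols)
  }
  # stable letter order: by the first (highest-mean) member of each column
  first <- vapply(cols, function(col) min(match(col, groups)), 0)
  cols <- cols[order(first)]
  vapply(groups, function(g) {
    paste(letters[which(vapply(cols, function(col) g %in% col, TRUE))],
          collapse = "")
  }, "")
}

#' One-way ANOVA with Tukey's post-hoc test across biomes
#'
#' Fits a one-way ANOVA of the efficiency on biome, runs Tukey's honestly
#' significant difference test on all pairwise contrasts, and assigns a
#' compact letter display so that biomes sharing a letter do not differ
#' significantly at `alpha` and biomes sharing no letter do.
#'
#' @param values numeric efficiency values.
#' @param biomes biome labels (>= 2 biomes with >= 2 values each).
#' @param alpha significance level (default 0.05).
#' @return object of class `biome_summary`: data frame `biome`, `n`,
#'   `mean`, `sd`, `letters`, ordered by decreasing mean; attributes
#'   `anova_f`, `anova_p`, `tukey` (pairwise data frame with `diff`, `lwr`,
#'   `upr`, `p_adj`), `alpha`.
#' @export
#' @examples
#' set.seed(1)
#' v <- c(rnorm(20, 0.6, 0.05), rnorm(20, 0.4, 0.05))
#' anova_tukey(v, rep(c("forest", "tundra"), each = 20))
anova_tukey <- function(values, biomes, alpha = 0.05) {
  keep <- !is.na(values) & !is.na(biomes)
  values <- values[keep]
  biomes <- factor(as.character(biomes[keep]))
  sizes <- table(biomes)
  if (length(sizes) < 2L) stop("need at least 2 biomes")
  if (any(sizes < 2L))
    stop("every biome needs at least 2 values; offending: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  d <- data.frame(y = values, g = biomes)
  fit <- stats::aov(y ~ g, data = d)
  ftab <- summary(fit)[[1]]
  tuk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  pair_names <- strsplit(rownames(tuk), "-", fixed = TRUE)
  tukey <- data.frame(a = vapply(pair_names, `[`, "", 1),
                      b = vapply(pair_names, `[`, "", 2),
                      diff = tuk[, "diff"], lwr = tuk[, "lwr"],
                      upr = tuk[, "upr"], p_adj = tuk[, "p adj"],
                      row.names = NULL, stringsAsFactors = FALSE)

  summ <- summarize_by_biome(values, biomes)
  gm <- attr(summ, "global_mean")
  # order groups by decreasing mean, ties alphabetically, for lettering
  ord <- order(-summ$mean, summ$biome)
  summ <- summ[ord, ]
  rownames(summ) <- NULL
  signif_pairs <- tukey[tukey$p_adj < alpha, c("a", "b")]
  summ$letters <- compact_letters(signif_pairs, summ$biome)

  structure(summ, class = c("biome_summary", "data.frame"),
            anova_f = ftab[["F value"]][1], anova_p = ftab[["Pr(>F)"]][1],
            tukey = tukey, alpha = alpha, global_mean = gm)
}

#' @export
print.biome_summary <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.3f, p = %.3g (alpha %g)\n",
              attr(x, "anova_f"), attr(x, "anova_p"), attr(x, "alpha")))
  print.data.frame(x)
  invisible(x)
}

#' Sample grid cells per biome for a biome-level summary
#'
#' Caps the number of cells per biome before ANOVA, since using all grid
#' cells makes every contrast significant.
#'
#' @param values per-cell values (vector).
#' @param biomes per-cell biome labels.
#' @param max_per_biome cap (default 10000).
#' @param seed sampling seed.
#' @return list with the sampled `values` and `biomes`.
#' @export
sample_cells_by_biome <- function(values, biomes, max_per_biome = 10000,
                                  seed = 1) {
  keep <- which(!is.na(values) & !is.na(biomes))
  set.seed(seed)
  idx <- unlist(lapply(split(keep, as.character(biomes[keep])), function(i) {
    if (length(i) > max_per_biome) sample(i, max_per_biome) else i
  }), use.names = FALSE)
  list(values = values[idx], biomes = biomes[idx])
}
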