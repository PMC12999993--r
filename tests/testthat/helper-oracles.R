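# Independent straight-line re-implementation of the efficiency model,
# one record at a time, kept deliberately separate from the package's
# vectorized code path.
oracle_efficiencies <- function(bg, nag, lap, ap, mbc, mbn, mbp,
                                soc, tn, tp, k = 0.5, emax = 1) {
  eea_nc <- (nag + lap) / bg
  eea_np <- (nag + lap) / ap
  eea_pc <- ap / bg
  eea_pn <- ap / (nag + lap)
  s_nc <- (1 / eea_nc) * ((mbn / mbc) / (tn / soc))
  s_np <- (1 / eea_np) * ((mbn / mbp) / (tn / tp))
  s_pc <- (1 / eea_pc) * ((mbp / mbc) / (tp / soc))
  s_pn <- (1 / eea_pn) * ((mbp / mbn) / (tp / tn))
  nue <- emax * ((s_nc * s_np) / ((s_nc + k) * (s_np + k)))^0.5
  pue <- emax * ((s_pc * s_pn) / ((s_pc + k) * (s_pn + k)))^0.5
  c(nue = nue, pue = pue)
}

# random valid observation records (all fields strictly positive)
random_records <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    bg = rlnorm(n, 4, 1), nag = rlnorm(n, 3, 1), lap = rlnorm(n, 3, 1),
    ap = rlnorm(n, 4, 1), mbc = rlnorm(n, 6, 1), mbn = rlnorm(n, 4, 1),
    mbp = rlnorm(n, 3, 1), soc = rlnorm(n, 3, 1), tn = rlnorm(n, 0.5, 1),
    tp = rlnorm(n, -0.5, 1)
  )
}

# Brute-force VIF: each predictor regressed on all the others with lm.
oracle_vifs <- function(x) {
  x <- as.data.frame(x)
  vapply(names(x), function(v) {
    fit <- lm(reformulate(setdiff(names(x), v), v), data = x)
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
}

# Brute-force iterative screening mirroring the documented rule: remove the
# largest VIF, ties to the later column, until all fall below the threshold.
oracle_screen <- function(x, threshold = 5) {
  x <- as.data.frame(x)
  repeat {
    if (ncol(x) < 2) return(setNames(rep(1, ncol(x)), names(x)))
    v <- oracle_vifs(x)
    if (max(v) < threshold) return(v)
    worst <- which(v >= max(v) - 1e-10)
    x[[names(x)[max(worst)]]] <- NULL
  }
}

# Tukey-Kramer adjusted p for one pair from the studentized range
# distribution, independent of stats::TukeyHSD.
oracle_tukey_p <- function(values, groups, a, b) {
  groups <- as.character(groups)
  k <- length(unique(groups))
  n <- length(values)
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  mse <- sum((values - gm[groups])^2) / (n - k)
  se <- sqrt(mse / 2 * (1 / gn[[a]] + 1 / gn[[b]]))
  q <- abs(gm[[a]] - gm[[b]]) / se
  ptukey(q, nmeans = k, df = n - k, lower.tail = FALSE)
}

# Small complete observation table used across tests.
complete_obs <- function(n = 10) {
  data.frame(
    site_id = sprintf("s%02d", seq_len(n)),
    bg = rep(100, n), nag = rep(50, n), lap = rep(30, n), ap = rep(160, n),
    mbc = rep(400, n), mbn = rep(40, n), mbp = rep(16, n),
    soc = rep(20, n), tn = rep(2, n), tp = rep(0.6, n)
  )
}
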