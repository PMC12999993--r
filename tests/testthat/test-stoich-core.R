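test_that("enzyme activity ratios match their definitions and flag failures", {
  r <- compute_eea_ratios(bg = 100, nag = 50, lap = 30, ap = 160)
  expect_equal(r$eea_nc, 0.8)
  expect_equal(r$eea_np, 0.5)
  expect_equal(r$eea_pc, 1.6)
  expect_equal(r$eea_pn, 2.0)
  expect_equal(r$eea_status, "ok")

  # identity case: NAG + LAP = BG = AP
  r <- compute_eea_ratios(bg = 80, nag = 50, lap = 30, ap = 80)
  expect_equal(unlist(r[1, 1:4]), c(eea_nc = 1, eea_np = 1,
                                    eea_pc = 1, eea_pn = 1))

  # ratio-system consistency on random activities
  set.seed(1)
  r <- compute_eea_ratios(rlnorm(50, 4), rlnorm(50, 3), rlnorm(50, 3),
                          rlnorm(50, 4))
  expect_equal(r$eea_pn, 1 / r$eea_np, tolerance = 1e-12)
  expect_equal(r$eea_pc, r$eea_nc * r$eea_pn, tolerance = 1e-12)

  # zero BG: the two ratios with BG in the denominator fail, the others hold
  r <- compute_eea_ratios(bg = 0, nag = 50, lap = 30, ap = 160)
  expect_true(is.na(r$eea_nc) && is.na(r$eea_pc))
  expect_equal(r$eea_np, 0.5)
  expect_equal(r$eea_pn, 2.0)
  expect_match(r$eea_status, "nonpositive_bg")

  # negative activity is coded, never thrown
  r <- compute_eea_ratios(bg = 100, nag = -5, lap = 30, ap = 160)
  expect_true(all(is.na(r[1, 1:4])))
  expect_match(r$eea_status, "negative_activity")
})

test_that("stoichiometric scalars follow the balance equations", {
  eea <- data.frame(eea_nc = 0.8, eea_np = 1, eea_pc = 1, eea_pn = 1,
                    eea_status = "ok")
  biomass <- data.frame(mbc = 100, mbn = 10, mbp = 10)
  nutrients <- data.frame(soc = 10, tn = 1, tp = 1)
  s <- compute_scalars(eea, biomass, nutrients)
  expect_equal(s$s_nc, 1.25)  # (1/0.8) * (0.1 / 0.1)

  # identity: unit EEA ratios and biomass ratios equal to substrate ratios
  eea1 <- data.frame(eea_nc = 1, eea_np = 1, eea_pc = 1, eea_pn = 1)
  b <- data.frame(mbc = 200, mbn = 20, mbp = 8)
  l <- data.frame(soc = 50, tn = 5, tp = 2)  # same elemental ratios as b
  s <- compute_scalars(eea1, b, l)
  expect_equal(unlist(s[1, 1:4]), c(s_nc = 1, s_np = 1, s_pc = 1, s_pn = 1))

  # s_nc decreases monotonically to 0 as the EEA ratio grows
  eeas <- data.frame(eea_nc = 10^(0:6), eea_np = 1, eea_pc = 1, eea_pn = 1)
  s <- compute_scalars(eeas, b[rep(1, 7), ], l[rep(1, 7), ])
  expect_true(all(diff(s$s_nc) < 0))
  expect_lt(s$s_nc[7], 1e-5)

  # nonpositive pool is coded per field
  s <- compute_scalars(eea1, data.frame(mbc = 100, mbn = 10, mbp = 0),
                       data.frame(soc = 10, tn = 1, tp = 1))
  expect_true(is.na(s$s_np) && is.na(s$s_pc) && is.na(s$s_pn))
  expect_match(s$s_status, "nonpositive_mbp")
})

test_that("efficiency formula reproduces its analytic values", {
  k <- model_constants()
  half <- data.frame(s_nc = 0.5, s_np = 0.5, s_pc = 0.5, s_pn = 0.5)
  expect_identical(compute_nue(half, k), 0.5)
  expect_identical(compute_pue(half, k), 0.5)

  zero <- data.frame(s_nc = 0, s_np = 3, s_pc = 0, s_pn = 3)
  expect_equal(compute_nue(zero, k), 0)

  s <- data.frame(s_nc = 1, s_np = 2, s_pc = 0.2, s_pn = 0.8)
  expect_equal(compute_nue(s, k), sqrt(2 / 3.75), tolerance = 1e-12)
  expect_equal(compute_pue(s, k), sqrt(0.16 / 0.91), tolerance = 1e-12)

  # saturation: efficiency approaches the maximum from below
  big <- data.frame(s_nc = 1e9, s_np = 1e9, s_pc = 1e9, s_pn = 1e9)
  expect_lt(compute_nue(big, k), 1)
  expect_gt(compute_nue(big, k), 1 - 1e-6)

  # symmetry: swapping the two scalar/constant pairs leaves NUE unchanged
  kc <- model_constants(k_nc = 0.2, k_np = 0.9)
  ks <- model_constants(k_nc = 0.9, k_np = 0.2)
  a <- compute_nue(data.frame(s_nc = 1.3, s_np = 0.4), kc)
  b <- compute_nue(data.frame(s_nc = 0.4, s_np = 1.3), ks)
  expect_equal(a, b, tolerance = 1e-15)

  # configurable maxima scale the output
  expect_equal(compute_pue(half, model_constants(pue_max = 0.8)), 0.4)
})

test_that("batch estimation agrees with the straight-line oracle", {
  obs <- random_records(1000, seed = 42)
  est <- estimate_efficiencies(obs)
  oracle <- t(mapply(oracle_efficiencies, obs$bg, obs$nag, obs$lap, obs$ap,
                     obs$mbc, obs$mbn, obs$mbp, obs$soc, obs$tn, obs$tp))
  expect_true(all(abs(est$nue - oracle[, "nue"]) < 1e-12))
  expect_true(all(abs(est$pue - oracle[, "pue"]) < 1e-12))
  expect_true(all(est$nue >= 0 & est$nue < 1))
  expect_true(all(est$pue >= 0 & est$pue < 1))
  expect_true(all(est$stoich_status == "ok"))
})

test_that("efficiencies are invariant to a common unit change per block", {
  obs <- random_records(50, seed = 7)
  base <- estimate_efficiencies(obs)
  scaled <- obs
  scaled[c("soc", "tn", "tp")] <- scaled[c("soc", "tn", "tp")] * 10
  expect_equal(estimate_efficiencies(scaled)$nue, base$nue,
               tolerance = 1e-12)
  scaled <- obs
  scaled[c("mbc", "mbn", "mbp")] <- scaled[c("mbc", "mbn", "mbp")] * 3.7
  expect_equal(estimate_efficiencies(scaled)$pue, base$pue,
               tolerance = 1e-12)
  scaled <- obs
  scaled[c("bg", "nag", "lap", "ap")] <- scaled[c("bg", "nag", "lap", "ap")] * 0.21
  expect_equal(estimate_efficiencies(scaled)$nue, base$nue,
               tolerance = 1e-12)
  # the percent declaration is the same as multiplying all pools by 10
  expect_equal(estimate_efficiencies(obs, soc_unit = "percent")$nue,
               base$nue, tolerance = 1e-12)
})

test_that("missing inputs silence exactly the efficiencies they feed", {
  obs <- complete_obs(4)
  obs$mbp[2] <- NA          # enters S_N:P, S_P:C, S_P:N -> both missing
  obs$ap[3] <- NA           # enters EEA_N:P and EEA_P:* -> both missing
  obs$mbc[4] <- -1          # coded, not thrown
  est <- estimate_efficiencies(obs)
  expect_false(anyNA(est[1, c("nue", "pue")]))
  expect_true(all(is.na(est[2, c("nue", "pue")])))
  expect_true(all(is.na(est[3, c("nue", "pue")])))
  expect_true(all(is.na(est[4, c("nue", "pue")])))
  expect_match(est$stoich_status[2], "missing_mbp")
  expect_match(est$stoich_status[3], "missing_activity")
  expect_match(est$stoich_status[4], "nonpositive_mbc")
  expect_error(estimate_efficiencies(obs[setdiff(names(obs), "bg")]),
               "lacks columns")
})
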