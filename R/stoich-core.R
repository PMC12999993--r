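#' Constants of the ecoenzymatic efficiency model
#'
#' The efficiency model is a double Michaelis-Menten form: each efficiency is
#' the geometric mean of two saturating terms in the stoichiometric scalars,
#' scaled by a theoretical maximum.  The maxima default to 1 (efficiency
#' cannot exceed 100 %) and every half-saturation constant defaults to 0.5,
#' the enzyme-activity ratio at which nutrient acquisition reaches half its
#' maximum potential.
#'
#' @param nue_max,pue_max theoretical maxima, dimensionless, in (0, 1].
#' @param k_nc,k_np,k_pc,k_pn half-saturation constants, dimensionless, > 0.
#' @return an object of class `model_constants`.
#' @export
#' @examples
#' model_constants()
model_constants <- function(nue_max = 1, pue_max = 1,
                            k_nc = 0.5, k_np = 0.5, k_pc = 0.5, k_pn = 0.5) {
  for (m in c(nue_max, pue_max)) {
    if (!is.numeric(m) || length(m) != 1L || is.na(m) || m <= 0 || m > 1)
      stop("efficiency maxima must be single values in (0, 1]")
  }
  for (k in c(k_nc, k_np, k_pc, k_pn)) {
    if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0)
      stop("half-saturation constants must be single positive values")
  }
  structure(list(nue_max = nue_max, pue_max = pue_max,
                 k_nc = k_nc, k_np = k_np, k_pc = k_pc, k_pn = k_pn),
            class = "model_constants")
}

#' @export
print.model_constants <- function(x, ...) {
  cat("Ecoenzymatic model constants\n")
  cat(sprintf("  NUE_max = %g, PUE_max = %g\n", x$nue_max, x$pue_max))
  cat(sprintf("  K(N:C) = %g, K(N:P) = %g, K(P:C) = %g, K(P:N) = %g\n",
              x$k_nc, x$k_np, x$k_pc, x$k_pn))
  invisible(x)
}

# Append a reason to a per-row status string ("ok" when clean).
add_status <- function(status, idx, reason) {
  hit <- which(idx)
  status[hit] <- ifelse(status[hit] == "ok", reason,
                        paste(status[hit], reason, sep = ";"))
  status
}

#' Enzyme activity ratios
#'
#' Computes the four acquisition-class activity ratios from the activities of
#' beta-glucosidase (BG, C acquisition), N-acetyl-glucosaminidase (NAG) plus
#' leucine-amino-peptidase (LAP) (N acquisition), and acid phosphatase
#' (AP, P acquisition):
#' `EEA_N:C = (NAG+LAP)/BG`, `EEA_N:P = (NAG+LAP)/AP`,
#' `EEA_P:C = AP/BG`, `EEA_P:N = AP/(NAG+LAP)`.
#'
#' Activities must be non-negative, and `BG`, `AP` and `NAG+LAP` must be
#' strictly positive for the ratios they enter.  Violations never raise in
#' batch mode: the affected ratios are returned as `NA` and the per-row
#' `eea_status` string records which ratio failed and why.
#'
#' @param bg,nag,lap,ap enzyme activities (nmol per g dry soil per h),
#'   vectors of a common length.
#' @return data frame with columns `eea_nc`, `eea_np`, `eea_pc`, `eea_pn`
#'   and `eea_status`.
#' @export
#' @examples
#' compute_eea_ratios(bg = 100, nag = 50, lap = 30, ap = 160)
compute_eea_ratios <- function(bg, nag, lap, ap) {
  n <- length(bg)
  stopifnot(length(nag) == n, length(lap) == n, length(ap) == n)
  status <- rep("ok", n)
  neg <- (!is.na(bg) & bg < 0) | (!is.na(nag) & nag < 0) |
    (!is.na(lap) & lap < 0) | (!is.na(ap) & ap < 0)
  status <- add_status(status, neg, "negative_activity")
  naglap <- nag + lap
  miss <- is.na(bg) | is.na(naglap) | is.na(ap)
  status <- add_status(status, miss & !neg, "missing_activity")

  ok <- !neg & !miss
  bad_bg     <- ok & bg <= 0
  bad_ap     <- ok & ap <= 0
  bad_naglap <- ok & naglap <= 0
  status <- add_status(status, bad_bg, "eea_nc,eea_pc:nonpositive_bg")
  status <- add_status(status, bad_ap, "eea_np:nonpositive_ap")
  status <- add_status(status, bad_naglap, "eea_nc,eea_pn:nonpositive_nag_lap")

  out <- data.frame(
    eea_nc = ifelse(ok & !bad_bg & !bad_naglap, naglap / bg, NA_real_),
    eea_np = ifelse(ok & !bad_ap & !bad_naglap, naglap / ap, NA_real_),
    eea_pc = ifelse(ok & !bad_bg & !bad_ap, ap / bg, NA_real_),
    eea_pn = ifelse(ok & !bad_naglap & !bad_ap, ap / naglap, NA_real_)
  )
  out$eea_status <- status
  out
}

#' Stoichiometric scalars
#'
#' The scalar S quantifies the balance between microbial biomass
#' stoichiometry (B, ratios of MBC/MBN/MBP) and substrate stoichiometry
#' (L, ratios of SOC/TN/TP), normalized by the corresponding enzyme-activity
#' ratio:
#' `S_N:C = (1/EEA_N:C) * (B_N:C / L_N:C)` and analogously for N:P, P:C and
#' P:N.  All biomass and nutrient pools must be strictly positive (they enter
#' denominators); invalid rows yield `NA` scalars with a coded `s_status`.
#'
#' @param eea data frame of enzyme-activity ratios as returned by
#'   [compute_eea_ratios()].
#' @param biomass data frame with columns `mbc`, `mbn`, `mbp`
#'   (mg per kg dry soil).
#' @param nutrients data frame with columns `soc`, `tn`, `tp` on one common
#'   mass basis (internally g per kg dry soil; only ratios enter the model).
#' @return data frame with columns `s_nc`, `s_np`, `s_pc`, `s_pn`, `s_status`.
#' @export
compute_scalars <- function(eea, biomass, nutrients) {
  n <- nrow(eea)
  stopifnot(nrow(biomass) == n, nrow(nutrients) == n)
  status <- rep("ok", n)
  for (f in c("mbc", "mbn", "mbp")) {
    bad <- !is.na(biomass[[f]]) & biomass[[f]] <= 0
    status <- add_status(status, bad, paste0("nonpositive_", f))
    biomass[[f]][bad] <- NA_real_
    status <- add_status(status, is.na(biomass[[f]]) & !bad,
                         paste0("missing_", f))
  }
  for (f in c("soc", "tn", "tp")) {
    bad <- !is.na(nutrients[[f]]) & nutrients[[f]] <= 0
    status <- add_status(status, bad, paste0("nonpositive_", f))
    nutrients[[f]][bad] <- NA_real_
    status <- add_status(status, is.na(nutrients[[f]]) & !bad,
                         paste0("missing_", f))
  }
  b_nc <- biomass$mbn / biomass$mbc
  b_np <- biomass$mbn / biomass$mbp
  b_pc <- biomass$mbp / biomass$mbc
  b_pn <- biomass$mbp / biomass$mbn
  l_nc <- nutrients$tn / nutrients$soc
  l_np <- nutrients$tn / nutrients$tp
  l_pc <- nutrients$tp / nutrients$soc
  l_pn <- nutrients$tp / nutrients$tn
  out <- data.frame(
    s_nc = (1 / eea$eea_nc) * (b_nc / l_nc),
    s_np = (1 / eea$eea_np) * (b_np / l_np),
    s_pc = (1 / eea$eea_pc) * (b_pc / l_pc),
    s_pn = (1 / eea$eea_pn) * (b_pn / l_pn)
  )
  out$s_status <- status
  out
}

saturating_pair <- function(s1, s2, k1, k2, smax) {
  v <- smax * sqrt((s1 * s2) / ((s1 + k1) * (s2 + k2)))
  v[!is.na(s1) & s1 < 0] <- NA_real_
  v[!is.na(s2) & s2 < 0] <- NA_real_
  v
}

#' Microbial nitrogen use efficiency
#'
#' `NUE = NUE_max * sqrt( (S_N:C * S_N:P) /
#' ((S_N:C + K_N:C) * (S_N:P + K_N:P)) )`, bounded in `[0, NUE_max)` for
#' finite non-negative scalars.
#'
#' @param s data frame of stoichiometric scalars ([compute_scalars()]).
#' @param constants a [model_constants()] object.
#' @return numeric vector of NUE values (`NA` where scalars are missing).
#' @export
compute_nue <- function(s, constants = model_constants()) {
  stopifnot(inherits(constants, "model_constants"))
  saturating_pair(s$s_nc, s$s_np, constants$k_nc, constants$k_np,
                  constants$nue_max)
}

#' Microbial phosphorus use efficiency
#'
#' `PUE = PUE_max * sqrt( (S_P:C * S_P:N) /
#' ((S_P:C + K_P:C) * (S_P:N + K_P:N)) )`, bounded in `[0, PUE_max)`.
#'
#' @inheritParams compute_nue
#' @return numeric vector of PUE values.
#' @export
compute_pue <- function(s, constants = model_constants()) {
  stopifnot(inherits(constants, "model_constants"))
  saturating_pair(s$s_pc, s$s_pn, constants$k_pc, constants$k_pn,
                  constants$pue_max)
}

#' Estimate NUE and PUE for a table of observations
#'
#' Chains [compute_eea_ratios()], [compute_scalars()], [compute_nue()] and
#' [compute_pue()] over an observation table.  An efficiency is produced for
#' a row if and only if all of its inputs are valid; no imputation happens
#' here (gap-filling is a separate, upstream step).  Bad records never raise
#' in batch mode; the `stoich_status` column records coded reasons.
#'
#' @param obs data frame with columns `bg`, `nag`, `lap`, `ap` (enzyme
#'   activities), `mbc`, `mbn`, `mbp` (microbial biomass, mg kg-1) and
#'   `soc`, `tn`, `tp` (nutrient pools).
#' @param constants a [model_constants()] object.
#' @param soc_unit basis of the nutrient pools: `"g_kg"` (default) leaves
#'   them untouched; `"percent"` multiplies all three by 10 to reach
#'   g per kg dry soil.  Only ratios enter the model, so any one consistent
#'   basis is acceptable.
#' @return `obs` augmented with the `eea_*` ratios, `s_*` scalars, `nue`,
#'   `pue` and `stoich_status` columns.
#' @export
#' @examples
#' obs <- data.frame(bg = 100, nag = 50, lap = 30, ap = 160,
#'                   mbc = 400, mbn = 40, mbp = 16,
#'                   soc = 20, tn = 2, tp = 0.6)
#' estimate_efficiencies(obs)[, c("nue", "pue", "stoich_status")]
estimate_efficiencies <- function(obs, constants = model_constants(),
                                  soc_unit = c("g_kg", "percent")) {
  soc_unit <- match.arg(soc_unit)
  need <- c("bg", "nag", "lap", "ap", "mbc", "mbn", "mbp", "soc", "tn", "tp")
  missing_cols <- setdiff(need, names(obs))
  if (length(missing_cols))
    stop("observation table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  nutrients <- obs[c("soc", "tn", "tp")]
  if (soc_unit == "percent")
    nutrients[] <- lapply(nutrients, function(v) v * 10)

  eea <- compute_eea_ratios(obs$bg, obs$nag, obs$lap, obs$ap)
  s <- compute_scalars(eea, obs[c("mbc", "mbn", "mbp")], nutrients)
  out <- obs
  out[c("eea_nc", "eea_np", "eea_pc", "eea_pn")] <-
    eea[c("eea_nc", "eea_np", "eea_pc", "eea_pn")]
  out[c("s_nc", "s_np", "s_pc", "s_pn")] <-
    s[c("s_nc", "s_np", "s_pc", "s_pn")]
  out$nue <- compute_nue(s, constants)
  out$pue <- compute_pue(s, constants)
  status <- ifelse(eea$eea_status == "ok", s$s_status,
                   ifelse(s$s_status == "ok", eea$eea_status,
                          paste(eea$eea_status, s$s_status, sep = ";")))
  out$stoich_status <- status
  out
}
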