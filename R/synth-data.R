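#' The eleven terrestrial biome categories
#'
#' Boreal, temperate and tropical/subtropical forests and grasslands, montane
#' grassland, tundra, wetland and cropland -- the classes used for stratified
#' generation and biome-level summaries.
#'
#' @return character vector of length 11.
#' @export
biome_levels <- function() {
  c("boreal_forest",
    "montane_grassland",
    "temperate_broadleaved_forest",
    "temperate_coniferous_forest",
    "temperate_grassland",
    "tropical_broadleaved_forest",
    "tropical_coniferous_forest",
    "tropical_grassland",
    "tundra",
    "cropland",
    "wetland")
}

# Per-biome location parameters.  soc_meanlog/soc_sdlog parameterize the
# log-normal SOC marginal (g kg-1); s_nc_gain scales the embedded SOC ->
# enzyme-allocation driver so that biome contrasts qualitatively follow the
# expected ordering (tropical forests high efficiency, tundra low);
# lat_center places sites in a plausible latitude band.
default_biome_params <- function() {
  data.frame(
    biome = biome_levels(),
    soc_meanlog = log(c(35, 25, 28, 30, 18, 28, 25, 15, 40, 12, 50)),
    soc_sdlog = 0.6,
    s_nc_gain = c(0.45, 0.62, 0.66, 0.66, 0.55, 0.85, 0.90, 0.75,
                  0.35, 0.62, 0.55),
    lat_center = c(58, 35, 45, 47, 42, 8, 15, 12, 70, 40, 30),
    stringsAsFactors = FALSE
  )
}

# Biome-mean table for the 11 non-SOC covariates, plus one shared SD per
# covariate; plausible field magnitudes, no claim of quantitative realism.
default_covariate_params <- function() {
  means <- rbind(
    boreal_forest                = c(0,  500,  450, 75, 0.60, 5.0, 35, 15, 18, 45,  80),
    montane_grassland            = c(3,  600,  700, 60, 0.45, 6.2, 40, 20, 20, 60,  60),
    temperate_broadleaved_forest = c(9,  900,  800, 70, 0.70, 5.8, 40, 22, 22, 55, 100),
    temperate_coniferous_forest  = c(7,  800,  750, 70, 0.65, 5.3, 35, 18, 20, 45,  90),
    temperate_grassland          = c(8,  450,  900, 55, 0.40, 6.8, 45, 25, 24, 75,  80),
    tropical_broadleaved_forest  = c(25, 2200, 1500, 80, 0.85, 4.8, 30, 35, 15, 35, 150),
    tropical_coniferous_forest   = c(22, 1500, 1400, 75, 0.80, 5.0, 32, 30, 16, 40, 130),
    tropical_grassland           = c(24, 1000, 1700, 60, 0.55, 6.0, 35, 28, 18, 60, 110),
    tundra                       = c(-8,  350,  300, 80, 0.30, 5.5, 40, 12, 15, 50,  40),
    cropland                     = c(12,  700,  950, 65, 0.50, 6.5, 42, 24, 22, 70, 100),
    wetland                      = c(12, 1100,  800, 80, 0.60, 6.0, 45, 25, 25, 55,  70)
  )
  colnames(means) <- c("mat", "map", "pet", "humidity", "ndvi", "ph",
                       "silt", "clay", "cec", "bsat", "depth")
  sds <- c(mat = 2.5, map = 150, pet = 150, humidity = 6, ndvi = 0.08,
           ph = 0.4, silt = 8, clay = 6, cec = 5, bsat = 10, depth = 25)
  lower <- c(mat = -20, map = 10, pet = 10, humidity = 5, ndvi = 0.01,
             ph = 3.5, silt = 1, clay = 1, cec = 1, bsat = 1, depth = 5)
  upper <- c(mat = 35, map = 4000, pet = 3000, humidity = 100, ndvi = 0.99,
             ph = 9, silt = 90, clay = 90, cec = 60, bsat = 100, depth = 300)
  list(means = means, sds = sds, lower = lower, upper = upper)
}

#' Configuration of the synthetic observation generator
#'
#' The generator draws strictly positive, right-skewed (log-normal) pools and
#' activities conditioned on biome, and embeds one known dominant driver: the
#' target stoichiometric scalar S_N:C follows a saturating function of SOC,
#' `S_N:C = gain * SOC / (SOC + soc_half) * noise`, implemented by scaling
#' the enzyme-allocation (EEA) ratios rather than by writing efficiencies
#' directly, so the full estimation chain is exercised.  The companion scalar
#' S_N:P is SOC-free (log-normal around `s_np_location`), which makes both
#' induced NUE and PUE rise then plateau with SOC while keeping PUE well
#' below NUE.
#'
#' @param n_per_biome observations per biome (11 biomes; the default yields
#'   2,002 rows).
#' @param seed integer; a fixed seed gives byte-identical output.
#' @param noise_sd log-scale SD of multiplicative measurement noise applied
#'   to every enzyme, biomass and nutrient channel after the latent
#'   efficiencies are fixed.
#' @param missingness named list of per-field missingness rates in `[0, 1]`,
#'   e.g. `list(ap = 0.1)`; applied after generation.
#' @param soc_half half-saturation (g kg-1) of the SOC driver.
#' @param s_np_location,s_np_sdlog,s_nc_sdlog scalar-noise parameters.
#' @param biome_params,covariate_params parameter tables; see
#'   `ecostoich:::default_biome_params`.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_per_biome = 182, seed = 1, noise_sd = 0.05,
                       missingness = list(), soc_half = 15,
                       s_np_location = 2, s_np_sdlog = 0.25,
                       s_nc_sdlog = 0.25,
                       biome_params = default_biome_params(),
                       covariate_params = default_covariate_params()) {
  if (!is.numeric(n_per_biome) || n_per_biome < 1)
    stop("invalid sim_config field: n_per_biome")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("invalid sim_config field: seed")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("invalid sim_config field: noise_sd")
  if (!is.list(missingness) ||
      (length(missingness) && (is.null(names(missingness)) ||
        any(unlist(missingness) < 0) || any(unlist(missingness) > 1))))
    stop("invalid sim_config field: missingness (rates must lie in [0, 1])")
  for (f in c("soc_half", "s_np_location", "s_np_sdlog", "s_nc_sdlog"))
    if (get(f) <= 0) stop("invalid sim_config field: ", f)
  if (any(biome_params$soc_sdlog <= 0) || any(biome_params$s_nc_gain <= 0))
    stop("invalid sim_config field: biome_params (scales must be positive)")
  structure(list(n_per_biome = as.integer(n_per_biome), seed = as.integer(seed),
                 noise_sd = noise_sd, missingness = missingness,
                 soc_half = soc_half, s_np_location = s_np_location,
                 s_np_sdlog = s_np_sdlog, s_nc_sdlog = s_nc_sdlog,
                 biome_params = biome_params,
                 covariate_params = covariate_params),
            class = "sim_config")
}

#' Generate a synthetic observation table with known ground truth
#'
#' Produces the full observation schema (coordinates, biome, the 12
#' environmental covariates, the four enzyme activities, microbial biomass
#' and nutrient pools) together with the latent per-row NUE/PUE and driver
#' description.  Enzyme activities are back-calculated from the target
#' scalars, so with zero measurement noise the stoichiometric estimator
#' recovers the latent efficiencies exactly.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `observations` (data frame) and `truth`
#'   (list: `nue_latent`, `pue_latent`, `s_nc`, `s_np`, `driver`, `link`).
#' @export
#' @examples
#' sim <- generate_observations(sim_config(n_per_biome = 5, seed = 42))
#' head(sim$observations)
generate_observations <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  bp <- cfg$biome_params
  cp <- cfg$covariate_params
  n <- cfg$n_per_biome * nrow(bp)
  biome <- rep(bp$biome, each = cfg$n_per_biome)
  bi <- rep(seq_len(nrow(bp)), each = cfg$n_per_biome)

  # coordinates: latitude band per biome, longitude uniform
  latitude <- stats::rnorm(n, bp$lat_center[bi], 5)
  latitude <- pmin(pmax(latitude, -89.9), 89.9)
  longitude <- stats::runif(n, -180, 180)

  # environmental covariates (normal around the biome mean, clamped to bounds)
  cov <- sapply(colnames(cp$means), function(v) {
    x <- stats::rnorm(n, cp$means[bi, v], cp$sds[[v]])
    pmin(pmax(x, cp$lower[[v]]), cp$upper[[v]])
  })
  cov <- as.data.frame(cov)

  # pools (log-normal, strictly positive)
  soc <- stats::rlnorm(n, bp$soc_meanlog[bi], bp$soc_sdlog[bi])
  tn <- soc * stats::rlnorm(n, log(0.08), 0.2)
  tp <- soc * stats::rlnorm(n, log(0.03), 0.3)
  mbc <- stats::rlnorm(n, log(400), 0.7)
  mbn <- mbc * stats::rlnorm(n, log(0.12), 0.15)
  mbp <- mbc * stats::rlnorm(n, log(0.04), 0.2)

  # embedded driver: saturating SOC -> S_N:C; S_N:P free of SOC
  f_soc <- soc / (soc + cfg$soc_half)
  s_nc <- bp$s_nc_gain[bi] * f_soc * stats::rlnorm(n, 0, cfg$s_nc_sdlog)
  s_np <- stats::rlnorm(n, log(cfg$s_np_location), cfg$s_np_sdlog)

  # latent efficiencies under the default constants (the ratio system forces
  # S_P:C = S_N:C / S_N:P and S_P:N = 1 / S_N:P)
  s_tab <- data.frame(s_nc = s_nc, s_np = s_np,
                      s_pc = s_nc / s_np, s_pn = 1 / s_np)
  constants <- model_constants()
  nue_latent <- compute_nue(s_tab, constants)
  pue_latent <- compute_pue(s_tab, constants)

  # back out enzyme activities that realize the target scalars
  eea_nc <- (1 / s_nc) * ((mbn / mbc) / (tn / soc))
  eea_np <- (1 / s_np) * ((mbn / mbp) / (tn / tp))
  bg <- stats::rlnorm(n, log(120), 0.8)
  naglap <- eea_nc * bg
  ap <- naglap / eea_np
  frac_nag <- stats::rbeta(n, 5, 5)
  nag <- frac_nag * naglap
  lap <- naglap - nag

  obs <- data.frame(site_id = sprintf("site_%04d", seq_len(n)),
                    latitude = latitude, longitude = longitude,
                    biome = biome, cov,
                    bg = bg, nag = nag, lap = lap, ap = ap,
                    mbc = mbc, mbn = mbn, mbp = mbp,
                    soc = soc, tn = tn, tp = tp,
                    stringsAsFactors = FALSE)

  # measurement noise, applied after the latent efficiencies are fixed
  noisy <- c("bg", "nag", "lap", "ap", "mbc", "mbn", "mbp",
             "soc", "tn", "tp")
  if (cfg$noise_sd > 0)
    for (f in noisy)
      obs[[f]] <- obs[[f]] * stats::rlnorm(n, 0, cfg$noise_sd)

  # declared missingness, applied last
  for (f in names(cfg$missingness)) {
    if (!f %in% names(obs))
      stop("invalid sim_config field: missingness (unknown field ", f, ")")
    rate <- cfg$missingness[[f]]
    if (rate > 0)
      obs[[f]][stats::runif(n) < rate] <- NA_real_
  }

  truth <- list(nue_latent = nue_latent, pue_latent = pue_latent,
                s_nc = s_nc, s_np = s_np,
                driver = "soc",
                link = list(type = "saturating",
                            soc_half = cfg$soc_half,
                            gain = stats::setNames(bp$s_nc_gain, bp$biome)))
  list(observations = obs, truth = truth)
}

# Smooth unit-variance random field: white noise run through a circular
# moving-average filter in both directions, twice.
smooth_field <- function(n_rows, n_cols, window) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  w <- rep(1 / window, window)
  for (pass in 1:2) {
    z <- apply(z, 2, function(col) stats::filter(col, w, circular = TRUE))
    z <- t(apply(z, 1, function(row) stats::filter(row, w, circular = TRUE)))
  }
  (z - mean(z)) / stats::sd(z)
}

#' Generate a synthetic covariate grid
#'
#' One aligned layer per covariate (the 11 environmental covariates plus
#' SOC) with smooth spatial autocorrelation (low-pass filtered noise), a
#' shared extent and an optional nodata mask.  Layer values are centred on
#' the biome-pooled means of the simulated observations and clamped to their
#' configured bounds, standing in for gridded global products at desk scale.
#'
#' @param cfg a [sim_config()] (supplies distributions and the seed).
#' @param n_rows,n_cols grid dimensions (positive).
#' @param extent `c(xmin, xmax, ymin, ymax)`, decimal degrees.
#' @param nodata_fraction fraction of cells masked to nodata in every layer.
#' @param seed grid seed (defaults to `cfg$seed`).
#' @return a [covariate_grid()] with layers
#'   `mat, map, pet, humidity, ndvi, ph, silt, clay, cec, bsat, depth, soc`.
#' @export
generate_covariate_grid <- function(cfg, n_rows = 60, n_cols = 60,
                                    extent = c(-10, 10, 35, 55),
                                    nodata_fraction = 0, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (n_rows < 1 || n_cols < 1) stop("grid dimensions must be positive")
  if (nodata_fraction < 0 || nodata_fraction > 1)
    stop("nodata_fraction must lie in [0, 1]")
  set.seed(seed)
  cp <- cfg$covariate_params
  window <- max(3L, round(min(n_rows, n_cols) / 8))
  layers <- list()
  for (v in colnames(cp$means)) {
    mu <- mean(cp$means[, v])
    sdv <- stats::sd(cp$means[, v]) + cp$sds[[v]]
    x <- mu + sdv * smooth_field(n_rows, n_cols, window)
    layers[[v]] <- pmin(pmax(x, cp$lower[[v]]), cp$upper[[v]])
  }
  soc_ml <- mean(cfg$biome_params$soc_meanlog)
  layers$soc <- exp(soc_ml + 0.6 * smooth_field(n_rows, n_cols, window))
  if (nodata_fraction > 0) {
    mask <- stats::runif(n_rows * n_cols) < nodata_fraction
    layers <- lapply(layers, function(m) { m[mask] <- NA_real_; m })
  }
  covariate_grid(layers, extent)
}
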