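---
title: "Estimating and upscaling soil microbial nutrient use efficiency from ecoenzymatic stoichiometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and upscaling soil microbial nutrient use efficiency from ecoenzymatic stoichiometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecostoich)
```

## The model

Soil microorganisms acquire carbon, nitrogen and phosphorus by producing
extracellular enzymes, and the relative investment across acquisition classes
carries information about how assimilated nutrients are partitioned between
biosynthesis and mineralization.  `ecostoich` estimates microbial nitrogen
and phosphorus use efficiency (NUE, PUE) from four enzyme activities --
β-glucosidase (BG, C acquisition), N-acetyl-glucosaminidase (NAG) and
leucine-amino-peptidase (LAP) (N acquisition), and acid phosphatase (AP, P
acquisition) -- together with microbial biomass pools (MBC, MBN, MBP) and
soil nutrient pools (SOC, TN, TP).

The enzyme-activity ratios are

$$\mathrm{EEA_{N:C}} = \frac{\mathrm{NAG+LAP}}{\mathrm{BG}},\quad
  \mathrm{EEA_{N:P}} = \frac{\mathrm{NAG+LAP}}{\mathrm{AP}},\quad
  \mathrm{EEA_{P:C}} = \frac{\mathrm{AP}}{\mathrm{BG}},\quad
  \mathrm{EEA_{P:N}} = \frac{\mathrm{AP}}{\mathrm{NAG+LAP}}.$$

Each stoichiometric scalar balances microbial biomass stoichiometry (B,
elemental ratios of the biomass pools) against substrate stoichiometry (L,
elemental ratios of the soil pools), normalized by the corresponding enzyme
ratio, e.g.

$$S_{\mathrm{N:C}} = \frac{1}{\mathrm{EEA_{N:C}}}
  \cdot \frac{B_{\mathrm{N:C}}}{L_{\mathrm{N:C}}},$$

and analogously for N:P, P:C and P:N.  Efficiencies follow a double
Michaelis--Menten form, the geometric mean of two saturating terms:

$$\mathrm{NUE} = \mathrm{NUE_{max}}
  \sqrt{\frac{S_{\mathrm{N:C}}\,S_{\mathrm{N:P}}}
  {(S_{\mathrm{N:C}}+K_{\mathrm{N:C}})(S_{\mathrm{N:P}}+K_{\mathrm{N:P}})}},
 \qquad
 \mathrm{PUE} = \mathrm{PUE_{max}}
  \sqrt{\frac{S_{\mathrm{P:C}}\,S_{\mathrm{P:N}}}
  {(S_{\mathrm{P:C}}+K_{\mathrm{P:C}})(S_{\mathrm{P:N}}+K_{\mathrm{P:N}})}}.$$

The maxima default to 1 (efficiency cannot exceed 100 %) and every
half-saturation constant K defaults to 0.5, the enzyme-activity ratio at
which acquisition reaches half its maximum potential; both are configurable
through `model_constants()` but these printed values are the standard
parameterization.  The form has convenient analytic anchors used throughout
the tests: efficiency is exactly `max/2` when each scalar equals its K,
strictly increasing in each scalar, bounded in `[0, max)`, symmetric under
exchange of the two scalar/constant pairs, and invariant to a common unit
change within the enzyme, biomass or nutrient block (only ratios enter).

Note one structural property of the ratio system: because
$\mathrm{EEA_{P:N}} = 1/\mathrm{EEA_{N:P}}$ and the B and L ratios obey the
same reciprocity, the four scalars carry only two degrees of freedom:
$S_{\mathrm{P:N}} = 1/S_{\mathrm{N:P}}$ and
$S_{\mathrm{P:C}} = S_{\mathrm{N:C}}/S_{\mathrm{N:P}}$.

```{r}
obs <- data.frame(bg = 100, nag = 50, lap = 30, ap = 160,
                  mbc = 400, mbn = 40, mbp = 16,
                  soc = 20, tn = 2, tp = 0.6)
estimate_efficiencies(obs)[, c("s_nc", "s_np", "nue", "pue")]
```

### Units and missing data

Pools are used on a common mass basis (internally g kg^-1^ dry soil; a
percent declaration multiplies all three nutrient pools by 10).  Since only
ratios enter, any single consistent basis is acceptable, but it must be
declared.  An efficiency is computed if and only if all of its inputs are
valid; invalid or missing inputs produce missing values with coded reasons
(`stoich_status`), never exceptions in batch mode, and no imputation happens
inside the estimator.  NUE and PUE validity is tracked per row and per
efficiency -- a record can support one and not the other -- which mirrors
survey compilations where the two efficiencies have different usable sample
sizes.

## Screening

Three screening rules are provided, matching common survey practice:

* **Completeness** (`check_completeness()`): a record enters estimation only
  if all four enzymes were reported together.
* **IQR outliers** (`flag_outliers_iqr()`): values outside
  `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` are flagged.  Quartiles use linear
  interpolation of order statistics (type 7) -- the dominant convention,
  declared here because the choice moves fences on small samples.  Flagging
  only reports; exclusion is a separate explicit step, since flagged survey
  values are reviewed rather than dropped blindly.  Whether the rule is
  applied to raw variables, computed efficiencies, or both is left to
  configuration (`iqr_targets`); the default screens the computed NUE/PUE.
* **VIF screening** (`screen_vif()`): predictors are removed iteratively,
  largest variance inflation factor first, until all retained VIFs fall
  below 5.  Ties remove the later column in schema order, which makes the
  trace deterministic without any seed.  Perfect collinearity is treated as
  infinite VIF and removed first; constant columns are dropped with a
  warning.

## Gap-filling and biome assignment

Missing covariates are filled by nearest-cell lookup (the value of the cell
containing the point, no interpolation) from aligned covariate layers, the
simplest defensible reading of coordinate-based extraction from gridded
products.  Measured values are never overwritten, per-field provenance is
recorded (`measured` / `gap_filled` / `missing`), and points over nodata or
outside the extent stay missing with a coded reason.  Cell membership is
half-open -- `[west, east)` in longitude, `(south, north]` in latitude -- so
boundary behaviour is exact and testable.

Biome classes come from three stacked sources (a cropland indicator, a
wetland indicator, and a vegetation map carrying the remaining nine of the
eleven biome categories).  Where several sources claim a cell the precedence
is cropland > wetland > vegetation; the source listing order is the only
guidance available, so that order was adopted and is stated here rather than
buried in code.

Because no georeferenced raster format is required at desk scale, grids are
carried by a light container (`covariate_grid()`) -- named matrices on one
WGS84 extent -- serialized as TSV matrices plus a YAML manifest that
round-trip exactly.

## Model comparison

`compare_models()` evaluates eight candidate regressions -- multiple linear
regression, bidirectional AIC stepwise regression, elastic net, least-angle
regression, a rule-based model-tree ensemble, bagged trees, boosted trees
and a random forest -- by repeated Monte-Carlo cross-validation: 100
iterations by default, each an independent random 80/20 train/validation
partition, scored on the validation fold by `R^2 = 1 - SSE/SST` (SST about
the validation-fold mean) and RMSE, and ranked by mean R² with RMSE breaking
ties.  All specs share one split sequence keyed by the seed, so the
comparison is paired.  No published hyperparameters exist for the panel, so
the defaults are conventional and logged: the elastic-net penalty and the
LAR step count are tuned by 5-fold cross-validation inside the training fold
(no leakage into validation), stepwise uses bidirectional AIC search, tree
ensembles use 500 learners, and boosted trees use depth-3 learners at
learning rate 0.1.  The least-angle regression path is implemented in the
package (the classic equiangular algorithm); the rule-based ensemble is a
regression-tree partition with linear models in the leaves and a
residual-boosted committee -- an equivalent of the commercial rule-based
learner in spirit, with no claim of exact parity.  Whether tuning should
happen per iteration or once globally is not externally specified; tuning
here happens per iteration, inside each training fold, which is the
leakage-safe choice.

## Random-forest upscaling

`fit_rf()` fits a 500-tree regression forest on the VIF-retained covariate
set (by default the 12 predictors MAP, MAT, PET, humidity, SOC, pH, silt,
clay, CEC, base saturation, depth, NDVI), keeping in-bag counts so per-tree
and out-of-bag (OOB) predictions stay retrievable.

**Permutation importance.**  `%IncMSE_j` is the relative increase in
forest-level OOB mean squared error when predictor *j* is permuted,
expressed in percent of the baseline OOB MSE and averaged over `n_perm`
permutations.  Implementations differ on whether this statistic is computed
per tree and averaged or at the forest level; the forest-level form is used
here and declared.  Significance uses one-sided permutation tests: the null
distribution refits the forest `n_null` times on a permuted response
(destroying every predictor-response association) and recomputes the same
averaged statistic, and `p = (1 + #\{null \ge observed\}) / (1 + n_null)` --
the add-one form, so p is never exactly zero.  p-values are deliberately not
corrected for multiple comparisons.  Using the same averaged statistic for
the observed value and for every null draw keeps the two exchangeable under
the null, which is what makes the p-value approximately uniform for an
uninformative predictor (a property the test suite checks).  Null draws are
retained on the result for audit.

**Partial dependence.**  The marginal effect of a predictor is the mean
ensemble prediction over the training rows with the predictor forced to each
point of an even grid spanning the 1st-99th percentiles of its training
values -- the range is trimmed because curves outside observed ranges are
extrapolation.

**Gridded prediction and uncertainty.**  `predict_grid()` applies the forest
to every cell of an aligned covariate grid, streaming cells in fixed-size
tiles so memory stays bounded (outputs are tile-size invariant, and tested to
be).  The per-cell prediction is the mean of the per-tree predictions (an
averaging forest, so it equals the ensemble prediction), the per-cell SD is
the standard deviation across the 500 trees, and relative uncertainty is
that SD divided by the global (masked) mean prediction, in percent.  Nodata
in any covariate propagates to all outputs.

## Biome summaries

`summarize_by_biome()` gives per-biome mean ± SD; `anova_tukey()` adds a
one-way ANOVA, Tukey's HSD on all pairwise contrasts (Tukey-Kramer for
unequal group sizes), and a compact letter display assigned by the standard
insert-and-absorb algorithm (groups processed in order of decreasing mean,
ties alphabetically) so that sharing a letter is equivalent to a
non-significant contrast at the chosen alpha.  When summaries are computed
from a prediction grid rather than observations, `sample_cells_by_biome()`
caps cells per biome (default 10,000, seeded) -- with *n* equal to all grid
cells every contrast becomes "significant", and the appropriate sampling
unit is genuinely ambiguous, so the cap is explicit and configurable.

## The synthetic generator and what it does (not) show

`generate_observations()` draws biome-conditioned observations for the
eleven biome categories with log-normal marginals for pools and enzyme
activities (strictly positive and right-skewed, as soil survey data are; no
distributional form is externally specified).  One known driver is embedded:
the target scalar $S_{\mathrm{N:C}}$ follows a saturating function of SOC,
$S_{\mathrm{N:C}} = a_b \cdot \mathrm{SOC}/(\mathrm{SOC} + 15) \cdot
\varepsilon$ with a per-biome gain $a_b$ and log-normal noise, while
$S_{\mathrm{N:P}}$ is SOC-free (log-normal around 2).  With the two degrees
of freedom of the ratio system this makes both induced NUE and PUE rise and
plateau with SOC while keeping PUE well below NUE, and the biome gains
order the induced efficiencies plausibly (tropical forests high, tundra
low) without any claim of quantitative realism.  Crucially, the driver is
implemented by scaling the enzyme-allocation ratios and back-calculating
activities -- not by writing efficiencies directly -- so the full estimation
chain is exercised: with zero measurement noise the estimator inverts the
generator to machine precision, a frozen test.  Measurement noise is
multiplicative log-normal per channel (default sdlog 0.05, a modest assay
error), applied after the latent efficiencies are fixed; missingness rates
are applied last.  The default size, 182 observations per biome (2,002
total), matches the scale of a global compilation.

`generate_covariate_grid()` produces aligned layers with smooth spatial
autocorrelation (low-pass filtered white noise rescaled to the configured
covariate distributions) and an optional nodata mask.

What passing tests on these data show: the estimator, screens, harness,
importance, uncertainty and summary machinery are correct, and the pipeline
recovers a known dominant driver and its saturating shape.  What they do not
show: anything about real-world covariance among covariates (the generator's
covariates are conditionally independent given biome), real spatial sampling
bias, or the true global magnitudes of NUE/PUE -- reproducing published
global maps would require the compiled field dataset and the external
gridded products, which are out of scope by design.

## Numerical choices and problem sizes

* Quantiles everywhere use type 7; VIF ties remove the later column; CLD
  ties process alphabetically.  All are documented determinism choices, not
  tuned values.
* All randomness hangs off explicit integer seeds; per-iteration fit seeds
  are derived from the root seed so paired comparisons and reruns are exact.
* Degenerate inputs (zero denominators, nonpositive pools, constant
  responses, all-nodata grids, < 4 finite values for fences) degrade to
  coded missing values or explicit errors, never silent numbers.
* The test suite and the acceptance script run the expensive stages at desk
  scale as the package's own verification sizes: driver-recovery uses 20
  seeded replicates of the full n = 2,002 generator with 500-tree forests
  and 3 importance permutations (ranking is insensitive to the permutation
  count; the averaged statistic at 500 permutations is the study-scale
  setting); p-value analytics use small forests with B = 500 and B = 30
  nulls; the acceptance script's cross-validation panel uses 20 iterations
  with 200-learner ensembles, while the final forest keeps 500 trees.

## Known limitations

* The stoichiometric estimator reflects enzymatic investment strategy, not
  isotopically measured assimilation; the two can disagree, and isotope
  methods are explicitly out of scope.
* The rule-based ensemble is an in-package equivalent, not the commercial
  algorithm; its CV ranking should be read accordingly.
* Gap-filling supports one NDVI layer per dataset; matching NDVI to each
  record's sampling year would need a per-record date that survey
  compilations often lack.
* Biome-source precedence (cropland > wetland > vegetation) follows listing
  order; no external ground truth for overlapping claims exists at desk
  scale.
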