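---
title: "Modelling nonresident seabird foraging distributions: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nonresident seabird foraging distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(foragedist)
```

This vignette is the package's own account of the science it implements:
the count models and their assumptions, the selection and validation
protocol, the spatial comparison statistic, the prioritization problem,
and — because several stages of this workflow are conventionally run in
GIS or commercial software whose internal settings are rarely written
down — the concrete numerical choices this implementation makes where the
workflow is usually left implicit.

## 1. The data the package expects (and emulates)

The unit of observation is a **3-km survey bin**: a segment of a strip
transect with a midpoint coordinate, a surveyed area (vessel-dependent
strip width of 100/200/300 m × 3 km, so 0.3/0.6/0.9 km²), a month and
year, per-species foraging counts, in-situ sea-surface temperature,
salinity and fluorescence, bathymetric and distance covariates, monthly
climate indices (NPGO, PDO, SOI, UI) and observation-condition
("detection") covariates. Counts are over-dispersed and zero-heavy: for
the most abundant species roughly one bin in six is non-zero; for the
rarest, one in forty.

`sim_config()` / `generate_survey_bins()` generate seeded synthetic
surveys with this structure. The defaults are the study conditions the
analysis assumes: 37 cruises spanning April–October over 2004–2013, 110
bins per cruise (≈ 4,070 bins), covariate means/SDs/ranges as in
`default_covariate_specs()`, and a ~4,700-cell 1-km² prediction grid.
Design choices worth knowing:

* **Geometry is planar Cartesian in kilometres.** Transects are parallel
  cross-shelf lines 10 km apart with bins every 3 km. Nothing in the
  protocol depends on a geographic projection at this spatial scale.
* **Covariates are truncated normals** (resample-until-in-range) matching
  their configured mean/SD/min/max — except depth, which follows a smooth
  cross-shelf profile (a shelf ramp to 200 m over the inner 85% of the
  offshore axis, then an exponential slope to ~2,076 m, with lognormal
  noise). The 200-m isobath therefore sits at a fixed offshore position
  and `dist_200m` is derived from the same geometry, giving the
  depth–distance collinearity the selection protocol has to cope with in
  real data. Its values are clipped to the configured envelope.
* **Climate series are stationary AR(1)** (default lag-1 autocorrelation
  0.5, configurable), location/scale-matched to each index and kept
  inside its range by innovation resampling; the series starts ≥ 3 months
  before the first cruise month so lags 0–3 always exist. The spatial
  covariance of the oceanographic fields is *not* asserted — the kriging
  functions expose the variogram instead.
* **What the generator does not emulate:** real cruise tracks and
  observer behaviour, real bathymetry, spatial autocorrelation in counts
  beyond what the shared covariates induce, and temporal autocorrelation
  within cruises. Passing tests therefore demonstrate that the protocol
  is implemented correctly and behaves as advertised *under its own
  assumptions*; they cannot certify performance on data violating them
  (e.g. strong residual spatial structure).

`generate_counts()` draws NB2 or ZINB counts from an explicit
`true_model()` with the `ln(area)` offset, so every simulation's truth is
visible in the test that uses it. Effect sizes used in the test suite are
chosen to be clearly detectable but not saturated (univariate z-scores
roughly 5–10 at the survey size), matching the moderate pseudo-R² regime
(≈ 0.08–0.26) typical of these data; saturated effects would make
monotone functional forms (log vs inverse-log) empirically
indistinguishable.

## 2. Engineered covariates

* **Contour index** = (max depth − min depth)/max depth per bin: a
  dimensionless, scale-invariant seafloor-complexity measure in [0, 1).
* **Climate lags**: `lag_series()` shifts monthly values with proper
  December→January rollover; lags 0–3 are attached as
  `<index>_lag<k>` columns.
* **Ordinary kriging** (`krige_surface()`): shipboard oceanographic
  fields are interpolated per cruise. The implementation solves the
  standard OK system (weights sum to one; with a zero nugget the surface
  honours the samples exactly) with an **exponential variogram fitted to
  the empirical semivariogram by weighted least squares** (weights = pair
  counts, bins up to half the maximum separation). "Detrending as
  necessary" is made explicit: a first-order polynomial trend is removed
  before kriging when its overall F-test has p < 0.05 (`detrend =
  "auto"`; `"never"`/`"always"` override). The kriging neighbourhood is
  global. Duplicate sample locations with conflicting values are an
  error; with identical values they collapse to one.
* **Surface quality filter** (`filter_surfaces()`): a cruise surface is
  rejected iff its mean kriging standard error lies more than 3 SD from
  the mean of all surfaces' mean standard errors — under a homogeneous
  batch this rejects < 1% of surfaces.
* **Gap-filling** (`fill_missing_tsg()`): missing underway (TSG) values
  are predicted from the nearest CTD cast within a **3-km radius** by OLS
  of TSG on CTD value controlling for month (linear) and year
  (categorical). Gaps with no CTD within the radius, or from a year
  absent from the calibration data, are flagged unfillable — never
  silently imputed.

## 3. Count models

`fit_nb()`/`fit_zinb()` return a `count_fit` with the classic modelling
methods. Parameterization is NB2 (variance μ + αμ²; α = 1/θ). Controls
are month + month² and year as indicator contrasts against the earliest
year; both are dropped automatically when the data span a single
month/year (degenerate designs would otherwise be rank-deficient). The
offset is `ln(area_km2)` and is never a removal candidate.

Numerical choices:

* **Pseudo-R² is McFadden's**, 1 − ℓ/ℓ₀, with a family-matched
  intercept + offset null (NB null for NB fits; intercept-only ZINB for
  ZINB fits). It is 0 for the intercept-only model and < 1 always.
* **Boundary LR test of α** uses the ½χ²₀ + ½χ²₁ mixture. When α̂ is at
  the boundary (< 10⁻⁷, including the fallback fit used when theta
  estimation diverges on equidispersed data) the statistic is 0 and
  p = 1. The NB log-likelihood entering the statistic is recomputed from
  per-observation densities: the packaged log-likelihood loses precision
  catastrophically at very large θ.
* **Vuong statistic** is the plain (uncorrected) √n·m̄/s(m); the p-value
  is one-sided in favour of ZINB, which is how the decision is used. Zero
  variance of m (identical likelihood vectors) is an error, not a 0/0.
* **Detection covariates enter only the inflation component** — they
  model failure to *see* birds, not bird abundance.
* **VIF** is 1/(1 − R²ⱼ) per design column; perfectly collinear columns
  report `Inf`.

## 4. The selection protocol

The two stages follow the survey protocol exactly; the points below are
where an implementation must commit:

* "Most significant" = **smallest p of the form's highest-order term**
  (the quadratic coefficient for quadratic forms). Ties break toward
  simpler forms (linear, log, inverse-log, quadratic) and shorter lags.
* **Inverse-log** is 1/ln(d + 1 km), log is ln(d + 1 km); the +1 km
  avoids singularities at near-zero distances (minimum observed distance
  0.02 km).
* Distance and climate candidates keep their best form only when its
  p < 0.20, the same keep threshold as the linear fallback — only
  covariates with some univariate support advance to the multivariable
  stage.
* **Backward stepwise** removes the worst non-significant term
  (quadratic pairs as a unit, judged by the quadratic term), then checks
  multicollinearity on **one linear-scale column per term**: raw v and v²
  are near-collinear by construction, so an expanded-design VIF would
  evict every quadratic pair regardless of the data; the per-term design
  asks the intended question (are distinct covariates redundant?). The
  generic `vif()` is still available for arbitrary designs.
* **Year interactions** (depth, 200-m isobath distance, SST, UI × year)
  are LR-tested one at a time against the main-effects model; all
  individually significant interactions enter jointly. Candidates not in
  the main-effects model are skipped.
* **Zero-inflation choice**: each detection covariate is tested singly in
  the ZINB inflation component; if the Vuong test prefers ZINB
  (one-sided p < 0.05) the final model is ZINB with all individually
  significant detection covariates, else NB.
* **Dominant climate index**: among retained basin-scale indices (NPGO,
  PDO, SOI), the one whose removal drops the log-likelihood most.
  Per-index log-likelihoods are not defined for a joint model, so the
  leave-one-out drop is the comparable quantity. Exact ties are reported
  as ties.

## 5. Validation

`kfold_validate()` implements 10-fold cross-validation repeated 20 times:
per fold, the model is refit on the training 90% and the held-out
pseudo-R² is 1 − ℓ_fit/ℓ_null with both log-likelihoods evaluated on the
held-out 10% (null = intercept + offset refit on the training split). The
decision statistic is the median over repeats of the median over folds.

The pass/fail decision is calibrated by permutation, a choice this
package makes explicit: the response is permuted (99 times by default),
each permuted dataset is cross-validated, and p is the proportion of
permuted statistics ≥ the observed one, compared against 0.05. Permuted
datasets are cross-validated with a **single repeat** — the null
statistic's location is what matters, and 20 repeats per permutation
would multiply the cost twenty-fold for no change in the decision.
Degenerate folds (all-zero training response, or held-out years unseen in
training) are skipped and counted.

## 6. Prediction, standardization, composites

Predictions are made at cell centroids with the reference offset
ln(1 km²); for ZINB the expected count is (1 − π)μ. Cells outside the
training envelope of any model covariate are flagged extrapolations.

Standardization is the z-score of log abundance, z = (log(x + 1) − μ)/σ,
with μ, σ the mean and **population** (n-denominator) SD over the
surface's own cells. Two choices are deliberate: log(x + 1) rather than
log(x), because predicted abundances below one would otherwise dominate
the scale with large negative logs; and the z-score itself rather than
its reciprocal — a reciprocal is undefined at the mean and would invert
the high-to-low mapping. Percent ranks use average ranks for ties,
rescaled to [0, 100]; the "highest-use" display mask is the upper 50%.

Composite maps average each species' standardized surfaces over its three
peak months (albatross May–July; fulmar/shearwaters June, July,
September; phalaropes July, September, October) and all years, then
average across species and percent-rank. Yearly maps average
*standardized* (not raw) predictions, so no species or year dominates by
population size.

Marginal-effect profiles set the focal covariate to a grid of values,
hold all other covariates at observed values, average the predicted
counts, and attach delta-method standard errors over the estimated
coefficients (count and inflation components).

## 7. The adapted Cramér–von Mises comparison

Two gridded distributions are first **log-normalized**:
pᵢ = log(xᵢ + 1)/Σlog(x + 1), removing the effect of population size
(deliberately not scale-invariant — doubling abundances changes p, and a
fixture test documents this). The statistic is

Ψ = Σᵢ (Γp₁ᵢ − Γp₂ᵢ)²,

where Γ is the cumulative sum of weights along a lexicographic sweep of
the grid. A one-dimensional sweep needs an origin and an axis, neither of
which should matter, so Ψ is averaged over **four corner sweeps that
alternate the primary axis** (y-ascending, y-descending, x-ascending,
x-descending). This keeps the two-cell worked example at Ψ = 1 under
every ordering, preserves Ψ = 0 ⇔ identical distributions, and makes the
statistic sensitive to separation along either grid axis — a single-axis
sweep is nearly blind to separation along its fast axis. Significance:
the second distribution's weights are permuted uniformly across cells
(1000 times by default) and p is the proportion of random Ψ ≥ observed Ψ
("≥", the conservative reading). `generate_mock_populations()` builds
pairs with an exact overlap coefficient Σ min(p₁, p₂) for power checks.

Note on magnitudes: raw Ψ on a ~2,500-cell grid with distributions spread
over many cells is far below 1 (cumulative differences are bounded by the
separated mass and shrink per cell); published per-study ranges for
"complete separation" depend on the grid and on any rescaling applied by
the original scripts, so this implementation reports raw Ψ and leaves any
rescaling to the caller.

## 8. Minimum-set prioritization

Planning units are the grid cells (uniform cost 1 by default — no
published per-cell cost exists for this workflow); the feature amount of
a cell for a species is its standardized abundance shifted to be
nonnegative (continuous habitat quality; a binary top-50% encoding can be
emulated by passing thresholded surfaces). Targets are scenario fractions
(10/30/50%) of each feature's total. The objective is

cost(selected) + BLM × exterior boundary length + Σⱼ spfⱼ · Bⱼ ·
shortfallⱼ/targetⱼ,

with boundary length counted as exposed 1-km edges (shared edges with
unselected cells plus grid-boundary edges), BLM default 10, and spf by
IUCN status (LC 1, NT 2, VU 3 — `iucn_spf()`). The shortfall base penalty
B is the cost of a greedy target-covering set, computed once per problem,
so penalties are on the cost scale and spf acts as a priority weight.

The solver is single-cell-flip simulated annealing: initial temperature =
SD of objective deltas over 1,000 random flips, 10⁵ flips by default with
geometric cooling ×0.999 every 100 flips, followed by greedy descent to a
single-flip local optimum (so the reported objective is monotone in the
polish phase and recomputable from the solution's components). Infeasible
targets error before search. `selection_frequency()` repeats the
optimization (100 runs by default) with independent sub-seeds and
percent-ranks the per-cell inclusion counts; the upper 50% is the
priority mask.

## 9. Problem sizes used by the test suite

The statistical checks run at the sizes their claims are about: parameter
recovery and the noise-covariate screening rate at the full survey size
(n = 4,073 and n = 4,070 bins; the screening null rate is within a few
percent of its analytic value only once the Wald tests are in their
asymptotic regime), CVM power on the 50 × 50 grid with 1,000
randomizations, and the remaining protocol simulations on surveys of
1,000–2,000 bins with 100 replicates, where their behaviour is
n-independent. Cross-validation checks use 350-bin surveys with 39
permutations (decision granularity 1/40 < 0.05), and the reserve oracle
compares against exhaustive enumeration on 8-cell instances over 100
seeds. Annealing step counts in tests (2,000–4,000 flips) are scaled to
those instance sizes; the package default (10⁵) is sized for the full
grid.

## 10. Known limitations

* No spatial or temporal autocorrelation structure in the count models
  (none is fitted in this protocol); standard errors on real transect
  data are accordingly optimistic.
* The kriging is global ordinary kriging with an exponential variogram;
  anisotropy and alternative variogram families are out of scope.
* The Vuong test is the uncorrected statistic; with many inflation
  parameters it is known to drift liberal, which is why the protocol
  tests detection covariates singly before the joint decision.
* The annealer guarantees a single-flip local optimum, not the global
  one; the brute-force oracle bounds its behaviour only at small sizes.
* Percent-rank maps are relative within a surface; they do not compare
  absolute abundance across species or scenarios.
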