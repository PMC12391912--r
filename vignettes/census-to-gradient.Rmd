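---
title: "From block censuses to diversity and biomass gradients: the models behind divgrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From block censuses to diversity and biomass gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divgrad)
```

`divgrad` analyses fine-scale ungulate censuses collected on a grid of 1-km
blocks, each divided into nine 333-m sub-blocks, straddling the boundary
between a protected savanna reserve and adjacent pastoral land. Two census
years with contrasting rainfall (a drought year and a normal year) are
compared. The questions the pipeline answers are where, along the signed
distance to the reserve boundary, ungulate *diversity* and *biomass* peak,
how the peaks differ between years, and which of the many correlated human-use
and resource covariates predict them consistently. This vignette explains
each model in the chain, its assumptions, and the numerical choices made
where the design was genuinely open. It states no empirical result that the
package's tests and `scripts/acceptance.R` do not themselves compute.

## The synthetic census generator

Field censuses at this scale are one-off efforts, so every stage of the
pipeline is developed and verified against a generator
(`simulate_landscape()`) that reproduces the statistical structure such data
have:

* **Geometry.** An `nx` by `ny` grid of 1-km blocks, nine sub-blocks each;
  a boundary column separates the reserve (negative signed distance) from
  pastoral land (positive). Coordinates are in metres, distances in
  kilometres.
* **Community.** A 19-species pool with geometric rank abundance
  (`geometric_rank_abundance()`, shape 0.4), so the two migratory grazers
  (wildebeest and zebra) jointly carry about two thirds of the individuals.
  Near the configured *diversity peak* (+5 km by default, width 4 km) the
  rank-abundance exponent is flattened (strength 0.6), producing a local
  maximum in evenness and hence in the effective number of species.
* **Abundance surface.** Total intensity is a Gaussian bump over distance
  (*biomass peak*, default -15 km, width 6 km) on a baseline of 0.25,
  multiplied by mean-one log-normal block heterogeneity (sd 0.4 on the log
  scale) and by a per-year multiplier (0.5 in the drought year).
* **Zeros.** Sub-block counts are Poisson given the local intensity, with
  two calibrated mechanisms controlling the fraction of empty sub-blocks:
  a global abundance scale found by root finding, and *mean-preserving
  structural zeros* (a sub-block is emptied with probability `s` while
  occupied sub-blocks carry intensity inflated by `1/(1-s)`). The defaults
  target zero fractions of 0.73 (drought) and 0.63 (normal). Because the
  structural zeros preserve expected counts, the year-over-year abundance
  ratio remains exactly the configured multiplier -- both calibration
  targets hold at once.
* **Abundance scale.** The minimal abundance meeting the zero targets
  spreads animals so thinly (a few per block off-peak) that observed
  diversity would measure sampling depth, not the community. The default
  `abundance_scale = 6` keeps the zero fractions on target while
  concentrating more animals in occupied sub-blocks, the clumping typical
  of herding ungulates; per-block samples are then deep enough that the
  evenness signal is observable. This is a fixed property of the default
  study conditions, not a tuning knob.
* **Covariates and flags.** Eighteen metric covariates (vegetation cover,
  height and colour for grass, shrub and tree layers; three rainfall
  components; distances to water, settlements, infrastructure; elevation
  and slope) are drawn from Gaussian random fields with exponential spatial
  correlation (ranges 3-20 km) plus local noise, clamped to their valid
  ranges. Vegetation attributes follow the field protocol's planned
  missingness: grass plots in three of the nine sub-blocks, shrub and tree
  attributes in the centre sub-block only. Six binary presence flags
  (fire, sheep/goats, cattle, carnivores, vehicles, litter) have logistic
  probabilities linear in boundary distance.

What the generator does *not* emulate: detection error correlated with
vegetation (counts are exact given presence), livestock counts as community
members, rainfall rasters, irregular block geometry, and temporal dynamics
within a census. Passing tests on synthetic grids therefore demonstrates
that the estimators recover what they are defined to recover under known
conditions -- not that any particular field inference is correct. The
"observations that are zeros" are sub-blocks without *wild* ungulates;
livestock appear only as covariates.

## Imputing unsampled vegetation: ordinary kriging

Vegetation attributes are observed on a sub-sample of sub-blocks.
`impute_covariates()` fills the rest, per covariate and census year, by
ordinary kriging: an empirical semivariogram (12 equal lag bins up to half
the bounding-box diagonal) is fitted by weighted least squares (weights =
pair counts) over spherical, exponential and Gaussian candidates, taking
the family with the smallest weighted residual; predictions solve the
ordinary-kriging system, whose unbiasedness constraint forces the weights
to sum to one. Numerical choices: neighbourhoods are all points within
twice the fitted range capped at the nearest 32 (64 in the generic
`krige()`), duplicate sites are averaged, non-convergent fits fall back to
a pure nugget with a warning, bounded covariates are clamped to their valid
range after prediction, and the empirical variogram deterministically
subsamples to at most 2000 points before pairing. Observed values are never
modified; a provenance column records `observed` versus `imputed`.

## Block aggregation with the missing-sub-block correction

Blocks at the study-area edge or containing impassable ground hold fewer
than nine censused sub-blocks. Summing raw counts would bias those blocks
low, so the expected block total for species $u$ in block $i$ is

$$c_{ui} = \sum_j^{Q_i} d_{uij} \times \frac{9}{Q_i},$$

with $Q_i$ the number of censused sub-blocks and $d_{uij}$ the sub-block
counts (`expected_block_total()`). The totals are kept as reals: they are
integers exactly when $Q_i = 9$. Metric covariates are averaged over
non-missing sub-blocks (after imputation where configured), presence flags
are OR-ed, and the signed boundary distance is averaged.

## Diversity: Hill numbers with jackknife bias adjustment

Diversity of order $q$ is the effective species number
$^qD = (\sum_u p_u^q)^{1/(1-q)}$, with the limit
$\exp(-\sum p_u \log p_u)$ at $q = 1$; order 0 is richness, order 2 the
reciprocal Simpson index, order 10 weighs evenness heavily, and order
$\infty$ is the reciprocal Berger-Parker index $1/\max p_u$, which is
undefined when several species tie for top abundance and is reported with
a tie marker in that case.

Raw richness undercounts species hidden in tall grass or shrub, so order-0
diversity is bias-adjusted with the jackknife family
(`jackknife_richness()`): the order-$k$ estimator is a linear combination
of the frequencies $f_i$ of species observed $i$ times. The package derives
the coefficients exactly from the generalized leave-$j$-out construction --
the order-$k$ estimator is $\sum_{j=0}^k (-1)^j \binom{k}{j} (n-j)^k / k!$
times the expected richness of an $(n-j)$-subsample, and a species observed
$i$ times survives subsampling with a hypergeometric probability. The
alternating sum is expanded in exact integer polynomial arithmetic before
evaluation, which is numerically stable at any sample size (the naive sum
loses about 18 digits at $n = 10^4$, $k = 5$). The order is chosen by the
sequential testing procedure of the jackknife literature at $\alpha = 0.05$
(two-sided): starting at order 0, each transition is tested with a normal
statistic whose variance is estimated from the frequency counts; the first
non-significant transition stops the cascade. Degenerate zero-variance
transitions count as significant exactly when the estimate difference is
positive. The final estimate interpolates between the stopped order $m$ and
$m+1$ with weight $T_m / z_{crit}$, which makes it continuous in the data;
orders are capped at 5 and at the largest observed frequency class, and the
estimate never drops below observed richness. Because the estimators need
integer frequencies while expected block totals are real, totals are
rounded half-up (never below 1 for an observed species) for the jackknife
only; relative abundances always use the unrounded values.

For the positive orders the unseen-species complement is unveiled: observed
proportions are scaled by the Turing sample coverage $1 - f_1/n$ and the
remaining mass is shared equally by the $^0D - S$ estimated unseen species
(fractional multiplicity allowed). With no singletons the adjustment is
inactive and every order reduces to the raw Hill number; with coverage zero
(every species a singleton) the sample carries no information about the
unseen mass and the adjustment is skipped. The adjusted profile is a
genuine Hill profile of a proper distribution, hence nonincreasing in $q$.

Biomass is the unit-weight sum $\sum_u c_{ui} w_u$, split into migratory
(wildebeest, zebra) and nonmigratory components. The unit masses ship as an
editable CSV (`species_attributes()`) with literature-typical values; no
mass is hard-coded in logic.

## Distributional regression by component-wise boosting

Responses with different supports get different two- or three-parameter
families (`response_spec()`):

| response | support | family | links |
|---|---|---|---|
| raw richness | 0, 1, 2, ... | negative binomial (mean-dispersion) | log, log |
| bias-adjusted richness | 1, 2, ... | zero-truncated negative binomial | log, log |
| diversity orders 1, 2, 10 | $[1, \infty)$ | shifted zero-adjusted gamma (shift 1) | log, log, logit |
| biomass (all / migratory / nonmigratory) | $[0, \infty)$ | zero-adjusted gamma (shift 0) | log, log, logit |

Diversity values of one (a single effective species) map to the point mass
at zero after the shift; observed ones make up roughly a fifth of blocks in
the normal year of the default scenario. The zero-adjusted gamma is a
hurdle-type mixture: mass $\nu$ at zero and, with probability $1-\nu$, a
gamma with mean $\mu$ and coefficient of variation $\sigma$. All
log-likelihoods and their per-parameter gradients on the link scale are
analytic and are verified against finite differences and normalization in
the test suite.

`boost_fit()` implements non-cyclical component-wise functional gradient
descent: per iteration the gradient of the log-likelihood with respect to
each linked predictor is the working response; every candidate base learner
is fitted to its parameter's gradient by (penalized) least squares; the one
(parameter, learner) pair whose tentative step most reduces the empirical
risk is updated by `step` times its fit. Numerical choices:

* P-spline learners: 20 interior knots, cubic basis, second-order
  difference penalty, penalized to 4 effective degrees of freedom (the
  penalty weight is found by root finding on the smoother trace); linear
  learners (used for binary flags) are unpenalized. Out-of-range
  prediction clamps to the training range of the predictor.
* Step length 0.1; offsets are the unconditional maximum-likelihood
  intercepts; the scale parameter gets only an intercept learner by
  default, since it is a nuisance parameter for prediction (this is
  configurable via `param_learners`).
* Variable coefficients: with `grouping` (typically land use and census
  year), each predictor gets one learner per group cell, fitted on that
  cell's rows only -- effects are estimated separately by cell and
  selection frequencies are per cell.
* Ties in risk reduction resolve to the lowest learner index; if no step
  reduces the risk even after halving the step 30 times, the iteration
  records a null update, so the training risk is nonincreasing *by
  construction* (and asserted in the tests).

Early stopping (`cv_tune()`) repeats stratified 80/20 subsampling, replays
the boosting path on each held-out part, and selects `mstop` as the argmin
of the mean held-out negative log-likelihood, iteration 0 (the offset
model) included. Subsamples that lose an entire learner cell are redrawn.
One caveat discovered while validating: because the resamples come from a
single fixed dataset, sample-wide spurious correlations are shared between
the training and held-out halves, so on pure noise the held-out curve is
nearly flat and its argmin is only *typically* (not always) near zero; the
tests assert the median-and-negligible-gain form of that statement.

## Stability selection

`stabsel_boost()` ranks predictors by how reproducibly boosting selects
them: complementary-pairs subsampling (default 50 half-samples) runs the
algorithm on each half until `q_sel` distinct learners have entered the
model; a learner is *stable* if its selection frequency on the location or
zero-part parameter reaches the threshold (default 0.7 -- a closed
threshold, 0.69 is out). Scale-parameter frequencies are reported but never
confer stability. The analytic bound on the expected number of falsely
stable learners, $\mathrm{PFER} \le q_{sel}^2 / ((2\pi_{thr}-1)\,p)$, is
reported with every result and verified empirically on all-noise designs in
the tests. Subsamples that never reach `q_sel` within the iteration cap are
flagged and removed from the frequency denominators with a warning.
`consistency_report()` cross-tabulates stable sets over analyses (response,
land use, census year).

## Gradient prediction

`gradient_curve()` predicts a fitted response along the signed boundary
distance on a 0.5-km grid spanning the observed range (finer steps add no
information below the 1-km block size), with metric covariates held at
their medians and flags at zero (`conditioning_record()`); land use follows
the sign of the distance, the census year is part of the conditioning.
Extrapolation beyond the observed range is refused unless explicitly
allowed. The peak is the grid argmax, ties resolving to the smallest
distance for determinism. `relative_change()` compares two curves (e.g.
drought versus normal year) as percent change per distance, masking
distances where the reference is zero. Because the generating process
scales biomass uniformly between years, the median change over the grid is
the robust summary of the drought decline; the pointwise extreme is
inflated by spline boundary bias at the range edges and is not reported.

## Pipeline, reproducibility, and problem sizes

`run_pipeline()` chains simulate, impute, aggregate, metrics, fit, stabsel
and gradient, writing per-stage CSVs and a JSON manifest; a single global
seed derives per-stage seeds, and identical configurations produce
byte-identical stage outputs. The packaged verification runs at desk scale,
chosen as the smallest sizes at which each property is informative: a
30 x 30-block landscape (16,200 sub-block records over two years, 1800
block records) for calibration and end-to-end recovery, 20 generator seeds
for the peak-recovery medians, 10,000 i.i.d. draws for maximum-likelihood
recovery per family, and 50 replicates of an all-noise design (p = 20,
n = 400) for the stability-selection error bound.

## Known limitations

* The jackknife order-selection cascade and the unseen-mass unveiling are
  one defensible reading of the bias-adjustment literature; other software
  makes different choices (e.g. no interpolation between orders), which
  shifts adjusted diversity slightly for rare-species-heavy blocks.
* Kriging is per-variable (no co-kriging) and isotropic, with a fixed
  candidate model set; anisotropy or trend surfaces are out of scope.
* The boosting implementation supports linear and P-spline base learners
  only -- no trees, no interaction learners, and no per-predictor
  selection between linear and nonlinear forms (a single spline learner
  per metric predictor keeps models small and selection interpretable).
* Standard errors and p-values for boosted coefficients are deliberately
  absent; stability selection is the supported inferential summary.
* The zero-adjusted gamma assumes the positive part is gamma-shaped;
  heavy-tailed biomass distributions would call for a different positive
  component.
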