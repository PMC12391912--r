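# divgrad

Diversity and biomass gradients of savanna ungulates from fine-scale block
censuses, analysed with boosted distributional regression.

## The problem

Censuses of a savanna ungulate community on a grid of 1-km blocks (each
nine 333-m sub-blocks) straddle the boundary between a protected reserve
and pastoral land, in a drought year and a normal rainfall year. Most
sub-blocks are empty, many blocks are incompletely censused, vegetation is
only sub-sampled, and the ~26 candidate predictors are strongly
intercorrelated. The scientific questions: where along the signed distance
to the reserve boundary do ungulate **diversity** and **biomass** peak, how
does drought move them, and which predictors matter consistently?

`divgrad` implements the full chain for researchers working with such
censuses (and, via a built-in generator, for anyone validating the
methodology):

1. **Synthetic censuses** — `simulate_landscape()` emulates the data's
   structure: geometric rank abundance dominated by migratory wildebeest
   and zebra, calibrated sub-block zero fractions (0.73 drought / 0.63
   normal by default), spatially correlated covariates with planned
   missingness, and configurable diversity/biomass peak locations.
2. **Kriging imputation** — `impute_covariates()`: automated variogram
   fitting (spherical/exponential/Gaussian by weighted least squares) and
   ordinary kriging of unsampled vegetation sub-blocks.
3. **Block aggregation** — expected totals
   `c_ui = sum_j d_uij * 9 / Q_i` correct for blocks with fewer than nine
   censused sub-blocks.
4. **Community metrics** — Hill numbers `^qD = (sum p^q)^(1/(1-q))` at
   orders 0, 1, 2, 10 and the reciprocal Berger–Parker index, with
   jackknife bias adjustment (sequential order selection) for undetected
   species; unit-weight biomass split migratory/nonmigratory.
5. **Boosted distributional regression** — non-cyclical component-wise
   gradient boosting with P-spline base learners and variable coefficients
   by land use × census year, over negative binomial, zero-truncated
   negative binomial, and (shifted) zero-adjusted gamma likelihoods, with
   cross-validated early stopping (`boost_fit()`, `cv_tune()`).
6. **Stability selection** — complementary-pairs subsampling with a 70%
   selection-frequency threshold and an analytic false-positive bound
   (`stabsel_boost()`).
7. **Gradient prediction** — response curves versus boundary distance with
   covariates at their medians, peak location, and drought-vs-normal
   percent change (`gradient_curve()`, `relative_change()`).

`run_pipeline()` chains all stages with one global seed, per-stage CSVs and
a JSON manifest.

## Worked example

```r
library(divgrad)

cfg    <- scenario_config(seed = 7)        # 30 x 30 blocks, two census years
grid   <- simulate_landscape(cfg)          # 16,200 sub-block records
round(subblock_zero_fraction(grid), 3)
#>  1999  2002
#> 0.729 0.627

blocks  <- aggregate_blocks(grid)          # 1,800 (block, year) records
metrics <- community_summary(blocks)       # diversity profiles + biomass
round(colMeans(metrics[metrics$year == 2002,
                       c("S_raw", "D0", "D1", "D2", "D10")], na.rm = TRUE), 2)
#> S_raw    D0    D1    D2   D10
#>  6.92 11.42  7.12  5.61  3.90
```

The realized zero fractions match the calibrated drought/normal targets,
and the mean diversity profile decreases with the order `q`, as it must:
bias-adjusted richness (`D0`) exceeds raw richness (`S_raw`), while order
10 weighs evenness so heavily that it approaches the reciprocal
Berger–Parker index. A single block works too:

```r
diversity_profile(c(wildebeest = 42, zebra = 17, impala = 3, topi = 1, oribi = 1))
#> $S_raw  5
#> $D0     6.83      # jackknife-adjusted richness (two singletons)
#> $D      D1 2.81   D2 2.11   D10 1.65
#> $D_inf  1.52      # 1 / 0.656, wildebeest dominance
```

Fitting the drought-year biomass gradient and locating its peak:

```r
res <- run_pipeline(list(
  seed = 7,
  fit  = list(responses = c("shannon", "biomass_total"),
              predictors = "dist_boundary_km", grouping = "year")))
attr(res$curves[["biomass_total_2002"]], "peak_km")   # peak inside the reserve
ch <- relative_change(res$curves[["biomass_total_1999"]],
                      res$curves[["biomass_total_2002"]])
median(ch$change_pct[abs(ch$dist) <= 20])             # drought decline, ~ -50%
```

See the vignette (`vignettes/census-to-gradient.Rmd`) for the models,
their assumptions, and every numerical choice.

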