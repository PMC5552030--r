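# slrveg

Probabilistic simulation of how coastal vegetation communities redistribute
under sea-level rise (SLR), for landscape and coastal ecologists working
with an elevation raster and a land-cover map.

Barrier-island communities — from salt marsh at the lagoon edge to oak
scrub on the highest ridges — organise along the elevation gradient because
relative elevation proxies depth to the water table and salinity. `slrveg`
turns that zonation into a forecasting tool:

* the **community–elevation proportion matrix** stores, at every 0.001 m
  elevation step *e*, the naive-Bayes posterior with abundance priors

  $$p(c \mid e) = \frac{n_c\,\hat f_c(e)}{\sum_j n_j\,\hat f_j(e)},$$

  where $\hat f_c$ is the Gaussian kernel density estimate of elevations
  within community *c* and $n_c$ its pixel count;
* SLR of *s* metres lowers every pixel's elevation relative to mean lagoon
  high water (MLHW) by *s*; pixels falling below mean lagoon water
  (−0.2 m MLHW) enter an **absorbing open-water state**;
* every remaining pixel independently redraws its community from the matrix
  row at its shifted elevation; replicate simulations (1000 by default)
  give medians and central 95% intervals of the final community
  proportions, a from×to contingency matrix, and percent-change tables on
  both a total-area and a remaining-land basis.

The package also provides the supporting analyses: a stratified
heteroscedastic GLS of elevation on community with exponential spatial
residual correlation (via `nlme`) and Nagelkerke pseudo-R², per-community
elevation density profiles, a subsample-size sensitivity analysis, and a
synthetic barrier-island generator so the entire pipeline is testable
without proprietary LiDAR/land-cover rasters. Everything is data-frame in,
tibble out, with `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Generate a synthetic barrier island, build the proportion matrix, and run
the 1.2 m SLR scenario with 100 replicates:

```r
library(slrveg)

grid <- generate_landscape(synthetic_config(rows = 250, cols = 250, seed = 42))
px   <- to_pixel_table(grid)
mat  <- build_proportion_matrix(px)              # 0.001 m steps
rs   <- replicate_simulations(px, mat, slr_scenario(rise = 1.2),
                              n_reps = 100, base_seed = 42)
rs
#> <replicate_summary> rise 1.2 m, 100 replicates of 45074 pixels; absorbed fraction 0.447
#> # A tibble: 19 × 5
#>    state    basis     median  lower  upper
#>  1 SMAR     total     0.0964 0.0941 0.0986
#>  ...
#> 10 ABSORBED total     0.447  0.447  0.447
#> 11 SMAR     remaining 0.174  0.170  0.178
#>  ...
#> 19 SCRB     remaining 0.158  0.154  0.162

percent_change_table(list(rs))
#> # A tibble: 9 × 4
#>    rise community initial percent_change
#> 1   1.2 SMAR         5739          -24.3
#> 2   1.2 WETS         1881          -33.8
#> 3   1.2 MANG         2114          -36.1
#> 4   1.2 PALM         2339          -44.1
#> 5   1.2 FWET         6063          -42.5
#> 6   1.2 HAMM         7273          -46.3
#> 7   1.2 PINE         7270          -45.1
#> 8   1.2 FRST         3186          -56.9
#> 9   1.2 SCRB         9209          -57.2
```

Reading the output: a 1.2 m rise submerges 44.7% of this landscape's
current vegetated area (the absorbed fraction is identical in every
replicate because inundation depends only on elevation). Losses steepen up
the gradient — oak scrub (SCRB) and upland forest (FRST) lose ~57% of their
area while salt marsh (SMAR) loses least — and on the land that remains,
salt marsh's share grows from ~13% to 17.4% while the narrow replicate
intervals show the predictions are limited by landscape size, not
simulation noise. `autoplot(rs)` draws the observed-versus-predicted
interval plot; `run_pipeline(run_config(...))` runs every stage end to end
and writes the CSV bundle plus a JSON run manifest.

A thin command-line front end with `generate`, `fit-gls`, `build-matrix`,
`simulate` and `run-all` subcommands is installed at
`system.file("cli", "slrveg.R", package = "slrveg")`.

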