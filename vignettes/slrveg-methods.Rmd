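---
title: "Modelling vegetation community response to sea-level rise with slrveg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling vegetation community response to sea-level rise with slrveg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slrveg)
```

## The model

Barrier-island vegetation communities organise along the elevation gradient,
because relative elevation is a proxy for depth to the water table and for
salinity exposure: salt marsh sits just above the lagoon's high-water line,
and scrub occupies the highest, driest ridges. `slrveg` exploits this
zonation with a probabilistic, aspatial model of community change under
sea-level rise (SLR):

1. **Reference frame.** All elevations are expressed in metres above mean
   lagoon high water (MLHW). SLR of $s$ metres raises MLHW by $s$, so every
   pixel's *relative* elevation falls by $s$: `shift_elevation(e, scenario)`
   returns $e - s$. A pixel at 1.2 m above MLHW sits at 1.0 m after a 0.2 m
   rise.
2. **Community–elevation proportion matrix.** From the current landscape,
   each community $c$ contributes a Gaussian kernel density estimate
   $\hat f_c(e)$ of its elevations and a pixel count $n_c$. At every
   discretised elevation step $e$ (default $\Delta$ = 0.001 m) the matrix
   stores the naive-Bayes posterior with abundance priors,
   $$p(c \mid e) = \frac{n_c \hat f_c(e)}{\sum_j n_j \hat f_j(e)}.$$
3. **Absorbing open water.** Mean lagoon water (MLW) sits ≈ 0.2 m below
   MLHW. A pixel whose shifted elevation falls below $-0.2$ m becomes open
   water deterministically and never returns.
4. **Monte-Carlo transition.** Each remaining pixel independently draws a
   new community from the matrix row at its shifted elevation. A replicate
   yields a from-community × to-state contingency matrix and final
   proportions on two bases: the total input pixel count, and the remaining
   (non-absorbed) land. Replicates (default 1000; replicate $r$ is seeded
   `base_seed + r`) give the median and central 95% interval (2.5th/97.5th
   percentiles) per community.

Because classification uses no neighbourhood information, the model
predicts the *collective* composition of the landscape, not the fate of any
particular pixel: under a no-change scenario the final proportions match the
initial ones closely even though many individual pixels swap communities
within elevation zones where communities overlap.

## The stratified elevation regression

The strength of the community–elevation relationship is quantified by a
maximum-likelihood generalized least squares fit of
$e_i = \mu_{c(i)} + \varepsilon_i$ with a per-community residual SD
("stratum SD") and, optionally, exponentially decaying spatial residual
correlation,
$$\mathrm{Cov}(\varepsilon_i, \varepsilon_j) =
  \sigma_{c(i)}\,\sigma_{c(j)}\, e^{-d_{ij}/r},$$
with $d_{ij}$ the Euclidean distance between cell centres in projected
metres and $r$ the range parameter. The spatial path delegates to
`nlme::gls()` (`varIdent` variances, `corExp` correlation, `method = "ML"`);
the iid path uses the exact closed-form ML solution and is cross-checked
against `nlme` in the tests, while the spatial path is validated against an
independent dense multivariate-normal likelihood maximised by grid search
plus Nelder–Mead. ML (not REML) is used so that models with and without the
correlation structure are comparable by likelihood. Fit quality is reported
as Nagelkerke's pseudo-$R^2$,
$$R^2 = \frac{1 - \exp\{2(\ell_0 - \ell_1)/n\}}{1 - \exp\{2\ell_0/n\}},$$
with the intercept-only iid model as the null $\ell_0$ — the simplest
defensible convention, since the construction is not uniquely defined for
GLS models. Wald 95% intervals are used throughout. Because the dense
spatial covariance makes the likelihood cubic in $n$, fits default to a
subsample of 2 000 pixels; up to 10 000 is feasible but is a long
single-core run.

```{r gls-example}
px <- sample_pixel_table(2000, synthetic_config(), seed = 1)
fit <- fit_stratified_gls(px, correlation = "none")
glance(fit)
head(tidy(fit), 3)
```

## The synthetic landscape generator

The original analysis used a LiDAR terrain model and an aerial-imagery land
cover map that are not redistributable, so the package ships a generator
(`generate_landscape()`) that emulates the *statistical* structure the
model relies on:

* **Per-community elevation distributions.** Defaults
  (`community_defaults()`) use the published stratified means and SDs of
  the nine communities, from salt marsh (0.14 ± 0.55 m) to oak scrub
  (1.96 ± 1.65 m). Salt marsh and freshwater wetland default to
  dual-peaked distributions — equal-weight two-component normal mixtures
  with modes at `mean ± delta` and within-mode SD
  $\sqrt{\mathrm{sd}^2 - \delta^2}$, preserving the marginal mean and SD.
  The separations ($\delta$ = 0.45 m and 0.90 m) are not estimates: field
  accounts attribute the dual peaks to marsh zonation or perched wetlands
  without quantifying them, so they are chosen only to make the bimodality
  unambiguous (≈ 3 within-mode SDs apart) and are flagged as arbitrary.
* **Landscape composition.** Community weights default to the published
  landscape shares (salt marsh 15.5%, …, oak scrub 17.9%), normalised to 1.
* **Terrain texture.** A latent field of moving-average-smoothed white
  noise (default length 8 cells) plus a gentle cross-shore ramp and low
  sinusoidal dune ridges (period 150 m) is rank-mapped onto the target
  marginal elevation distribution — the weighted community mixture plus a
  sub-MLW open-water tail (default 10% of cells, uniform on $[-2, -0.2]$ m).
  Rank mapping keeps the marginal an exact iid sample from the target while
  the latent field supplies spatial clumping of both elevation and, through
  it, community labels. Cell size is 3 m.
* **Assignment.** Cells at or above $-0.2$ m draw a community from the
  analytic posterior $p(c \mid e) \propto w_c f_c(e)$ (exact normal
  densities, not KDE); lower cells become open water.

One consequence worth stating plainly: *on the landscape*, elevations within
community $c$ follow $f_c$ truncated at $-0.2$ m, so for low-lying or
wide-ranging communities the landscape sample mean differs from the
configured mean (oak scrub ≈ 2.27 m rather than 1.96 m, because its wide
distribution loses its submerged tail). The untruncated samplers
(`sample_pixel_table()`, `sample_community_elevations()`) recover the
configured moments exactly and are the generating model for the regression
benchmarks. The generator reproduces zonation, overlap, bimodality, spatial
clumping and composition; it does **not** reproduce the real island's
hypsometry, shoreline geometry, or land-cover classification error, so
passing tests demonstrate the correctness and calibration of the *method*,
not a forecast for any real landscape.

## Numerical choices

* **KDE.** Gaussian kernels with Silverman's rule-of-thumb bandwidth per
  community (`stats::bw.nrd0`), overridable and logged in the run manifest.
  Densities are computed as exact sums over sample points (in compiled
  code), not binned FFT approximations; terms beyond 39 bandwidths
  underflow to exactly zero in double precision, so the windowed sum equals
  the full sum bit-for-bit.
* **Matrix bounds and underflow.** Steps span
  `[min(e) − 3·max(bw), max(e) + 3·max(bw)]` snapped to the $\Delta$ grid,
  covering the KDE support. Rows where every density underflows inherit the
  nearest supported row, so lookups never return an undefined multinomial.
* **Lookup.** Elevations snap to the nearest step with ties toward the
  higher step; elevations beyond the grid clamp to the boundary rows.
* **Degenerate inputs.** A constant stratum yields its exact mean with zero
  SD; strata with fewer than two pixels are flagged unidentifiable;
  communities with fewer than two pixels are dropped from density profiles
  and the matrix with a warning.
* **Seeding.** Every stochastic stage takes an explicit integer seed;
  replicate $r$ uses `base_seed + r`, and subsample $i$ of the sensitivity
  analysis uses `base_seed + 1000·i`, so any replicate can be reproduced in
  isolation. Identical configurations give byte-identical output files.

## Problem sizes

The package's own validation runs at desk scale: landscapes of 380 × 380
cells (≈ 10⁵ land pixels) for the fixed-point, absorption and sensitivity
checks, 100 replicates per scenario, 100 synthetic datasets of n = 2 000
for regression recovery, and brute-force likelihood oracles at n ≤ 200.
The same code runs unchanged at larger sizes; the full published analysis
scale (3.4 × 10⁷ pixels, 1000 replicates, GLS at n = 10⁴) is a matter of
hours on one core, dominated by the dense-covariance GLS.

## Raster formats

No GeoTIFF reader is required: grids are exchanged as ESRI ASCII rasters
(`.asc`, plain text, exact round-trip, CRS carried in a `.prj` sidecar) or
single-band TIFF (`.tif`) with a JSON sidecar recording the linear scaling
of samples into [0, 1] (reduced precision; convenient for image tools).
Land-cover rasters hold integer codes — `1..9` indexing the community list,
`0` open water, nodata honoured — and an optional code map can group raw
survey classes into the nine modelled communities at read time. The
georeference is carried opaquely; the model itself is aspatial and uses
coordinates only for inter-pixel distances in the spatial regression.

## Known limitations

The model deliberately excludes accretion, erosion, salt-water intrusion,
storm surge, fire and freeze dynamics, and any spatial interaction between
pixels; it is a first-approximation reallocation of communities along the
elevation gradient. Prediction intervals reflect only multinomial sampling
noise, so they narrow as $1/\sqrt{N}$ and understate structural
uncertainty. The elevation–community relationship is assumed stationary
under SLR. Where elevation is not the dominant control (mangrove versus
wet scrub-shrub, whose published distributions overlap almost completely),
the classifier redistributes pixels between such communities freely.
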