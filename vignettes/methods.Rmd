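---
title: "Methods: oversampled NH3 enhancements and population-weighted inequality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oversampled NH3 enhancements and population-weighted inequality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nh3ineq)
```

This vignette documents the statistical model behind `nh3ineq`, the
parameters that matter, what the synthetic-scene generator does and does
not emulate, and the numerical and design choices made where the method
leaves them open.

## 1. From soundings to gridded columns

A Level-2-like sounding is an elliptical footprint (semi-axes $a$, $b$ in
km, major-axis azimuth $\theta$) carrying a total vertical column density
$C_i$ (molecules cm$^{-2}$) and a 1$\sigma$ retrieval uncertainty
$\sigma_i$. After a quality postfilter (cloud fraction $\le$ a threshold,
default 0.1 in `filter_pixels()` and 0.2 in the pipeline default, and a
passing sensitivity flag — infrared retrievals lose skill at low thermal
contrast), footprints are averaged onto a regular 0.01° grid
($\approx$ 1 km, much finer than a 12 km footprint).

The spatial response at offset $(dx, dy)$ in the footprint's rotated
frame is the generalized Gaussian

$$S(dx, dy) = \exp\!\left[-\ln 2\left(\left|\tfrac{dx}{a}\right|^k +
\left|\tfrac{dy}{b}\right|^k\right)\right],$$

normalised so $S = 1$ at the centre and exactly $S = 1/2$ at the
footprint edge along each principal axis — i.e. the response FWHM equals
the footprint diameter for every exponent $k$, which makes the smooth
($k = 2$) and sharp-edged ($k \approx 18$; a top-hat as
$k \to \infty$) representations directly comparable. Cell $j$ receives

$$\hat C_j = \frac{\sum_i S_{ij}\,\sigma_i^{-2}\,C_i}
{\sum_i S_{ij}\,\sigma_i^{-2}},$$

an inverse-variance weighted mean — the minimum-variance choice when
uncertainties are independent. A cell is valid when its accumulated
weight reaches a threshold (default: the weight equivalent of one pixel
at half response with the median uncertainty).

Numerical choices: offsets are evaluated in km via equirectangular
scaling at the pixel latitude (sub-metre error at footprint scale);
cells are evaluated at their centres (no cell-area integration, since
spacing $\ll$ footprint); each pixel's influence is truncated where
$S < 10^{-4}$, and the truncated support is boxed by its circumscribed
radius $r = (\log_2 10^4)^{1/k}\sqrt{a^2 + b^2}$, which bounds cost
without clipping rotated super-Gaussian footprints. An independently
coded double-loop oracle in the test suite confirms agreement to
$10^{-12}$ relative for both exponents, and constant column fields are
conserved to the same precision.

## 2. Enhancements over a percentile background

The exposure signal is the enhancement $\Delta = \hat C - B$ over a
regional background $B$, taken as a low percentile (default the 10th,
computed with linear interpolation between order statistics —
`stats::quantile` type 7) of valid cells. Cells at or below $B$ are
*flagged and excluded*, not clipped to zero: the analysis concerns block
groups that carry an enhancement, and zero-filling would dilute their
means.

The percentile itself is an empirical choice, made by
`select_background_decile()`: for each decile $d \in \{10, \dots, 90\}$
the absolute inequalities computed from raw columns and from
enhancements must agree within $1.96\sqrt{\mathrm{SEM}_{raw}^2 +
\mathrm{SEM}_\Delta^2}$ for every group; the highest passing decile is
chosen, falling back to 10 (with a warning) when none passes. The premise
is physical: block-group-scale variability should not be driven by the
regional background, so subtracting it must not change absolute
inequalities. When it does — at high deciles — the cause is a sampling
effect (the set of above-background block groups shrinks and the
population distribution underneath changes), not a real signal. Whether
this equivalence is assessed by a formal test or by inspection is a
configuration choice here (`z = 1.96` by default); nothing downstream
depends on the exact criterion. Stratified runs (calm/windy, cool/hot
subsets of one period) always reuse the all-days background of that
period, so strata share a reference level; separate time periods compute
their own.

## 3. Block-group aggregation and inequality metrics

Enhancements are aggregated to block-group polygons by exact area
weighting: each ring is clipped against every grid cell it touches
(Sutherland–Hodgman; areas by the shoelace formula after equirectangular
scaling) and enhanced cells are averaged with intersection areas as
weights. A cell-centre containment fallback (`method = "centers"`) is
available and agrees closely whenever polygons span many cells. A block
group "has an enhancement" when any of its area lies over enhanced valid
cells (coverage > 0; no minimum-coverage cutoff by default).

For group $g$ with population $p_i$ in block group $i$, over the
*eligible* subset (block groups where $g$'s population share is at or
above the unweighted mean share across the region — a raw-count basis is
available by flag),

$$\bar x_g = \frac{\sum_i p_i x_i}{\sum_i p_i}, \qquad
\mathrm{SEM}_g = \sqrt{\textstyle\sum_i w_i^2 (x_i - \bar x_g)^2},
\quad w_i = \frac{p_i}{\sum p}.$$

The weighted-SEM estimator is stated explicitly because the uncertainty
treatment is otherwise underdetermined; it reduces to the usual
$s/\sqrt{n}$ under equal weights. Inequality versus the reference group
$r$ is $A = \bar x_g - \bar x_r$ (absolute) and $100\,A/\bar x_r$
(relative, %), with $\mathrm{SEM}_A = \sqrt{\mathrm{SEM}_g^2 +
\mathrm{SEM}_r^2}$. Absolute inequality is invariant to adding a
constant to all block-group values; relative inequality is not — both
are asserted in the tests. The eligibility comparison carries a
$10^{-9}$ relative tolerance so block groups exactly at the threshold
are kept regardless of floating-point summation order; without it the
all-equal-shares case (every block group eligible) is broken by
ulp-level noise.

`decompose_trend()` recomputes per-period inequalities under two
demographic vintages, separating column-driven change (along one
vintage's series) from composition-driven change (between vintages at a
fixed period).

## 4. Meteorological stratification and distance profiles

Days are split at the median of morning (8 am–12 pm LT) wind speed or
air temperature; at-median days join the lower (calm/cool) stratum so
the strata always partition the record. An all-identical record is a
degenerate input and errors.

Block-group enhancements are binned by distance to the nearest permitted
swine facility (haversine; facility coordinates are taken as the source
points) in half-open 1 km bins, the first being the "at facility" bin
[0, 1) km. The downfield spatial extent is the outer edge of the last
bin in the contiguous-from-source run whose mean is at least twice the
noise floor, where the noise floor is twice the standard deviation of
block-group enhancements at 15–20 km — far enough that facility
influence is assumed negligible. Non-contiguous exceedances beyond the
first failing bin are deliberately not counted (the scan answers "how
far does the *connected* signal reach"). Stratified profiles reuse the
all-days noise floor: computed per stratum, the windy/cool bands are
often empty because far-field block groups drop below the shared
background, and a common floor is also what makes extents comparable
across strata.

## 5. The synthetic-scene generator

`generate_scene()` builds scenes with the statistical structure the
analysis assumes, with every default chosen once as a realistic regional
configuration:

| parameter | default | meaning |
|---|---|---|
| region_bounds | 1° × 1° (~100 km square) | analysis region |
| n_facilities | 100 | point sources, in ~8 clusters |
| facility_cluster_sd | 15 km | within-cluster scatter |
| emission_strength_range | 1–4 × 10^15 molec cm^-2 | column enhancement at r = 0 |
| decay_length_km | 10 | e-folding of each source term |
| background_column | 4 × 10^15 molec cm^-2 | uniform tropospheric background |
| baseline_shares | 0.25 / 0.10 / 0.02 / 0.63 | regional mean composition |
| proximity_bias | 1 | demographic link slope |
| hot_source_multiplier | 1.5 | source scale on hot days |
| calm_decay_multiplier | 1.5 | decay scale on calm days |

The truth field is
$B + \sum_f s_f \exp(-d_f/L)$ — isotropic exponential decay, additive
across facilities; a statistical stand-in for the observed downfield
decay, *not* a dispersion model (no plume physics, no stability classes,
no chemistry). Facility clustering leaves part of the region more than
20 km from any source so the far-field noise band is populated.
Demographic composition uses a softmax (multinomial-logistic) link: for
non-reference groups the linear predictor is
$\log(\text{base share}) + \beta z_i$ with proximity covariate
$z_i = e^{-d_i/L}$ and slope $\beta$ = `proximity_bias`; block-group
totals are lognormal. Populations are *expected* counts
(total × share), not a multinomial draw: integer rounding interacts with
the share-≥-mean eligibility knife edge to select near-random block-group
subsets, which would make the zero-bias null hold only statistically
rather than by construction. The cost is that census-like integer count
noise is not emulated.

Each scene records its `designed_inequality`: the package's own
percentile-background, area-weighting, eligibility, and
population-weighting machinery applied directly to the noiseless truth
field at analysis-grid resolution. That is the no-measurement limit the
satellite-sampled pipeline should recover; the measurement layer
(footprint averaging, uncertainty weighting, retrieval noise, sampling)
is exactly what sits between the two numbers. Recovery within three
combined standard mean errors at ~10,000 soundings is part of the test
suite (absolute gaps recover nearly unbiased; relative gaps are pulled
slightly toward zero by footprint smoothing of the reference group's far
field, well within the tolerance).

`simulate_columns()` places soundings uniformly (12 km diameter at
nadir, elongating off-nadir with random orientation), averages the truth
field over a 5 × 5 response-weighted quadrature of each footprint,
applies multiplicative Gaussian noise of CV `noise_cv`, and sets
$\sigma_i = \max(\text{noise\_cv}, 10^{-3}) \times$ the footprint-mean
truth — heteroscedastic, and strictly positive even in noise-free runs
so inverse-variance weights stay defined. Per-day modulation (hot days
scale sources by 1.5; calm days scale the decay length by 1.5) gives the
stratified analyses a known truth: calm-stratum extents exceed windy
ones and hot-stratum near-source means exceed cool ones, as asserted in
the acceptance tests. `generate_meteorology()` draws lognormal winds
(mean 3 m s$^{-1}$), normal temperatures (mean 24 °C, sd 4), and
exponential daily precipitation (mean 0.14 mm).

What passing tests on these scenes do **not** show about real data: the
generator has no spatially varying background, no retrieval biases
correlated with surface type or thermal contrast, no orbit geometry
(sampling is uniform), integer census counts are not emulated, and all
non-reference groups share one proximity covariate — their softmax
shares are proportional, so their eligible subsets and weights, and
hence their inequalities, are mathematically identical. Real groups
differ spatially; distinguishing them would need group-specific
covariates, which the single `proximity_bias` scalar deliberately does
not attempt.

## 6. Problem sizes and determinism

Scene generation and simulation are pure functions of (configuration,
seed); the RNG state of the caller is saved and restored. The standard
validation runs use 60 days × 200 soundings (12,000 pixels) on a
100 × 100-cell 0.01° grid with 144 block groups — chosen as the smallest
configuration at which the between-block-group SEMs are informative —
and complete in well under a minute each; unit tests use a 0.3° scene
with 36 block groups. The full test suite and the acceptance script each
run end-to-end in a few minutes on one CPU.

## 7. Known limitations

- Equirectangular local geometry limits scenes to a few degrees of
  extent (fine for the intended regional scale).
- The decile-selection equivalence criterion is a configured choice, not
  an inference procedure with controlled error rates.
- Area weighting treats polygon rings without holes; multi-ring block
  groups must be split upstream.
- The passive-sampler calculator is deliberately elementary: a
  time-weighted mean times (1 − bias), for illustrating monitoring-design
  consequences, not an instrument model.
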