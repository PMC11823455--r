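# nh3ineq

Satellite ammonia (NH3) column oversampling and demographic
exposure-inequality analysis.

## The problem

Industrial-scale animal feeding operations emit large amounts of NH3, and
the communities living nearest to them are disproportionately exposed.
Ground monitoring near such facilities is sparse, so satellite infrared
sounders are often the only observational record — but their footprints
(~12 km) are far coarser than the census block groups (~600–3000 people)
at which demographic composition is reported. This package implements the
full chain from Level-2-like satellite soundings to block-group-scale,
population-weighted exposure-inequality statistics, for researchers in
environmental epidemiology and air-quality remote sensing:

1. **Quality postfilter** — drop cloudy and low-sensitivity soundings
   (`filter_pixels()`).
2. **Oversampling** — long-term averaging of overlapping elliptical
   footprints onto a 0.01° grid. Each sounding *i* contributes to cell *j*
   with weight `S_ij / σ_i²`, where the spatial response is the
   generalized Gaussian

   `S(dx, dy) = exp(−ln2 · (|dx/a|^k + |dy/b|^k))`

   in the footprint's rotated frame (semi-axes `a`, `b`; `S = 0.5` at the
   footprint edge). `k = 2` is the smooth Gaussian representation,
   `k ≈ 18` the sharp-edged physical response (`oversample()`).
3. **Enhancements** — ΔNH3 = column − background, where the background is
   a low percentile (default the 10th) of the regional column
   distribution; the percentile is chosen as the highest decile for which
   raw-column and enhancement inequalities remain statistically
   equivalent (`compute_background()`, `select_background_decile()`).
4. **Block-group aggregation** — exact area-weighted means of enhanced
   cells within each polygon (`aggregate_blockgroups()`).
5. **Inequality metrics** — for each demographic group, the
   population-weighted mean over its eligible block groups (share ≥
   regional mean share),

   `x̄_w = Σ p_i x_i / Σ p_i`,  `SEM = √(Σ w_i² (x_i − x̄_w)²)`,

   and the absolute / relative (%) gap versus the reference group with
   SEMs combined in quadrature (`compute_inequality()`).
6. **Physical drivers** — median-split stratification on morning wind and
   temperature (`median_split()`), and binned enhancement-versus-distance
   profiles around the nearest facility with a downfield spatial extent
   defined by signal ≥ 2 × the far-field (15–20 km) 2σ noise
   (`distance_profile()`, `spatial_extent()`).

A synthetic-scene generator (`generate_scene()`, `simulate_columns()`,
`generate_meteorology()`) produces fully self-contained scenes — clustered
exponential-decay point sources, demographic composition tied to source
proximity, elliptical overlapping footprints, heteroscedastic retrieval
noise — whose designed inequality is known exactly, so the entire pipeline
is testable without external data.

## Worked example

```r
library(nh3ineq)

rep <- run_all(scene_config(seed = 1), n_days = 60, pixels_per_day = 200,
               noise_cv = 0.1, config = run_config(seed = 2))
print(rep)
#> <nh3_report> 1 period(s); reference group: white
#>   all: 9372 pixels, background 1.17e+16, extent 10 km
#>     black             +85.4% (abs +6.13e+15, sem 1.3e+15)
#>     hispanic          +85.4% (abs +6.13e+15, sem 1.3e+15)
#>     american_indian   +85.4% (abs +6.13e+15, sem 1.3e+15)
print(rep$scene)
#> <nh3_scene> 100 facilities, 144 block groups, 4 groups (ref white)
#> designed relative inequality (%):
#>           black        hispanic american_indian
#>          100.73          100.73          100.73
```

Reading this: 12,000 simulated morning soundings (9372 after the QC
postfilter) were oversampled to a 0.01° grid; the 10th-percentile
background is 1.17 × 10^16 molecules cm^-2; block-group ΔNH3 columns are
85% higher for each non-reference group than for the reference group
(absolute gap 6.1 ± 1.3 × 10^15 molecules cm^-2), recovering the scene's
designed gap of 101% to well within three combined standard mean errors.
(The three non-reference groups coincide exactly because the generator
ties them all to one proximity covariate; see the methods vignette.)
Stratified runs show the designed physics:

```r
st <- rep$periods$all$strata
st$calm$extent_km; st$windy$extent_km
#> [1] 17
#> [1] 10
st$hot$profile$mean[1]; st$cool$profile$mean[1]
#> [1] 2.56e+16
#> [1] 1.52e+16
```

Enhancements stay above the noise floor 7 km farther downfield on calm
days than on windy days, and near-source enhancements are highest on hot
days — the bidirectional-flux signature. Finally, the time-integration
arithmetic showing why two-week passive samplers miss acute episodes:

```r
passive_sampler_bias_example(peak_ppm = 1.7, peak_hours = 8,
                             baseline_ppb = 10, window_days = 14,
                             low_bias_fraction = 0.40)
#> [1] 30.14286
```

An episode at the 1.7 ppm acute respiratory standard lasting 8 h is
reported as ~30 ppb.

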