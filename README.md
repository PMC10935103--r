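# bambooflux

Processing chain for half-hourly eddy-covariance carbon flux records from
subtropical Moso bamboo (*Phyllostachys edulis*) forests — and for anyone
who needs a tested, reproducible reference implementation of the classic
tower-data workflow: friction-velocity screening, gap filling, flux
partitioning, windowed light-response parameters, phenology-period
statistics, and driver attribution by correlation and path analysis.

Sign convention throughout: **negative NEE = net CO2 uptake (carbon
sink)**; half-hourly fluxes are in mg CO2 m⁻² s⁻¹, accumulated sums in
gC m⁻².

## The methods at its core

1. **u\* screening** — nighttime (PAR < 5 µmol m⁻² s⁻¹) records with
   friction velocity u\* < 0.2 m s⁻¹ have NEE rejected (weak turbulence
   underestimates nocturnal efflux).
2. **Gap filling** — meteorological gaps ≤ 2 h by linear interpolation,
   longer gaps by the mean-diurnal-variation estimate (same half-hour slot,
   ±7 days); NEE gaps are model-filled, never interpolated.
3. **Respiration** — nighttime NEE = RE identifies the Lloyd–Taylor model
   `RE(Ts) = R_ref · exp(E0 · [1/(T_ref − T0) − 1/(Ts + 273.15 − T0)])`
   with T_ref = 283.15 K, T0 = 227.13 K, fitted by bounded
   Levenberg–Marquardt least squares.
4. **Light response** — in each of 73 calendar-anchored 5-day windows per
   year, daytime data fit the rectangular hyperbola
   `−NEE = α·PAR·Pmax / (α·PAR + Pmax) − RE`,
   yielding the apparent quantum efficiency α and maximum photosynthetic
   rate Pmax series, Gaussian-smoothed for trend display.
5. **Partitioning** — RE = NEE at night, Lloyd–Taylor prediction by day;
   **GEP = RE − NEE** everywhere (exactly zero at night); accumulation to
   daily/5-day/annual gC m⁻² via × 1800 s × 12/44 / 1000.
6. **Phenology** — every day labelled with one of six periods of the
   bamboo on-/off-year cycle (FG_ON, LS_ON, NF_ON, LR_OFF, LS_OFF,
   NF_OFF); per-period mean ± sd statistics on the 5-day series.
7. **Drivers** — stratified Pearson correlations, and standardized
   per-equation OLS path analysis on the graph
   {VPD, Prec, PAR, LAI, Ta, Ts} → Pmax, → RE; Pmax → GEP; GEP, RE → NEE,
   with indirect effects as exact chain products.

A synthetic tower generator (`generate_meteorology()`, `generate_fluxes()`,
`inject_gaps_and_low_ustar()`, `simulate_tower_dataset()`) produces
seasonal subtropical meteorology and fluxes from known ground-truth
parameters, with seeded gaps and low-turbulence episodes, so every stage is
testable by parameter recovery.

## Worked example

```r
library(bambooflux)

met   <- generate_meteorology(days = 365, seed = 1)
truth <- flux_truth(365, noise_sd = 0.05, seed = 1, low_ustar_fraction = 0.1)
rec   <- inject_gaps_and_low_ustar(generate_fluxes(met, truth), truth)$records

flt <- apply_ustar_filter(rec, threshold = 0.2)
flt$n_rejected
#> [1] 909

lt <- fit_lloyd_taylor(flt$records)
lt
#> <lloyd_taylor_fit> r_ref = 0.0801 mg m-2 s-1, e0 = 309.2 K (n = 7874, rmse = 0.0504)

lr     <- fit_light_year(flt$records)
filled <- fill_nee(flt$records, lt, lr)
part   <- derive_re_gep(filled$records, lt)
aggregate_fluxes(part, "annual")
#>   period    nee   re  gep fill_fraction
#> 1   2011 -171.2 1253 1425       0.05188
```

Reading the output: the filter removed 909 low-turbulence nighttime
records; the respiration fit recovered the generating parameters
(truth: R_ref = 0.08, E0 = 309) to within the noise; and the year
accumulates to an annual NEE of −171 gC m⁻² — a net carbon sink — with
GEP = RE − NEE holding exactly (1425 = 1253 − (−171.2)). About 5% of
half-hours are filled rather than observed.

The whole chain, file-in/file-out, is one call (or the bundled
`inst/scripts/bambooflux` command-line wrapper):

```r
sim <- simulate_tower_dataset(years = 2, seed = 7, out_dir = "demo_data")
res <- run_pipeline(read_pipeline_config(sim$paths$config), out_dir = "demo_out")
```

which writes daily/5-day/annual flux tables, the light-response series,
period statistics, correlation and path-coefficient tables, and a run log,
each stamped with a hash of the configuration; identical config and inputs
give byte-identical outputs.

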