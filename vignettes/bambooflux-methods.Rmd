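---
title: "Processing half-hourly bamboo-forest carbon fluxes: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing half-hourly bamboo-forest carbon fluxes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bambooflux)
```

## The problem

An eddy-covariance tower over a Moso bamboo (*Phyllostachys edulis*) forest
delivers half-hourly net ecosystem exchange (NEE, mg CO2 m^-2^ s^-1^;
negative = net uptake, i.e. a carbon sink) together with
micrometeorology: photosynthetically active radiation (PAR,
umol m^-2^ s^-1^), air and soil temperature (Ta, Ts, degC), vapour pressure
deficit (VPD, hPa), precipitation (Prec, mm per 30 min) and friction
velocity (u*, m s^-1^). Before any ecological statement can be made, the
record must be screened, gap-filled and partitioned, and the resulting
fluxes summarised over the bamboo forest's peculiar two-year phenology
(alternating on-years with mass shoot production and off-years with
hardly any). `bambooflux` implements that chain end-to-end, plus a
synthetic tower generator with known ground truth so that every stage can
be validated by parameter recovery rather than by eyeballing.

## Screening and gap filling

**u\* screening.** Under weak nocturnal turbulence, respired CO2 drains
below the canopy and the tower underestimates the efflux. Nighttime
records (PAR < 5 umol m^-2^ s^-1^) with u\* below a threshold (default
0.2 m s^-1^, the conventional value for this forest type) have their NEE
rejected. The filter is applied to nighttime records only — daytime
turbulence is not the stated failure mode — and the paired daytime record
is kept. PAR < 5 rather than PAR = 0 defines night because it is robust
to sensor offsets around dawn and dusk.

**Meteorological gaps.** Gaps of at most 2 h (four records, boundary
inclusive) are filled by linear interpolation between the flanking
observations. Longer gaps, and short gaps that touch a series boundary,
use the mean-diurnal-variation (MDV) estimate: the mean of observed values
in the same half-hour slot within +/-7 days. The +/-7-day half-width is the
community default and a configuration knob (`mdv_window_days`). MDV reads
only pre-fill values, which makes filling idempotent and keeps observed
values untouchable; a slot whose MDV window holds no observation stays
missing and is counted in the gap report. On a perfectly periodic diurnal
signal the MDV estimate is exact, which is the property the tests use.

**NEE gaps** are never filled by interpolation. They are model-filled
(below) so that the filled series respects the flux physics.

## Partitioning model

Nighttime NEE is pure ecosystem respiration (RE) — there is no
photosynthesis — so nighttime, u\*-accepted, observed NEE–Ts pairs identify
the Lloyd–Taylor model

$$RE(T_s) = R_{ref}\,\exp\!\left(E_0\left[\tfrac{1}{T_{ref}-T_0} -
\tfrac{1}{T_s+273.15-T_0}\right]\right)$$

with the standard constants $T_{ref} = 283.15$ K and $T_0 = 227.13$ K, so
$R_{ref}$ is the respiration at 10 degC and $E_0$ (K) the temperature
sensitivity. The fit is Levenberg–Marquardt nonlinear least squares with
box bounds $R_{ref} \in (0, 10]$, $E_0 \in (0, 1000]$, three start points
tried in turn, and tight convergence tolerances (`ftol = ptol = 1e-15`) so
that noiseless data are recovered to numerical precision. A window with
fewer than 10 usable pairs or (near-)constant Ts — where $E_0$ is
unidentifiable — returns a flagged failure; the pipeline then falls back
to the pooled fit. The default fit scope is one fit per calendar year
(`lloyd_taylor_scope = "annual"`), the minimal assumption; Ts is the
shallow soil temperature, which co-varies most with surface respiration.

Daytime NEE follows the rectangular hyperbola

$$-NEE = \frac{\alpha\,PAR\,P_{max}}{\alpha\,PAR + P_{max}} - RE$$

whose initial slope is the apparent quantum efficiency $\alpha$
(mg CO2 umol^-1^; conventionally reported x1000 as ug umol^-1^) and whose
asymptote is the maximum photosynthetic rate $P_{max}$
(mg CO2 m^-2^ s^-1^).

Filling: nighttime NEE gaps take the Lloyd–Taylor prediction at the
record's Ts; daytime gaps take the hyperbola prediction from the covering
5-day window fit (nearest converged window if the covering fit failed,
with the fallback logged). Partitioning then sets RE = NEE at night and
RE = Lloyd–Taylor prediction by day, and GEP = RE - NEE everywhere — so
nighttime GEP is exactly zero by construction and the identity
GEP = RE - NEE is conserved at every aggregation level by linearity.

Accumulation converts each half-hour from CO2 mass flux to carbon:
value x 1800 s x 12/44 / 1000, giving gC m^-2^ per day, per 5-day window
or per calendar year. The conversion lives only at aggregation; everything
half-hourly stays in mg CO2 m^-2^ s^-1^. A constant NEE of 0.1 mg CO2
m^-2^ s^-1^ accumulates to 2.3564 gC m^-2^ d^-1^, the closed-form check
used in the tests.

## Windowed light-response parameters

Daytime half-hours are too few to fit the hyperbola daily, so $\alpha$ and
$P_{max}$ are fitted in non-overlapping 5-day windows anchored to the
calendar year: windows 1–72 are five days from January 1 and window 73
absorbs the year-end remainder (five days in common years, six in leap
years), so every year yields exactly 73 fits that partition it. Each
window fit requires at least 20 daytime observed records (about six
residual degrees of freedom per parameter); RE is a free third parameter
because that is what fitting the full equation to daytime data means —
its agreement with the Lloyd–Taylor RE is a diagnostic, not a constraint.
Bounds are $\alpha \in (10^{-5}, 0.05]$, $P_{max} \in (0.01, 5]$,
$RE \in [0, 2]$ with start values (0.002, 0.5, 0.1); fits pinned at a
bound, under-sampled windows and constant-PAR (rank-deficient) designs are
flagged and excluded from downstream statistics but kept in the table.

The raw series is noisy, so a discrete Gaussian kernel (default
`sigma = 2` windows, i.e. a 10-day bandwidth; a knob, since the filter's
bandwidth is a free choice) smooths the converged values; flagged windows
get zero weight and the kernel renormalises, so constants are preserved
and excluded windows do not leak.

**An identifiability limit worth knowing.** $P_{max}$ is sharply
identified by the light-saturated end of the curve; on synthetic years the
fitted series tracks the generating seasonal trajectory almost perfectly.
$\alpha$ is identified by the low-light end, where the within-window
variation of true respiration (Lloyd–Taylor RE moves with Ts while the
window model holds RE constant) projects onto the slope. Even noiseless
synthetic years therefore show percent-level to tens-of-percent window
errors in $\alpha$ — largest in winter windows with a compressed PAR range
— while the window *median* error stays small. This is a property of the
windowed constant-RE method itself, not of the optimizer; consumers of the
$\alpha$ series should lean on the smoothed trend, not individual windows.

## Phenology statistics

A phenology calendar assigns each year an on/off class and dates the
periods: FG_ON (fast growth of new culms) and LS_ON (leaf spreading) in
on-years; LR_OFF (leaf renewal) and LS_OFF (leaf spreading) in off-years;
all remaining days are NF_ON/NF_OFF. Labelling is a strict partition —
every day gets exactly one label. Because the published period dates are
not available as data, the calendar is a required input file, and the
synthetic module emits a plausible one (FG in April, LS_ON May–June;
LR_OFF April to mid-May, LS_OFF mid-May to July; odd years on). Period
statistics (mean +/- sd) are computed on the 5-day series — the resolution
at which $P_{max}$ exists and in which the published period means are
expressed — with each 5-day block labelled by its majority day, ties going
to the earlier period.

## Driver attribution

Pearson correlations between the six drivers (VPD, Prec, PAR, LAI, Ta, Ts)
and the responses (NEE, RE, GEP, $P_{max}$, $\alpha$) are computed per
stratum on pairwise-complete 5-day observations, with two-sided p-values
and the conventional star notation (* p < 0.05, ** p < 0.01).

The path model is classic per-equation standardized OLS on the directed
graph: all six factors point to $P_{max}$ and to RE; $P_{max}$ points to
GEP; GEP and RE point to NEE. Within a stratum all variables are z-scored,
each endogenous variable is regressed on its parents without intercept,
and the coefficients are the path coefficients (PCs). Full-information SEM
estimation is deliberately out of scope: per-equation OLS is the
reproducible baseline, and under collinear drivers it can legitimately
produce |PC| > 1 (suppression), which is flagged rather than forbidden.
A perfectly singular design falls back to ridge with penalty 1e-8 and a
warning; strata with fewer than 15 complete rows are refused. Indirect
effects multiply along the two chains (factor -> Pmax -> GEP -> NEE and
factor -> RE -> NEE) and are exact products by construction. For a
single-parent equation the PC equals the Pearson correlation — the bridge
identity that ties the two analyses together and is asserted in the tests.
Missing 5-day entries (failed window fits) are dropped listwise within a
stratum.

## The synthetic tower

The generator emulates a subtropical monsoon site: PAR follows a diurnal
half-sine (zero at night) with a summer-peaking amplitude and a random
daily cloudiness factor; Ta combines annual (mean 16.6 degC, amplitude
9.5 degC, peaking late July) and diurnal (4 degC) sinusoids with
autocorrelated weather noise; Ts is a damped (x0.6), 15-day-lagged copy
with a small diurnal cycle; VPD derives from Ta and a diurnally varying
relative humidity, so it co-varies with temperature; precipitation is a
sparse gamma-marked event process summing to roughly 1400 mm a^-1^. VPD is
generated and handled in hPa throughout: published magnitudes for this
climate printed in kPa reach values that are physically implausible in
that unit, so the package does not attempt to reproduce them.

Fluxes come from the forward model NEE = RE(Ts) - hyperbola(PAR) + noise,
with daily trajectories of $\alpha$ (2.3–3.3 ug umol^-1^, winter-peaked)
and $P_{max}$ (0.15–0.75 mg m^-2^ s^-1^, summer-peaked) in opposite phase
— matching the negative association observed for this forest type — and
scalar $R_{ref} = 0.08$ mg m^-2^ s^-1^, $E_0 = 309$ K, noise sd 0.05
mg m^-2^ s^-1^ by default. Records classified as night carry pure
respiration (no photosynthetic term below the 5 umol threshold), keeping
the generator consistent with the partitioning convention RE = NEE at
night. Gap injection punches non-overlapping windows of mixed lengths, and
a configurable fraction of nighttime records is forced below the u*
threshold with NEE halved — the advective underestimation the filter must
remove. Baseline nighttime u* sits above 0.2 m s^-1^, so the injection
mask is exactly the set of records the filter should reject, which is what
the filter tests assert. Everything is seeded: a fixed seed regenerates
the dataset bit-identically.

What the generator does *not* emulate: storage and advection fluxes,
energy-balance closure, synoptic weather systems, instrument spikes and
calibration drift, or the remote-sensing artefacts of a real LAI product.
Passing recovery tests therefore demonstrates that the algorithms are
correct and unbiased under their own assumptions — not that real tower
data satisfy those assumptions.

## Numerical choices and degenerate inputs

* Nonlinear fits: `minpack.lm::nlsLM` (Levenberg–Marquardt) with box
  bounds, multi-start for the respiration fit, `maxiter = 500`,
  `ftol = ptol = 1e-15`.
* Degenerate designs (constant Ts, constant PAR, under-sampled windows)
  are flagged failures, never silent numbers.
* Ties in majority-day block labelling go to the earlier period.
* Gaussian smoothing renormalises its kernel over valid entries; at the
  series edges this truncates the kernel, so exact mass conservation holds
  only away from the boundaries.
* The config hash stamped into every output table is a 32-bit FNV-1a of
  the serialized configuration; identical config and inputs give
  byte-identical outputs, which the determinism tests check literally.
* Test and acceptance problem sizes — 60–365-day synthetic records,
  100-seed recovery ensembles, n = 500 path samples — were chosen as the
  smallest sizes at which the recovery properties stabilise.

## Known limitations

* The $\alpha$ series carries the identifiability bias described above.
* MDV filling assumes the diurnal cycle is stationary over +/-7 days;
  frontal weather breaks that assumption and the filled values inherit it.
* The annual Lloyd–Taylor scope ignores seasonal respiration acclimation;
  a per-period refit is a planned configuration extension.
* Path coefficients from per-equation OLS are not maximum-likelihood SEM
  estimates; with strongly collinear drivers the two can differ, and no
  significance test is attached to indirect effects.
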