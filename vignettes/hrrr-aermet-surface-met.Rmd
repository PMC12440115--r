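---
title: "Deriving AERMET surface meteorology from gridded forecasts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving AERMET surface meteorology from gridded forecasts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrrrmet)
```

## The problem

Steady-state dispersion models such as AERMOD and the R-LINE line-source
model consume hourly surface meteorology in AERMET's `.sfc` format:
twenty-seven fields per hour covering date, turbulent fluxes, stability
parameters, boundary-layer depths, wind, temperature, moisture, pressure
and cloud cover. Traditionally these files are produced by running the
AERMET preprocessor on weather-station observations, which ties every
receptor to its nearest station — often tens of kilometres away — and makes
the preprocessing itself a multi-stage chore.

`hrrrmet` instead derives the `.sfc` fields from an hourly, 3-km gridded
forecast product in the layout of NOAA's High-Resolution Rapid Refresh
(HRRR). Most AERMET fields map directly onto HRRR surface variables; the
few that do not (the convective velocity scale, the Monin-Obukhov length,
the Bowen ratio, albedo, wind direction) are computed from the fields that
are available, using the equations of the AERMOD formulation. On a 3-km
grid no site is ever farther than the cell half-diagonal,
$3000/\sqrt{2} \approx 2{,}121$ m, from a forecast cell center.

## The three preparation scenarios

**Scenario 1 — direct derivation.** Every field is taken or computed
directly from the hourly forecast variables:

* Sensible heat flux $H$, friction velocity $u_*$, surface roughness
  $z_0$, wind speed, 2-m temperature (converted to Kelvin), relative
  humidity and 1-h precipitation pass through. The planetary boundary
  layer height stands in for the convective mixing height $Z_{ic}$, and
  the equilibrium-level geopotential height for the mechanical mixing
  height $Z_{im}$ (a proxy carried through verbatim, without
  reinterpretation).
* The convective velocity scale is
  $w_* = \left( \dfrac{g \, H \, Z_{ic}}{\rho \, c_p \, T_{ref}} \right)^{1/3}$
  with $g = 9.8$ m/s², $\rho = 1.293$ kg/m³, $c_p = 1004$ J/(kg·K) and
  $T_{ref}$ the 2-m temperature in Kelvin. The cube root is real only for
  $H > 0$; stable hours are emitted as the AERMET missing sentinel −9.
* The Monin-Obukhov length is
  $L = \dfrac{\rho \, c_p \, T_{ref} \, u_*^3}{k \, g \, H}$, $k = 0.4$.
  **Sign convention:** this expression carries no leading minus sign, so
  $L > 0$ on convective (daytime, $H>0$) hours — the opposite of the
  textbook micrometeorology convention in which daytime $L$ is negative.
  It is implemented exactly as written because the downstream AERMET
  convention it reproduces behaves that way; users comparing against
  surface-layer literature should negate. Near-neutral hours with
  $|H| < \varepsilon$ (default $10^{-6}$ W/m², configurable) return the
  +8888 sentinel rather than dividing by zero.
* Wind direction is
  $\mathrm{WD} = \left(180 + \frac{180}{\pi}\arctan2(u, v)\right) \bmod 360$,
  the meteorological "blowing from" direction. Calm hours ($u = v = 0$)
  are reported as 0 with a logged count.
* Albedo is 1 at night; in daytime it is the reflected fraction
  $(\mathrm{SW}\!\downarrow - \mathrm{SW}\!\uparrow)/\mathrm{SW}\!\downarrow$,
  clamped to $[0,1]$ because instrument- or model-level noise can report
  more reflected than incoming radiation.
* The Bowen ratio is $|H / \lambda E|$. Hours with exactly zero latent
  heat flux would be infinite, so they fall back to the location's series
  median of $|H/\lambda E|$, computed in a first pass over all non-zero
  hours and applied in a second pass.
* Cloud cover becomes a decile, $\lfloor \% / 10 \rfloor$. Pressure is
  written as Pa/10, exactly as specified for the target format even
  though that yields tens of pascals rather than millibars; this is
  deliberate and flagged here so nobody "fixes" it silently.
* The vertical potential temperature gradient has no forecast proxy and
  is not used by R-LINE; it is fixed at the −9 missing sentinel. The
  precipitation type code is fixed at 11 (liquid), the wind measurement
  height at 10 m, the temperature height at 2 m, the ASOS wind adjustment
  flag at `NAD` (no ASOS data is involved) and the substitution flag at
  `NoSubs`.

**Scenario 2 — physical bounds.** Raw $H$ is clamped to $[-64, 800]$
W/m², latent heat to $[-100, 800]$ W/m², $u_*$ and $z_0$ to $[0, 2]$, and
$Z_{ic}$ capped at 4000 m. $w_*$ and $L$ are then *recomputed from the
clamped inputs* and themselves clamped to $[0, 2]$ and $[-8888, 8888]$;
the Bowen ratio is limited to $[-10, 10]$. Clamping is idempotent, and on
inputs whose raw *and* derived values already lie inside the bounds
Scenario 2 reproduces Scenario 1 exactly. Note the second condition is
not implied by the first: $|L|$ diverges as $H \to 0$, so any series in
which the heat flux crosses zero (every real dawn and dusk) will see the
$L$ clamp engage even with perfectly plausible raw inputs.

**Scenario 3 — CBL/SBL split.** Hours are classified by the visible beam
downward solar flux: flux $> 0$ is daytime/convective (CBL), flux $\le 0$
(zero at night, and any small negative noise) is stable (SBL). On CBL
hours the sensible heat flux is replaced by the surface energy-balance
residual
$H = (\mathrm{SW}\!\downarrow + \mathrm{LW}\!\downarrow - \mathrm{SW}\!\uparrow - \mathrm{LW}\!\uparrow) - G - \lambda E$,
and $w_*$ and $L$ are recomputed from it, all under the same Scenario-2
bounds. SBL hours retain their Scenario-2 values byte for byte. Only $H$,
$w_*$ and $L$ are touched on CBL hours; the Bowen ratio and albedo keep
their Scenario-2 values, since the split is defined as a recalculation of
the stability parameters alone. The latent heat flux entering the energy
balance is the Scenario-2-clamped one (the split is defined *on top of*
Scenario 2); the four radiation components and the ground heat flux have
no stated bounds and enter raw.

## Ingest: grids, precipitation, gaps

The analysis-hour (f00) files carry every variable except that their
precipitation is identically zero; the one-hour forecast (f01) carries
forecast rainfall. `merge_precip()` therefore takes everything from f00
and only `precip_1h` from f01, matched by timestamp, and refuses
mismatched hour sets.

Missing hours are repaired by `fill_missing_hours()`: each gap hour copies
the nearest earlier observed hour, walking back at most `max_backtrack`
hours (default 6). The cap prevents a long outage from being papered over
with a stale copy; hours beyond it are flagged `unfillable` and excluded
from `.sfc` output with a logged count. Filling a complete series is a
no-op, and refilling a filled series changes nothing.

Timestamps are UTC throughout ingest; conversion to the local standard
time conventional in `.sfc` files happens once, in the record builders,
via an integer UTC offset. Hours are labeled hour-ending, local hours
00–23 mapping to the 1–24 range the format requires.

`select_grid_cell()` matches a site to its nearest cell center —
great-circle distance for latitude/longitude grids, Euclidean for
projected ones. Production HRRR uses a Lambert conformal grid; synthetic
test grids are planar, which is sufficient for the geometry being tested.

## The `.sfc` dialect

The exact column widths of AERMET-written files are not part of the format
contract, and AERMOD reads the file free-format. `write_sfc()` therefore
emits whitespace-delimited fields at fixed decimal precisions: $H$ and $L$
to 0.1; $u_*$, $w_*$ and $z_0$ to 0.0001; Bowen ratio and albedo to 0.01;
wind speed to 0.01 with direction in whole degrees; temperature, pressure,
humidity and the mixing heights to 0.1; precipitation to 0.01. One header
line carries the coordinates and station identifiers (defaulting to
"00000" when unknown). `read_sfc()` inverts the writer within those
precisions, tolerates arbitrary whitespace, and rejects malformed lines by
line number — it exists so externally produced, observation-based `.sfc`
references can be ingested for comparison. Compatibility with AERMET
19191's own fixed-column reader has not been verified against that binary.

## Evaluation statistics

Dispersion predictions in µg/m³ are converted to ppb with the factor 0.53
(molar volume 24.465 L/mol at 25 °C and 1 atm over the NO₂ molar mass
46.006 g/mol), hourly predictions are averaged to daily values, and
prediction/observation pairs are compared with:

* the coefficient of determination $R^2$ of the simple regression of
  observed on predicted values (equal to the squared Pearson
  correlation),
* Willmott's (1981) original index of agreement
  $d = 1 - \dfrac{\sum_i (P_i - O_i)^2}{\sum_i \left( |P_i - \bar O| + |O_i - \bar O| \right)^2} \in [0, 1]$.
  The refined $d_1$ variant is deliberately not used; the citation trail
  for this statistic points at the original. When both series are the
  same constant, $d$ is defined as 1 (perfect agreement).
* the relative IOA difference
  $100\,(d_{\mathrm{forecast}} - d_{\mathrm{obs}})/d_{\mathrm{forecast}}$,
  positive when forecast-driven meteorology outperforms station-driven,
* stratification by monitor-to-station distance into half-open bins
  $[0,2)$, $[2,10)$, $[10,20)$, $[20,35)$, $[35,\infty)$ km — half-open so
  every distance lands in exactly one bin, with the last bin closed on the
  left to honor its "$\ge 35$ km" definition. Strata pool all site-days
  (site-day counts, not site counts, are the natural $n$ here),
* multivariate OLS of a per-site statistic (IOA or its relative
  difference) on site covariates — land-use percentages, coordinates,
  station distance, elevation statistics, traffic volume, mean
  concentration — with t-test p-values flagged at $p < 0.05$ and no
  multiplicity correction, matching the flag-only reporting convention.
  Zero-variance and (near-)perfectly collinear covariates are rejected by
  name rather than silently dropped.

## The synthetic generator, and what it does not emulate

`generate_hourly_series()` emulates the statistical structure the
derivations assume: a clipped-sinusoid diurnal solar cycle modulated by
season and a beta-distributed clearness (so convective and stable hours
both occur every day), temperature and sensible heat correlated with the
solar flux, nighttime heat flux mildly negative, plausible flux, wind,
humidity, pressure and boundary-layer-height ranges, occasional
zero-latent-heat hours (exercising the Bowen median fallback), values
pushed outside the physical bounds at a configurable rate (default 2%),
and listed missing hours. A single integer seed governs all randomness.

Default problem sizes used in the tests — a synthetic year of 8,760 hours
for round-trip checks, roughly 10,000 fuzzed hours for bound containment,
1,000 hours for closed-form recovery, 200 sites for coefficient recovery,
10,000 sites for grid geometry — were chosen as the smallest sizes at
which the properties are sharp.

What the generator does *not* emulate: HRRR's spatial covariance and
Lambert projection (cells are independent, grids planar), realistic cloud
/ radiation coupling, precipitation persistence, or model biases of a real
forecast system. Passing tests therefore demonstrate the correctness of
the derivations, bounds, format and statistics — not that any particular
forecast archive is accurate. The headline comparison of forecast-driven
versus observation-driven dispersion skill requires external monitor,
traffic and archive data and is out of scope here.

For the geometry stress test, note that uniform random sites essentially
never land within 1 m of a cell-diagonal midpoint (the region where the
nearest-center distance exceeds $2{,}120.3$ m occupies a few square metres
per 9 km² cell), so the test's site sampler mixes uniform sites with
sites scattered within 10 m of randomly chosen diagonal midpoints. That
is a designed stress sample, still fully seeded.

## Numerical and degenerate-input choices

* $c_p$ enters as 1004 J/(kg·K); with $\rho$ in kg/m³ this is the only
  dimensionally consistent choice yielding $w_*$ in m/s.
* $w_*$ at $H \le 0$: −9 sentinel (real cube root undefined); at
  $H \to 0^+$ it tends to 0 continuously.
* $L$ at $|H| < \varepsilon$: +8888 sentinel, chosen to coincide with the
  upper physical bound so bounded records remain bounded.
* Albedo clamped to $[0,1]$; cloud percent clamped to $[0,100]$ before
  the floor; calm winds get direction 0 with a logged count.
* The Bowen median fallback is computed per scenario from that scenario's
  (possibly clamped) inputs, keeping each scenario self-contained.
* Ties at bin edges: distance bins are half-open on the right, so 2, 10,
  20 and 35 km fall in the higher stratum; 35 km is in "$\ge$ 35 km".

## Known limitations

* No GRIB2 reader is bundled: ingest consumes the column-per-variable
  table format keyed by the verbatim HRRR inventory description strings
  (see `hrrr_variable_registry()`), which is also the registry a GRIB2
  extraction would use. Wiring that registry to an external GRIB decoder
  is left to deployment.
* Upper-air (`.pfl`) profiles, AERMET input decks, sub-hourly data and
  precipitation-type inference are out of scope.
* The equilibrium-level geopotential height is an unusual proxy for the
  mechanical mixing height; it is passed through without reinterpretation,
  so its plausibility is the upstream product's responsibility.
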