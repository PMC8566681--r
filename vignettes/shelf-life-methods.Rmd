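---
title: "Methods: induction periods, kinetics and shelf-life models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: induction periods, kinetics and shelf-life models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxistab)
```

## The measurement being modelled

Accelerated oxidative-stability instruments seal a few grams of oil in a
heated chamber under 600–800 kPa of oxygen and record the chamber pressure
for hours to days. Oxygen is consumed slowly while the oil's antioxidants
hold, then rapidly once autoxidation propagates; the elapsed time to that
change of regime is the induction period (IP). The package's analysis chain
is: detect IPs on pressure records, fit the temperature law, extrapolate to
ambient, and relate the resulting shelf-lives to the oil's fatty-acid
composition.

## Two-tangent induction-period detection

`two_tangent_ip()` defines the IP as the time where the baseline tangent
intersects the tangent at the steepest-descent point:

1. compute a smoothed derivative by moving local-linear fits
   (`smoothed_derivative()`), window `max(5 samples, 0.5 h / dt)` — local
   least-squares slopes rather than finite differences so the derivative
   remains usable at realistic noise levels;
2. take the steepest-descent time `t*` as the minimum of the smoothed
   derivative, earliest sample on ties (making detection deterministic);
3. fit the descent tangent over `±max(5, 1%)` samples around `t*`;
4. fit the baseline tangent over `[5%, 50%]·t*` — the first 5% of the
   record is skipped because real instruments show equilibration
   transients as the chamber reaches temperature;
5. intersect the two lines; report the time to 2 decimals, the precision
   at which IP tables are conventionally printed.

An onset only counts if the two tangent slopes differ by at least
`min_slope_separation` (default 1 kPa/h); a flat or baseline-only record
therefore raises "no oxidation onset detected" rather than returning a
spurious intersection. When a run limit is configured (`censor_at`,
instruments of this class cap runs at 240 h), a missing or too-late onset
yields a *censored* measurement — flagged, never silently dropped, and
excluded from kinetic fits with a warning.

**Accuracy domain.** On noiseless simulated curves the detector recovers
the closed-form IP within 1% whenever the onset is sharp relative to the
induction time (steepness `s ≥ 0.5 /h` at the default 0.05 h sampling).
When the IP shrinks toward the sigmoid's own width (`s·IP` below roughly
10, e.g. an IP of 2–3 h at `s = 1`), the pre-onset record is too short for
a clean baseline fit and the error grows; simulating such conditions
requires a proportionally steeper onset.

## The curve simulator and its ground truth

`simulate_curve()` generates

\[ P(t) = p_0 - m_1 t - \frac{d}{1 + e^{-s (t - t_c)}} + \varepsilon_t,
\qquad \varepsilon_t \sim N(0, \sigma^2), \]

a linear baseline (slope `m1`, kPa/h) plus a logistic consumption phase
(total drop `d` kPa, steepness `s` /h, centre `t_c` h). Published records
of such instruments are not available as raw data; the logistic form is
this package's choice because it captures the "sudden change in the rate
of oxygen consumption" that defines the IP while admitting an exact
ground truth: intersecting the baseline line with the tangent at the
steepest point of the noiseless curve gives

\[ \mathrm{IP}_{\text{true}} = t_c - 2/s, \]

independent of `d` and `m1` (the tangent at `t_c` has slope
`-m1 - sd/4` and sits `d/2` below the baseline; the offset is
`(d/2)/(sd/4) = 2/s`). Defaults: `p0 = 800` kPa (the upper setpoint of the
instrument class), `dt = 0.05` h, `noise_sd = 0.5` kPa (≈0.06% of `p0`),
chosen so that detection error stays below the 2-decimal print precision
of IP tables. Noise is additive, homoscedastic and seeded; identical seeds
reproduce curves bit for bit. Heteroscedastic noise, chamber
thermodynamics, sample-mass effects (negligible in instrument
optimisation studies) and any oxygen-pressure→IP coupling are *not*
modelled; passing tests on simulated curves therefore validates the
detection geometry and the pipeline plumbing, not instrument physics.

`simulate_temperature_series()` places `t_c = 10^(log\_ip0 - k_0 T) + 2/s`
so the ground-truth IP follows a prescribed temperature law exactly, and
extends each record to at least `1.5·t_c`.

## Kinetics and the day-rounding convention

`fit_kinetics()` regresses `log10(IP)` on temperature in °C. The law is
called "zero-order Arrhenius" in the oxidative-stability-index literature
even though temperature enters linearly in °C, not as reciprocal kelvin;
the package implements the convention as printed, with base-10 logarithms
(required to reproduce published intercepts). R² is the squared Pearson
correlation of log10 IP with temperature, identical to the regression R²
for a simple OLS fit.

Two deliberate precision conventions, both verified against the packaged
reference tables:

- **Parameters are stored at 4 decimals** (`log_ip0`, `k0`; full-precision
  copies in `log_ip0_full`, `k0_full`). Published shelf-life tables are
  computed from the 4-decimal parameters: extrapolating from
  full-precision fits changes four of the twenty reference day counts by
  ±1 day, while the 4-decimal path reproduces all twenty.
- **Hours are rounded to whole hours before the day conversion**
  (`hours_to_days()`: round half away from zero, divide by 24, round half
  away from zero). The plain `round(h/24)` rule disagrees with one
  reference cell (an extrapolated 13523.84 h → 563.49 days printed as
  564); rounding to 13524 h first gives 563.5 → 564 and reproduces every
  reference day count.

`extrapolate_shelf_life()` only extrapolates *downward* in temperature —
asking for a temperature inside or above the fitting range is an error,
because the accelerated-test design has no support there. Censored IPs are
excluded from fits with a warning; at least three distinct temperatures
are required.

## Composition metrics

Saturation classes are derived from the double-bond count encoded in the
`Cx:y` code (SFA: y = 0, MUFA: y = 1, PUFA: y ≥ 2, UFA = MUFA + PUFA), so
new codes extend the classes without a lookup table. The calculated iodine
value is the standard weighted sum over unsaturated acids (coefficients
0.95, 0.86, 1.732, 2.616, 0.785, 0.723 for C16:1, C18:1, C18:2, C18:3,
C20:1, C22:1); applied to the packaged compositions it reproduces all ten
reference iodine values to ±0.1. `ND` (not detected) entries are read as
zero, consistent with how the reference class sums were formed; totals may
exceed 100 by at most 1 unit to absorb rounding of printed inputs.

## Correlation screen and grouped regression

`oil_records()` assembles one row per oil: computed class aggregates and
iodine value, reported shelf-lives, smoke point, acid value, the group
indicator, and log10 IPs at 70/90/100 °C. Pumpkin seed oil is excluded by
default (its chlorophyll content makes it an outlier in the
shelf-life–composition relationship). One oil's 70 °C IP is censored; its
log IP cell is filled from the oil's reported kinetic law — the
substitution that regenerates the reference correlation rows exactly — and
flagged in `log_ip_filled`.

`pearson_with_significance()` is the standard two-tailed t-test on
`n − 2` degrees of freedom. No multiple-testing correction is applied
across the screen, matching how such tables are reported.
`fit_grouped_model()` fits `y = b0 + b1·X1 + b2·X2` by OLS; overall
significance is the F-test with `(2, n − 3)` degrees of freedom, which is
the (unstated) test that reproduces the reference p-values. The X₂
assignment is *data*, shipped with the reference tables: it encodes the
two-curve structure of the shelf-life–UFA scatter, attributed to
tocopherol-profile differences that are not quantified as predictors here,
and the package makes no attempt to infer it. `predict_shelf_life()` uses
unrounded coefficients and flags negative predictions rather than clamping
them.

Two reference cells do not reproduce and are flagged by
`reproduce_tables()` rather than asserted:

- the acid-value correlation row (computed −0.068/−0.079 vs reported
  −0.089/−0.100) cannot be regenerated from the reported acid-value table
  at any input precision we tried — most plausibly the original
  computation used unpublished replicate-level values;
- one coefficient of the SFA/20 °C model (computed group offset 599.31,
  reported 600; its multiple r = 0.8374 and p = 0.0266 reproduce exactly),
  consistent with a rounding slip in the reported equation.

## Problem sizes and numerical choices

The validation suite runs entirely at desk scale: detection accuracy is
established on single simulated curves (~1200–2700 samples), the
stochastic error bound on 200 seeded noisy replicates (median relative
error < 1%, maximum < 5% at default noise), and the end-to-end pipeline
on three-temperature series — a few seconds each on one CPU. The grouped
regression is cross-checked against a direct normal-equations solve on
randomized 6–15-point designs to 1e-9 relative agreement. Ties in the
steepest-descent search break to the earliest time; all seeded runs are
reproducible bit for bit.

## Known limitations

- The simulator's logistic form is a stylised stand-in for real oxidation
  curves; conclusions about detection accuracy transfer to instrument data
  only insofar as real onsets are comparably sharp.
- Shelf-life extrapolation carries no confidence interval (three-point
  fits leave one residual degree of freedom; none is reported in this
  literature).
- The prediction models are calibrated on nine oils; they interpolate
  within that composition range and the two predefined oil groups, and the
  group label of a new oil must be supplied, not inferred.
- Pressure-setpoint effects on the IP (600 vs 800 kPa) are documented for
  the instrument class but no quantitative coupling is modelled; `p0` is a
  bookkeeping parameter.
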