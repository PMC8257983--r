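---
title: "Methods: geolocator tracks, stopover segmentation and wind support"
author: "swiftmigr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geolocator tracks, stopover segmentation and wind support}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swiftmigr)
```

# Scope

`swiftmigr` implements an analysis pipeline for long-distance bird migration
recorded by light-level geolocators (GLS), exercised end to end on synthetic
data with planted, analytically known properties.  The pipeline has five
stages: (1) geolocation of light series by the threshold method, (2)
stopover segmentation of daily-position tracks, (3) per-bird route metrics
and paired seasonal statistics, (4) altitude-resolved tailwind annotation
against gridded pressure-level winds, and (5) a departure-date
counterfactual that asks how much wind support a bird gained by departing
on its actual date rather than up to three days earlier or later.

Real GLS archives for northern-breeding common swifts (*Apus apus*) are not
publicly deposited, and reanalysis wind archives are not downloadable in an
offline build, so the package ships a first-class synthetic-data generator
that emulates the study design: cohorts of 19 (autumn) and 20 (spring)
birds migrating between Swedish Lapland (~67.8 N, 20.3 E) and sub-Saharan
Africa (~5.5 N, 17.5 E), observed at one position per day with
geolocator-scale noise, latitude gaps around the equinoxes, and structured
wind fields.  Every downstream stage is validated against the generator's
closed forms or an independent oracle.

# Threshold geolocation

**Model.** Light is thresholded into day and night.  Sunrise and sunset are
the interpolated crossings of the light threshold; a sunrise-sunset pair
gives solar noon (the midpoint, corrected by the equation of time) and day
length; a sunset-sunrise pair gives solar midnight and night length.
Longitude follows from noon (or midnight) at 15 degrees per hour.  Latitude
solves the sunrise equation
`cos(z0) = sin(phi) sin(delta) + cos(phi) cos(delta) cos(H)` for the
half-day hour angle `H` implied by day length, with `delta` the solar
declination and `z0` the sun zenith angle of the calibrated threshold.  The
solar ephemeris (declination, equation of time) uses Spencer's
low-precision Fourier fits (~0.3 degrees and ~1 minute), ample because GLS
positional noise is one to two orders of magnitude larger.

**Parameters.** `zenith` (degrees, default 93): a civil-twilight-like value
typical of GLS threshold calibrations; deployment-specific calibration
protocols are rarely reported in enough detail to reproduce, so the value
is exposed in `geolocation_config()` rather than automated (no Hill-Ekstrom or
template-fit calibration; those are out of scope).  `threshold` (sensor
units, default 32, midway between the synthetic low/high levels).
`equinox_window` (days, default 10): latitudes within this calendar window
of Mar 20 / Sep 22 are reported unknown.  A calendar window was chosen over
a declination cutoff because daily-resolution tracks make sub-day equinox
timing irrelevant; the same window also implies the declination dead zone
used when a twilight pair is positioned directly.

**Numerical choices.** Up to two fixes per calendar day (day-side and
night-side) are averaged, with a circular mean for longitude so that
antimeridian fixes average correctly; fixes are assigned to calendar days
in local solar time at the previous fix's longitude (UTC for the first).
When the sunrise equation has two in-range roots the equator-side branch is
taken; when it has none the latitude is reported unknown rather than
clipped.  Equinox-flagged latitudes are linearly interpolated between the
flanking valid fixes (constant extension at track ends) *only* where
geometry is needed downstream - segmentation, route length, wind
annotation - and the interpolation is marked in the output.

# Stopover segmentation

A stopover ("restricted geographic movement") is a maximal run of at least
`min_days` consecutive days whose positions all lie within `radius_km` of
the run's iteratively updated spherical centroid, found by a single greedy
forward pass; all other days are travel.  Defaults: `radius_km = 200`
(the scale of GLS daily scatter) and `min_days = 2` (the shortest stopovers
reported for tracked swifts).  Residency criteria are rarely
reported in full in GLS studies, so this rule is an explicit, configurable
choice of this package, stated as such.

Two refinements proved necessary on noisy data and are part of the design:

* **Merge pass.** A single noisy fix splits one true residency into two
  adjacent runs.  Consecutive stopover runs separated by at most
  `max_merge_gap = 1` day whose centroids lie within `radius_km` of each
  other are merged, the gap day reassigned to the stopover.  Without it,
  recovered stopover counts are biased upward by about one split per
  two birds at default noise.
* **Boundary convention.** The day a bird arrives at a stopover site cannot
  be distinguished from residency in daily positions, so boundary days
  belong to the stopover segment.  Correspondingly, the generator's ground
  truth counts a residency as its stationary days plus the arrival day, and
  the migration summary counts the final arrival day as travel (the flight
  into the destination), which is what makes a 15 Aug to 26 Sep migration
  with a 22-day stopover come out as 42 = 20 travel + 22 stopover days.

Segmentation quality is measured as stopover-count and stopover-duration
mean absolute error (MAE) against the script of 100 simulated birds (50 per
season) at default noise.  This benchmark deliberately disables the equinox
mask: equinox-induced latitude interpolation error is a property of the
*geolocation* stage (and of the GLS method itself), and folding it into the
segmentation benchmark would measure the wrong component.  With the mask
on, autumn tracks crossing the Sahara near the September equinox show
degraded in-window segmentation, exactly as real GLS studies do.

An autumn stopover whose centroid lies north of `initial_lat_cutoff = 55`
degrees is flagged "initial" (the brief post-departure fueling stop); a
spring stopover beginning on the first track day is flagged likewise.
Initial stopovers are excluded from the migration-speed denominator but not
from stopover-day totals.

# Route metrics

All geometry is spherical with radius 6371.0 km: haversine distances,
spherical initial bearings, and spherical-linear interpolation along legs.
An ellipsoid would change distances by ~0.3%, far below GLS noise, and
consistency matters more than absolute accuracy because the detour is a
ratio of route length to great-circle distance.

Conventions, chosen so that the usual migration-characteristics arithmetic
comes out consistently: `total_days` is the *difference* of arrival and
departure dates (15 Aug to 26 Sep = 42; 14 May to 29 May = 15);
`travel_speed = distance / travel_days`;
`migration_speed = distance / (total_days - initial_stopover_days)`;
`percent_flight = 100 travel_days / total_days`.  Departure is the first
day of the first travel segment; arrival is the first day of the terminal
residency.  Barrier-crossing durations count days between first entry and
first exit of a latitude band in the travel direction, with and without
in-band stopover days.

Paired seasonal comparisons use the paired t test and the Wilcoxon
signed-rank test (statistic V, the sum of ranks of positive differences;
19 all-positive pairs give V = 19*20/2 = 190), with differences oriented
autumn minus spring, plus a sign-flip permutation alternative.  Mixed-effects
likelihood-ratio modelling of these quantities is deliberately out of
scope; the permutation analogue preserves the paired per-bird structure
instead.

# Wind support

Winds are gridded u (eastward) and v (northward) components on longitude x
latitude x pressure level x time, the reanalysis component convention (the
velocity air moves toward).  Sampling interpolates multilinearly in
longitude, latitude and time and linearly in log-pressure, with no
extrapolation outside the hull.  The tailwind/crosswind decomposition along
a track azimuth `a` is `Vt = u sin a + v cos a`, `Vc = u cos a - v sin a`,
preserving magnitude.

Each flight step joins two consecutive travel days; wind is sampled at the
step's spatial midpoint at 12:00 UTC of the step date (daily GLS positions
carry no time of day; the midpoint/noon choice is symmetric and
config-overridable).  The selected flight level is the tailwind argmax over
levels within 1000-500 hPa - the 500 hPa cap corresponds to ~5,500 m, the
highest flight altitudes reported for migrating swifts - with exact ties
broken toward the highest pressure (lowest altitude).  The
tailwind-maximising level is taken as the predicted flight altitude; other
definitions (e.g. energetic optima) are possible and out of scope.
Altitudes attach to pressure levels via the International Standard
Atmosphere troposphere inversion (1013.25 hPa -> 0 m, 500 hPa -> 5574 m).
The assumed airspeed (10.6 m/s) is used only to report tailwind:airspeed
ratios and never enters selection.

# Departure counterfactual

For offsets -3..+3 days the entire schedule (track dates and segment dates)
is shifted; the spatial route is reused unchanged (no re-routing under
counterfactual winds).  Per-step tailwinds are binned by step-midpoint
latitude (5-degree bins) and each offset is differenced against offset 0
per bird and bin; the per-bin summary averages over birds and the six
nonzero offsets.  Negative values mean the actual departure date gave
better en-route winds.  "Average over the six nonzero offsets" is one of several reasonable
summaries and is fixed and stated here.
Empty bird/offset/bin combinations are kept as explicit `n = 0` rows with
`NA` values, never as zeros.

The departure-location test samples the tailwind each bird would have met
at its departure point, on each offset date, along its first-step azimuth
at the best allowed level, and applies a sign-flip permutation test: each
bird's whole difference vector keeps or flips its sign, and the statistic
is the sum of squared per-offset mean differences.  A squared omnibus
statistic is used because offset effects need not share a sign (a temporal
ramp moves opposite offsets in opposite directions, which a mean-difference
statistic cannot see).  The seasonal wind gain is
`100 (mean_spring - mean_autumn) / mean_autumn` over occupied bins in the
25-55 degree band; a seasonal gain can be defined as a ratio of band
means, of per-bird means, or of model estimates; the band-mean definition
is fixed and documented here, and a non-positive autumn mean yields an
explicit "undefined" result.

# The synthetic generator: what it emulates and what it does not

**Tracks.** True positions follow great-circle legs at constant per-leg
daily displacement and hold station during scripted stopovers.  The default
autumn scenario (19 birds, departure 15 Aug with 10-day between-bird SD)
runs southeast across the Baltic - with a short optional initial stopover
north of 55 N, present with probability 6/19, the frequency reported for tracked
northern swifts -
then via central Europe and Iberia, a Sahel stage, and arrival ~40 days
after departure; the spring scenario (20 birds, departure 14 May, 6-day SD)
crosses directly to a single Mediterranean stopover and arrives 15 days
after departure.  Leg speeds are 450-800 km per flight day, matching the
reported travel-speed range; stopover durations are fixed per scenario
(between-bird duration variation is not emulated).

**Observation model.** Observed positions are true positions plus
independent Gaussian noise per day, default SD 1.0 degree latitude and 0.5
degree longitude - conventional magnitudes for GLS daily fixes, exposed in
the scenario rather than hard-coded because the original error magnitudes
are unstated.  No autocorrelation, shading artifacts, or habitat effects
are emulated; passing recovery tests therefore show correctness of the
estimators under the stated noise model, not robustness to real-world GLS
pathologies.  Latitudes within the equinox window are masked, emulating the
published tracks' "unknown latitude" days.

**Winds.** Fields are closed-form: per-component base + linear spatial
gradients + linear temporal ramp + a pressure-Gaussian jet + an optional
latitude-travelling Gaussian pulse.  Autumn defaults plant a modest
southward jet at 850 hPa (~1460 m, tailwind ~2-3 m/s for southbound birds);
spring defaults plant a strong northward jet at 700 hPa (~3010 m, ~8 m/s)
plus a poleward-travelling pulse locked to the scheduled passage.  These
reproduce the qualitative study conditions - weaker, lower autumn support;
stronger, higher spring support.  No realistic atmospheric physics is
attempted.  One shared field serves the whole cohort, so with departure
jitter the travelling pulse decouples from individual schedules and the
cohort-level counterfactual signal is attenuated; the clean ground-truth
case for the counterfactual is the single-bird `planted_advantage_scenario()`,
whose pulse tracks the one scheduled passage exactly and makes the actual
departure date provably optimal at every latitude.

**Light.** Step-function light from the solar ephemeris, including polar
day/night as all-high/all-low days.  Clouds and shading are not emulated,
so geolocation round-trip tolerances (0.5 degrees latitude, 0.2 longitude)
reflect discretisation alone.

**Determinism.** One master seed; per-bird streams derive deterministically
from bird index, so identical (scenario, seed) pairs are byte-identical.

# Problem sizes and tolerances

The validation suite runs at these sizes, chosen to give stable Monte Carlo
estimates at interactive runtimes: oracle-equivalence sweeps (rotation,
interpolation, level selection) at 1000 random cases each (1e-12, 1e-9 and
exact agreement respectively); geolocation round trips at seven latitudes
0-60 with 1-minute sampling; stopover recovery on 100 birds (count MAE
bound 0.5, duration MAE bound 1.5 days); noise-free script recovery to
0.1%; counterfactual closed forms to 1e-6 with 100 sign-recovery
replicates; type-I error of the permutation and paired tests on >= 1000
null replicates against the bands 0.03-0.07 and 0.035-0.065.

# Known limitations

* The zenith calibration, residency criterion and equinox interpolation
  rules are choices of this package, exposed as configuration; other
  defensible choices exist and shift absolute (not relative) results.
* Segmentation near an equinox inherits interpolated-latitude drift; counts
  and durations for in-window stopovers are correspondingly less reliable.
* Route lengths computed from noisy daily fixes are inflated by the noise
  (each day adds a positive-length detour), as in any GLS study; detour
  percentages from noisy tracks are upper bounds on the scripted detour.
* The wind generator's one-field-per-cohort design cannot express
  individual wind selectivity except through the single-bird planted
  scenario.
* Movement-model smoothing, hidden-Markov segmentation, wind-drift
  compensation and flight energetics are out of scope.
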