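---
title: "Estimating potato tuber mass from chamber CO2 dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating potato tuber mass from chamber CO2 dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tubertrace)
```

## The model and its assumptions

Potato tubers store carbon almost entirely as starch, a polymer of the
monomer C~6~H~10~O~5~. The package describes tuber growth through a chain of
four lumped photosynthesis stages: light energy is stored in ATP via
chlorophyll; glucose is synthesised in the canopy from CO~2~ and water; in
the tuber, glucose is either respired back (releasing ATP) or polymerised
into a starch monomer using that ATP. `stage_reactions()` bundles these as
reaction objects, and `derive_net_stoichiometry()` combines two units of
glucose synthesis with one respiration and one polymerisation, cancelling
glucose and closing the ATP budget:

```{r}
derive_net_stoichiometry()
```

Six CO~2~ molecules are consumed per stored monomer. From there, three
identities connect gas state to harvestable mass: starch mass is monomer
mass m~1~ times monomer count; tuber fresh mass is starch mass divided by
the varietal starch fraction eta (10--25 %, default 0.2); and in a sealed
chamber of volume V the absorbed molecule count is exactly
V (n(0) - n(t)), with n the CO~2~ number concentration.

The model's central assumption is that *all* environmental influence
(light, temperature, humidity) is already encoded in the measured CO~2~
dynamics: the package never models photosynthetic response surfaces, only
the carbon bookkeeping downstream of the measured trace.

### Stoichiometric modes

The published form of the rate equation multiplies the CO~2~ drawdown by
six, whereas the net reaction stores one monomer per *six* CO~2~; the two
readings differ by a factor of 36. Rather than silently picking one, the
estimators expose a `mode` switch on `plant_params()`:

* `mass_balance` (default): f = m~1~/(6 eta) kg tuber per molecule, the
  elementally conserving reading of the net reaction. In this mode the
  starch mass gained equals (162.14/264.06) of the CO~2~ mass absorbed --
  the molar-mass ratio of one monomer to six CO~2~ -- which is asserted in
  the test suite.
* `as_published_drawdown`: f = 6 m~1~/eta, the literal printed drawdown
  formula.
* `as_published_flux`: the integral leaf-flux variant, applying 6/eta
  directly to the absorbed CO~2~ *mass* (thereby dropping the
  m~1~/m~CO2~ ratio present in the drawdown formula); it is kept as its
  own mode precisely because it is not algebraically equivalent to the
  former.

Both `as_published` modes emit a warning whenever used, and at any fixed
input the final masses order as as_published_drawdown >= as_published_flux >= mass_balance. Which mode
produced the published 7.82 kg verification figure cannot be settled
without the untabulated absorption-rate curve behind it, so the package
asserts neither; the comparison ratio itself is reproduced exactly:

```{r}
compare_to_observation(7.82, 5.24)
```

### Partition correction

A sealed-chamber drawdown credits *all* absorbed carbon to tubers, but the
plant also builds stem, leaves and roots and spends carbon on metabolism.
The correction divides the predicted mass *increment* by a partition ratio
rho (whole-plant biomass : tuber biomass; `PARTITION_RATIO_20_24C` = 1.46
at 20--24 degC). The increment, not the total, is scaled because the
planting mass m~tubers~(0) is measured, not predicted. Default is 1 (off):
the ratio is a literature constant for one temperature band, not a law.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `eta_starch` | -- | 0.2 | mid varietal range; warns outside 0.10--0.25 |
| `m_tubers0` | kg | 0 | seed tuber mass at planting (0.225 in the worked verification) |
| `partition_ratio` | -- | 1 | off unless the user opts into the 1.46 correction |
| `volume` | m^3^ | -- | chamber volume; drawdown scales with 1/V |
| `temperature`, `pressure` | K, Pa | 295.15, 101325 | ideal-gas ppm conversion; constant per run |
| `leak_coefficient` | 1/s | 0 | first-order relaxation towards ambient |

All internal arithmetic is SI (kg, m, s, K, Pa); ppm, grams and days appear
only at the I/O layer. Gas conversions use the exact SI Boltzmann and
Avogadro constants and assume ideal-gas behaviour -- real-gas corrections
are far below sensor noise at greenhouse conditions. Atomic weights are a
bundled IUPAC table, so molar masses never depend on an external service.

## Unsealed chambers

The sealed balance extends to leaky chambers by crediting two exchange
terms before attributing drawdown to the plant:
absorbed(t) = V (n(0) - n(t)) + injected(t) - leaked(t), with
leaked(t) = k V times the time integral of (n - n~ambient~) and injections
counted as instantaneous impulses (well-mixed assumption; a ramped
injection is several impulses). The first-order leak law is the simplest
model consistent with a small over-pressure of CO~2~ relative to ambient;
k is a user input, though `estimate_leak_coefficient()` offers a log-linear
fit from a plant-free decay trace as convenience plumbing. No pressure
-driven advection or multi-zone exchange is modelled.

## Numerical choices

* **Quadrature.** Cumulative integrals (leaf flux, leak) use the composite
  trapezoid rule on the native sample grid -- exact for piecewise-linear
  integrands, second-order otherwise, and free of resampling artefacts.
* **Reaction algebra.** Coefficients are exact integer rationals, so stage
  cancellation yields exactly zero, never a floating-point residue.
  ATP and the light-energy term are opaque tokens: they pass through the
  algebra but are excluded from the elemental ledger (the chlorophyll
  stage is bundled for completeness and is quantitatively inert).
* **Negative drawdown.** Nighttime respiration raises chamber CO~2~; the
  raw signed mass estimate is retained (so integrated quantities stay
  consistent) and `clamp_nonnegative()` provides the floored reporting
  view. Series with net-release segments are flagged.
* **Ties and degenerate inputs.** Estimation requires >= 2 samples;
  strictly increasing timestamps are enforced at construction; a leaky
  chamber spec passed to the sealed estimator is an error pointing to the
  unsealed path rather than a silent wrong answer.

## What the simulator emulates -- and what it does not

`simulate_chamber()` steps dn/dt = -A(t)/V - k (n - n~amb~) with explicit
Euler at a 60 s default step, plus impulse injections, absorption saturating
at the CO~2~ actually available, and i.i.d. Gaussian sensor noise in ppm
under a recorded seed. The forcing A(t) is a minimal construction: peak
whole-plant uptake A~max~ scaled by a logistic canopy-growth multiplier and
a photoperiod square wave, with dark respiration as a fraction of uptake.
The default scenario is a 20-day tuber-formation run in a sealed 40 m^3^
chamber at 22 degC, 1200 ppm initial CO~2~, A~max~ = 1.2x10^18^
molecules/s, 6-day canopy half-time, 16 h photoperiod, 10 % dark
respiration, 2 ppm noise -- values chosen to produce a realistic day/night
sawtooth drawing the chamber down by several hundred ppm over the period,
at the scale of the single-plant verification experiment (0.225 kg seed
tuber, 0.38 m^2^ leaf area). Explicit Euler was chosen over an adaptive
solver because it is transparent, exactly testable against closed forms
(constant forcing gives a linear drawdown to machine precision), and
adequate for smooth forcing at this step size.

The ground-truth tuber series is computed from the *exactly* accumulated
absorption, never from the trace, so round trips test the estimators, not
the simulator against itself. What the simulator does **not** emulate:
mechanistic photosynthesis (light or temperature response), sensor drift or
calibration error, humidity effects, imperfect mixing. Passing round-trip
tests therefore demonstrates the correctness of the carbon bookkeeping, not
the fidelity of any plant model: with real data the dominant error sources
are sensor drift and the partition ratio, neither of which the synthetic
scenarios probe.

`bundled_flux_profile()` is a synthetic stand-in for a leaf-level
absorption-rate curve: a smooth 20-day hump with the verification
geometry's 0.38 m^2^ leaf area, scaled so the plant absorbs roughly a
quarter kilogram of CO~2~ over the period. It exercises the integral
estimator's interface; it is not a digitisation of any measured curve.

## Problem sizes used in validation

The test suite validates round trips at the full 20-day, 60 s-step scenario
(28,801 samples, runs in well under a second per simulation); the
noise-averaging check uses 100 seeds at a 900 s step, and the invariant
sweeps use 100 short random traces. The sealed round trip recovers truth
within 0.5 %, the unsealed one (leak 2x10^-5^ /s, two 2x10^23^-molecule
injections) within 1 %.

## Known limitations

* The starch fraction enters as a constant; real tubers change composition
  over the season.
* The partition ratio is a single-temperature literature constant, applied
  uniformly in time.
* Constant chamber T and P per run; per-sample columns are read but only
  their means are used.
* The sealed estimator uses only the trace endpoints, so a slow sensor
  drift translates one-to-one into mass error; no drift correction is
  attempted.
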