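---
title: "Thick-target activation yields and radiopharmaceutical QC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thick-target activation yields and radiopharmaceutical QC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radioyield)
```

## The physical model

When a charged-particle beam traverses a target thick enough to degrade its
energy appreciably, the activation rate must be integrated over the energy
the beam loses inside the material. With particle flux $I_p$ (beam current
over charge state), target atom density $N_A f n / M$ per gram (molar mass
$M$ of the formula unit, $n$ reactive atoms per formula, isotopic atom
fraction $f$), excitation function $\sigma(E)$ and mass stopping power
$S(E)$, the end-of-bombardment activity of a product with decay constant
$\lambda$ after irradiating for time $t$ is

$$
A_{EOB} \;=\; \frac{N_A\, I_p\, f\, n}{M}\,\bigl(1 - e^{-\lambda t}\bigr)
\int_{E_e}^{E_0} \frac{\sigma(E)}{S(E)}\, dE ,
$$

where the exit energy $E_e$ solves $\int_{E_e}^{E_0} dE/S(E) = \rho\Delta x$
with $\rho\Delta x$ the areal density (pellet mass over beam-facing area).
The formulation assumes:

- the pellet fully intercepts a uniform beam (areal density = mass / pellet
  area; the default pellet diameter is 7 mm) — no radial beam model;
- continuous slowing down with no straggling or secondary-particle
  production;
- target composition constant through the irradiation (no burn-up, which is
  negligible at µA·hours).

Generalising the atomic weight to a compound molar mass with an explicit
enrichment factor is a deliberate design choice: oxide targets and enriched
materials are the practical case, and a pure element with $f = n = 1$
recovers the elemental form. Whether a given published calculation used the
elemental or compound convention is often unstated; both are expressible
here through the `material()` description.

## Numerical choices

**Interpolation contracts.** Excitation functions are piecewise-linear,
zero strictly below the first tabulated energy (reactions have thresholds)
and clamped to the last value above the grid — clamping avoids inventing
high-energy behaviour the table does not support. Stopping powers are
interpolated linearly in log–log space, where they are near power-law at
MeV energies, and extrapolation is refused outright: transport must stop at
the table edge rather than guess.

**Transport.** Under log–log interpolation every stopping-power segment is
an exact power law, so the range integral $\int dE/S$ has a closed form per
segment; the exit energy is then a one-dimensional root find
(`uniroot`, tolerance $10^{-9}$ MeV, well inside the $10^{-6}$ MeV contract
the tests assert against a $10^6$-step fine-grid oracle). When the residual
range at the table's lower edge is smaller than the areal density the beam
is declared stopped and $E_e = 0$; additional target mass beyond that point
leaves the yield unchanged, which the tests check to $10^{-9}$ relative.

**Yield integral.** $\int \sigma/S\,dE$ is split at every knot of either
table, so each piece is smooth, and evaluated by adaptive quadrature at
relative tolerance $10^{-10}$ per piece; agreement with a $10^6$-point
trapezoid evaluation is asserted to $10^{-7}$ relative. These tolerances
are orders of magnitude below the tens-of-percent uncertainty of simulated
nuclear data, so numerics never dominate.

**Units.** µA, MeV, mg and mm at every interface; cross-sections in
millibarn ($10^{-27}$ cm²), converted internally; activities in MBq.
Particle flux is $I/(ze)$ with $z = 1$ for deuterons.

## Co-production and inventories

Every open channel on every isotope of the target element is modelled as
its own excitation-function table; the inventory sums contributions per
product (a product fed by both (d,n) and (d,2n) channels accumulates both),
lists stable products with zero activity, and refuses reactions whose
target isotope is missing from the composition. Decay correction
$A e^{-\lambda \Delta t}$ with signed $\Delta t$ moves activities between
reference times; radionuclidic purity is reported as decay-corrected
fractions normalised to 1.

## Quality-control conventions

- **Carrier-free ceilings.** $\lambda N_A / M$ (TBq/mg) and $\lambda N_A$
  (MBq/nmol) bound any measured specific or molar activity from above; a
  measurement above the ceiling indicates an assay error, and the test
  suite treats a synthetic violation as a hard failure.
- **Apparent molar activity.** A decade-spaced chelator titration gives a
  staircase, not a point estimate. The estimator takes the smallest
  chelator amount whose bound fraction reaches a threshold (default 0.90,
  configurable), divides the spiked activity by it, and flags the result as
  a lower bound when even the smallest tabulated amount labels above
  threshold. A 50%-point convention would also be defensible; the threshold
  convention was chosen because labeling protocols state acceptance as
  ">90% bound", and with decade spacing either convention is quantised to
  within one decade, which is the precision the tests assert.
- **TLC yield.** A linear baseline is fitted through the region-free flanks
  of the lane and subtracted; the yield is the product region's share of
  the baseline-subtracted counts over all regions. Degenerate traces (no
  counts above baseline) are an error, not a 0/0.
- **SUV/SUVR.** SUV normalises concentration by the injected dose
  decay-corrected to scan start per gram of body mass, density 1 g/mL —
  the standard small-animal convention; whether a published value was
  decay-corrected or lean-mass-normalised is often unstated, so the
  convention is fixed and documented here. SUVR cancels dose, mass and
  decay by construction, which the tests assert as an invariance.
- The DOTA molar mass used for µg→nmol conversion is packaged as
  404.42 g/mol.

## What the synthetic generator emulates

No public repository provides the measured campaign logs or the simulated
nuclear-data tables this pipeline consumes, so the package generates every
input with known ground truth:

- **Excitation functions**: a smooth threshold-rise/peak/decline shape
  $\sigma \propto u^2 e^{2(1-u)}$, $u = (E - E_{thr})/(E_{pk} - E_{thr})$,
  optionally rescaled to pass exactly through a published single-energy
  cross-section (104.73 mb at 9 MeV for the (d,n) channel on Ca-42). The
  shape below the pinned energy is a stand-in: the true simulated curves
  are not tabulated in the open literature for this range.
- **Stopping powers**: $S(E) = a E^{-p}$ on a log grid, default
  $260\,E^{-0.8}$ so that $S(9\,\mathrm{MeV}) \approx 45$ MeV·cm²/g — the
  right scale for ~4.5 MeV/u deuterons in light-element oxides. With this
  default, Table-2-style setups (4.6–22.4 mg, 1–8 µA, ~8 h) produce EOB
  yields in the observed hundreds-of-MBq range.
- **Campaigns**: 23 runs drawn uniformly inside the published envelopes;
  "experimental" yields are the model yields times $(1 + b)$ times
  unit-mean lognormal noise. Defaults $b = -0.207$, CV = 0.1 mirror the
  reported ~20.7% model overestimate; lognormal noise is chosen because
  activities are positive and assay errors multiplicative. No noise model
  is reported for such campaigns; this one is the package's choice.
- **Titrations**: bound fraction is a sharp Hill-type step in the tube's
  labeling capacity; **TLC**: Gaussian peaks (default areas 9:1) on a
  linear baseline with Poisson counting noise; **ROI tables**: built
  backwards from prescribed SUVs so quantification round-trips exactly.

All randomness flows from one integer seed; fixture directories are
byte-reproducible. What passing tests show is therefore *internal
consistency*: the pipeline recovers known ground truth under a plausible
noise model. They do not validate the nuclear data themselves — real
excitation functions have structure the two-parameter shape lacks, real
stopping powers deviate from a single power law at the low-energy end, and
real TLC baselines are not exactly linear.

## Problem sizes

The test suite and the acceptance script run at the study's own scales:
23-run campaigns, 5-point titrations, 201-channel TLC traces, 50-point
stopping tables, 400-point excitation functions. The heavy oracles
(the $10^6$-step transport grid and $10^6$-point trapezoid) run once each;
the whole suite completes in a few seconds on one core.

## Known limitations

- No stacked-target transport, beam heating, or dose-rate estimation.
- Excitation-function shapes below the pinned energy are synthetic; users
  with real simulated tables should supply them as `xs_*.csv` files.
- The AMA estimator inherits the titration's decade quantisation; finer
  spacing gives proportionally finer estimates.
- TOML sidecars mentioned in some workflows are realised as YAML files
  with identical keys (`truth.yaml`, `roi_meta.yaml`).
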