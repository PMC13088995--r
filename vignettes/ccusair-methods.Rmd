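---
title: "Methods: from airport emissions to attributable deaths and net benefit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from airport emissions to attributable deaths and net benefit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccusair)
```

# Overview

`ccusair` implements an airport-level assessment chain for carbon capture,
utilization and storage (CCUS) adoption in aviation. Four pathways are
compared against a business-as-usual (BAU) trajectory: direct air capture
(DAC) or point-source capture at a waste-to-energy plant (PSC), each coupled
with permanent storage (CCS) or conversion of the captured CO2 into
synthetic jet fuel (CCU). The chain is

1. **synthetic world** — seeded generation of an airport registry, exposed
   populations, baseline mortality rates and BAU emission inventories;
2. **scenario engine** — a proportional adoption ramp and per-pathway
   pollutant multipliers turning the BAU inventory into four scenario
   inventories, with CO2 offset accounting;
3. **dispersion** — a sector-averaged Gaussian plume converting annual
   emitted masses into long-term mean ground-level concentrations over the
   20-km exposure disk;
4. **exposure-response** — GEMM hazard ratios (PM2.5) and log-linear
   relative risks (CO, SO2, NO2) mapped through the population attributable
   fraction onto age-, sex- and cause-stratified baseline deaths;
5. **economics** — pathway fuel costs against displaced JET-A purchases and
   carbon-price revenues, yielding yearly net-benefit bands.

Every stage is deterministic given one master seed; per-stage child seeds
(`child_seed()`) let any stage be regenerated independently.

# The synthetic world

The generator emulates the *statistical structure* of the study inputs, not
any real airport. Defaults, all overridable through `world_config()`:

* **Wind speeds** are lognormal with median 3.5 m/s and log-SD 0.4 —
  a typical spread of mean annual 10-m wind speeds across world airports.
  Only a scalar mean speed per airport exists, which is why dispersion is
  sector-averaged (below).
* **Populations** within 20 km are lognormal across airports (median
  500,000, log-SD 0.8), correlated with the airport's traffic size factor,
  and spread over twenty 5-year age bands, flat to age 59 and decaying
  geometrically (factor 0.75 per band) above 60.
* **Baseline mortality rates** follow a geometric age gradient anchored at
  the 70–74 band (factors 1.3–1.4 per 5-year band), with male/female ratios
  above one for cardiovascular and respiratory causes and slightly below
  one for type 2 diabetes. These choices produce the elderly-skewed,
  male-dominant mortality structure the analysis expects, with the diabetes
  exception running the other way.
* **BAU emissions** start in 2025 at per-airport means of 9×10^5 t CO2,
  1,200 t NO2, 2,000 t CO, 400 t SO2 and 60 t PM2.5 per year — the
  magnitude of a busy international airport's landing-and-take-off
  inventory — scaled by a lognormal airport size factor and growing
  deterministically at +1.5 %/yr.

What the generator does **not** emulate: spatial wind roses, diurnal or
seasonal emission cycles, correlated regional background pollution, or
real-world airport rankings. Passing tests therefore demonstrate the
correctness and internal consistency of the computational chain, not
predictive accuracy for any real airport.

# Scenario engine

Adoption is zero in 2025 and complete in 2050, linear in between
(`ramp_fraction()`). For each local pollutant the scenario mass is

$$m_s(y) = m_{BAU}(y)\,\bigl(1 + f(y)(\kappa_p - 1)\bigr),$$

where $\kappa_p$ is the fully-deployed emission factor relative to BAU.
The packaged $\kappa$ defaults are **illustrative, not authoritative**:
PSC-CCS scrubs flue gas as a co-benefit ($\kappa$ 0.60–0.95), DAC carries a
small energy penalty (1.05), and both CCU pathways add fuel-synthesis
process emissions (1.05–1.30). They were chosen once to reproduce the
qualitative pathway ordering (PSC-CCS cleanest, the two CCU pathways
dirtiest and near-identical) and can be overridden per scenario.

CO2 is handled by the fate rule: the source-level emission is unchanged,
and an offset stream $f(y)\,m_{CO2,BAU}(y)$ records captured-and-stored
(CCS) or displaced fossil (CCU, times a configurable neutrality factor,
default 1) carbon. Saved net carbon (SNC) is the difference in net CO2
between BAU and scenario; at full CCS deployment it equals the whole BAU
CO2 mass.

# Dispersion

Only a mean wind speed is available per airport, so the crosswind-integrated
ground-level reflected Gaussian plume is distributed uniformly around the
compass (sector averaging), giving a radius-only field whose mean over the
exposure disk of radius $R$ is

$$\bar{C} = \frac{1}{\pi R^2} \int_{r_{min}}^{R}
  \sqrt{\tfrac{2}{\pi}}\; \frac{Q}{u\,\sigma_z(r)}
  \exp\!\left(-\frac{H^2}{2\sigma_z(r)^2}\right)\,dr .$$

$\sigma_z$ uses Briggs open-country coefficients (class D, neutral, by
default; all six classes packaged). Numerical choices: composite trapezoid
with 2,000 points (halving the resolution moves the default-geometry answer
by well under 0.5 %; tests verify 0.1 % agreement with a 10^6-point
re-evaluation), inner cutoff $r_{min}$ = 100 m against the $1/\sigma_z(r)$
near-source growth, release height $H$ = 0 (ground-level aircraft
operations). Annual masses convert to rates by
$Q = m \cdot 10^6 / (365.25 \cdot 24 \cdot 3600)$ g/s; concentrations are
stored in µg/m³. Chemistry, secondary aerosol formation, terrain and
building wakes are out of scope.

# Exposure-response

The six PM2.5 causes use the GEMM form

$$HR(C) = \exp\!\left( \frac{\theta \log(1 + z/\alpha)}
  {1 + e^{-(z-\mu)/\nu}} \right), \qquad z = \max(0, C - 2.4),$$

with cause-level parameters for ischemic heart disease, stroke, COPD, lung
cancer and lower respiratory infections transcribed from the GEMM source
publication. Two deliberate design points:

* The original GEMM also publishes age-resolved coefficients for ischemic
  heart disease and stroke. The packaged table ships cause-level
  coefficients applied to all eligible ages because the age-resolved values
  could not be transcribed with confidence; the ERF schema (an `age_band`
  column whose rows override the all-age row for their band) and the
  accounting support age-specific coefficients fully, and tests exercise
  that path with a synthetic age-varying table.
* Type 2 diabetes is not among the original GEMM causes; its row is a
  synthetic GEMM-form extension, flagged in the table, with a conservative
  slope.

The four gaseous causes use a log-linear relative risk per 10 µg/m³
(per 1 mg/m³ for CO), with placeholder slopes (0.008–0.020) chosen once so
that gaseous causes dominate the disease mix — the qualitative pattern the
assessment expects — and marked non-authoritative in the packaged CSV.
Adult-onset PM2.5 causes apply to ages 25+; lower respiratory infections
and all gaseous causes apply to all ages. Risk functions are sex-invariant:
sex differentials arise through baseline rates and population structure.

Attributable deaths per stratum are
`count × baseline_rate × (RR − 1)/RR`, an annual flow (not cumulative), so
deaths can never exceed a stratum's baseline deaths.

A consequence of the default emission magnitudes worth stating plainly:
default aviation-attributable PM2.5 disk means (~0.05 µg/m³) sit below the
GEMM counterfactual of 2.4 µg/m³, so the six PM2.5 causes contribute
exactly zero deaths in the default world — the "close to zero" corner of
the disease mix. The GEMM machinery is exercised in unit tests at higher
concentrations.

# Economics

Per year and pathway: $C = N_A P_A - N_J P_J$ (alternative-energy cost
minus displaced JET-A), $Re = SNC \cdot P_C$ at the low and high carbon
price, $N = Re - C$ at each band edge. Pathway costs per tonne of fuel
interpolate linearly between published 2020 and 2050 anchors (2649.90 →
1144.30 DAC-CCS; 7549.90 → 4062.50 DAC-CCU; 856.65 → 697.00 PSC-CCS;
4283.25 → 3252.88 PSC-CCU); an exponential-decay interpolation is available
behind a switch. BAU fuel tonnage is inferred from the CO2 inventory at
3.16 t CO2 per tonne of kerosene. Nominal USD, no discounting.

The packaged price series is a placeholder (the study's own price paths are
not published in the main text): JET-A flat at 600 USD/t, carbon price
rising linearly 8→18 (low) and 12→28 (high) USD/t over 2024–2050. The
levels were fixed analytically, once, from a margin inequality: revenue per
tonne of fuel covered is (t CO2/t fuel) × carbon price = 3.16 · P_C, and
for every net-benefit band to stay negative — with the cheapest pathway,
PSC-CCS, least negative — that revenue must stay below the cheapest cost
margin over JET-A, 697 − 600 = 97 USD/t in 2050; 3.16 × 28 = 88.5 < 97.
Naive combinations of a higher JET-A price with steeper carbon-price paths
invert the sign of the result, which is why the series is chosen jointly
rather than term by term. Users supplying their own `prices.csv` should be
aware the qualitative conclusion is configuration-dependent.

# Reporting, sensitivity and problem sizes

`run_pipeline()` writes every stage table as CSV plus a checksum manifest;
reruns under the same seed are byte-identical, and `resume = TRUE`
regenerates any deleted intermediate exactly (stages are recomputed
deterministically from the master seed rather than re-parsed from CSV, so
no precision is lost through round-trips). `write_reports()` produces the
scenario-year, sex, age, disease, airport-ranking and cost-benefit cuts;
all mortality cuts reconcile to one grand total. `sensitivity_sweep()`
re-evaluates the pipeline under θ ± SE, β ± SE or cost-anchor
perturbations.

The packaged test and example configurations use 3–20 airports over
2025–2050 — enough to exercise every code path, all ten diseases, twenty
age bands and both sexes, while a full run completes in seconds. The study
scale (1134 airports) runs in a few minutes and changes totals, not
structure.

# Known limitations

* Uniform wind rose and a single stability class; no receptor-level
  spatial detail within the disk.
* Placeholder κ multipliers, gaseous slopes and price paths: qualitative
  orderings, not magnitudes, are the reproducible claims.
* Mortality only — no years-of-life-lost, morbidity, or monetized health
  benefit; no CO2 transport/storage itemization (absorbed into the
  per-tonne pathway cost).
* Annual steady-state coupling throughout: no atmospheric or demographic
  feedbacks between years.
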