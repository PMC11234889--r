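---
title: "An event-driven model of children's dust and soil ingestion from micro-level activity time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An event-driven model of children's dust and soil ingestion from micro-level activity time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlatsim)
```

## The problem

Children between roughly six months and six years ingest indoor dust and
outdoor soil mainly by mouthing their hands and objects. The ingestion rate
(mg/day) that results is among the most uncertain exposure factors in
health-risk assessment, yet it multiplies directly into dose estimates for
lead, pesticides, PFAS, and other contaminants carried by dust. Direct
measurement is impractical; the tractable route is mechanistic: observe
*what* a child touches second by second, attach physical parameters to each
contact, and integrate.

`mlatsim` implements that route. Its input is a set of micro-level activity
time series (MLATS): one tab-delimited text file per body part (left hand,
right hand, mouth) listing sequential records of activity type (`constant`
or `repetitive`), location, object/surface, and duration in seconds. Such
files are produced by videotranslation software operated by trained coders;
this package consumes the text format only and never touches video.

## The exposure model

### Dermal loading dynamics

The state variable of each hand is its loading $L$ (mg/cm²) of dust plus
soil. Each contact with a surface of loading $L_{surf}$ applies

$$L' = \mathrm{clip}\left(L + TF \cdot f_{SA} \cdot (L_{surf} - L),\; 0,\; L_{max}\right)$$

where $TF$ is the transfer fraction (fraction of the loading difference
moved per contact), $f_{SA}$ the fraction of the hand's surface in contact,
and $L_{max}$ a saturation cap. The functional form was a genuinely open
design choice: the requirement was a rule supporting loading, off-loading,
and a maximum hand loading. Net first-order relaxation toward the surface
loading satisfies all three, is dimensionally consistent, reduces to simple
one-way adherence when $L \ll L_{surf}$, and has a fixed point at
$L = L_{surf}$ (a dirty hand sheds onto a clean surface). The contacted
surface itself is an *undepleted reservoir*: its loading is redrawn from its
distribution at the next contact, consistent with treating every contact as
an independent event. This is a known simplification — repeated contact with
one small surface would in reality deplete it.

Handwashes multiply both loading components by $(1 - \text{efficiency})$.

### Ingestion

Each mouthing record is a discrete event occurring instantaneously on
contact. It ingests

$$m = L_{source} \cdot A_{mouth} \cdot RE \quad (\text{mg})$$

with $A_{mouth}$ the mouthed area (cm²) and $RE$ the mouthing removal
efficiency. When the source is a hand, the hand's total mass drops by
exactly $m$; we spread that removal uniformly over the whole hand (uniform
mixing) rather than depleting only the mouthed sub-area. The alternative —
tracking spatial heterogeneity of loading within a hand — is unsupported by
any observable in the data; the uniform-mixing choice slightly accelerates
apparent depletion under repeated mouthing and is flagged for sensitivity
analysis. Object sources (toys, pacifiers) are undepleted reservoirs, with
per-object loading distributions configurable (a pacifier override ships in
the default configuration).

Mouth records with object `Hands` draw half the mouthed area from each hand,
unless a dominant hand is configured. Hand records with object `Mouth`
describe the same physical contact from the hand's viewpoint and are
therefore no-ops in the engine — counting both would double-count the event.

### Media and bookkeeping

Each hand's loading is tracked as separate dust and soil components. Contacts
in outdoor locations (configurable token set, default `Outdoor`, `Yard`,
`Patio`, `Porch`) load the soil component and are labelled `soil` in the
ingestion ledger; everything else is indoor dust. Unlisted location tokens
default to indoor/dust. The component split is what lets a hand-to-mouth
event attribute its ingested mass to medium even when the hand carries a
mixture.

The ledger records one entry per ingestion event (time, pathway, medium,
mass); cumulative mass is non-decreasing by construction, and the engine
also reports the total mass ever transferred onto the hands so tests can
assert the hand-to-mouth pathway never ingests more than was ever loaded.

### Variance partition and event expansion

The model distinguishes parameters that vary per contact from those fixed
per child:

* **per (sub-)contact:** $TF$, $f_{SA}$, $RE$, $A_{mouth}$, and all surface
  loadings — every contact is an independent event;
* **per child:** hand area, body weight, $L_{max}$.

`repetitive` records (crawling, bouncing a ball) are expanded into
sub-contacts at a default 0.5 contacts/s, each applying the contact step;
`constant` records are a single contact at record start. The observation
format distinguishes the two activity types but not their event counts, so
the rate is an explicit, configurable assumption.

The three body-part series are assumed to start simultaneously; total
durations may disagree by up to 2 % (videotape trimming) before an error is
raised. `Not_In_View` records contribute elapsed time but no events.

### Dose algorithms

Observed ingestion extrapolates to daily rates by medium through a
time-activity profile (active hours indoors/outdoors per day):
$\text{mg/day}(\text{dust}) = \text{mg/h}(\text{dust}) \times h_{indoor}$,
and analogously for soil. The resulting intake rate feeds the standard dose
equations

$$D_{der} = \frac{C \cdot SA \cdot AF \cdot ABS \cdot EF \cdot CF}{BW},
\qquad
D_{ing} = \frac{C \cdot IR \cdot EF \cdot CF}{BW}$$

in mg/kg/day with $CF = 10^{-6}$ kg/mg. $EF$ is treated as a unitless
pass-through multiplier in $[0, 1]$ (its published definition names it
without specifying structure). At the all-ones input both equations return
$10^{-6}$, which tests use as a units sentinel.

## Exposure-factor distributions

Factors are named parametric distributions with explicit units and support:
`point`, `uniform`, `triangular`, `normal`, `lognormal` (parameterized by
geometric mean and geometric SD, the exposure-science convention), and
`empirical`. Truncation to the support is by **rejection**, not clipping —
clipping would concentrate probability mass at the bounds — with a cap of
10⁴ retry rounds before a pathological-truncation error. Units are validated
against a registry (fractions must have support within $[0,1]$), so a factor
file in the wrong units fails loudly at load time.

The shipped default configuration (`inst/extdata/factors-default.yaml`)
contains placeholder, literature-style magnitudes chosen once to be
plausible for young children (e.g. geometric-mean indoor surface loading
0.005 mg/cm², hand area GM 150 cm², body weight GM 12 kg). They are clearly
labelled non-authoritative: deriving real distributions is a
measurement-campaign task outside this package's scope.

## The synthetic MLATS generator

Testing an event-driven engine requires inputs with known statistical
structure, so the generator is first-class, tested code rather than a
fixture. Hand series are realizations of a **semi-Markov chain**: states are
(location, object) pairs, transitions follow a configurable stochastic
matrix, and dwell times are lognormal (GM seconds, GSD) truncated at 1 s —
positive, right-skewed, matching how observed contact durations behave. The
final dwell is clipped so the series tiles the configured window exactly.
The mouth series is generated by thinning: hand-mouthing and object-mouthing
events at configured rates (events/h) are inserted into a background
`Nothing` stream with their own dwell distribution.

All randomness flows from one master seed through documented per-body-part
substreams (a multiplicative-hash seed derivation), so regenerating one body
part never perturbs the others. What the generator does **not** emulate:
circadian structure, location-dependent mouthing rates, correlation between
hand and mouth activity, or coder idiosyncrasies of real videotranslation.
Tests passing on synthetic series therefore validate the *mechanics* of the
pipeline, not the realism of any particular parameter set.

The particle-counter fixture generator plays the same role for the
laboratory side: it builds a bin table over log-spaced diameters (lognormal
number-weighted size distribution, GM 20 µm, GSD 2 — a typical house-dust
scale) whose counts recover a target spiked mass through the volumetric
computation within 1 %. Counts are integers: a floor-then-greedy-top-up
scheme (large-particle bins first) keeps the rounding residual below the
finest bin's per-particle mass. Pre-rounding counts are retained so
linearity in the target mass is exact.

## Population Monte Carlo and convergence

A virtual child is one draw of (activity series, per-child factors,
per-event factors). Child $i$ seeds the RNG with a deterministic substream
of the master seed, so adding children never changes earlier children.
Percentiles use the nearest-rank method (the $\lceil pn \rceil$-th order
statistic) — deterministic and exact at point masses.

The simulation count is judged stable where further replicates stop moving
the results. Both the running mean and the running 95th percentile are
monitored, because ingestion distributions are right-skewed and a stable
mean can hide an unstable tail. At the end of each window (default 10 % of
iterations) the criterion requires the relative change of both summaries
over the window *and* at single-step probes inside the window to fall below
the tolerance (default 1 %). The single-step probes matter: a stream that
merely oscillates (e.g. alternating 0/1) has a running mean exactly equal at
window endpoints and would otherwise be declared stable, which is the wrong
answer for a criterion meant to detect settled results.

## Laboratory computations

* **Gravimetric**: mass = post − pre weighing of wipe or vacuum sock. The
  balance sensitivity is 0.1 mg; the detection limit defaults to 3× that
  (0.3 mg). Sub-LOD results are flagged (routed to the volumetric method);
  negative differences within −LOD report 0 mg with the flag, beyond it they
  are a weighing-blunder error.
* **Volumetric**: $M = V \times \rho$, with
  $V = (\text{rinse}/\text{aliquot}) \sum_i n_i \frac{\pi}{6} d_i^3$ over
  size bins ($d_i$ the bin midpoint; geometric mean of edges when edges are
  given, matching log-scaled sizing). Default rinse 150 mL.
* **Pycnometer**: calibration volume = water mass ÷ water density at the
  recorded temperature, averaged over replicates (nominally 10). Note the
  standard protocol text says "multiplied by the density of water", which is
  dimensionally inconsistent for obtaining a volume; this package divides.
  Density by displacement: water volume added over the dust =
  added water mass ÷ $\rho_w(T)$; dust volume = calibrated volume − water
  volume; $\rho$ = dust mass ÷ dust volume, averaged over up to three runs.
* **Water density**: an 11-point table over 10–35 °C (2.5 °C steps) computed
  from the standard air-free-water temperature polynomial, linearly
  interpolated. Temperatures outside the table are errors, not
  extrapolations.
* **Hand area**: filled 1 cm² cells of digitized hand-trace grids, summed
  over both hands. Image digitization itself is out of scope.
* **Hand rinse**: gained loading = (post-rinse mass − pre-rinse mass) /
  traced area, floored at 0 with a negative-gain flag. No correction is
  applied for sub-100 % rinse removal efficiency.

## Numerical choices and problem sizes

* Clock-mismatch tolerance 2 %; contact-step bounds enforced by clipping at
  0 and $L_{max}$; ties in simultaneous events resolved in the fixed order
  wash, left hand, right hand, mouth.
* Rejection-sampling retry cap 10⁴ rounds.
* The test suite sizes its stochastic checks as: 10⁴ replicates for the
  Monte Carlo mean of the contact-then-mouthing composition (3-standard-
  error band), 10³ seeded child simulations for the mass-conservation sweep,
  2×10⁴-long streams for convergence checks, and 10⁵-draw samples for
  distribution moments. The full suite runs in under two minutes on one CPU.

## Known limitations

* Surfaces are undepleted reservoirs; no environmental mass balance.
* No dermal absorption kinetics beyond the dose algorithm; no inhalation,
  food-borne, or bioavailability adjustment (a constant direct-ingestion
  term is available but off by default).
* The uniform-mixing depletion choice for mouthed hands (above).
* The semi-Markov generator is not fitted to real videotranslation data;
  its defaults are plausible, not estimated.
* Shipped factor distributions are placeholders, not study results.
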