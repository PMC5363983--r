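---
title: "An individual-based life-cycle model of Nitocra spinipes under temperature and food limitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An individual-based life-cycle model of Nitocra spinipes under temperature and food limitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NitocraSim)
```

## The model

`NitocraSim` simulates the life cycle of the brackish-water harpacticoid
copepod *Nitocra spinipes*, a standard test species in aquatic
ecotoxicology, one individual and one day at a time. Each animal passes
through an aggregated naupliar phase (six instars in nature), an
aggregated copepodite phase (five instars) and adulthood; instars are not
resolved individually. Four daily rates govern phase progression —
naupliar development `pN_DEV`, copepodite development `pC_DEV`, latency
`pL` (fertilization to first clutch) and embryonic development `pE_DEV`
(brood-to-brood cycle) — together with stage-specific daily death
probabilities, a mean brood size, a mean number of broods per female and
a sex probability at maturation.

Individual variability in development enters through a dimensionless
*duration deviate*: when an individual enters a phase it draws a gamma
variate with mean 1 and shape α (Table-calibrated per phase), and the
phase completes on the day the cumulative sum of daily rates reaches that
deviate. Durations are therefore gamma distributed with CV `1/sqrt(α)`
and positively skewed, reproducing the "laggard" animals in observed
development-time histograms. The deviate is drawn once per phase (not per
day), so an individual stays consistently fast or slow while daily rates
vary with food; each embryonic cycle draws a fresh deviate.

## Response functions

All rates and probabilities respond to two environmental axes, calibrated
at a reference of 22 °C and ample food.

*Temperature.* Durational parameters use either independently fitted
three-parameter exponential decays, `D(t) = a + b·e^{-c·t}` (the default,
and the only basis for the verification experiments), or a shared
Bělehrádek power law `D(t) = 250·(t + 7.2)^{-1.86}·s` that presumes
equiproportional stage durations; latency has only the Bělehrádek form.
Brood size and the three death probabilities follow quadratic optimum
curves calibrated on 15–25 °C. Outside that range the quadratics are
still evaluated but warn, probabilities are clamped to [0, 1] and brood
size to ≥ 0; near the 20 °C survival optimum the raw naupliar quadratic
dips slightly below zero and is clamped to 0.

*Food.* Because the species dwells on the vessel floor, the suspended
algal ration (cells/mL of *Rhodomonas salina*) is converted to a bottom
food concentration (µg C/cm²) through the vessel volume, bottom area and
the per-cell carbon content. Each stage ingests according to a Holling
type-III functional response `a_max·c²/(c² + k²)`; life-cycle parameters
then depend on the *ingested carbon* per individual and day (power laws
for development, exponential saturation for brood size, rational or cubic
curves for mortality), which couples individuals through competition for
a shared, depletable pool.

*Normalization.* Every function carries a normalizing factor, the
reciprocal of its value at the reference condition, so that
`factor × f(x)` equals 1 at reference. In `normalized` mode the default
parameters are scaled multiplicatively on both axes — an interaction-free
assumption, made explicit here because the calibration experiments varied
one axis at a time and interactive effects are documented for related
species. In `direct` mode (used in all verification experiments) one
axis's function value is taken as the absolute parameter and the other
axis stays at reference.

The per-cell carbon content defaults to 2.64 × 10⁻⁵ µg (26.4 pg C per
cell). The calibration sources never state this conversion; the value is
chosen once so that the standard ration of 2.5 × 10⁵ cells/mL in 6-well
geometry (8 mL over 9.6 cm²) equals the reference bottom concentration of
5.5 µg C/cm², the unique concentration that reproduces the tabulated food
normalizing factors (7.43, 11.8, 0.0324, 690, 1111) simultaneously to
within 1% — except the copepodite-mortality factor (tabulated 333,
recomputed ≈ 325, within 5%), whose exact reference ration is not
recoverable. Both the conversion and the reference concentration are
configurable.

```{r}
round(1 / temperatureResponse("pN_DEV", 22), 2)   # reference naupliar duration
round(normalizationFactor("pN_DEV", "food"), 2)   # food normalizing factor
```

## Food depletion at minute resolution

Within a day, ingestion is integrated over 1440 one-minute steps: each
minute every living individual takes 1/1440 of its current daily Holling
ration, the total is removed from the vessel pool, and the bottom
concentration falls. If one minute's demand exceeds the remaining food,
allocation is proportional and the pool floors at exactly zero, so carbon
is conserved to floating precision. The loop is deterministic given the
stage composition — stochasticity enters only through survival,
development and brood draws — and is implemented in C++ for speed. Food
is fully replaced (reset, not topped up) every second day, the simplified
schedule of the laboratory's replacement rhythm. Algal degradation and
growth between feedings are not modelled.

## The daily scheduler

Each simulated day applies, in order: (1) feeding-day reset, (2)
minute-loop ingestion, (3) computation of each individual's effective
parameters from temperature and its realized ration, (4) Bernoulli
survival, (5) development advancement and stage transitions, (6)
reproduction. The published process diagram does not fully pin this
order; placing mortality before molting means an individual cannot molt
and die on the same day, and the order is isolated in one scheduler
function so alternatives are testable. Newly hatched nauplii enter the
population the following day with age 0 and fresh deviates. Sex is
assigned once, at maturation, with probability 0.5 by default — the data
show a temperature-linked shift in adult sex ratios but offer no
functional form, so none is modelled. In population mode a female is
fertilized (permanently) on the first day she shares the vessel with a
living adult male — the simplest rule consistent with simulating
individually fertilized females; mating behaviour is otherwise not
modelled. The latency clock starts at fertilization and its completion
releases the first clutch; each subsequent embryonic cycle releases
another, until the female's brood budget (drawn at maturation, mean 3.64)
is spent.

Realized durations are recorded *fractionally*: within the completion day
the crossing time of the threshold is interpolated linearly, so under a
constant rate the realized duration equals `deviate/rate` exactly.
Recording the integer completion day instead would bias every mean
duration upward by about half a day and simulated means could never
converge to the response-function values they are verified against.

## Monte-Carlo replication and seeds

`runMonteCarlo()` summarizes daily stage abundances over replicates with
percentile 2.5%/97.5% bounds — percentiles rather than a normal
approximation because the quantities are small counts. Replicate `r` of
master seed `m` uses the split seed `(69069·(m + r) + 12345) mod 2³¹−1`,
so any replicate is reproducible in isolation, and identical
configuration and seed reproduce a run bit for bit.

## Verification experiments

`runDevelopmentTest()` re-creates the laboratory development test:
72 nauplii for 35 days at each temperature regime (simulated at the
*measured* mean temperatures 14.86, 19.34 and 24.90 °C, through which the
exponential-decay fits pass exactly), or 35 nauplii for 45 days at each
of six rations at 22 °C, housed in groups of six sharing a 24-well food
pool, reproduction disabled. The experimental isolation of copepodites
into 96-well plates midway is not modelled; the group vessel is kept
throughout, which slightly strengthens late competition at low rations.

`runReproductionTest()` simulates 50 individually fertilized females for
15 days and compares clutch sizes and brood-to-brood periods against the
theoretical function values with one-sided t-tests. The temperature
setups use 15.00, 19.34 and 24.90 °C: the tabulated theoretical periods
are only consistent with the nominal temperature at 15 °C and with the
measured mean at 20 °C, so each setup uses the temperature its tabulated
value implies. For the food setups a female depletes her own 24-well
pool, so the theoretical brood size is evaluated at her mean realized
ration. The direction of the published one-sided test is unstated;
`oneSampleT()` defaults to testing in the direction of the observed
deviation and returns both one-sided p-values so either convention can be
read off.

Two caveats, both visible in the test suite rather than hidden:

* The embryonic gamma shape α = 3.5 implies a per-cycle duration CV of
  0.53, while the measured embryonic CV is about 0.22 and the published
  simulated SDs are about 0.2 of the mean. The package follows the
  calibrated α.
* With α = 3.5, a 15-day window right-censors long embryonic cycles
  (and adult death censors a few more), so per-brood period means fall
  below the theoretical value — at 15 °C by roughly 13%. Per-female mean
  summaries are less affected and both are reported. A multi-day latency
  before every brood at very low rations is noted in the source data but
  has no functional form and is not modelled.

```{r}
rt <- runReproductionTest("25C", nFemales = 20, seed = 1)
rt$summary
rt$theoretical
```

## Exact contingency statistics

`fisherExactRxC()` implements the Freeman–Halton extension of Fisher's
exact test for r × 2 tables by complete enumeration of all tables with
the observed margins; the two-sided p sums the probabilities of tables no
more probable than the observed one (relative tie tolerance 10⁻⁷, the
convention of mainstream software). A dynamic-programming count enforces
an enumeration guard of 10⁷ candidate tables; the largest packaged
fixture enumerates ~3.8 × 10⁵. The suite cross-checks the enumeration
against the closed-form 2 × 2 hypergeometric construction and against the
reference network-algorithm implementation. Notably, re-computing the six
packaged alive/dead and female/male tables shows that five of the six
p-values printed alongside them coincide with Pearson's chi-squared
statistic at printed precision, and only the food sex-ratio value with
the exact test — the suite documents this reconstruction explicitly.
Kruskal–Wallis, Shapiro–Wilk and Bartlett pretests are not reimplemented:
their inputs (raw individual measurements) are not part of the packaged
summaries.

## Numerical choices and problem sizes

The suite verifies parameter recovery with 10⁴ isolated individuals
(development means within ±0.1–0.15 d of the function values), 20 seeds
of 50 females for reproduction, 500 replicates per food setup for the
monotone stress ordering (lower ration ⇒ slower development, higher
mortality, smaller clutches) and 100 replicates for the zero-food
criterion, where no individual ever reaches the copepodite stage — the
starvation development rate of 0.0009 d⁻¹ cannot cross a mean-1 deviate
within 45 days. These sizes put Monte-Carlo error well below each stated
tolerance while keeping the default suite inside a few minutes.

What passing these tests shows — and what it does not: the generator
reproduces the calibrated functions and the structural behaviour of the
laboratory system (stage ordering, conservation, competition, censoring).
It does not validate the model against raw field or laboratory
time-series, which are not packaged; the published time-series comparison
is replaced by a band-coverage property on model-generated data.

## Known limitations

Toxicant effect submodels, multi-vessel metapopulations, instar-resolved
development, temperature×food interaction surfaces, algal dynamics and a
temperature-dependent sex ratio are out of scope. The quadratic optimum
curves carry no extrapolation guarantee outside 15–25 °C.
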