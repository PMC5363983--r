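# NitocraSim

Individual-based simulation of the life cycle of the brackish-water
harpacticoid copepod *Nitocra spinipes* — a standard test species in
aquatic ecotoxicology — under combined temperature and food limitation,
with the statistical machinery used to verify the model against the
laboratory life-cycle experiments it was calibrated on.

The package is aimed at ecotoxicologists and population modellers who
want to extrapolate individual-level bioassay endpoints (development
times, survival, brood sizes, sex ratios) to population-level dynamics
under non-optimal temperature and food conditions.

## The model in brief

Each copepod is simulated daily through nauplius → copepodite → adult.
Phase `i` completes when the cumulative sum of its daily rates reaches a
gamma-distributed individual deviate with mean 1 and shape αᵢ, so phase
durations are gamma with CV 1/√αᵢ. Daily rates and probabilities derive
from empirical response functions:

* temperature: exponential decay `D(t) = a + b·e^(−c·t)` (or a shared
  Bělehrádek law `D(t) = 250·(t + 7.2)^(−1.86)·s`) for durations, and
  quadratic optimum curves for brood size and daily mortality;
* food: a Holling type-III ingestion response
  `IC = a_max·C²/(C² + k²)` of the benthic carbon concentration
  `C` (µg C/cm²), with power/saturation/rational/cubic links from the
  ingested carbon `IC` to development, brood size and mortality.

Food in a vessel is a shared, depletable pool: ingestion is integrated
in 1440 one-minute steps per day, so individuals compete and the ration
falls between the every-second-day feedings. Each function carries a
normalizing factor (its reciprocal at the 22 °C / 5.5 µg C/cm²
reference) so the calibrated default parameters can be scaled
multiplicatively on either axis, or the functions applied directly as in
the verification experiments.

An exact Freeman–Halton test (complete enumeration for r × 2 tables)
reproduces the contingency statistics for the packaged alive/dead and
female/male counts.

## Worked example

```r
library(NitocraSim)

# reference naupliar duration at the 22 degC culture temperature
1 / temperatureResponse("pN_DEV", 22)
#> [1] 5.84615

# development test at the measured 20C-setup temperature: 72 nauplii,
# 35 days, reproduction disabled, temperature functions applied directly
sm <- runDevelopmentTest("20C", replicates = 100, masterSeed = 1)
mcMean(sm)[36, ]
#>     nauplii copepodites      adults        dead
#>        0.00        0.00       66.03        5.97

# realized stage durations of a single large cohort
cfg <- simConfig(temperature_C = 19.34, mode = "direct_temperature",
                 nInitial = 1e4, days = 60, reproduction = FALSE)
d <- stageDurations(runSimulation(cfg, seed = 101))
tapply(d$duration, d$stage, mean)
#> copepodite   nauplius
#>  10.070154   6.432873

# exact test on the temperature sex-ratio counts
tab <- fixtureTable("temperature-sexratio")
fisherExactRxC(tab)$p.value
#> [1] 0.0003011803
```

At 19.34 °C the exponential-decay fits predict mean naupliar and
copepodite durations of 6.44 d and 10.12 d; the simulated cohort
recovers both within Monte-Carlo error. By day 35 of the development
test essentially every survivor has matured; mortality is low because
the quadratic survival curves have their optimum close to 20 °C. The
small sex-ratio p-value reflects the shift toward females at warmer
temperatures.

A thin command-line front end ships with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "copepodsim.R", package = "NitocraSim"))') \
    devtest --setup 20C --replicates 1000 --seed 1 --out out/
```

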