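## Verification experiment runners: the development test (isolated cohorts,
## reproduction disabled) and the reproduction test (individually simulated
## fertilized females). Both use direct mode: one axis's response functions
## are applied as absolute parameter values, the other stays at reference.

.DEV_SETUPS <- list(
  ## temperature setups use the measured mean temperature of each regime
  "15C" = list(temperature = 14.86, mode = "direct_temperature",
               nInitial = 72, days = 35),
  "20C" = list(temperature = 19.34, mode = "direct_temperature",
               nInitial = 72, days = 35),
  "25C" = list(temperature = 24.90, mode = "direct_temperature",
               nInitial = 72, days = 35),
  ## food setups run at the 22 degC culture temperature
  "food_0"      = list(cells = 0,      mode = "direct_food"),
  "food_1.25e4" = list(cells = 1.25e4, mode = "direct_food"),
  "food_2.5e4"  = list(cells = 2.5e4,  mode = "direct_food"),
  "food_5e4"    = list(cells = 5e4,    mode = "direct_food"),
  "food_1.25e5" = list(cells = 1.25e5, mode = "direct_food"),
  "food_2.5e5"  = list(cells = 2.5e5,  mode = "direct_food"),
  "food_5e5"    = list(cells = 5e5,    mode = "direct_food"))

#' Configuration of a named development-test setup
#'
#' Temperature setups ("15C", "20C", "25C"): 72 nauplii observed for 35
#' days at the measured mean temperature of the regime (14.86, 19.34,
#' 24.90 °C), food assumed abundant, temperature functions applied
#' directly. Food setups ("food_0" .. "food_5e5"): 35 nauplii for 45 days
#' at 22 °C in 24-well geometry, housed in groups of six sharing a food
#' pool that is replaced every second day, food functions applied
#' directly. Reproduction is disabled throughout to emulate individual
#' isolation.
#'
#' @param setup Setup name, see above.
#' @param replicates,masterSeed Monte-Carlo settings stored in the config.
#' @return A [SimConfig-class].
#' @export
developmentTestConfig <- function(setup, replicates = 1000, masterSeed = 1) {
  if (!setup %in% names(.DEV_SETUPS))
    stop("unknown setup '", setup, "'; available: ",
         paste(names(.DEV_SETUPS), collapse = ", "))
  s <- .DEV_SETUPS[[setup]]
  if (s$mode == "direct_temperature") {
    simConfig(temperature_C = s$temperature, foodCellsPerML = 2.5e5,
              vessel = vessel("well24"), nInitial = s$nInitial,
              days = s$days, reproduction = FALSE,
              mode = "direct_temperature", replicates = replicates,
              masterSeed = masterSeed)
  } else {
    simConfig(temperature_C = 22, foodCellsPerML = s$cells,
              vessel = vessel("well24"), nInitial = 35, days = 45,
              reproduction = FALSE, mode = "direct_food", groupSize = 6,
              replicates = replicates, masterSeed = masterSeed)
  }
}

#' Run the development test for a named setup
#'
#' Monte-Carlo replication of the stage-abundance time series of the
#' development test (see [developmentTestConfig()] for the conditions).
#'
#' @param setup Setup name.
#' @param replicates Monte-Carlo replicates.
#' @param masterSeed Master seed.
#' @return A [MonteCarloSummary-class] of daily stage abundances.
#' @export
#' @examples
#' sm <- runDevelopmentTest("20C", replicates = 20)
#' mcMean(sm)[36, ]
runDevelopmentTest <- function(setup, replicates = 1000, masterSeed = 1) {
  runMonteCarlo(developmentTestConfig(setup, replicates, masterSeed))
}

.REPRO_TEMPS <- c("15C" = 15.0, "20C" = 19.34, "25C" = 24.90)

#' Run the reproduction test
#'
#' Repeatedly simulates individual fertilized females over 15 days at the
#' conditions of a named setup and compares clutch sizes and inter-clutch
#' (brood-to-brood) periods with the theoretical values derived from the
#' response functions. Females start as fertilized adults; the latency
#' clock runs first and releases the first clutch, after which the embryonic
#' cycle sets the brood-to-brood period. Offspring are recorded but not
#' recruited (isolated females). For the temperature setups the theoretical
#' period and brood size are the direct function values at the setup
#' temperature (15 °C nominal; 19.34 and 24.90 °C measured means). For the
#' food setups — where females feed individually in 24-well vessels and
#' deplete their pool — the theoretical brood size is evaluated at the mean
#' realized daily ration, since no undepleted reference exists.
#'
#' @param setup One of "15C", "20C", "25C", "food_2.5e4", "food_5e4",
#'   "food_1.25e5", "food_2.5e5", "food_5e5".
#' @param nFemales Number of simulated females.
#' @param days Observation window, days.
#' @param seed RNG seed.
#' @return List with `broods` (per-clutch records: female, day, size, and
#'   for embryo-phase clutches the brood-to-brood period), `perFemale`
#'   (per-female mean clutch size and period), `theoretical` (function
#'   values), `summary` (mean/SD/n per endpoint) and `tTests` (one-sided
#'   [oneSampleT()] of simulated vs theoretical, sided toward the observed
#'   deviation).
#' @export
#' @examples
#' rt <- runReproductionTest("25C", nFemales = 10, seed = 1)
#' rt$summary
runReproductionTest <- function(setup, nFemales = 50, days = 15, seed = 1) {
  if (setup %in% names(.REPRO_TEMPS)) {
    cfg <- simConfig(temperature_C = .REPRO_TEMPS[[setup]],
                     foodCellsPerML = 2.5e5, vessel = vessel("well24"),
                     nInitial = nFemales, days = days,
                     reproduction = TRUE, recruitOffspring = FALSE,
                     mode = "direct_temperature", startStage = "adult",
                     startFertilized = TRUE, pFemaleInit = 1,
                     masterSeed = seed)
    theoPeriod <- 1 / temperatureResponse("pE_DEV", cfg@temperature_C,
                                          warn = FALSE)
    theoBS <- temperatureResponse("BS", cfg@temperature_C, warn = FALSE)
  } else {
    cells <- switch(setup,
      "food_2.5e4" = 2.5e4, "food_5e4" = 5e4, "food_1.25e5" = 1.25e5,
      "food_2.5e5" = 2.5e5, "food_5e5" = 5e5,
      stop("unknown setup '", setup, "'"))
    cfg <- simConfig(temperature_C = 22, foodCellsPerML = cells,
                     vessel = vessel("well24"), nInitial = nFemales,
                     days = days, reproduction = TRUE,
                     recruitOffspring = FALSE, mode = "direct_food",
                     startStage = "adult", startFertilized = TRUE,
                     pFemaleInit = 1, groupSize = 1, masterSeed = seed)
    theoPeriod <- 1 / lifeCycleParams()@pE_DEV
    theoBS <- NA_real_   # filled from the realized ration below
  }
  res <- runSimulation(cfg, seed = seed)
  br <- res@broods
  if (cfg@mode == "direct_food") {
    ## reconstruct the mean realized daily ration of one isolated female
    fd <- replicate(days, NA_real_)
    carbon <- .nominalCarbon(cfg@foodCellsPerML, cfg@vessel)
    for (d in seq_len(days)) {
      if (isFeedingDay(d - 1L, cfg@feedIntervalDays))
        carbon <- .nominalCarbon(cfg@foodCellsPerML, cfg@vessel)
      step <- simulateFeedingDay(carbon, 3L, cfg@vessel)
      fd[d] <- step$intake
      carbon <- step$carbon
    }
    theoBS <- foodResponse("BS", mean(fd), warn = FALSE)
  }
  emb <- br[br$phase == "embryo", ]
  perFemale <- data.frame(
    id = sort(unique(br$id)),
    meanSize = tapply(br$size, br$id, mean)[as.character(sort(unique(br$id)))],
    meanPeriod = tapply(emb$period, factor(emb$id, sort(unique(br$id))),
                        mean))
  summ <- rbind(
    brood_size = c(mean = mean(br$size), sd = sd(br$size), n = nrow(br)),
    period = c(mean = mean(emb$period), sd = sd(emb$period), n = nrow(emb)))
  tT <- list(
    brood_size = oneSampleT(br$size, theoBS),
    period = oneSampleT(emb$period, theoPeriod))
  list(setup = setup, broods = br, perFemale = perFemale,
       theoretical = list(period = theoPeriod, brood_size = theoBS),
       summary = summ, tTests = tT, config = cfg, seed = seed)
}
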