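## S4 classes for the central objects: life-cycle parameter set, vessel
## geometry, simulation configuration, single-run result and Monte-Carlo
## summary.

#' Life-cycle parameter set
#'
#' Holds the per-individual life-cycle parameters at reference conditions:
#' daily development rates (d^-1) for the naupliar, copepodite, latency and
#' embryonic phases, the gamma shape of each phase's duration deviate, mean
#' brood size and broods per female with their CVs, daily death probabilities
#' per stage and the probability that a maturing individual is female.
#'
#' @slot pN_DEV,pC_DEV,pL,pE_DEV Daily development rates, d^-1.
#' @slot alpha_N,alpha_C,alpha_L,alpha_E Gamma shape of the duration deviate
#'   (duration CV is `1/sqrt(alpha)`).
#' @slot pBS,cv_BS Mean brood size (nauplii per clutch) and its CV.
#' @slot pNB,cv_NB Mean broods per female and its CV.
#' @slot pS_NAU,pS_COP,pS_ADU Daily death probabilities, d^-1.
#' @slot p_female Probability of female sex at maturation.
#' @export
setClass("LifeCycleParams",
  representation(
    pN_DEV = "numeric", pC_DEV = "numeric", pL = "numeric", pE_DEV = "numeric",
    alpha_N = "numeric", alpha_C = "numeric", alpha_L = "numeric",
    alpha_E = "numeric",
    pBS = "numeric", cv_BS = "numeric", pNB = "numeric", cv_NB = "numeric",
    pS_NAU = "numeric", pS_COP = "numeric", pS_ADU = "numeric",
    p_female = "numeric"),
  validity = function(object) {
    msg <- character()
    rates <- c(object@pN_DEV, object@pC_DEV, object@pL, object@pE_DEV)
    shapes <- c(object@alpha_N, object@alpha_C, object@alpha_L, object@alpha_E)
    probs <- c(object@pS_NAU, object@pS_COP, object@pS_ADU, object@p_female)
    if (any(!is.finite(rates)) || any(rates <= 0))
      msg <- c(msg, "development rates must be positive")
    if (any(!is.finite(shapes)) || any(shapes <= 0))
      msg <- c(msg, "gamma shapes must be positive")
    if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
      msg <- c(msg, "probabilities must lie in [0, 1]")
    if (object@pBS < 0 || object@pNB < 0 || object@cv_BS < 0 ||
        object@cv_NB < 0)
      msg <- c(msg, "brood parameters must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' Construct a life-cycle parameter set
#'
#' With no arguments, returns the calibrated reference parameterization
#' (22 °C, abundant food): rates 0.129/0.111/0.308/0.315 d^-1, gamma shapes
#' 30.0/14.3/26.1/3.5, brood size 24.0 (CV 0.44), 3.64 broods per female
#' (CV 0.37) and daily death probabilities 2.65e-3/4.83e-3/3.19e-3.
#'
#' @param ... Named slot overrides, e.g. `lifeCycleParams(pBS = 30)`.
#' @return A [LifeCycleParams-class] object.
#' @export
#' @examples
#' p <- lifeCycleParams()
#' 1 / p@pN_DEV  # mean naupliar duration at reference, days
lifeCycleParams <- function(...) {
  d <- loadCoefficients()$defaults
  args <- list(
    pN_DEV = d$pN_DEV$value, pC_DEV = d$pC_DEV$value,
    pL = d$pL$value, pE_DEV = d$pE_DEV$value,
    alpha_N = d$pN_DEV$alpha, alpha_C = d$pC_DEV$alpha,
    alpha_L = d$pL$alpha, alpha_E = d$pE_DEV$alpha,
    pBS = d$pBS$value, cv_BS = d$pBS$cv,
    pNB = d$pNB$value, cv_NB = d$pNB$cv,
    pS_NAU = d$pS_NAU$value, pS_COP = d$pS_COP$value,
    pS_ADU = d$pS_ADU$value, p_female = d$p_female$value)
  args <- modifyList(args, list(...))
  do.call(new, c("LifeCycleParams", args))
}

setMethod("show", "LifeCycleParams", function(object) {
  cat("LifeCycleParams (reference conditions)\n")
  cat(sprintf("  development rates [1/d]: N %.3f  C %.3f  L %.3f  E %.3f\n",
              object@pN_DEV, object@pC_DEV, object@pL, object@pE_DEV))
  cat(sprintf("  gamma shapes:            N %.1f  C %.1f  L %.1f  E %.1f\n",
              object@alpha_N, object@alpha_C, object@alpha_L, object@alpha_E))
  cat(sprintf("  brood size %.1f (CV %.2f), broods/female %.2f (CV %.2f)\n",
              object@pBS, object@cv_BS, object@pNB, object@cv_NB))
  cat(sprintf("  daily death prob: NAU %.2e  COP %.2e  ADU %.2e\n",
              object@pS_NAU, object@pS_COP, object@pS_ADU))
})

#' Incubation vessel geometry
#'
#' @slot volume_mL Medium volume, mL.
#' @slot bottomArea_cm2 Bottom area, cm^2; food is expressed per unit bottom
#'   area because the species is bottom dwelling.
#' @slot carbonPerCell_ug Carbon content of one algal cell, ug C.
#' @export
setClass("Vessel",
  representation(volume_mL = "numeric", bottomArea_cm2 = "numeric",
                 carbonPerCell_ug = "numeric"),
  validity = function(object) {
    if (any(c(object@volume_mL, object@bottomArea_cm2,
              object@carbonPerCell_ug) <= 0))
      "volume, bottom area and carbon per cell must all be positive"
    else TRUE
  })

#' Construct a vessel, or fetch a microplate preset
#'
#' Presets mirror the laboratory setups: `"well96"` (0.27 mL, 0.32 cm^2),
#' `"well24"` (2 mL, 1.9 cm^2) and `"well6"` (8 mL, 9.6 cm^2). The default
#' carbon content per *Rhodomonas salina* cell (2.64e-5 ug = 26.4 pg C) is
#' calibrated so that the standard ration of 2.5e5 cells/mL in the 6-well
#' geometry equals the reference bottom concentration of 5.5 ug C/cm2.
#'
#' @param preset One of `"well96"`, `"well24"`, `"well6"`, or `NULL` when
#'   giving explicit geometry.
#' @param volume_mL,bottomArea_cm2 Explicit geometry (override the preset).
#' @param carbonPerCell_ug Carbon per algal cell, ug.
#' @return A [Vessel-class] object.
#' @export
#' @examples
#' vessel("well6")
#' vessel(volume_mL = 1, bottomArea_cm2 = 1)
vessel <- function(preset = NULL, volume_mL = NULL, bottomArea_cm2 = NULL,
                   carbonPerCell_ug = NULL) {
  coef <- loadCoefficients()
  if (is.null(carbonPerCell_ug)) carbonPerCell_ug <- coef$carbon_per_cell_ug
  if (!is.null(preset)) {
    if (!preset %in% names(coef$vessels))
      stop("unknown vessel preset '", preset, "'; available: ",
           paste(names(coef$vessels), collapse = ", "))
    geo <- coef$vessels[[preset]]
    if (is.null(volume_mL)) volume_mL <- geo$volume_mL
    if (is.null(bottomArea_cm2)) bottomArea_cm2 <- geo$bottom_area_cm2
  }
  if (is.null(volume_mL) || is.null(bottomArea_cm2))
    stop("either a preset or explicit volume_mL and bottomArea_cm2 required")
  new("Vessel", volume_mL = volume_mL, bottomArea_cm2 = bottomArea_cm2,
      carbonPerCell_ug = carbonPerCell_ug)
}

setMethod("show", "Vessel", function(object) {
  cat(sprintf("Vessel: %.3g mL, %.3g cm2 bottom, %.3g ug C/cell\n",
              object@volume_mL, object@bottomArea_cm2,
              object@carbonPerCell_ug))
})

#' Simulation configuration
#'
#' @slot temperature_C Water temperature, °C.
#' @slot foodCellsPerML Nominal algal concentration at each feeding, cells/mL.
#' @slot vessel A [Vessel-class]; food carbon and bottom concentration derive
#'   from it.
#' @slot nInitial Number of individuals at day 0.
#' @slot days Simulated days.
#' @slot reproduction Whether females reproduce.
#' @slot recruitOffspring Whether hatched nauplii join the population the
#'   following day (disabled in isolated-female reproduction tests, where
#'   offspring are only recorded).
#' @slot mode `"direct_temperature"`, `"direct_food"` or `"normalized"`; the
#'   direct modes apply one axis's response functions as absolute parameter
#'   values and keep the other axis at reference, the normalized mode scales
#'   the default parameters multiplicatively on both axes.
#' @slot temperatureVariant `"exp_decay"` or `"belehradek"` for the
#'   durational temperature functions (latency always uses Bělehrádek).
#' @slot startStage `"nauplius"` or `"adult"`.
#' @slot startFertilized Whether initial adult females start fertilized.
#' @slot pFemaleInit Sex probability applied to initial adults.
#' @slot groupSize Individuals sharing one food vessel (NA = whole cohort).
#' @slot feedIntervalDays Days between food replacements.
#' @slot replicates Monte-Carlo replicates for [runMonteCarlo()].
#' @slot masterSeed Master seed from which replicate seeds are split.
#' @export
setClass("SimConfig",
  representation(
    temperature_C = "numeric", foodCellsPerML = "numeric", vessel = "Vessel",
    nInitial = "numeric", days = "numeric", reproduction = "logical",
    recruitOffspring = "logical", mode = "character",
    temperatureVariant = "character", startStage = "character",
    startFertilized = "logical", pFemaleInit = "numeric",
    groupSize = "numeric", feedIntervalDays = "numeric",
    replicates = "numeric", masterSeed = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.finite(object@temperature_C))
      msg <- c(msg, "temperature_C must be finite")
    if (object@foodCellsPerML < 0)
      msg <- c(msg, "foodCellsPerML must be non-negative")
    if (object@days < 1) msg <- c(msg, "days must be >= 1")
    if (object@nInitial < 0) msg <- c(msg, "nInitial must be >= 0")
    if (object@replicates < 1) msg <- c(msg, "replicates must be >= 1")
    if (!object@mode %in% c("direct_temperature", "direct_food", "normalized"))
      msg <- c(msg, "mode must be direct_temperature, direct_food or normalized")
    if (!object@temperatureVariant %in% c("exp_decay", "belehradek"))
      msg <- c(msg, "temperatureVariant must be exp_decay or belehradek")
    if (!object@startStage %in% c("nauplius", "adult"))
      msg <- c(msg, "startStage must be nauplius or adult")
    if (object@feedIntervalDays < 1)
      msg <- c(msg, "feedIntervalDays must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Construct a simulation configuration
#'
#' Temperature is deliberately required — there is no silent default. In the
#' direct modes the other axis is held at reference: `direct_temperature`
#' assumes abundant food (no depletion loop), `direct_food` runs the
#' minute-resolution feeding loop at the configured ration with the culture
#' temperature 22 °C behind the unmodelled axes.
#'
#' @param temperature_C Water temperature, °C (required).
#' @param foodCellsPerML Nominal algal concentration, cells/mL.
#' @param vessel A [Vessel-class] (default 24-well plate geometry).
#' @param nInitial,days,replicates,masterSeed Scalars, see slots.
#' @param reproduction,recruitOffspring,startFertilized Logical flags.
#' @param mode,temperatureVariant,startStage Character selectors.
#' @param pFemaleInit Sex probability for initial adults.
#' @param groupSize Individuals per shared food vessel (NA = all together).
#' @param feedIntervalDays Days between complete food replacements.
#' @return A validated [SimConfig-class].
#' @export
#' @examples
#' cfg <- simConfig(temperature_C = 19.34, mode = "direct_temperature",
#'                  nInitial = 72, days = 35, reproduction = FALSE)
simConfig <- function(temperature_C, foodCellsPerML = 2.5e5,
                      vessel = NitocraSim::vessel("well24"),
                      nInitial = 72, days = 35,
                      reproduction = TRUE, recruitOffspring = TRUE,
                      mode = "normalized", temperatureVariant = "exp_decay",
                      startStage = "nauplius", startFertilized = FALSE,
                      pFemaleInit = 0.5, groupSize = NA_real_,
                      feedIntervalDays = 2, replicates = 1000,
                      masterSeed = 1) {
  if (missing(temperature_C))
    stop("temperature_C is required; no default temperature is assumed")
  new("SimConfig", temperature_C = temperature_C,
      foodCellsPerML = foodCellsPerML, vessel = vessel,
      nInitial = nInitial, days = days, reproduction = reproduction,
      recruitOffspring = recruitOffspring, mode = mode,
      temperatureVariant = temperatureVariant, startStage = startStage,
      startFertilized = startFertilized, pFemaleInit = pFemaleInit,
      groupSize = groupSize, feedIntervalDays = feedIntervalDays,
      replicates = replicates, masterSeed = masterSeed)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n")
  cat(sprintf("  %.2f degC, %.3g cells/mL, mode %s (%s)\n",
              object@temperature_C, object@foodCellsPerML, object@mode,
              object@temperatureVariant))
  cat(sprintf("  %d initial %s, %d days, reproduction %s\n",
              as.integer(object@nInitial), object@startStage,
              as.integer(object@days),
              if (object@reproduction) "on" else "off"))
})

#' Single-run simulation result
#'
#' @slot abundance Integer matrix, one row per day (day 0 = initial state)
#'   with columns `nauplii`, `copepodites`, `adults`, `dead` (cumulative).
#' @slot events Data frame `(id, day, event, value)`: `birth`,
#'   `molt_copepodite` and `maturation` (value = realized phase duration in
#'   days, fractional), `sex` (1 female / 2 male), `clutch` (value = clutch
#'   size) and `death` (value = age in days).
#' @slot broods Data frame `(id, day, size, period, phase)` per clutch;
#'   `period` is the realized latency or inter-clutch interval in days.
#' @slot config The [SimConfig-class] used.
#' @slot seed The RNG seed of this run.
#' @export
setClass("SimResult",
  representation(abundance = "matrix", events = "data.frame",
                 broods = "data.frame", config = "SimConfig",
                 seed = "numeric"))

setMethod("show", "SimResult", function(object) {
  final <- object@abundance[nrow(object@abundance), ]
  cat(sprintf("SimResult: %d days, seed %d\n",
              nrow(object@abundance) - 1L, as.integer(object@seed)))
  cat("  final counts:",
      paste(names(final), final, sep = "=", collapse = "  "), "\n")
  cat(sprintf("  %d events, %d clutches\n",
              nrow(object@events), nrow(object@broods)))
})

#' Monte-Carlo summary of replicated simulations
#'
#' @slot mean,lower,upper Numeric day x stage matrices: replicate means and
#'   percentile 2.5% / 97.5% bounds of the daily stage abundances. For
#'   strongly skewed count distributions (e.g. rare deaths) the replicate
#'   mean can fall outside the percentile bounds; only `lower <= upper` is
#'   guaranteed.
#' @slot replicates Number of replicates.
#' @slot config The shared [SimConfig-class].
#' @slot masterSeed Seed the replicate seeds were split from.
#' @export
setClass("MonteCarloSummary",
  representation(mean = "matrix", lower = "matrix", upper = "matrix",
                 replicates = "numeric", config = "SimConfig",
                 masterSeed = "numeric"),
  validity = function(object) {
    if (any(object@lower > object@upper + 1e-9))
      "lower percentile bound exceeds upper bound"
    else TRUE
  })

setMethod("show", "MonteCarloSummary", function(object) {
  cat(sprintf("MonteCarloSummary: %d replicates, %d days, master seed %d\n",
              as.integer(object@replicates), nrow(object@mean) - 1L,
              as.integer(object@masterSeed)))
})

#' Accessors for simulation results
#'
#' `abundance()` returns the daily stage-count matrix of a run,
#' `simEvents()` its individual event log, `broodRecords()` its clutch
#' records; `mcMean()`, `mcLower()` and `mcUpper()` return the Monte-Carlo
#' band matrices.
#'
#' @param object A [SimResult-class] or [MonteCarloSummary-class].
#' @return A matrix or data frame, see above.
#' @export
setGeneric("abundance", function(object) standardGeneric("abundance"))

#' @rdname abundance
#' @export
setGeneric("simEvents", function(object) standardGeneric("simEvents"))

#' @rdname abundance
#' @export
setGeneric("broodRecords", function(object) standardGeneric("broodRecords"))

#' @rdname abundance
#' @export
setGeneric("mcMean", function(object) standardGeneric("mcMean"))

#' @rdname abundance
#' @export
setGeneric("mcLower", function(object) standardGeneric("mcLower"))

#' @rdname abundance
#' @export
setGeneric("mcUpper", function(object) standardGeneric("mcUpper"))

#' @rdname abundance
setMethod("abundance", "SimResult", function(object) object@abundance)

#' @rdname abundance
setMethod("simEvents", "SimResult", function(object) object@events)

#' @rdname abundance
setMethod("broodRecords", "SimResult", function(object) object@broods)

#' @rdname abundance
setMethod("mcMean", "MonteCarloSummary", function(object) object@mean)

#' @rdname abundance
setMethod("mcLower", "MonteCarloSummary", function(object) object@lower)

#' @rdname abundance
setMethod("mcUpper", "MonteCarloSummary", function(object) object@upper)
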