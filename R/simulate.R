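## Daily scheduler and run engines. Process order within a day:
## feeding reset -> minute-loop ingestion -> effective parameters ->
## survival -> development/stage transitions -> reproduction; newborn
## nauplii enter the population the following day. Mortality precedes
## molting, so an individual cannot molt and die on the same day.

.STAGE_COLS <- c("nauplii", "copepodites", "adults", "dead")

#' Split a replicate seed from a master seed
#'
#' Deterministic counter-based splitting: replicate `r` of master seed `m`
#' uses `(69069 * (m + r) + 12345) mod (2^31 - 1)`, so any replicate is
#' reproducible in isolation.
#'
#' @param masterSeed Master seed (non-negative integer).
#' @param r Replicate index (1-based, vectorized).
#' @return Integer-valued seed(s) below 2^31.
#' @export
splitSeed <- function(masterSeed, r) {
  (69069 * ((masterSeed %% 2147483647) + r) + 12345) %% 2147483647
}

## Per-run closures mapping (stage, ingested carbon) -> daily parameters,
## fixed by mode/variant/temperature at run start. All warnings are raised
## once here rather than daily.
.makeParamFuns <- function(config, params) {
  mode <- config@mode
  t <- config@temperature_C
  variant <- config@temperatureVariant
  if (mode == "direct_temperature") {
    tr <- function(p, v = variant) temperatureResponse(p, t, v, warn = FALSE)
    if (t < 15 || t > 25)
      warning("quadratic optimum functions are calibrated on 15-25 degC")
    consts <- list(dev = c(tr("pN_DEV"), tr("pC_DEV")),
                   death = c(tr("pS_NAU"), tr("pS_COP"), tr("pS_ADU")),
                   lat = tr("pL", "belehradek"), emb = tr("pE_DEV"),
                   bs = tr("BS"))
    list(
      devRate = function(stage, ic) consts$dev[stage],
      deathProb = function(stage, ic) consts$death[stage],
      latRate = function(ic) rep(consts$lat, length(ic)),
      embRate = function(ic) rep(consts$emb, length(ic)),
      bsMean = function(ic) rep(consts$bs, length(ic)))
  } else if (mode == "direct_food") {
    list(
      devRate = function(stage, ic) {
        r <- numeric(length(stage))
        i <- stage == 1L
        if (any(i)) r[i] <- foodResponse("pN_DEV", ic[i], warn = FALSE)
        if (any(!i)) r[!i] <- foodResponse("pC_DEV", ic[!i], warn = FALSE)
        r
      },
      deathProb = function(stage, ic) {
        p <- numeric(length(stage))
        for (s in 1:3) {
          i <- stage == s
          if (any(i))
            p[i] <- foodResponse(c("pS_NAU", "pS_COP", "pS_ADU")[s], ic[i],
                                 warn = FALSE)
        }
        p
      },
      latRate = function(ic) rep(params@pL, length(ic)),
      embRate = function(ic) rep(params@pE_DEV, length(ic)),
      bsMean = function(ic) foodResponse("BS", ic, warn = FALSE))
  } else {
    ft <- function(p, v = variant)
      normalizationFactor(p, "temperature", v) *
        temperatureResponse(p, t, v, warn = TRUE)
    tfac <- c(N = ft("pN_DEV"), C = ft("pC_DEV"),
              SN = ft("pS_NAU"), SC = ft("pS_COP"), SA = ft("pS_ADU"),
              L = ft("pL", "belehradek"), E = ft("pE_DEV"), BS = ft("BS"))
    ffac <- function(p) normalizationFactor(p, "food")
    ff <- c(N = ffac("pN_DEV"), C = ffac("pC_DEV"), SN = ffac("pS_NAU"),
            SC = ffac("pS_COP"), SA = ffac("pS_ADU"), BS = ffac("BS"))
    clamp01 <- function(x) pmin(pmax(x, 0), 1)
    list(
      devRate = function(stage, ic) {
        r <- numeric(length(stage))
        i <- stage == 1L
        if (any(i)) r[i] <- params@pN_DEV * tfac["N"] * ff["N"] *
            foodResponse("pN_DEV", ic[i], warn = FALSE)
        if (any(!i)) r[!i] <- params@pC_DEV * tfac["C"] * ff["C"] *
            foodResponse("pC_DEV", ic[!i], warn = FALSE)
        r
      },
      deathProb = function(stage, ic) {
        p <- numeric(length(stage))
        base <- c(params@pS_NAU, params@pS_COP, params@pS_ADU)
        tf <- tfac[c("SN", "SC", "SA")]
        ffv <- ff[c("SN", "SC", "SA")]
        nm <- c("pS_NAU", "pS_COP", "pS_ADU")
        for (s in 1:3) {
          i <- stage == s
          if (any(i))
            p[i] <- base[s] * tf[s] * ffv[s] *
              foodResponse(nm[s], ic[i], warn = FALSE)
        }
        clamp01(p)
      },
      latRate = function(ic) rep(params@pL * tfac["L"], length(ic)),
      embRate = function(ic) rep(params@pE_DEV * tfac["E"], length(ic)),
      bsMean = function(ic)
        pmax(params@pBS * tfac["BS"] * ff["BS"] *
               foodResponse("BS", ic, warn = FALSE), 0))
  }
}

#' Run a single simulation
#'
#' Executes the daily scheduler for one replicate. Identical seeds and
#' configurations reproduce identical results bit for bit.
#'
#' @param config A [SimConfig-class].
#' @param seed RNG seed for this run.
#' @param trackEvents Keep the per-individual event log (disable for large
#'   Monte-Carlo sweeps where only abundances are needed).
#' @param params [LifeCycleParams-class] overriding the calibrated defaults
#'   (gamma shapes, CVs and reference rates), mainly for frozen-parameter
#'   checks.
#' @return A [SimResult-class].
#' @export
#' @examples
#' cfg <- simConfig(temperature_C = 19.34, mode = "direct_temperature",
#'                  nInitial = 20, days = 20, reproduction = FALSE)
#' res <- runSimulation(cfg, seed = 1)
#' tail(abundance(res), 3)
runSimulation <- function(config, seed = config@masterSeed,
                          trackEvents = TRUE, params = lifeCycleParams()) {
  validObject(config)
  set.seed(seed)
  pf <- suppressWarnings(.makeParamFuns(config, params))
  useFood <- config@mode != "direct_temperature"
  days <- as.integer(config@days)
  n0 <- as.integer(config@nInitial)

  pop <- .newPopulation(n0, params, config@startStage,
                        config@startFertilized, config@pFemaleInit)
  gsz <- if (is.na(config@groupSize)) max(n0, 1L)
         else as.integer(config@groupSize)
  pop$group <- ((seq_len(n0) - 1L) %/% gsz) + 1L
  pop$fertDay <- rep(-1L, n0)
  if (config@startFertilized) pop$fertDay[pop$fertilized] <- 0L

  nominal <- .nominalCarbon(config@foodCellsPerML, config@vessel)
  carbon <- rep(nominal, max(pop$group, 1L))

  refIC <- vapply(.STAGES, function(s)
    hollingIngestion(s, referenceConditions()$bottom_concentration_ugC_cm2),
    numeric(1))

  ab <- matrix(0L, nrow = days + 1L, ncol = 4L,
               dimnames = list(0:days, .STAGE_COLS))
  ab[1L, ] <- c(tabulate(pop$stage[pop$alive], 3L), sum(!pop$alive))

  ev <- list(); evn <- 0L
  logEv <- function(id, day, event, value) {
    if (!trackEvents || length(id) == 0) return()
    evn <<- evn + 1L
    ev[[evn]] <<- data.frame(id = id, day = day, event = event,
                             value = value)
  }
  br <- list(); brn <- 0L
  queue <- list()

  for (day in seq_len(days)) {
    ## newborns queued yesterday enter today
    if (length(queue)) {
      sizes <- vapply(queue, `[[`, numeric(1), "size")
      groups <- vapply(queue, `[[`, numeric(1), "group")
      ntot <- sum(sizes)
      nb <- .newPopulation(as.integer(ntot), params,
                           idOffset = length(pop$id), day = day)
      nb$group <- rep(as.integer(groups), times = sizes)
      nb$fertDay <- rep(-1L, ntot)
      for (f in names(pop)) pop[[f]] <- c(pop[[f]], nb[[f]])
      logEv(nb$id, day, "birth", 0)
      queue <- list()
    }
    n <- length(pop$id)
    alive <- pop$alive

    ## feeding-day reset and minute-loop ingestion
    ic <- numeric(n)
    if (useFood) {
      if (isFeedingDay(day - 1L, config@feedIntervalDays))
        carbon[] <- nominal
      for (g in unique(pop$group[alive])) {
        i <- which(alive & pop$group == g)
        fd <- simulateFeedingDay(carbon[g], pop$stage[i], config@vessel)
        ic[i] <- fd$intake
        carbon[g] <- fd$carbon
      }
    } else {
      ic[alive] <- refIC[pop$stage[alive]]
    }

    ## survival
    ia <- which(alive)
    if (length(ia)) {
      pDeath <- pf$deathProb(pop$stage[ia], ic[ia])
      surv <- applyDailySurvival(length(ia), pDeath)
      died <- ia[!surv]
      if (length(died)) {
        pop$alive[died] <- FALSE
        logEv(pop$id[died], day, "death", day - pop$birthday[died])
      }
    }

    ## development and stage transitions (survivors only)
    idev <- which(pop$alive & pop$stage < 3L)
    if (length(idev)) {
      rate <- pf$devRate(pop$stage[idev], ic[idev])
      prev <- pop$progress[idev]
      pop$progress[idev] <- prev + rate
      pop$steps[idev] <- pop$steps[idev] + 1L
      comp <- pop$progress[idev] >= pop$deviate[idev] & rate > 0
      if (any(comp)) {
        ci <- idev[comp]
        frac <- (pop$deviate[ci] - prev[comp]) / rate[comp]
        dur <- pop$steps[ci] - 1L + frac
        stg <- pop$stage[ci]
        molt <- ci[stg == 1L]
        mat <- ci[stg == 2L]
        if (length(molt)) {
          logEv(pop$id[molt], day, "molt_copepodite", dur[stg == 1L])
          pop$stage[molt] <- 2L
          pop$deviate[molt] <- drawDevelopmentDeviate(length(molt),
                                                      params@alpha_C)
          pop$progress[molt] <- 0
          pop$steps[molt] <- 0L
        }
        if (length(mat)) {
          logEv(pop$id[mat], day, "maturation", dur[stg == 2L])
          pop$stage[mat] <- 3L
          sx <- assignSex(length(mat), params@p_female)
          pop$sex[mat] <- sx
          logEv(pop$id[mat], day, "sex", sx)
          fem <- mat[sx == 1L]
          if (length(fem))
            pop$broodsRemaining[fem] <-
              as.integer(drawBroodCount(length(fem), params@pNB,
                                        params@cv_NB))
        }
      }
    }

    ## reproduction
    if (config@reproduction) {
      malePresent <- any(pop$alive & pop$stage == 3L & pop$sex == 2L)
      if (malePresent) {
        newf <- which(pop$alive & pop$stage == 3L & pop$sex == 1L &
                        !pop$fertilized)
        if (length(newf)) {
          pop$fertilized[newf] <- TRUE
          pop$fertDay[newf] <- day
          pop$reproPhase[newf] <- 1L
          pop$reproDeviate[newf] <- drawDevelopmentDeviate(length(newf),
                                                           params@alpha_L)
          pop$reproProgress[newf] <- 0
          pop$reproSteps[newf] <- 0L
        }
      }
      ## latency/embryo clocks advance from the day after fertilization
      irep <- which(pop$alive & pop$fertilized & pop$reproPhase %in% 1:2 &
                      pop$broodsRemaining > 0L & pop$fertDay < day)
      if (length(irep)) {
        phase <- pop$reproPhase[irep]
        rate <- numeric(length(irep))
        rate[phase == 1L] <- pf$latRate(ic[irep[phase == 1L]])
        rate[phase == 2L] <- pf$embRate(ic[irep[phase == 2L]])
        prev <- pop$reproProgress[irep]
        pop$reproProgress[irep] <- prev + rate
        pop$reproSteps[irep] <- pop$reproSteps[irep] + 1L
        comp <- which(pop$reproProgress[irep] >= pop$reproDeviate[irep] &
                        rate > 0)
        for (j in comp) {
          i <- irep[j]
          frac <- (pop$reproDeviate[i] - prev[j]) / rate[j]
          period <- pop$reproSteps[i] - 1L + frac
          size <- drawBroodSize(1L, pf$bsMean(ic[i]), params@cv_BS)
          brn <- brn + 1L
          br[[brn]] <- data.frame(
            id = pop$id[i], day = day, size = size, period = period,
            phase = if (pop$reproPhase[i] == 1L) "latency" else "embryo")
          logEv(pop$id[i], day, "clutch", size)
          pop$broodsRemaining[i] <- pop$broodsRemaining[i] - 1L
          if (pop$broodsRemaining[i] > 0L) {
            pop$reproPhase[i] <- 2L
            pop$reproDeviate[i] <- drawDevelopmentDeviate(1L,
                                                          params@alpha_E)
            pop$reproProgress[i] <- 0
            pop$reproSteps[i] <- 0L
          } else {
            pop$reproPhase[i] <- 3L
          }
          if (config@recruitOffspring && size > 0)
            queue[[length(queue) + 1L]] <- list(size = size,
                                                group = pop$group[i])
        }
      }
    }

    ab[day + 1L, ] <- c(tabulate(pop$stage[pop$alive], 3L),
                        sum(!pop$alive))
  }

  empty_ev <- data.frame(id = integer(), day = integer(),
                         event = character(), value = numeric())
  empty_br <- data.frame(id = integer(), day = integer(), size = numeric(),
                         period = numeric(), phase = character())
  new("SimResult", abundance = ab,
      events = if (evn) do.call(rbind, ev) else empty_ev,
      broods = if (brn) do.call(rbind, br) else empty_br,
      config = config, seed = seed)
}

#' Monte-Carlo replication with percentile confidence bands
#'
#' Runs `replicates` independent simulations, with per-replicate seeds split
#' deterministically from the master seed (see [splitSeed()]), and summarizes
#' the daily stage abundances as replicate means with percentile 2.5%/97.5%
#' bounds — appropriate for count data, unlike a normal approximation.
#'
#' @param config A [SimConfig-class].
#' @param replicates Number of replicates (default from the config).
#' @param masterSeed Master seed (default from the config).
#' @return A [MonteCarloSummary-class].
#' @export
runMonteCarlo <- function(config, replicates = config@replicates,
                          masterSeed = config@masterSeed) {
  if (replicates < 2) stop("replicates must be >= 2")
  days <- as.integer(config@days)
  arr <- array(0, dim = c(days + 1L, 4L, replicates))
  for (r in seq_len(replicates)) {
    res <- runSimulation(config, seed = splitSeed(masterSeed, r),
                         trackEvents = FALSE)
    arr[, , r] <- res@abundance
  }
  dn <- list(0:days, .STAGE_COLS)
  mk <- function(m) matrix(m, nrow = days + 1L, ncol = 4L, dimnames = dn)
  new("MonteCarloSummary",
      mean = mk(apply(arr, c(1, 2), mean)),
      lower = mk(apply(arr, c(1, 2), quantile, probs = 0.025)),
      upper = mk(apply(arr, c(1, 2), quantile, probs = 0.975)),
      replicates = replicates, config = config, masterSeed = masterSeed)
}

#' Extract realized stage durations from a run
#'
#' Realized durations are fractional: within the completion day the crossing
#' time of the development threshold is interpolated linearly, so under a
#' constant rate the realized duration equals `deviate / rate` exactly and
#' sample means are unbiased estimates of the theoretical mean duration.
#'
#' @param result A [SimResult-class] run with `trackEvents = TRUE`.
#' @return Data frame `(id, stage, duration)` with stage `"nauplius"` or
#'   `"copepodite"`.
#' @export
stageDurations <- function(result) {
  ev <- result@events
  ev <- ev[ev$event %in% c("molt_copepodite", "maturation"), ]
  data.frame(id = ev$id,
             stage = ifelse(ev$event == "molt_copepodite", "nauplius",
                            "copepodite"),
             duration = ev$value)
}
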