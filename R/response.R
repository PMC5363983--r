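## Response-function layer: pure functions mapping temperature (degC) and
## ingested carbon (ug C per individual per day) to effective life-cycle
## parameters, plus the normalization scheme that anchors every function at
## the reference conditions (22 degC; 5.5 ug C/cm2 bottom food).

.TEMP_PARAMS <- c("pN_DEV", "pC_DEV", "pE_DEV", "pL", "BS",
                  "pS_NAU", "pS_COP", "pS_ADU")
.FOOD_PARAMS <- c("pN_DEV", "pC_DEV", "BS", "pS_NAU", "pS_COP", "pS_ADU")
.STAGES <- c("nauplius", "copepodite", "adult")

#' Holling type-III ingestion response
#'
#' Daily carbon ration of one individual as a sigmoid function of the bottom
#' food concentration: `a_max * c^2 / (c^2 + k^2)`, with stage-specific
#' maximum ration `a_max` and half-saturation concentration `k`.
#'
#' @param stage `"nauplius"`, `"copepodite"` or `"adult"`.
#' @param cFood Bottom food concentration, ug C/cm^2 (vectorized).
#' @return Ingested carbon, ug C per individual per day.
#' @export
#' @examples
#' hollingIngestion("nauplius", 3.1993)  # half of the 0.2981 maximum
hollingIngestion <- function(stage, cFood) {
  stage <- match.arg(stage, .STAGES)
  if (any(!is.finite(cFood)) || any(cFood < 0))
    stop("cFood must be finite and non-negative")
  ing <- loadCoefficients()$ingestion[[stage]]
  ing$a_max * cFood^2 / (cFood^2 + ing$k^2)
}

.evalTempFun <- function(fun, t) {
  switch(fun$type,
    exp_decay = 1 / (fun$a + fun$b * exp(-fun$c * t)),
    belehradek = 1 / (fun$a * (t + fun$t0)^fun$b * fun$scale),
    quadratic = (fun$c0 + fun$c1 * t + fun$c2 * t^2) / fun$divisor,
    stop("unknown temperature function type '", fun$type, "'"))
}

#' Temperature response functions
#'
#' Evaluates the calibrated temperature dependence of a life-cycle parameter.
#' Durational parameters (`pN_DEV`, `pC_DEV`, `pE_DEV`, `pL`) return a daily
#' rate whose reciprocal is the mean phase duration; two fitted variants
#' exist, a three-parameter exponential decay (independent fits per phase,
#' the default used in verification) and a shared Bělehrádek power law
#' (assumes equiproportional stage durations; the only variant available for
#' latency). `BS` returns the expected brood size and the `pS_*` parameters
#' the daily death probability, both from quadratic optimum curves
#' calibrated on 15–25 °C; outside that range the quadratics are evaluated
#' but a warning is emitted, and probabilities are clamped to \[0, 1\]
#' (brood size to >= 0) with a warning when the raw polynomial leaves the
#' physical range.
#'
#' @param parameter One of `pN_DEV`, `pC_DEV`, `pE_DEV`, `pL`, `BS`,
#'   `pS_NAU`, `pS_COP`, `pS_ADU`.
#' @param t Temperature, °C (vectorized).
#' @param variant `"exp_decay"` or `"belehradek"` (durational parameters
#'   only; ignored for the quadratic parameters).
#' @param warn Emit range/clamping warnings (disable in tight loops).
#' @return Parameter value: rate or probability in d^-1, or a count for `BS`.
#' @export
#' @examples
#' 1 / temperatureResponse("pN_DEV", 14.86)  # mean naupliar duration, days
temperatureResponse <- function(parameter, t, variant = "exp_decay",
                                warn = TRUE) {
  parameter <- match.arg(parameter, .TEMP_PARAMS)
  variant <- match.arg(variant, c("exp_decay", "belehradek"))
  if (any(!is.finite(t))) stop("temperature must be finite")
  funs <- loadCoefficients()$temperature[[parameter]]
  quadratic <- !is.null(funs$quadratic)
  fun <- if (quadratic) funs$quadratic else funs[[variant]]
  if (is.null(fun))
    stop("no '", variant, "' temperature function for ", parameter,
         " (latency has only the Belehradek variant)")
  if (quadratic && warn && any(t < 15 | t > 25))
    warning("quadratic optimum functions are calibrated on 15-25 degC; ",
            "no extrapolation guarantee at t outside that range")
  val <- .evalTempFun(fun, t)
  if (quadratic) {
    if (parameter == "BS") {
      if (any(val < 0)) {
        if (warn) warning("brood size clamped to 0")
        val <- pmax(val, 0)
      }
    } else if (any(val < 0 | val > 1)) {
      if (warn) warning("death probability clamped to [0, 1]")
      val <- pmin(pmax(val, 0), 1)
    }
  }
  val
}

.checkIC <- function(parameter, ic) {
  stage <- loadCoefficients()$food[[parameter]]$stage
  amax <- loadCoefficients()$ingestion[[stage]]$a_max
  if (any(!is.finite(ic)) || any(ic < 0))
    stop("ingested carbon must be finite and non-negative")
  if (any(ic > amax * (1 + 1e-8)))
    stop("ingested carbon exceeds the ", stage, " Holling maximum of ",
         amax, " ug C/d")
  stage
}

#' Food response functions
#'
#' Evaluates the dependence of a life-cycle parameter on the daily ingested
#' carbon of the stage that the parameter belongs to (naupliar IC for
#' `pN_DEV`/`pS_NAU`, copepodite IC for `pC_DEV`/`pS_COP`, adult IC for
#' `BS`/`pS_ADU`). Development rates follow power laws, brood size an
#' exponential saturation (0 at zero ration), and death probabilities a
#' rational (naupliar, adult) or cubic (copepodite) curve; probabilities
#' are clamped to \[0, 1\].
#'
#' @param parameter One of `pN_DEV`, `pC_DEV`, `BS`, `pS_NAU`, `pS_COP`,
#'   `pS_ADU`.
#' @param ic Ingested carbon, ug C per individual per day (vectorized);
#'   must not exceed the stage's Holling maximum.
#' @param warn Emit clamping warnings.
#' @return Parameter value, as for [temperatureResponse()].
#' @export
#' @examples
#' foodResponse("pN_DEV", 0)  # starvation: 0.0009 1/d, ~3 years
foodResponse <- function(parameter, ic, warn = TRUE) {
  parameter <- match.arg(parameter, .FOOD_PARAMS)
  .checkIC(parameter, ic)
  fun <- loadCoefficients()$food[[parameter]]
  val <- switch(fun$type,
    power = fun$c0 + fun$c1 * ic^fun$c2,
    exp_saturation = fun$c0 * (1 - exp(-fun$c1 * ic)),
    rational = 1 / (fun$c0 + fun$c1 * ic),
    cubic = fun$c0 + fun$c1 * ic + fun$c2 * ic^2 + fun$c3 * ic^3,
    stop("unknown food function type '", fun$type, "'"))
  if (parameter %in% c("pS_NAU", "pS_COP", "pS_ADU") &&
      any(val < 0 | val > 1)) {
    if (warn) warning("death probability clamped to [0, 1]")
    val <- pmin(pmax(val, 0), 1)
  }
  val
}

#' Normalizing factor of a response function
#'
#' The reciprocal of the response function at the reference condition
#' (22 °C on the temperature axis; on the food axis the ingestion at the
#' reference bottom concentration, 5.5 ug C/cm2). Multiplying `factor *
#' f(x)` therefore yields a dimensionless scaling that equals 1 at
#' reference, which is how the response functions modulate the default
#' parameters in `normalized` mode.
#'
#' @param parameter Parameter name, as in [temperatureResponse()] /
#'   [foodResponse()].
#' @param axis `"temperature"` or `"food"`.
#' @param variant Temperature variant for durational parameters.
#' @param cRef Reference bottom concentration, ug C/cm2 (food axis).
#' @return Positive scalar.
#' @export
#' @examples
#' normalizationFactor("pN_DEV", "temperature")  # 5.85 d at 22 degC
normalizationFactor <- function(parameter, axis = c("temperature", "food"),
                                variant = "exp_decay",
                                cRef = referenceConditions()$bottom_concentration_ugC_cm2) {
  axis <- match.arg(axis)
  ref <- referenceConditions()
  if (axis == "temperature") {
    1 / temperatureResponse(parameter, ref$temperature_C, variant,
                            warn = FALSE)
  } else {
    parameter <- match.arg(parameter, .FOOD_PARAMS)
    stage <- loadCoefficients()$food[[parameter]]$stage
    1 / foodResponse(parameter, hollingIngestion(stage, cRef), warn = FALSE)
  }
}

#' Effective life-cycle parameter under temperature and food
#'
#' Combines the response functions into the value the simulator uses.
#' `mode = "direct"` applies one axis's function as the absolute parameter
#' value, the verification-experiment convention: give either `t` or `ic`,
#' never both. A parameter without a function on the requested direct axis
#' (latency and embryonic development have no food dependence) falls back
#' to its reference default. `mode = "normalized"` scales the reference
#' default multiplicatively by `factor_t * f_t(t)` and `factor_f * f_f(ic)`
#' for whichever axes are given — an interaction-free assumption, since the
#' calibration varied one axis at a time. Death probabilities are clamped
#' to \[0, 1\] and rates to >= 0.
#'
#' @param parameter Parameter name (see [temperatureResponse()]).
#' @param t Temperature, °C, or `NULL`.
#' @param ic Ingested carbon, ug C/d, or `NULL`.
#' @param mode `"direct"` or `"normalized"`.
#' @param variant Temperature variant for durational parameters.
#' @param params [LifeCycleParams-class] supplying the defaults.
#' @param warn Emit clamping warnings.
#' @return Parameter value.
#' @export
#' @examples
#' effectiveParameter("pE_DEV", t = 19.34, mode = "direct")  # 1/3.39 per day
effectiveParameter <- function(parameter, t = NULL, ic = NULL,
                               mode = c("normalized", "direct"),
                               variant = "exp_decay",
                               params = lifeCycleParams(), warn = TRUE) {
  mode <- match.arg(mode)
  parameter <- match.arg(parameter, .TEMP_PARAMS)
  if (parameter == "pL") variant <- "belehradek"  # only fitted variant
  default <- switch(parameter, BS = params@pBS,
                    pN_DEV = params@pN_DEV, pC_DEV = params@pC_DEV,
                    pE_DEV = params@pE_DEV, pL = params@pL,
                    pS_NAU = params@pS_NAU, pS_COP = params@pS_COP,
                    pS_ADU = params@pS_ADU)
  if (mode == "direct") {
    if (!is.null(t) && !is.null(ic))
      stop("direct mode applies one axis at a time; give t or ic, not both")
    if (is.null(t) && is.null(ic))
      stop("direct mode needs t or ic")
    if (!is.null(t))
      return(temperatureResponse(parameter, t, variant, warn = warn))
    if (!parameter %in% .FOOD_PARAMS) return(rep(default, length(ic)))
    return(foodResponse(parameter, ic, warn = warn))
  }
  val <- default
  if (!is.null(t))
    val <- val * normalizationFactor(parameter, "temperature", variant) *
      temperatureResponse(parameter, t, variant, warn = warn)
  if (!is.null(ic) && parameter %in% .FOOD_PARAMS)
    val <- val * normalizationFactor(parameter, "food") *
      foodResponse(parameter, ic, warn = warn)
  if (parameter %in% c("pS_NAU", "pS_COP", "pS_ADU"))
    val <- pmin(pmax(val, 0), 1)
  else
    val <- pmax(val, 0)
  val
}
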