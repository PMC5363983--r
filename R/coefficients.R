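## Coefficient tables (ingestion, temperature, food, defaults) are shipped
## as a human-readable YAML file and cached per session after validation.

.coefCache <- new.env(parent = emptyenv())

.coefPath <- function() {
  system.file("extdata", "model_coefficients.yaml", package = "NitocraSim",
              mustWork = TRUE)
}

#' Load the model coefficient tables
#'
#' Reads the versioned YAML file holding every coefficient of the life-cycle
#' model: Holling type-III ingestion parameters per stage, temperature and
#' food response-function coefficients with their normalizing factors, the
#' default life-cycle parameters, reference conditions and vessel presets.
#' Loading validates completeness; a missing block or coefficient is an error.
#'
#' @param path Path to a coefficient YAML file. Defaults to the file shipped
#'   with the package.
#' @return A named list with elements `reference`, `defaults`, `ingestion`,
#'   `temperature`, `food`, `vessels` and `carbon_per_cell_ug`.
#' @export
#' @examples
#' coef <- loadCoefficients()
#' coef$ingestion$adult
loadCoefficients <- function(path = NULL) {
  default <- is.null(path)
  if (default && !is.null(.coefCache$coef)) return(.coefCache$coef)
  if (default) path <- .coefPath()
  coef <- yaml::yaml.load_file(path)
  .validateCoefficients(coef)
  if (default) .coefCache$coef <- coef
  coef
}

.validateCoefficients <- function(coef) {
  need <- c("version", "reference", "defaults", "ingestion", "temperature",
            "food", "vessels", "carbon_per_cell_ug")
  miss <- setdiff(need, names(coef))
  if (length(miss))
    stop("coefficient file incomplete, missing block(s): ",
         paste(miss, collapse = ", "))
  stages <- c("nauplius", "copepodite", "adult")
  for (s in stages) {
    ing <- coef$ingestion[[s]]
    if (is.null(ing$a_max) || is.null(ing$k))
      stop("ingestion coefficients incomplete for stage ", s)
  }
  tpar <- c("pN_DEV", "pC_DEV", "pE_DEV", "pL", "BS",
            "pS_NAU", "pS_COP", "pS_ADU")
  miss <- setdiff(tpar, names(coef$temperature))
  if (length(miss))
    stop("temperature functions missing for: ", paste(miss, collapse = ", "))
  fpar <- c("pN_DEV", "pC_DEV", "BS", "pS_NAU", "pS_COP", "pS_ADU")
  miss <- setdiff(fpar, names(coef$food))
  if (length(miss))
    stop("food functions missing for: ", paste(miss, collapse = ", "))
  dpar <- c("pN_DEV", "pC_DEV", "pL", "pE_DEV", "pBS", "pNB",
            "pS_NAU", "pS_COP", "pS_ADU")
  miss <- setdiff(dpar, names(coef$defaults))
  if (length(miss))
    stop("default parameters missing for: ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Reference conditions of the model calibration
#'
#' The response functions are anchored at a culture temperature of 22 °C and,
#' on the food axis, at the bottom food concentration corresponding to the
#' standard ration of 2.5e5 algal cells/mL (5.5 ug C/cm2). Normalizing
#' factors are reciprocals of the response functions at these conditions.
#'
#' @return Named list with `temperature_C` and `bottom_concentration_ugC_cm2`.
#' @export
referenceConditions <- function() {
  ref <- loadCoefficients()$reference
  list(temperature_C = ref$temperature_C,
       bottom_concentration_ugC_cm2 = ref$bottom_concentration_ugC_cm2)
}
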