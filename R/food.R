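## Food dynamics: nominal algal concentrations -> benthic carbon, and
## competitive depletion of the food pool in one-minute steps over a day.

#' Convert an algal cell concentration to a bottom food concentration
#'
#' The species grazes on the vessel floor, so the carbon of all suspended
#' cells is referred to the bottom area:
#' `cells/mL * volume_mL * carbonPerCell_ug / bottomArea_cm2`.
#'
#' @param cellsPerML Nominal algal concentration, cells/mL (vectorized).
#' @param vessel A [Vessel-class].
#' @return Bottom food concentration, ug C/cm^2.
#' @export
#' @examples
#' cellsToBottomConcentration(2.5e5, vessel("well6"))  # 5.5 ug C/cm2
cellsToBottomConcentration <- function(cellsPerML, vessel) {
  stopifnot(is(vessel, "Vessel"))
  if (any(cellsPerML < 0)) stop("cellsPerML must be non-negative")
  cellsPerML * vessel@volume_mL * vessel@carbonPerCell_ug /
    vessel@bottomArea_cm2
}

## total carbon in a freshly fed vessel [ug C]
.nominalCarbon <- function(cellsPerML, vessel) {
  cellsPerML * vessel@volume_mL * vessel@carbonPerCell_ug
}

#' Simulate one day of competitive feeding in a vessel
#'
#' Ingestion is integrated over 24 h in 1440 one-minute steps: every minute
#' each living individual ingests 1/1440 of its Holling type-III daily
#' ration at the current bottom concentration, the total is removed from
#' the vessel's food pool, and the concentration falls accordingly. If one
#' minute's aggregate demand exceeds the remaining food, the allocation is
#' scaled proportionally and the pool floors at zero. The loop is
#' deterministic given the stage composition; carbon is conserved exactly.
#'
#' @param totalCarbon Food carbon in the vessel at day start, ug C.
#' @param stages Integer vector of living feeders' stages (1 nauplius,
#'   2 copepodite, 3 adult), or a character vector of stage names.
#' @param vessel A [Vessel-class].
#' @return List: `intake` (ug C ingested today, one entry per individual in
#'   input order), `carbon` (remaining pool), `consumed` (total removed).
#' @export
#' @examples
#' simulateFeedingDay(50, c("adult"), vessel("well6"))$intake  # ~ 0.2623
simulateFeedingDay <- function(totalCarbon, stages, vessel) {
  stopifnot(is(vessel, "Vessel"))
  if (is.character(stages))
    stages <- match(stages, c("nauplius", "copepodite", "adult"))
  if (length(stages) == 0)
    return(list(intake = numeric(0), carbon = totalCarbon, consumed = 0))
  if (any(is.na(stages)) || any(!stages %in% 1:3))
    stop("stages must be nauplius/copepodite/adult")
  ing <- loadCoefficients()$ingestion
  res <- .minuteLoopCpp(totalCarbon, vessel@bottomArea_cm2,
                        tabulate(stages, 3L),
                        c(ing$nauplius$a_max, ing$copepodite$a_max,
                          ing$adult$a_max),
                        c(ing$nauplius$k, ing$copepodite$k, ing$adult$k))
  list(intake = res$intake[stages], carbon = res$carbon,
       consumed = res$consumed)
}

#' Feeding schedule
#'
#' Food is fully replaced (reset to the nominal amount, not topped up)
#' every `interval` days, starting on day 0 — the simplified every-second-day
#' schedule used in simulations.
#'
#' @param day Day index, 0-based (vectorized).
#' @param interval Days between replacements.
#' @return Logical: is food replaced at the start of this day?
#' @export
#' @examples
#' isFeedingDay(0:5)  # TRUE FALSE TRUE FALSE TRUE FALSE
isFeedingDay <- function(day, interval = 2) {
  if (any(day < 0)) stop("day must be >= 0")
  day %% interval == 0
}
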