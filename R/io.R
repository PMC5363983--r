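## Configuration files, tidy output writing, run manifests and scripted
## re-computation of the tabulated verification quantities.

.CONFIG_KEYS <- c("preset", "temperature_C", "food_cells_per_mL", "vessel",
                  "vessel_volume_mL", "vessel_bottom_area_cm2",
                  "carbon_per_cell_ug", "n_initial", "days", "reproduction",
                  "recruit_offspring", "mode", "temperature_variant",
                  "start_stage", "start_fertilized", "p_female_init",
                  "group_size", "feed_interval_days", "replicates",
                  "master_seed")

#' Load a simulation configuration from YAML or JSON
#'
#' Keys carry their units in their names (`temperature_C`,
#' `food_cells_per_mL`, ...) to prevent unit mistakes. `preset` may name a
#' development-test setup (`devtest-20C`, `devtest-food_2.5e4`, ...), whose
#' settings individual keys then override. Unknown keys are an error, named
#' exhaustively; `temperature_C` has no default and is required unless a
#' preset supplies it.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated [SimConfig-class].
#' @export
loadConfig <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::yaml.load_file(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  base <- NULL
  if (!is.null(raw$preset)) {
    if (!grepl("^devtest-", raw$preset))
      stop("unknown preset '", raw$preset, "'")
    base <- developmentTestConfig(sub("^devtest-", "", raw$preset))
  }
  ves <- if (!is.null(raw$vessel)) vessel(raw$vessel,
           carbonPerCell_ug = raw$carbon_per_cell_ug)
  else if (!is.null(raw$vessel_volume_mL) ||
           !is.null(raw$vessel_bottom_area_cm2))
    vessel(volume_mL = raw$vessel_volume_mL,
           bottomArea_cm2 = raw$vessel_bottom_area_cm2,
           carbonPerCell_ug = raw$carbon_per_cell_ug)
  else if (!is.null(base)) base@vessel
  else vessel("well24")
  pick <- function(key, slot, fallback) {
    if (!is.null(raw[[key]])) raw[[key]]
    else if (!is.null(base)) slot(base, slot)
    else fallback
  }
  if (is.null(raw$temperature_C) && is.null(base))
    stop("temperature_C is required (no default temperature is assumed)")
  simConfig(
    temperature_C = pick("temperature_C", "temperature_C", NULL),
    foodCellsPerML = pick("food_cells_per_mL", "foodCellsPerML", 2.5e5),
    vessel = ves,
    nInitial = pick("n_initial", "nInitial", 72),
    days = pick("days", "days", 35),
    reproduction = pick("reproduction", "reproduction", TRUE),
    recruitOffspring = pick("recruit_offspring", "recruitOffspring", TRUE),
    mode = pick("mode", "mode", "normalized"),
    temperatureVariant = pick("temperature_variant", "temperatureVariant",
                              "exp_decay"),
    startStage = pick("start_stage", "startStage", "nauplius"),
    startFertilized = pick("start_fertilized", "startFertilized", FALSE),
    pFemaleInit = pick("p_female_init", "pFemaleInit", 0.5),
    groupSize = pick("group_size", "groupSize", NA_real_),
    feedIntervalDays = pick("feed_interval_days", "feedIntervalDays", 2),
    replicates = pick("replicates", "replicates", 1000),
    masterSeed = pick("master_seed", "masterSeed", 1))
}

#' Build a run manifest
#'
#' Records everything needed to reproduce an output bit for bit: the full
#' configuration, coefficient-file version, master seed and package version.
#'
#' @param config A [SimConfig-class].
#' @param masterSeed Seed used.
#' @return Named list, serializable as JSON.
#' @export
runManifest <- function(config, masterSeed = config@masterSeed) {
  cfgList <- lapply(slotNames(config), function(s) {
    v <- slot(config, s)
    if (is(v, "Vessel"))
      list(volume_mL = v@volume_mL, bottomArea_cm2 = v@bottomArea_cm2,
           carbonPerCell_ug = v@carbonPerCell_ug)
    else v
  })
  names(cfgList) <- slotNames(config)
  list(package = "NitocraSim",
       package_version = as.character(utils::packageVersion("NitocraSim")),
       coefficients_version = loadCoefficients()$version,
       master_seed = masterSeed,
       timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
       config = cfgList)
}

#' Write tidy outputs of a run
#'
#' Writes deterministic CSVs — per-day stage counts (`abundance.csv`),
#' event log (`events.csv`), clutch records (`broods.csv`) and, when a
#' Monte-Carlo summary is given, long-format percentile bands
#' (`bands.csv`) — plus the manifest as `manifest.json`. Given the same
#' result the CSVs are byte-identical across runs.
#'
#' @param result A [SimResult-class].
#' @param outdir Output directory (created if needed).
#' @param summary Optional [MonteCarloSummary-class].
#' @param manifest Optional manifest list (default built from the result).
#' @return Invisibly, the paths written.
#' @export
writeOutputs <- function(result, outdir, summary = NULL, manifest = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  w <- function(df, file) {
    p <- file.path(outdir, file)
    write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  ab <- data.frame(day = as.integer(rownames(result@abundance)),
                   result@abundance, check.names = FALSE)
  w(ab, "abundance.csv")
  w(result@events, "events.csv")
  w(result@broods, "broods.csv")
  if (!is.null(summary)) {
    days <- as.integer(rownames(summary@mean))
    stages <- colnames(summary@mean)
    bands <- data.frame(
      day = rep(days, times = length(stages)),
      stage = rep(stages, each = length(days)),
      mean = as.vector(summary@mean),
      lower = as.vector(summary@lower),
      upper = as.vector(summary@upper))
    w(bands, "bands.csv")
  }
  if (is.null(manifest)) manifest <- runManifest(result@config)
  mp <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths <- c(paths, mp)
  invisible(paths)
}

.TARGETS <- list(
  t1 = list(what = "exact test p, temperature sex-ratio counts",
            fixture = "temperature-sexratio"),
  t2 = list(what = "exact test p, temperature copepodite mortality",
            fixture = "temperature-copepodite-mortality"),
  t3 = list(what = "exact test p, temperature naupliar mortality",
            fixture = "temperature-naupliar-mortality"),
  t4 = list(what = "exact test p, food naupliar mortality",
            fixture = "food-naupliar-mortality"),
  t5 = list(what = "exact test p, food copepodite mortality",
            fixture = "food-copepodite-mortality"),
  t6 = list(what = "exact test p, food sex-ratio counts",
            fixture = "food-sexratio"))

#' Recompute a tabulated verification quantity
#'
#' Executes the recipe behind one verification target and returns the
#' freshly computed value next to the tabulated one. Targets `t1`–`t6` are
#' the exact-test p-values on the packaged contingency fixtures; `t7`–`t9`
#' are reference durations/reciprocals of the temperature functions at
#' 22 °C (naupliar development, embryonic development, reciprocal naupliar
#' daily mortality); `t10`–`t12` evaluate the brood-size quadratic at the
#' measured 15 °C and 25 °C setup temperatures and the embryonic-development
#' duration at the measured 20 °C setup temperature.
#'
#' @param id Target id, `"t1"` .. `"t12"`.
#' @return List: `id`, `description`, `value` (computed), `expected`
#'   (tabulated), `n` (problem size: table total or evaluation count).
#' @export
#' @examples
#' reproduceTarget("t7")
reproduceTarget <- function(id) {
  fix <- experimentFixtures()
  temps <- fix$measured_temperatures
  dur <- function(p, t, digits = 2)
    round(1 / temperatureResponse(p, t, warn = FALSE), digits)
  r <- switch(id,
    t7 = list(description = "reference naupliar duration at 22 degC [d]",
              value = dur("pN_DEV", 22),
              expected = loadCoefficients()$temperature$pN_DEV$exp_decay$factor,
              n = 1),
    t8 = list(description = "reference embryonic duration at 22 degC [d]",
              value = dur("pE_DEV", 22),
              expected = loadCoefficients()$temperature$pE_DEV$exp_decay$factor,
              n = 1),
    t9 = list(description = "reciprocal naupliar daily mortality at 22 degC [d]",
              value = round(1 / temperatureResponse("pS_NAU", 22,
                                                    warn = FALSE)),
              expected = loadCoefficients()$temperature$pS_NAU$quadratic$factor,
              n = 1),
    t10 = list(description = "brood size at measured 15C-setup temperature",
               value = round(temperatureResponse("BS", temps$`15C`$mean,
                                                 warn = FALSE), 2),
               expected = fix$development_summaries$`15C`$brood_size$mean,
               n = 1),
    t11 = list(description = "brood size at measured 25C-setup temperature",
               value = round(temperatureResponse("BS", temps$`25C`$mean,
                                                 warn = FALSE), 2),
               expected = fix$development_summaries$`25C`$brood_size$mean,
               n = 1),
    t12 = list(description = "embryonic duration at measured 20C-setup temperature [d]",
               value = dur("pE_DEV", temps$`20C`$mean),
               expected = fix$development_summaries$`20C`$embryonic$mean,
               n = 1),
    {
      if (!id %in% names(.TARGETS))
        stop("unknown target id '", id, "'; available: ",
             paste(c(names(.TARGETS), paste0("t", 7:12)), collapse = ", "))
      tg <- .TARGETS[[id]]
      tab <- fixtureTable(tg$fixture)
      list(description = tg$what,
           value = fisherExactRxC(tab)$p.value,
           expected = attr(tab, "reported_p"),
           n = sum(tab))
    })
  c(list(id = id), r)
}
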