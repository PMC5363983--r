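test_that("identical seeds reproduce identical runs bit for bit", {
  cfg <- simConfig(temperature_C = 18, foodCellsPerML = 2.5e5,
                   nInitial = 24, days = 20, mode = "normalized",
                   groupSize = 6)
  a <- suppressWarnings(runSimulation(cfg, seed = 123))
  b <- suppressWarnings(runSimulation(cfg, seed = 123))
  expect_identical(abundance(a), abundance(b))
  expect_identical(simEvents(a), simEvents(b))
  expect_identical(broodRecords(a), broodRecords(b))
  c <- suppressWarnings(runSimulation(cfg, seed = 124))
  expect_false(identical(abundance(a), abundance(c)))
})

test_that("replicate seeds split deterministically from the master seed", {
  expect_identical(splitSeed(1, 1:3), splitSeed(1, 1:3))
  expect_true(all(splitSeed(0:5, 1) < 2^31))
  cfg <- simConfig(temperature_C = 19.34, mode = "direct_temperature",
                   nInitial = 30, days = 15, reproduction = FALSE,
                   masterSeed = 77)
  sm1 <- runMonteCarlo(cfg, replicates = 5)
  sm2 <- runMonteCarlo(cfg, replicates = 5)
  expect_identical(mcMean(sm1), mcMean(sm2))
  # replicate 3 in isolation equals its slice of the sweep
  r3 <- runSimulation(cfg, seed = splitSeed(77, 3), trackEvents = FALSE)
  arr <- sapply(1:5, function(r)
    abundance(runSimulation(cfg, seed = splitSeed(77, r),
                            trackEvents = FALSE))[16, "adults"])
  expect_identical(abundance(r3)[16, "adults"], arr[3])
})

test_that("no development happens without food; nobody is lost", {
  cfg <- developmentTestConfig("food_0", masterSeed = 1)
  cfg@days <- 10
  res <- runSimulation(cfg, seed = 4)
  ab <- abundance(res)
  expect_true(all(rowSums(ab) == 35))
  expect_true(all(ab[, "copepodites"] == 0))
  expect_true(all(ab[, "adults"] == 0))
  # starvation rate 0.0009/d cannot cross a mean-1 deviate in 10 days
  expect_equal(nrow(stageDurations(res)), 0)
})

test_that("Monte-Carlo bands bracket the mean and are percentile-shaped", {
  cfg <- simConfig(temperature_C = 19.34, mode = "direct_temperature",
                   nInitial = 72, days = 35, reproduction = FALSE)
  sm <- runMonteCarlo(cfg, replicates = 40, masterSeed = 5)
  expect_true(all(mcLower(sm) <= mcUpper(sm)))
  # the mean lies inside the percentile band nearly everywhere (it can
  # escape only for strongly skewed count cells, e.g. rare deaths)
  inside <- mcLower(sm) <= mcMean(sm) + 1e-9 &
    mcUpper(sm) >= mcMean(sm) - 1e-9
  expect_gte(mean(inside), 0.9)
  expect_equal(dim(mcMean(sm)), c(36, 4))
  # the relative band narrows for larger cohorts (binomial scaling)
  relWidth <- function(n) {
    cc <- simConfig(temperature_C = 19.34, mode = "direct_temperature",
                    nInitial = n, days = 20, reproduction = FALSE)
    s <- runMonteCarlo(cc, replicates = 40, masterSeed = 6)
    (mcUpper(s)[15, "copepodites"] - mcLower(s)[15, "copepodites"]) / n
  }
  expect_lt(relWidth(320), relWidth(20))
})

test_that("direct-mode simulated means recover the function values", {
  cfg <- simConfig(temperature_C = 19.34, mode = "direct_temperature",
                   nInitial = 2000, days = 60, reproduction = FALSE)
  d <- stageDurations(runSimulation(cfg, seed = 31))
  mn <- tapply(d$duration, d$stage, mean)
  expect_equal(unname(mn["nauplius"]),
               1 / temperatureResponse("pN_DEV", 19.34), tolerance = 0.02)
  expect_equal(unname(mn["copepodite"]),
               1 / temperatureResponse("pC_DEV", 19.34), tolerance = 0.02)
})

test_that("development-test presets encode the experimental conditions", {
  cfg <- developmentTestConfig("20C")
  expect_equal(cfg@nInitial, 72)
  expect_equal(cfg@days, 35)
  expect_false(cfg@reproduction)
  expect_equal(cfg@temperature_C, 19.34)
  expect_equal(cfg@mode, "direct_temperature")
  cfgf <- developmentTestConfig("food_2.5e4")
  expect_equal(cfgf@nInitial, 35)
  expect_equal(cfgf@days, 45)
  expect_equal(cfgf@groupSize, 6)
  expect_equal(cfgf@mode, "direct_food")
  expect_error(developmentTestConfig("30C"), "unknown setup")
})

test_that("population-mode females need a male before reproducing", {
  # all-female cohort: fertilization never happens, no clutches
  frozen <- lifeCycleParams(pS_ADU = 0, pS_NAU = 0, pS_COP = 0)
  cfg <- simConfig(temperature_C = 22, nInitial = 6, days = 12,
                   reproduction = TRUE, mode = "normalized",
                   vessel = bigReferenceVessel(), startStage = "adult",
                   startFertilized = FALSE, pFemaleInit = 1)
  res <- runSimulation(cfg, seed = 8, params = frozen)
  expect_equal(nrow(broodRecords(res)), 0)
  # with a male present, clutches appear and offspring are recruited
  cfg2 <- simConfig(temperature_C = 22, nInitial = 6, days = 14,
                    reproduction = TRUE, mode = "normalized",
                    vessel = bigReferenceVessel(), startStage = "adult",
                    startFertilized = FALSE, pFemaleInit = 0.5)
  res2 <- runSimulation(cfg2, seed = 8, params = frozen)
  expect_gt(nrow(broodRecords(res2)), 0)
  expect_gt(abundance(res2)[15, "nauplii"], 0)
})

test_that("the reproduction test reports broods, periods and comparisons", {
  rt <- runReproductionTest("25C", nFemales = 25, seed = 2)
  expect_setequal(colnames(rt$broods),
                  c("id", "day", "size", "period", "phase"))
  expect_true(all(rt$broods$size >= 0))
  expect_true(all(rt$broods$period > 0))
  expect_equal(rt$theoretical$period,
               1 / temperatureResponse("pE_DEV", 24.90), tolerance = 1e-9)
  expect_equal(rt$theoretical$brood_size,
               temperatureResponse("BS", 24.90), tolerance = 1e-9)
  expect_true(all(c("p.value", "side") %in% names(rt$tTests$period)))
  # food setup: theoretical brood size comes from the realized ration
  rtf <- runReproductionTest("food_2.5e4", nFemales = 15, seed = 2)
  expect_lt(rtf$theoretical$brood_size, 24)
  expect_gt(rtf$theoretical$brood_size, 0)
  expect_error(runReproductionTest("food_0"), "unknown setup")
})
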