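test_that("development deviates are gamma with mean 1 and CV 1/sqrt(alpha)", {
  set.seed(42)
  x <- drawDevelopmentDeviate(1e4, 30)
  expect_equal(mean(x), 1, tolerance = 0.01)
  expect_lt(abs(sd(x) / mean(x) - 1 / sqrt(30)), 0.01)
  expect_gt(sampleSkewness(x), 0)
  # the skewness survives at every calibrated shape
  for (a in c(30.0, 14.3, 26.1, 3.5)) {
    y <- drawDevelopmentDeviate(5e3, a)
    expect_gt(sampleSkewness(y), 0)
  }
  expect_error(drawDevelopmentDeviate(10, 0), "positive")
  expect_error(drawDevelopmentDeviate(10, -2), "positive")
})

test_that("daily survival is Bernoulli with the right compound rate", {
  set.seed(7)
  expect_true(all(applyDailySurvival(1000, 0)))
  expect_false(any(applyDailySurvival(1000, 1)))
  expect_error(applyDailySurvival(10, 1.2), "\\[0, 1\\]")
  # survival over 8 days at the naupliar reference death probability
  p <- 2.65e-3
  alive <- rep(TRUE, 1e5)
  for (d in 1:8) alive[alive] <- applyDailySurvival(sum(alive), p)
  expect_equal(mean(alive), (1 - p)^8, tolerance = 0.002 / (1 - p)^8)
})

test_that("brood-size and brood-count samplers honor mean, CV, truncation", {
  set.seed(11)
  expect_identical(drawBroodSize(5, 24, 0), rep(24, 5))
  expect_identical(drawBroodSize(5, 0, 0.5), rep(0, 5))
  x <- drawBroodSize(1e5, 24, 0.44)
  expect_true(all(x >= 0) && all(x == round(x)))
  expect_equal(mean(x), 24, tolerance = 0.2 / 24)
  expect_identical(drawBroodCount(3, 3.64, 0), rep(4, 3))
  y <- drawBroodCount(1e5)
  expect_equal(mean(y), 3.64, tolerance = 0.05 / 3.64)
  expect_error(drawBroodSize(3, -1, 0.2), "non-negative")
})

test_that("sex assignment is a configurable Bernoulli", {
  set.seed(3)
  expect_identical(assignSex(10, 1), rep(1L, 10))
  expect_identical(assignSex(10, 0), rep(2L, 10))
  expect_equal(mean(assignSex(1e4, 0.5) == 1L), 0.5, tolerance = 0.03)
  expect_error(assignSex(5, 1.5), "\\[0, 1\\]")
})

test_that("development completes on the threshold-crossing day", {
  # frozen deviates (huge shape) and reference rates: naupliar phase
  # completes on day ceil(1/0.129) = 8 with realized duration 1/0.129
  frozen <- lifeCycleParams(alpha_N = 1e9, alpha_C = 1e9,
                            pS_NAU = 0, pS_COP = 0, pS_ADU = 0)
  cfg <- simConfig(temperature_C = 22, foodCellsPerML = 2.5e5,
                   vessel = bigReferenceVessel(), nInitial = 5, days = 20,
                   reproduction = FALSE, mode = "normalized")
  res <- runSimulation(cfg, seed = 2, params = frozen)
  molt <- simEvents(res)[simEvents(res)$event == "molt_copepodite", ]
  expect_equal(nrow(molt), 5)
  expect_true(all(molt$day == 8))
  expect_equal(molt$value, rep(1 / 0.129, 5), tolerance = 1e-4)
})

test_that("reproduction cycles: first clutch after latency, then embryo cadence", {
  # frozen deviates and CVs at 22 degC: first clutch on day ceil(3.23),
  # subsequent clutches every ceil(3.25) days, constant clutch size
  frozen <- lifeCycleParams(alpha_L = 1e9, alpha_E = 1e9, cv_BS = 0,
                            cv_NB = 0, pNB = 3)
  cfg <- simConfig(temperature_C = 22, nInitial = 1, days = 15,
                   reproduction = TRUE, recruitOffspring = FALSE,
                   mode = "direct_temperature", startStage = "adult",
                   startFertilized = TRUE, pFemaleInit = 1)
  res <- runSimulation(cfg, seed = 5, params = frozen)
  br <- broodRecords(res)
  expect_equal(br$day, c(4, 8, 12))
  expect_equal(br$phase, c("latency", "embryo", "embryo"))
  # the frozen deviate still jitters at ~1e-5 (gamma shape 1e9)
  expect_equal(br$period[1], 1 / temperatureResponse("pL", 22, "belehradek"),
               tolerance = 1e-3)
  expect_equal(br$period[2:3],
               rep(1 / temperatureResponse("pE_DEV", 22), 2),
               tolerance = 1e-3)
  expect_true(all(br$size == br$size[1]))
  # exhausted brood budget: no further clutches
  expect_equal(nrow(br), 3)
})

test_that("stage sequence is irreversible and conservation holds daily", {
  cfg <- simConfig(temperature_C = 19.34, mode = "direct_temperature",
                   nInitial = 72, days = 35, reproduction = FALSE)
  res <- runSimulation(cfg, seed = 9)
  ab <- abundance(res)
  expect_true(all(rowSums(ab) == 72))
  # cumulative dead never decreases; adults never decrease (no exit path)
  expect_true(all(diff(ab[, "dead"]) >= 0))
  # per-individual event order: molt before maturation, nothing after death
  ev <- simEvents(res)
  for (i in unique(ev$id)) {
    e <- ev[ev$id == i, ]
    m <- e$day[e$event == "molt_copepodite"]
    a <- e$day[e$event == "maturation"]
    d <- e$day[e$event == "death"]
    if (length(a)) expect_true(length(m) == 1 && m <= a)
    if (length(d)) expect_true(all(e$day <= d))
  }
})

test_that("simulated durations converge to the reference means", {
  # constant reference conditions: mean naupliar duration 1/0.129 = 7.75 d,
  # copepodite 1/0.111 = 9.01 d
  cfg <- simConfig(temperature_C = 22, foodCellsPerML = 2.5e5,
                   vessel = bigReferenceVessel(), nInitial = 3000,
                   days = 60, reproduction = FALSE, mode = "normalized")
  res <- runSimulation(cfg, seed = 21)
  d <- stageDurations(res)
  mn <- tapply(d$duration, d$stage, mean)
  expect_equal(unname(mn["nauplius"]), 1 / 0.129, tolerance = 0.012)
  expect_equal(unname(mn["copepodite"]), 1 / 0.111, tolerance = 0.012)
  expect_gt(sampleSkewness(d$duration[d$stage == "nauplius"]), 0)
  expect_gt(sampleSkewness(d$duration[d$stage == "copepodite"]), 0)
})
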