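test_that("Holling ingestion matches its closed form and is saturating", {
  expect_equal(hollingIngestion("nauplius", 0), 0)
  # half-saturation: exactly half the maximum ration
  expect_equal(hollingIngestion("nauplius", 3.1993), 0.2981 / 2)
  # direct evaluation of the printed adult curve at the reference ration
  expect_equal(hollingIngestion("adult", 5.5),
               0.2623 * 5.5^2 / (5.5^2 + 1.5053^2), tolerance = 1e-12)
  # monotone, bounded by the maximum ration
  cc <- seq(0, 100, length.out = 400)
  for (s in c("nauplius", "copepodite", "adult")) {
    v <- hollingIngestion(s, cc)
    expect_true(all(diff(v) >= 0))
    expect_lt(max(v), loadCoefficients()$ingestion[[s]]$a_max)
  }
  expect_error(hollingIngestion("adult", -1), "non-negative")
})

test_that("temperature functions hit the tabulated stage means", {
  # (measured setup temperature, tabulated duration mean) pairs
  cases <- data.frame(
    p = rep(c("pN_DEV", "pC_DEV", "pE_DEV"), each = 3),
    t = rep(c(14.86, 19.34, 24.90), 3),
    d = c(9.52, 6.44, 5.57, 12.31, 10.12, 8.86, 4.08, 3.39, 3.18))
  for (i in seq_len(nrow(cases)))
    expect_equal(round(1 / temperatureResponse(cases$p[i], cases$t[i]), 2),
                 cases$d[i], info = paste(cases$p[i], cases$t[i]))
  expect_equal(round(temperatureResponse("BS", 24.90), 2), 10.95)
  expect_equal(round(1 / temperatureResponse("pL", 22, "belehradek"), 2),
               3.23)
})

test_that("quadratic functions warn and clamp outside physical ranges", {
  expect_warning(temperatureResponse("pS_NAU", 30), "calibrated")
  # near the survival optimum the raw quadratic goes slightly negative
  expect_warning(v <- temperatureResponse("pS_NAU", 19.72), "clamped")
  expect_identical(v, 0)
  # out of calibration range and negative: warns for both, clamps to 0
  bs <- suppressWarnings(temperatureResponse("BS", 30))
  expect_identical(bs, 0)
  expect_silent(temperatureResponse("pS_ADU", 22, warn = FALSE))
  expect_error(temperatureResponse("pL", 22, "exp_decay"), "Belehradek")
  expect_error(temperatureResponse("pX", 22), "arg")
})

test_that("food functions match printed intercepts and clamp probabilities", {
  expect_equal(foodResponse("pN_DEV", 0), 0.0009)
  expect_equal(foodResponse("BS", 0), 0)
  expect_equal(foodResponse("pS_NAU", 0), 1 / 25.3937)
  expect_error(foodResponse("pN_DEV", -0.1), "non-negative")
  # stage-appropriate bound: copepodite functions reject naupliar rations
  expect_error(foodResponse("pC_DEV", 0.2), "Holling maximum")
  for (ic in c(0, 0.01, 0.05)) {
    v <- foodResponse("pS_COP", ic, warn = FALSE)
    expect_true(v >= 0 && v <= 1)
  }
})

test_that("normalizing factors are reciprocals of the reference response", {
  # temperature axis: printed factors at printed rounding
  expect_equal(round(normalizationFactor("pN_DEV", "temperature"), 2), 5.85)
  expect_equal(round(normalizationFactor("pC_DEV", "temperature"), 2), 9.38)
  expect_equal(round(normalizationFactor("pE_DEV", "temperature"), 2), 3.25)
  expect_equal(round(normalizationFactor("pL", "temperature",
                                         "belehradek"), 2), 3.23)
  expect_equal(round(normalizationFactor("pS_NAU", "temperature")), 975)
  expect_equal(round(normalizationFactor("pS_COP", "temperature")), 147)
  expect_equal(round(normalizationFactor("pS_ADU", "temperature")), 250)
  # food axis: printed factor times reference response within 1%
  # (copepodite mortality 5%: the tabulated 333 is not exactly recoverable
  # from the reference ration)
  printed <- c(pN_DEV = 7.43, pC_DEV = 11.8, BS = 0.0324, pS_NAU = 690,
               pS_COP = 333, pS_ADU = 1111)
  for (p in names(printed)) {
    ratio <- printed[[p]] / normalizationFactor(p, "food")
    tol <- if (p == "pS_COP") 0.05 else 0.01
    expect_lt(abs(ratio - 1), tol, label = paste("factor ratio", p))
  }
  # Belehradek variants share the temperature factors
  expect_equal(round(normalizationFactor("pN_DEV", "temperature",
                                         "belehradek"), 2), 5.85,
               tolerance = 0.01)
})

test_that("effective parameters return defaults at reference conditions", {
  p <- lifeCycleParams()
  ref <- referenceConditions()
  defaults <- c(pN_DEV = p@pN_DEV, pC_DEV = p@pC_DEV, pE_DEV = p@pE_DEV,
                pL = p@pL, BS = p@pBS, pS_NAU = p@pS_NAU, pS_COP = p@pS_COP,
                pS_ADU = p@pS_ADU)
  for (nm in names(defaults)) {
    stage <- loadCoefficients()$food[[nm]]$stage
    ic <- if (is.null(stage)) NULL
          else hollingIngestion(stage, ref$bottom_concentration_ugC_cm2)
    v <- effectiveParameter(nm, t = ref$temperature_C, ic = ic,
                            mode = "normalized", warn = FALSE)
    tol <- if (nm == "pS_COP") 0.05 else 0.01
    expect_lt(abs(v / defaults[[nm]] - 1), tol, label = nm)
  }
})

test_that("direct mode applies one axis and composes as documented", {
  expect_equal(1 / effectiveParameter("pE_DEV", t = 19.34, mode = "direct"),
               3.39, tolerance = 5e-4)
  expect_error(effectiveParameter("pN_DEV", t = 20, ic = 0.1,
                                  mode = "direct"), "one axis")
  expect_error(effectiveParameter("pN_DEV", mode = "direct"), "needs")
  # no food function for embryonic development: direct food falls back
  expect_equal(effectiveParameter("pE_DEV", ic = 0.1, mode = "direct"),
               lifeCycleParams()@pE_DEV)
  # starvation survival composition: default x temp scaling x food scaling
  v <- effectiveParameter("pS_NAU", t = 22, ic = 0, warn = FALSE)
  manual <- lifeCycleParams()@pS_NAU *
    normalizationFactor("pS_NAU", "temperature") *
    temperatureResponse("pS_NAU", 22, warn = FALSE) *
    normalizationFactor("pS_NAU", "food") * (1 / 25.3937)
  expect_equal(v, min(manual, 1), tolerance = 1e-12)
})

test_that("optimum curves peak where the vertex formula says", {
  # brood size maximum at c1/(2*|c2|)
  tt <- seq(5, 30, by = 0.001)
  bs <- suppressWarnings(temperatureResponse("BS", tt, warn = FALSE))
  expect_equal(tt[which.max(bs)], 4.0229 / (2 * 0.143), tolerance = 1e-3)
  # survival minima (= optima) lie near the observed 20 degC optimum
  for (p in c("pS_NAU", "pS_COP", "pS_ADU")) {
    v <- temperatureResponse(p, tt, warn = FALSE)
    expect_gt(tt[which.min(v)], 17)
    expect_lt(tt[which.min(v)], 20.5)
  }
})

test_that("an exact 3-point fit recovers the exponential-decay coefficients", {
  co <- loadCoefficients()$temperature
  tt <- c(14.86, 19.34, 24.90)
  # fitting through unrounded function values recovers each printed triple
  for (p in c("pN_DEV", "pC_DEV", "pE_DEV")) {
    est <- oracleExpDecayFit(tt, 1 / temperatureResponse(p, tt))
    printed <- unlist(co[[p]]$exp_decay[c("a", "b", "c")])
    expect_equal(unname(est), unname(printed), tolerance = 1e-8)
  }
  # through the rounded tabulated naupliar means the printed coefficients
  # come back within 0.5% (the other triples are ill-conditioned at
  # 2-decimal rounding)
  est <- oracleExpDecayFit(tt, c(9.52, 6.44, 5.57))
  expect_lt(max(abs(est / c(5.3676, 373.3086, 0.3027) - 1)), 0.005)
})

test_that("coefficient loading validates completeness", {
  coef <- loadCoefficients()
  expect_equal(coef$version, 1)
  broken <- coef
  broken$food$pS_ADU <- NULL
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(broken, tmp)
  expect_error(loadCoefficients(tmp), "pS_ADU")
})
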