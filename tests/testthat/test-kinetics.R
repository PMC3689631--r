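# Fractional synthesis, the conveyor-belt model and lag/rate estimation.

test_that("fractional synthesis is the EM1 ratio with clamping", {
  expect_equal(fractionalSynthesis(0, 0.02)$raw, 0)
  expect_equal(fractionalSynthesis(0.02, 0.02)$raw, 1)
  expect_equal(fractionalSynthesis(0.0135, 0.027)$raw, 0.5)
  over <- fractionalSynthesis(0.03, 0.027)
  expect_gt(over$raw, 1)
  expect_equal(over$clamped, 1)
  expect_error(fractionalSynthesis(0.01, 0), "degenerate")
})

test_that("fractional synthesis is scale-invariant", {
  set.seed(3)
  for (i in 1:10) {
    em1 <- runif(1, 0, 0.03); mx <- runif(1, 0.01, 0.05)
    s <- runif(1, 0.1, 10)
    expect_equal(fractionalSynthesis(em1, mx)$raw,
                 fractionalSynthesis(s * em1, s * mx)$raw,
                 tolerance = 1e-12)
  }
})

test_that("the conveyor curve has the right shape and values", {
  expect_equal(predictF(4, 4, 1), 0)
  expect_equal(predictF(2, 4, 1), 0)
  expect_equal(predictF(5, 4, log(2)), 0.5)
  expect_equal(predictF(1e4, 4, 1), 1, tolerance = 1e-12)
  ff <- predictF(seq(0, 40, 0.5), 7, 0.3)
  expect_true(all(diff(ff) >= 0))
  expect_true(all(ff >= 0 & ff < 1))
  expect_error(predictF(1, -1, 1), "tau")
  expect_error(predictF(1, 1, 0), "k")
})

test_that("series convert to f and round-trip the forward model", {
  curve <- simulateBodyWater(buildProtocolSchedule(durationDays = 28))
  days <- c(3, 6, 10, 13, 17, 21, 24, 28)
  model <- defaultLabelingModel()
  fTrue <- predictF(days, 5, 0.8)
  em1 <- vapply(seq_along(days), function(i)
    em1Max(timeAveragedEnrichment(curve, days[i]), model) * fTrue[i],
    numeric(1))
  series <- tapeStripSeries("S1", "A", TRUE, days, em1, curve)
  pts <- seriesToF(series)
  expect_equal(pts$f, fTrue, tolerance = 1e-9)

  # zero EM1 gives zero f
  z <- tapeStripSeries("S1", "B", FALSE, days, rep(0, length(days)), curve)
  expect_equal(seriesToF(z)$f, rep(0, length(days)))

  # a day-0 strip has no accumulated precursor: flagged and excluded
  d0 <- tapeStripSeries("S1", "C", TRUE, c(0, days), c(0, em1), curve)
  expect_warning(p0 <- seriesToF(d0), "excluded")
  expect_equal(nrow(p0), length(days))
  expect_equal(nrow(attr(p0, "excluded")), 1)
})

test_that("noise-free fits recover generating parameters", {
  days <- seq(3, 30, by = 3)
  pts <- data.frame(day = days, f = predictF(days, 12, 0.15))
  fit <- fitConveyor(pts, fitConfig(nBoot = 0))
  expect_equal(lagDays(fit), 12)
  expect_equal(replacementRate(fit), 0.15, tolerance = 1e-6)

  pts2 <- data.frame(day = days, f = predictF(days, 4, 1))
  fit2 <- fitConveyor(pts2, fitConfig(nBoot = 0))
  expect_equal(lagDays(fit2), 4)
  expect_equal(replacementRate(fit2), 1, tolerance = 1e-6)
})

test_that("degenerate series are flagged rather than fitted blindly", {
  expect_error(fitConveyor(data.frame(day = c(1, 2), f = c(0, 0.5)),
                           fitConfig(nBoot = 0)), "insufficient")
  # no rise at all: k non-identifiable, tau only bounded below
  flat <- data.frame(day = c(3, 5, 8), f = c(0, 0, 0))
  fit <- fitConveyor(flat, fitConfig(nBoot = 0))
  expect_true("nonIdentifiableK" %in% fitFlags(fit))
  expect_equal(lagDays(fit), 8)
  # saturated everywhere post-lag: k only bounded below
  days <- seq(3, 15, 3)
  sat <- data.frame(day = days, f = predictF(days, 2, 5))
  fitS <- fitConveyor(sat, fitConfig(nBoot = 0))
  expect_true("kLowerBound" %in% fitFlags(fitS))
  # a single point on the rise cannot pin tau and k jointly
  one <- data.frame(day = c(3, 6, 10), f = c(0, 0, 0.4))
  fitO <- fitConveyor(one, fitConfig(nBoot = 0))
  expect_true("sparseRise" %in% fitFlags(fitO))
})

test_that("bootstrap intervals are seeded, ordered and cover the estimate", {
  set.seed(99)
  days <- seq(3, 21, 2)
  f <- pmax(0, predictF(days, 6, 0.5) * (1 + rnorm(length(days), 0, 0.05)))
  cfg <- fitConfig(nBoot = 40, seed = 5)
  fit1 <- fitConveyor(data.frame(day = days, f = f), cfg)
  fit2 <- fitConveyor(data.frame(day = days, f = f), cfg)
  expect_equal(fit1@tauCI, fit2@tauCI)
  expect_equal(fit1@kCI, fit2@kCI)
  expect_lte(fit1@tauCI[1], lagDays(fit1))
  expect_gte(fit1@tauCI[2], lagDays(fit1))
  expect_lte(fit1@kCI[1], replacementRate(fit1))
  expect_gte(fit1@kCI[2], replacementRate(fit1))
})

test_that("lag estimates are nearly unbiased under measurement noise", {
  set.seed(42)
  days <- seq(3, 21, by = 2)
  fTrue <- predictF(days, 4, 1)
  taus <- replicate(30, {
    f <- pmax(0, fTrue * (1 + rnorm(length(days), 0, 0.05)))
    lagDays(fitConveyor(data.frame(day = days, f = f),
                        fitConfig(nBoot = 0)))
  })
  expect_lt(abs(mean(taus) - 4), 0.5)
})

test_that("appearance time is the first threshold crossing", {
  pts <- data.frame(day = c(3, 8, 12, 16), f = c(0, 0, 0.6, 0.9))
  expect_equal(appearanceTime(pts), 12)
  low <- data.frame(day = c(3, 8), f = c(0.01, 0.02))
  at <- appearanceTime(low)
  expect_true(is.na(at))
  expect_equal(attr(at, "censoredAt"), 8)
  # lesional-like site: tau 4, k 1 sampled at 3, 5, 8 appears at day 5
  les <- data.frame(day = c(3, 5, 8), f = predictF(c(3, 5, 8), 4, 1))
  expect_equal(appearanceTime(les), 5)
  expect_error(appearanceTime(pts, threshold = 0), "threshold")
})

test_that("site comparison summarizes groups and within-subject spread", {
  mkfit <- function(sid, site, les, tau, k)
    new("ConveyorFit", subjectId = sid, siteId = site, lesional = les,
        tau = tau, k = k, rss = 0, tauCI = c(NA_real_, NA_real_),
        kCI = c(NA_real_, NA_real_), nPoints = 5L, flags = character(0))
  fits <- list(mkfit("S1", "a", TRUE, 4, 1), mkfit("S1", "b", TRUE, 4.5, 1),
               mkfit("S1", "c", FALSE, 15, 0.15),
               mkfit("S1", "d", FALSE, 15, 0.15))
  cmp <- compareSites(fits)
  les <- cmp$groups[cmp$groups$lesional, ]
  uni <- cmp$groups[!cmp$groups$lesional, ]
  expect_equal(les$tauMedian, 4.25)
  expect_equal(uni$tauMedian, 15)
  expect_equal(uni$tauMax - uni$tauMin, 0)       # identical fits
  ws <- cmp$withinSubject
  expect_equal(ws$tauRange[ws$lesional], 0.5)    # two sites, 4.0 and 4.5
  expect_error(compareSites(fits[1:2]), "per group")
})
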