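# Dosing protocol expansion, the one-compartment impulse model and
# time-averaged precursor enrichment.

test_that("weekly protocols expand to the right number of events", {
  # 16 consecutive days starting Monday contain 12 weekdays
  expect_equal(nrow(dosingEvents(buildProtocolSchedule(durationDays = 16))),
               24)
  # 38 days contain 28 weekdays
  expect_equal(nrow(dosingEvents(buildProtocolSchedule(durationDays = 38))),
               56)
  # one day, once daily, dosing every day
  expect_equal(nrow(dosingEvents(buildProtocolSchedule(
    durationDays = 1, dosesPerDay = 1, weekdayPattern = 1:7))), 1)
  expect_error(buildProtocolSchedule(durationDays = 16,
                                     weekdayPattern = integer(0)),
               "weekday")
  expect_error(buildProtocolSchedule(durationDays = 0), "durationDays")
})

test_that("an empty schedule yields an identically zero curve", {
  empty <- new("DosingSchedule",
               events = data.frame(day = numeric(0), volumeML = numeric(0),
                                   purity = numeric(0)))
  curve <- simulateBodyWater(empty)
  expect_true(all(curve@enrichment == 0))
})

test_that("a single dose with no turnover settles at dose/volume", {
  sched <- new("DosingSchedule",
               events = data.frame(day = 0.5, volumeML = 50, purity = 0.70))
  curve <- simulateBodyWater(sched, bodyWaterParams(35, 0),
                             grid = seq(0, 5, 0.25))
  expect_equal(enrichmentAt(curve, 3), 35 / 35000)
  expect_equal(enrichmentAt(curve, 0.25), 0)
})

test_that("closed-form superposition matches numerical ODE integration", {
  skip_if_not_installed("deSolve")
  sched <- buildProtocolSchedule(durationDays = 21)
  params <- bodyWaterParams()
  curve <- simulateBodyWater(sched, params)
  # avoid exact dose instants, where the jump makes the value ambiguous
  tt <- seq(0.1, 24.9, by = 0.2)
  ode <- oracleBodyWater(dosingEvents(sched), params$bodyWaterVolume,
                         params$waterTurnoverRate, tt)
  expect_equal(enrichmentAt(curve, tt), ode, tolerance = 1e-8)
})

test_that("protracted dosing rises to a plateau with weekend dips", {
  curve <- simulateBodyWater(buildProtocolSchedule(durationDays = 38))
  p <- enrichmentAt(curve, 1:38)
  # rise: later weeks sit above the first week
  expect_gt(mean(p[22:26]), mean(p[1:5]))
  # weekend dip: Monday morning (day 7 + 0.2) below previous Friday night
  expect_lt(enrichmentAt(curve, 7.2), enrichmentAt(curve, 4.9))
  # plateau bounded by continuous-intake limit: daily intake / (V * k)
  bound <- (2 * 50 * 0.7 / 42000) / 0.10
  expect_true(all(curve@enrichment <= bound))
})

test_that("dosing superposition is linear", {
  sched <- buildProtocolSchedule(durationDays = 14)
  ev <- dosingEvents(sched)
  odd <- new("DosingSchedule", events = ev[seq(1, nrow(ev), 2), ])
  even <- new("DosingSchedule", events = ev[seq(2, nrow(ev), 2), ])
  tt <- seq(0, 18, 0.1)
  total <- enrichmentAt(simulateBodyWater(sched), tt)
  parts <- enrichmentAt(simulateBodyWater(odd), tt) +
    enrichmentAt(simulateBodyWater(even), tt)
  expect_equal(total, parts, tolerance = 1e-12)
})

test_that("measured saliva points interpolate piecewise-linearly", {
  curve <- interpolateMeasured(data.frame(day = c(0, 10),
                                          enrichment = c(0, 0.02)))
  expect_equal(enrichmentAt(curve, 5), 0.01)
  # held flat beyond the last point
  expect_equal(enrichmentAt(curve, 15), 0.02)
  const <- interpolateMeasured(data.frame(day = c(1, 5, 9),
                                          enrichment = 0.012))
  expect_equal(enrichmentAt(const, c(2, 7)), c(0.012, 0.012))
  # zero at labeling start is assumed when no earlier point exists
  expect_equal(enrichmentAt(const, 0), 0)
  expect_error(interpolateMeasured(data.frame(day = c(3, 3),
                                              enrichment = c(0.1, 0.2))),
               "distinct")
  expect_error(interpolateMeasured(data.frame(day = 1, enrichment = 0.1)),
               "insufficient")
})

test_that("time-averaged enrichment matches closed forms and quadrature", {
  const <- interpolateMeasured(data.frame(day = c(0, 30),
                                          enrichment = c(0.015, 0.015)))
  expect_equal(timeAveragedEnrichment(const, 12), 0.015)
  ramp <- interpolateMeasured(data.frame(day = c(0, 10),
                                         enrichment = c(0, 0.02)))
  expect_equal(timeAveragedEnrichment(ramp, 10), 0.01)
  expect_error(timeAveragedEnrichment(ramp, 0), "day > 0")

  # simulated sawtooth vs fine-grid quadrature of the same superposition
  curve <- simulateBodyWater(buildProtocolSchedule(durationDays = 21))
  for (t in c(6, 13, 20.5)) {
    tt <- seq(0, t, length.out = 200001)
    vals <- enrichmentAt(curve, tt)
    quad <- sum((head(vals, -1) + vals[-1]) / 2) * (tt[2] - tt[1]) / t
    expect_equal(timeAveragedEnrichment(curve, t), quad,
                 tolerance = 1e-6)
  }
})

test_that("the time average lies between the curve extremes", {
  set.seed(11)
  for (i in 1:10) {
    days <- sort(sample(1:30, 5))
    curve <- interpolateMeasured(data.frame(day = days,
                                            enrichment = runif(5, 0, 0.03)))
    t <- runif(1, 1, 30)
    avg <- timeAveragedEnrichment(curve, t)
    span <- enrichmentAt(curve, seq(0, t, 0.01))
    expect_gte(avg, min(span) - 1e-12)
    expect_lte(avg, max(span) + 1e-12)
  }
})
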