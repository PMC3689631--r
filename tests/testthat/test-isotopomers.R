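# Natural-abundance and labeled mass-isotopomer distributions, EM1 and the
# calibrated amplification.

test_that("degenerate and single-atom distributions are exact", {
  # mono-isotopic molecule: all mass in M0
  d <- naturalAbundanceDistribution(elementalFormula(F = 5), 3)
  expect_equal(fractions(d), c(1, 0, 0, 0))

  # one carbon: M0/M1 follow the 13C abundance
  d1 <- naturalAbundanceDistribution(elementalFormula(C = 1), 2)
  expect_equal(fractions(d1)[1], isotopeAbundances$C[1])
  expect_equal(fractions(d1)[2], isotopeAbundances$C[2])

  expect_error(elementalFormula(), "at least one atom")
  expect_error(naturalAbundanceDistribution(elementalFormula(C = 2), 0),
               "truncationOrder")
})

test_that("convolution matches exhaustive enumeration per entry", {
  for (counts in list(c(C = 3, H = 7, N = 1, O = 2),     # free alanine
                      c(C = 10, H = 8, F = 5, N = 1, O = 2),  # PFB ester
                      c(C = 2, H = 5, N = 1, O = 2),     # glycine
                      c(C = 1, O = 2),
                      c(H = 2, O = 1, S = 1))) {
    d <- naturalAbundanceDistribution(elementalFormula(counts), 4L)
    expect_equal(fractions(d), oracleNatural(counts, 4L),
                 tolerance = 1e-12)
  }
})

test_that("distributions normalize and stay within [0, 1]", {
  set.seed(7)
  for (i in 1:20) {
    counts <- c(C = sample(0:6, 1), H = sample(1:10, 1),
                N = sample(0:2, 1), O = sample(0:3, 1))
    counts <- counts[counts > 0]
    if (!length(counts)) next
    # truncation covering every possible mass shift makes a full
    # distribution
    full <- sum(counts * c(C = 1, H = 1, N = 1, O = 2)[names(counts)])
    d <- naturalAbundanceDistribution(elementalFormula(counts),
                                      max(full, 1))
    expect_true(all(fractions(d) >= 0 & fractions(d) <= 1))
    expect_equal(sum(fractions(d)), 1, tolerance = 1e-9)
  }
})

test_that("labeled distribution reduces to natural abundance at p = 0", {
  f <- defaultAnalyteFormula()
  m <- defaultLabelingModel()
  expect_equal(fractions(labeledDistribution(f, m, 0)),
               fractions(naturalAbundanceDistribution(f)),
               tolerance = 1e-14)
})

test_that("pure binomial labeling matches the closed form", {
  # 3 sites, full exchange, p = 0.05, no natural abundance:
  # M1 = 3 * 0.05 * 0.95^2
  f <- elementalFormula(C = 3, H = 7, N = 1, O = 2)
  m <- labelingModel(nSites = 3, siteExchangeFraction = 1)
  d <- labeledDistribution(f, m, 0.05, naturalAbundance = FALSE)
  expect_equal(fractions(d)[2], 3 * 0.05 * 0.95^2, tolerance = 1e-12)
})

test_that("labeling raises M1 above natural abundance", {
  f <- defaultAnalyteFormula()
  m <- defaultLabelingModel()
  nat <- naturalAbundanceDistribution(f)
  lab <- labeledDistribution(f, m, 0.02)
  expect_gt(fractions(lab)[2], fractions(nat)[2])
  expect_error(labeledDistribution(f, m, -0.01), "enrichment")
  expect_error(labeledDistribution(f, m, 0.8), "enrichment")
})

test_that("EM1 excess is the M1 difference and validates inputs", {
  f <- defaultAnalyteFormula()
  nat <- naturalAbundanceDistribution(f)
  expect_equal(em1Excess(nat, nat), 0)

  a <- new("IsotopomerDistribution", fractions = c(0.8, 0.105, 0.05),
           truncationOrder = 2L)
  b <- new("IsotopomerDistribution", fractions = c(0.85, 0.08, 0.03),
           truncationOrder = 2L)
  expect_equal(em1Excess(a, b), 0.025)

  short <- naturalAbundanceDistribution(f, 2)
  expect_error(em1Excess(nat, short), "truncation")
})

test_that("EM1 agrees with the enumeration oracle under labeling", {
  counts <- c(C = 10, H = 8, F = 5, N = 1, O = 2)
  f <- elementalFormula(counts)
  m <- defaultLabelingModel(f)
  p <- 0.015
  em1Pkg <- em1Excess(labeledDistribution(f, m, p),
                      naturalAbundanceDistribution(f))
  em1Oracle <- oracleLabeled(counts, m@nSites, m@siteExchangeFraction,
                             p, 4L)[2] - oracleNatural(counts, 4L)[2]
  expect_equal(em1Pkg, em1Oracle, tolerance = 1e-10)
})

test_that("EM1max is calibrated to the 2.7 amplification", {
  m <- defaultLabelingModel()
  expect_equal(em1Max(0), 0)
  # low-enrichment limit: EM1max(p)/p -> 2.7 within 1% at p = 1e-6
  expect_equal(amplification(m), 2.7, tolerance = 0.01)
  # plateau EM1 at 1% body water is ~2.7% (0.027)
  expect_equal(em1Max(0.01), 0.027, tolerance = 0.04)
  # binomial saturation makes EM1max sub-linear
  expect_lt(em1Max(0.02), 2 * em1Max(0.01))
  expect_true(m@siteExchangeFraction > 0 && m@siteExchangeFraction <= 1)
})

test_that("EM1max increases strictly on the physiological range", {
  ps <- seq(0, 0.25, by = 0.01)
  vals <- vapply(ps, em1Max, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("unreachable amplification targets are rejected", {
  # one site cannot amplify 2.7-fold
  expect_error(calibrateExchangeFraction(target = 2.7, nSites = 1),
               "not reachable")
})
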