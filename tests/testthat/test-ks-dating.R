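test_that("the KDE is normalised on its fixed grid", {
  set.seed(5)
  x <- rnorm(10000, 0.5, 0.05)
  dc <- kdeDensity(x, ksMax = 1.5)
  step <- dc$grid[2] - dc$grid[1]
  expect_equal(step, 0.001, tolerance = 1e-9)
  integral <- sum((dc$density[-1] + dc$density[-length(dc$density)]) / 2) *
    step
  expect_equal(integral, 1, tolerance = 0.01)
  expect_lt(abs(dc$grid[which.max(dc$density)] - 0.5), 0.01)

  # identical values peak at the value
  dc2 <- kdeDensity(rep(0.3, 50), ksMax = 1)
  expect_lt(abs(dc2$grid[which.max(dc2$density)] - 0.3), 0.0125)

  expect_error(kdeDensity(c(0.1, 0.2)), "insufficient data")
})

test_that("mixture fitting recovers simulated components", {
  set.seed(6)
  one <- fitKsMixture(kdeDensity(rnorm(8000, 0.5, 0.05), ksMax = 1.5))
  expect_equal(one@k, 1L)
  expect_lt(abs(peakMeans(one) - 0.5), 0.01)

  two <- fitKsMixture(kdeDensity(c(rnorm(1500, 0.2, 0.04),
                                   rnorm(3500, 0.8, 0.08)), ksMax = 1.5))
  expect_equal(two@k, 2L)
  expect_lt(max(abs(peakMeans(two) - c(0.2, 0.8))), 0.03)

  flat <- structure(list(grid = seq(0, 1, 0.001),
                         density = rep(0, 1001), bandwidth = 0.025,
                         n = 0L), class = "DensityCurve")
  expect_error(fitKsMixture(flat), "degenerate")
})

test_that("rate correction aligns ortholog peaks exactly", {
  same <- computeCorrection(c(a = 0.9, b = 0.9, c = 0.9))
  expect_equal(unname(correctionCoefficients(same)), rep(1, 3))

  m <- computeCorrection(c(sp1 = 1.0, sp2 = 2.0))
  expect_equal(m@reference, 1.5)
  expect_equal(unname(correctionCoefficients(m)), c(1.5, 0.75))
  # corrected peaks coincide by construction
  expect_equal(unname(correctionCoefficients(m) * m@peaks), c(1.5, 1.5))
  expect_error(computeCorrection(c(a = 1, b = 0)), "> 0")
})

test_that("corrections scale paralog and ortholog Ks as documented", {
  m <- computeCorrection(c(sp1 = 1.0, sp2 = 2.0))
  expect_equal(applyCorrection(0.8, m, "sp2"), 0.8 * 0.75)
  expect_equal(applyCorrection(0.8, m, "sp1", "sp2"),
               0.8 * sqrt(1.5 * 0.75))
  ident <- computeCorrection(c(sp1 = 1, sp2 = 1))
  expect_equal(applyCorrection(c(0.1, 0.5), ident, "sp1"), c(0.1, 0.5))
  expect_error(applyCorrection(0.5, m, "nope"), "unknown species")
})

test_that("dating is linear in the corrected peak and calibration", {
  m <- computeCorrection(c(sp1 = 1.2, sp2 = 1.2),
                         calibration = c(163, 184))
  atRef <- dateEvents(c(div = m@reference), m)
  expect_equal(c(atRef$age_lo, atRef$age_hi), c(163, 184))
  half <- dateEvents(c(ev = 0.5 * m@reference), m)
  expect_equal(c(half$age_lo, half$age_hi), c(81.5, 92))
  zero <- dateEvents(c(ev = 0), m)
  expect_equal(c(zero$age_lo, zero$age_hi), c(0, 0))
  expect_error(dateEvents(c(ev = -0.1), m), ">= 0")
})

test_that("the dating pipeline brackets a known WGD age", {
  # two lineages with a 1.5x rate asymmetry; true WGD at 50 My on the
  # calibration-midpoint clock
  res <- runDating(seed = 2L, n = 800L, trueAge = 50)
  expect_equal(res$dated$event, "wgd")
  expect_lt(res$dated$age_lo, 50)
  expect_gt(res$dated$age_hi, 50)
  # the multiplicative correction narrows the 50% raw peak asymmetry
  # (it cannot remove it exactly when the outgroup rate differs from a
  # lineage's own rate; the residual is what the dated interval absorbs)
  m <- res$model
  corr <- vapply(names(res$paralogPeaks), function(sp) {
    applyCorrection(res$paralogPeaks[[sp]], m, sp)
  }, numeric(1))
  relDiff <- function(v) abs(v[1] - v[2]) / mean(v)
  expect_lt(relDiff(corr), relDiff(res$paralogPeaks))
  expect_lt(relDiff(corr), 0.25)
  # determinism
  res2 <- runDating(seed = 2L, n = 800L, trueAge = 50)
  expect_identical(res$dated, res2$dated)
})
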