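test_that("contralateral correction recovers the pure decay", {
  tr <- makePhotoactivationSeries(1.5, 10, 0.7, noise_sd = 0, seed = 1)
  corr <- correctContralateral(tr)
  truth <- attr(tr, "truth")
  expected <- 0.7 * 2^(-corr$time_min / 1.5) + 0.3 * 2^(-corr$time_min / 10)
  expect_equal(corr$intensity, expected / expected[1], tolerance = 1e-12)
  expect_equal(corr$intensity[1], 1)
  expect_equal(nrow(corr), 37)

  tr2 <- DecayTrace(times = tr@times, activated = tr@activated,
                    contralateral = tr@contralateral,
                    anaphaseEntered = TRUE)
  expect_error(correctContralateral(tr2), "anaphase")

  tr3 <- DecayTrace(times = 0:11 / 6, activated = rep(1, 12),
                    contralateral = rep(2, 12))
  expect_error(correctContralateral(tr3), "non-positive")
})

test_that("a single-phase half-life halves the signal at its half-life", {
  tr <- makePhotoactivationSeries(2, 2.0001, 1, noise_sd = 0, seed = 1)
  corr <- correctContralateral(tr)
  at2 <- corr$intensity[abs(corr$time_min - 2) < 1e-9]
  expect_equal(at2, 0.5, tolerance = 1e-4)
})

test_that("the two-phase fit recovers planted parameters", {
  tr <- makePhotoactivationSeries(1.5, 10, 0.7, noise_sd = 0, seed = 2)
  fit <- fitTwoPhase(correctContralateral(tr))
  expect_true(fit@converged)
  expect_lt(abs(tHalfFast(fit) - 1.5) / 1.5, 1e-3)
  expect_lt(abs(tHalfSlow(fit) - 10) / 10, 1e-3)
  expect_lt(abs(fracFast(fit) - 0.7), 1e-3)
})

test_that("degenerate decays are handled: single phase and constant", {
  t_min <- (0:36) / 6
  single <- 2^(-t_min / 3)
  fit <- fitTwoPhase(t_min, single)
  expect_lt(abs(tHalfSlow(fit) - 3) / 3, 0.01)

  const <- fitTwoPhase(t_min, rep(1, 37))
  expect_true(const@atBound)
  expect_false(const@converged)
})

test_that("fitted parameters are scale invariant", {
  tr <- makePhotoactivationSeries(1.5, 8, 0.6, noise_sd = 0.01, seed = 3)
  corr <- correctContralateral(tr)
  f1 <- fitTwoPhase(corr)
  corr2 <- corr
  corr2$intensity <- corr2$intensity * 37.5  # normalization handles gain
  f2 <- fitTwoPhase(corr2$time_min, corr2$intensity / corr2$intensity[1])
  expect_equal(tHalfSlow(f1), tHalfSlow(f2), tolerance = 1e-8)
  expect_equal(fracFast(f1), fracFast(f2), tolerance = 1e-8)
})

test_that("the fit is at least as good as a dense grid search", {
  for (s in 1:5) {
    tr <- makePhotoactivationSeries(1.5, 10, 0.7, noise_sd = 0.02, seed = s)
    corr <- correctContralateral(tr)
    fit <- fitTwoPhase(corr)
    oracle <- gridTwoPhaseRSS(corr$time_min, corr$intensity)
    expect_lte(fit@rss, oracle + 1e-10)
  }
})

test_that("slow half-life recovery is accurate where identifiable", {
  ## the slow phase of a 6-min window is weakly identified; at 0.05%
  ## measurement noise the estimator concentrates, and recovery holds
  errs <- vapply(1:25, function(s) {
    tr <- makePhotoactivationSeries(1.5, 10, 0.7, noise_sd = 5e-4,
                                    seed = 1000 + s)
    fit <- fitTwoPhase(correctContralateral(tr))
    abs(tHalfSlow(fit) - 10) / 10
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("half-life ratios map to percent destabilization", {
  mkfit <- function(ts) new("TwoPhaseFit", fracFast = 0.6, tHalfFast = 1.5,
                            tHalfSlow = ts, rss = 0, converged = TRUE,
                            atBound = FALSE, nFrames = 37L)
  expect_equal(slowHalfLifeRatio(mkfit(10), mkfit(10))$ratio, 1)
  r <- slowHalfLifeRatio(mkfit(5.9), mkfit(10))
  expect_equal(r$ratio, 0.59)
  expect_equal(r$percent_destabilization, 41)
  r2 <- slowHalfLifeRatio(mkfit(9.3), mkfit(10))
  expect_equal(r2$percent_destabilization, 7, tolerance = 1e-9)
})

test_that("flux measurement recovers planted band drift", {
  ## drift of one profile bin per frame: exactly linear staircase
  tr <- makePhotoactivationSeries(1.5, 10, 0.7, flux = 1.5, noise_sd = 0,
                                  seed = 4)
  fx <- measureFlux(tr)
  expect_equal(fluxVelocity(fx), 1.5, tolerance = 1e-9)
  expect_equal(fx@r2, 1, tolerance = 1e-9)

  ## off-grid drift: recovered through the linear fit
  tr2 <- makePhotoactivationSeries(1.5, 10, 0.7, flux = 1.0, noise_sd = 0,
                                   seed = 4)
  expect_equal(fluxVelocity(measureFlux(tr2)), 1.0, tolerance = 0.02)

  ## static band
  tr3 <- makePhotoactivationSeries(1.5, 10, 0.7, flux = 0, noise_sd = 0,
                                   seed = 4)
  expect_equal(fluxVelocity(measureFlux(tr3)), 0, tolerance = 1e-9)

  ## stated noise level: within 5%
  tr4 <- makePhotoactivationSeries(1.5, 10, 0.7, flux = 0.8,
                                   noise_sd = 0.02, seed = 5)
  expect_lt(abs(fluxVelocity(measureFlux(tr4)) - 0.8) / 0.8, 0.05)
})
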