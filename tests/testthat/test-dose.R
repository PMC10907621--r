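test_that("viability and toxicity formulas hit their anchor points", {
  expect_equal(viabilityMetrics(1.0, 1.0, 0.2)$viability, 100)
  expect_equal(viabilityMetrics(1.0, 1.0, 0.2)$toxicity, 0)
  expect_equal(viabilityMetrics(0.2, 1.0, 0.2)$viability, 0)
  expect_equal(viabilityMetrics(0.2, 1.0, 0.2)$toxicity, 100)
  expect_equal(viabilityMetrics(0.6, 1.0, 0.2)$viability, 50)
  expect_error(viabilityMetrics(0.5, 0.2, 0.2), "denominator")

  ## viability + toxicity is identically 100
  set.seed(8)
  for (i in 1:20) {
    s <- runif(3)
    if (abs(s[2] - s[3]) < 1e-3) next
    vm <- viabilityMetrics(s[1], s[2], s[3])
    expect_equal(vm$viability + vm$toxicity, 100)
  }

  ## invariance under positive affine transforms of the signal scale
  vm1 <- viabilityMetrics(0.7, 1.2, 0.3)
  vm2 <- viabilityMetrics(0.7 * 5 + 2, 1.2 * 5 + 2, 0.3 * 5 + 2)
  expect_equal(vm1$viability, vm2$viability, tolerance = 1e-12)

  ## media normalization swaps the baseline
  expect_equal(viabilityMetrics(0.6, 1.0, 0.2, signal_media = 0.1)$viability,
               (0.6 - 0.1) / (1.0 - 0.1) * 100)
})

test_that("viability rescue positions the sample between WT references", {
  expect_equal(viabilityRescue(0.5, 0.5, 1.0), 0)
  expect_equal(viabilityRescue(1.0, 0.5, 1.0), 100)
  expect_equal(viabilityRescue(0.75, 0.5, 1.0), 50)
  expect_error(viabilityRescue(0.7, 1.0, 1.0), "denominator")
})

test_that("the 4PL fit recovers planted curves and the midpoint", {
  doses <- 10^seq(0, 3, length.out = 8)
  plate <- makeViabilityPlate(c(20, 100, 50, 1.2), doses, noise_sd = 0,
                              seed = 1)
  sample <- plate[plate$condition == "sample", ]
  fit <- fitFourParameter(sample$dose, sample$absorbance)
  expect_lt(abs(ic50(fit) - 50) / 50, 1e-3)
  expect_lt(abs(hillSlope(fit) - 1.2) / 1.2, 1e-3)
  expect_lt(abs(fit@bottom - 20) / 20, 1e-3)
  expect_lt(abs(fit@top - 100) / 100, 1e-3)

  ## response at dose = ic50 equals (top + bottom) / 2
  pred <- fit@bottom + (fit@top - fit@bottom) /
    (1 + (ic50(fit) / ic50(fit))^hillSlope(fit))
  expect_equal(pred, (fit@top + fit@bottom) / 2)

  ## via the plate wrapper: viability scale, plateau toxicity = 100 - bottom
  pf <- fitPlate(plate)$fit
  expect_lt(abs(ic50(pf) - 50) / 50, 1e-3)
  expect_equal(plateauToxicity(pf), 100 - pf@bottom)

  flat <- fitFourParameter(doses, rep(80, 8))
  expect_true(flat@flat)
  expect_true(is.na(hillSlope(flat)))

  expect_error(fitFourParameter(c(1, 2, 3), c(1, 2, 3)), "4 distinct")
})

test_that("the 4PL fit beats a dense grid search", {
  doses <- 10^seq(0, 3, length.out = 8)
  for (s in 1:3) {
    plate <- makeViabilityPlate(c(15, 95, 80, 1.6), doses, noise_sd = 0.03,
                                seed = s)
    sample <- plate[plate$condition == "sample", ]
    fit <- fitFourParameter(sample$dose, sample$absorbance)
    oracle <- grid4PLRSS(sample$dose, sample$absorbance)
    expect_lte(sum(fit@residuals^2), oracle + 1e-8)
  }
})

test_that("sensitivity classes follow the printed toxicity cutoffs", {
  expect_identical(classifySensitivity(c(45, 15, 30)),
                   c("sensitive", "insensitive", "intermediate"))
  expect_identical(classifySensitivity(c(40, 20)),
                   c("intermediate", "intermediate"))
  expect_error(classifySensitivity(NA_real_), "finite")
})

test_that("plate controls define the viability scale by construction", {
  plate <- makeViabilityPlate(c(20, 100, 50, 1.2),
                              10^seq(0, 3, length.out = 6),
                              noise_sd = 0, seed = 2)
  expect_true(all(plate$absorbance[plate$condition == "DMN"] == 20))
  expect_true(all(plate$absorbance[plate$condition == "DMSO"] == 100))
  ## response at dose closest to ic50 sits midway between the plateaus
  mid <- plate$absorbance[which.min(abs(plate$dose - 50))]
  close_doses <- makeViabilityPlate(c(20, 100, 50, 1.2), 50, noise_sd = 0,
                                    seed = 3)
  expect_equal(close_doses$absorbance[close_doses$condition == "sample"],
               rep(60, 3))
})
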