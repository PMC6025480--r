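test_that("quantitative fit inverts its own noiseless signals exactly", {
  sp <- defaultFatSpectrum()
  te <- quantitativeEchoes()
  grid <- expand.grid(pdff = seq(0, 100, by = 5), psi = c(-60, 0, 60),
                      r2s = c(20, 60, 100))
  S <- simulateSignal(1 - grid$pdff / 100, grid$pdff / 100, te, sp,
                      psiHz = grid$psi, r2sPerS = grid$r2s)
  fm <- fitQuantitative(seriesFromSignals(S, te))
  est <- fm@pdff[, 1, 1]
  expect_lt(max(abs(est - grid$pdff)), 0.1)
  expect_lt(max(abs(fm@psi[, 1, 1] - grid$psi)), 0.1)
  # R2* is unidentifiable only in degenerate cases; check away from them
  ok <- grid$pdff > 1 & grid$pdff < 99
  expect_lt(max(abs(fm@r2s[, 1, 1] - grid$r2s)[ok]), 0.5)
  expect_true(all(fm@valid))
  expect_lt(max(fm@residual), 1e-6)
})

test_that("uncorrected fit inverts single-peak no-decay signals", {
  sp1 <- singlePeakSpectrum()
  te <- highresEchoes()
  cases <- expand.grid(pdff = c(0, 20, 40, 90), psi = c(-50, 0, 50))
  S <- simulateSignal(1 - cases$pdff / 100, cases$pdff / 100, te, sp1,
                      psiHz = cases$psi)
  fm <- fitUncorrected(seriesFromSignals(S, te))
  expect_lt(max(abs(fm@pdff[, 1, 1] - cases$pdff)), 0.1)
  expect_lt(max(abs(fm@psi[, 1, 1] - cases$psi)), 0.5)
  expect_error(r2sMap(fm), "does not estimate")
})

test_that("uncorrected estimator is biased on full-model signals, growing with R2*", {
  sp <- defaultFatSpectrum()
  te <- highresEchoes()
  # at high fat content with realistic decay the error exceeds 1 pp, in the
  # direction of a reduced apparent fat fraction
  Shi <- simulateSignal(0.25, 0.75, te, sp, psiHz = 0, r2sPerS = 60)
  fmHi <- fitUncorrected(seriesFromSignals(Shi, te))
  expect_gt(abs(fmHi@pdff[1, 1, 1] - 75), 1)
  expect_lt(fmHi@pdff[1, 1, 1], 75)
  # at BAT-like fat fraction, T2* decay and the spectral mismatch both
  # depress the estimate: error magnitude grows monotonically with R2*
  r2sGrid <- c(0, 40, 80, 120)
  S <- simulateSignal(0.77, 0.23, te, sp, psiHz = 0, r2sPerS = r2sGrid)
  fm <- fitUncorrected(seriesFromSignals(S, te))
  bias <- fm@pdff[, 1, 1] - 23
  expect_true(all(diff(abs(bias)) > 0))
  expect_true(all(bias < 0))
})

test_that("refined objective never exceeds the dense-grid brute force", {
  set.seed(77)
  sp <- defaultFatSpectrum()
  te <- quantitativeEchoes()
  n <- 500
  pdff <- runif(n, 0, 100)
  psi <- runif(n, -150, 150)
  r2s <- runif(n, 0, 200)
  S <- simulateSignal(1 - pdff / 100, pdff / 100, te, sp, psiHz = psi,
                      r2sPerS = r2s)
  S <- S + matrix(complex(real = rnorm(6 * n, 0, 1 / 80),
                          imaginary = rnorm(6 * n, 0, 1 / 80)), 6, n)
  fm <- fitQuantitative(seriesFromSignals(S, te))
  refined <- 6 * fm@residual[, 1, 1]^2
  oracle <- bruteForceObjective(S, te, sp, seq(-200, 200, by = 1),
                                seq(0, 250, by = 2))
  expect_true(all(refined <= oracle + 1e-9 * colSums(Mod(S)^2)))
})

test_that("fit masks invalid voxels and honours the fit mask", {
  te <- quantitativeEchoes()
  sp <- defaultFatSpectrum()
  S <- simulateSignal(c(0, 0.5), c(0, 0.5), te, sp)
  fm <- fitQuantitative(seriesFromSignals(S, te))
  expect_false(fm@valid[1, 1, 1])  # all-zero voxel
  expect_true(fm@valid[2, 1, 1])
  mask <- array(c(FALSE, TRUE), c(2, 1, 1))
  fm2 <- fitQuantitative(seriesFromSignals(S, te), mask = mask)
  expect_false(fm2@valid[1, 1, 1])
})

test_that("swap check leaves in-range solutions alone and fixes aliased ones", {
  sp <- defaultFatSpectrum()
  te <- quantitativeEchoes()
  # 3 x 3 x 3 neighborhood, noiseless, psi within the search range
  n <- 27
  S <- simulateSignal(rep(0.3, n), rep(0.7, n), te, sp, psiHz = 20,
                      r2sPerS = 50)
  ser <- new("EchoSeries", data = array(t(S), c(3, 3, 3, 6)), teS = te,
             spacingMm = c(1, 1, 1), originMm = c(0, 0, 0), axes = 1:3,
             protocolName = "t", orientation = "coronal", seed = 1L)
  fm <- fitQuantitative(ser)
  sc <- swapCheck(fm, ser)
  expect_identical(sc$nSwapped, 0L)
  # center voxel aliased: true psi beyond the +/-200 Hz search range
  dfDom <- peakFrequencies(sp)[which.max(sp@amplitudes)]
  psiTrue <- rep(20, n); psiTrue[14] <- 20 - dfDom  # ~ +454 Hz
  S2 <- simulateSignal(rep(0.3, n), rep(0.7, n), te, sp, psiHz = psiTrue,
                       r2sPerS = 50)
  ser2 <- ser; ser2@data <- array(t(S2), c(3, 3, 3, 6))
  fm2 <- fitQuantitative(ser2)
  sc2 <- swapCheck(fm2, ser2)
  expect_gte(sc2$nSwapped, 1L)
  # the corrected branch has the lower residual and the right fat fraction
  expect_lte(sc2$maps@residual[2, 2, 2], fm2@residual[2, 2, 2])
  expect_lt(abs(sc2$maps@pdff[2, 2, 2] - 70), 1)
})

test_that("swap rate is negligible on a uniform noisy phantom", {
  set.seed(13)
  sp <- defaultFatSpectrum()
  te <- quantitativeEchoes()
  n <- 1000
  S <- simulateSignal(rep(0.12, n), rep(0.88, n), te, sp, psiHz = 10,
                      r2sPerS = 35)
  S <- S + matrix(complex(real = rnorm(6 * n, 0, 1 / 50),
                          imaginary = rnorm(6 * n, 0, 1 / 50)), 6, n)
  ser <- seriesFromSignals(S, te)
  fm <- fitQuantitative(ser)
  sc <- swapCheck(fm, ser)
  expect_lt(sc$nSwapped / n, 0.001)
})

test_that("per-voxel PDFF noise stays below 3 pp for pure tissues at snr 80", {
  set.seed(99)
  sp <- defaultFatSpectrum()
  te <- quantitativeEchoes()
  n <- 300
  for (pdffTrue in c(0, 88)) {
    S <- simulateSignal(rep(1 - pdffTrue / 100, n), rep(pdffTrue / 100, n),
                        te, sp, psiHz = 25, r2sPerS = 40)
    S <- S + matrix(complex(real = rnorm(6 * n, 0, 1 / 80),
                            imaginary = rnorm(6 * n, 0, 1 / 80)), 6, n)
    fm <- fitQuantitative(seriesFromSignals(S, te))
    expect_lt(sd(fm@pdff[, 1, 1]), 3)
  }
})

test_that("magnitude fit mode recovers fat fraction without phase information", {
  sp <- defaultFatSpectrum()
  te <- quantitativeEchoes()
  S <- simulateSignal(0.7, 0.3, te, sp, psiHz = 83, r2sPerS = 50)
  fm <- fitQuantitative(seriesFromSignals(S, te),
                        opts = fitOptions(fitMode = "magnitude"))
  expect_lt(abs(fm@pdff[1, 1, 1] - 30), 1)
  expect_lt(abs(fm@r2s[1, 1, 1] - 50), 2)
})

test_that("echo-count preconditions are enforced", {
  te4 <- highresEchoes()
  S <- simulateSignal(0.5, 0.5, te4, singlePeakSpectrum())
  expect_error(fitQuantitative(seriesFromSignals(S, te4)), "6 echoes")
  te2 <- te4[1:2]
  S2 <- simulateSignal(0.5, 0.5, te2, singlePeakSpectrum())
  expect_error(fitUncorrected(seriesFromSignals(S2, te2)), "3 echoes")
})
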