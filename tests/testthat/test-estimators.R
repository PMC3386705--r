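test_that("RLD-2 inverts the gate ratio and flags non-decaying counts", {
  est <- fitRLD2(gateCounts(2718.28, 1000, binWidth = 1))
  expect_true(isValid(est))
  expect_equal(tau(est), 1, tolerance = 1e-5)

  # noiseless expected counts recover tau exactly for any tau, h
  for (tauTrue in c(0.3, 1, 4)) {
    for (h in c(0.5, 2)) {
      gc <- expectedGateCounts(singleExp(tau = tauTrue), gatedConfig(h))
      expect_equal(tau(fitRLD2(gc)), tauTrue, tolerance = 1e-12)
    }
  }

  expect_false(isValid(fitRLD2(gateCounts(100, 100, binWidth = 1))))
  expect_false(isValid(fitRLD2(gateCounts(100, 0, binWidth = 1))))
  expect_error(fitRLD2(gateCounts(3, 2, 0.2, 3.2, 1)), "geometry")
})

test_that("GRLD reduces to RLD-2 at S = 1, R = 2 on arbitrary counts", {
  set.seed(42)
  for (i in 1:200) {
    p <- randomCountPair()
    h <- stats::runif(1, 0.1, 3)
    a <- fitGRLD(gateCounts(p[1], p[2], 1, 2, h))
    b <- fitRLD2(gateCounts(p[1], p[2], 1, 2, h))
    expect_equal(tau(a), tau(b), tolerance = 1e-9)
  }
})

test_that("GRLD recovers the lifetime from noiseless overlapping gates", {
  gc <- expectedGateCounts(singleExp(tau = 1), gatedConfig(1, 0.2, 3.2))
  expect_equal(tau(fitGRLD(gc)), 1, tolerance = 1e-9)
  # the published large-R geometry is accepted
  gc2 <- expectedGateCounts(singleExp(tau = 2),
                            gatedConfig(0.5, 0.25, 12.25))
  expect_equal(tau(fitGRLD(gc2)), 2, tolerance = 1e-9)
  # geometry constraints: 1/S and R-S must be integers
  expect_error(fitGRLD(gateCounts(3, 2, 0.3, 3.3, 1)), "integer")
  # ratio at or beyond the P range: invalid, not an error
  est <- fitGRLD(gateCounts(10, 40, 0.2, 3.2, 1))
  expect_false(isValid(est))
})

test_that("GRLD fast inverse agrees with bisection", {
  inv <- flimtd:::.grldInverse(0.2, 3.2)
  for (ratio in c(0.05, 0.3, 1.2307, 2.2, 2.9)) {
    xb <- flimtd:::.grldSolve(ratio, 0.2, 3.2)
    tb <- -1 / log(xb)
    expect_equal(inv(ratio), tb, tolerance = 1e-6)
  }
  # outside the invertible range: NA, matching the bisection's refusal
  expect_true(is.na(inv(3.0)))
  expect_true(is.na(flimtd:::.grldSolve(3.0, 0.2, 3.2)))
})

test_that("RLD-M equals RLD-2 at M = 2 and is exact on log-linear data", {
  set.seed(43)
  for (i in 1:200) {
    p <- randomCountPair()
    h <- stats::runif(1, 0.1, 3)
    a <- fitRLDM(decayHistogram(p, h))
    b <- fitRLD2(gateCounts(p[1], p[2], 1, 2, h))
    expect_equal(tau(a), tau(b), tolerance = 1e-9)
  }
  # noiseless counts: ln N_j exactly linear in j
  for (M in c(4L, 8L, 16L)) {
    hist <- expHist(singleExp(tau = 1.7), 6.8, M)
    expect_equal(tau(fitRLDM(hist)), 1.7, tolerance = 1e-12)
  }
  # zero bin invalidates the logarithm
  bad <- decayHistogram(c(5, 3, 2, 0, 1, 1, 1, 1), 1)
  expect_false(isValid(fitRLDM(bad)))
})

test_that("IEM applies the Simpson weight pattern and closed form", {
  expect_equal(flimtd:::.simpsonWeights(7),
               c(1, 4, 2, 4, 2, 4, 1) / 3)
  expect_equal(sum(flimtd:::.simpsonWeights(51)), 50)

  # M = 3 closed form: tau = h (1 + 4x + x^2) / (3 (1 - x^2))
  x <- 0.9
  hist <- decayHistogram(100 * c(1, x, x^2), 1)
  expect_equal(tau(fitIEM(hist)), (1 + 4 * x + x^2) / (3 * (1 - x^2)))
  expect_equal(tau(fitIEM(hist)), 9.49123, tolerance = 1e-5)
  # ... within 0.01% of the tau matching x = 0.9
  expect_equal(tau(fitIEM(hist)), -1 / log(0.9), tolerance = 1e-3)

  # constant offset leaves the denominator unchanged
  N <- counts(expHist(singleExp(tau = 1.2), 6, 7))
  d0 <- N[1] - N[7]
  Nb <- N + 12.5
  expect_equal(Nb[1] - Nb[7], d0)

  expect_error(fitIEM(decayHistogram(rep(1, 8), 1)), "odd")
  expect_false(isValid(fitIEM(decayHistogram(c(1, 2, 3), 1))))
})

test_that("Omega LUT inverts the truncation map over four decades", {
  u <- exp(seq(log(0.01), log(10), length.out = 200))
  g <- flimtd:::.truncatedCentroid(u)
  back <- omegaCalibrate(g, sharedLUT)
  expect_true(all(abs(back - u) / u < 1e-3))
  # closed-form anchor: g(1) = 1 - e^{-1}/(1 - e^{-1})
  expect_equal(flimtd:::.truncatedCentroid(1), 0.41802, tolerance = 1e-5)
  expect_equal(omegaCalibrate(0.41802, sharedLUT), 1, tolerance = 1e-3)
  # saturation: uniform-limit centroid 1/2 is not invertible
  expect_true(is.na(omegaCalibrate(0.5, sharedLUT)))
  expect_true(is.na(omegaCalibrate(0.62, sharedLUT)))
  # small-u limit: calibration approaches the identity
  expect_equal(omegaCalibrate(0.01, sharedLUT), 0.01, tolerance = 1e-2)
})

test_that("CMM centroid, calibration and saturation behave as specified", {
  # all photons in bin 0: raw centroid is half a bin
  pl <- photonList(rep(0L, 50), 64, 0.125)
  est <- fitCMM(pl, sharedLUT)
  expect_equal(est@diagnostics$rawCentroid, 0.125 / 2)

  # noiseless expected histogram at tau = T: raw centroid ~ 0.418 T,
  # calibrated back to T within LUT + half-bin tolerance
  Tw <- 8
  hist <- expHist(singleExp(tau = Tw), Tw, 256)
  est2 <- fitCMM(hist, sharedLUT)
  expect_equal(est2@diagnostics$rawCentroid / Tw, 0.418, tolerance = 2e-3)
  expect_equal(tau(est2), Tw, tolerance = 0.01)

  # uniform photons saturate the centroid
  unif <- decayHistogram(rep(10, 32), 0.25)
  expect_false(isValid(fitCMM(unif, sharedLUT)))
  expect_false(isValid(fitCMM(photonList(integer(0), 8, 1), sharedLUT)))
})

test_that("CMM histogram and photon-list forms agree exactly", {
  set.seed(7)
  codes <- sample.int(64, 500, replace = TRUE,
                      prob = exp(-(1:64) / 12)) - 1L
  pl <- photonList(codes, 64, 0.1)
  hist <- decayHistogram(counts(pl), 0.1)
  expect_identical(tau(fitCMM(pl, sharedLUT)), tau(fitCMM(hist, sharedLUT)))
})

test_that("MLE recovers tau from noiseless counts and matches RLD-2 at M = 2", {
  hist <- expHist(singleExp(tau = 1.3), 8, 64)
  expect_equal(tau(fitMLE(hist)), 1.3, tolerance = 1e-8)

  set.seed(44)
  for (i in 1:20) {
    p <- randomCountPair()
    h <- stats::runif(1, 0.3, 2)
    expect_equal(tau(fitMLE(decayHistogram(p, h))),
                 tau(fitRLD2(gateCounts(p[1], p[2], 1, 2, h))),
                 tolerance = 1e-6)
  }
  expect_false(isValid(fitMLE(decayHistogram(c(0, 0, 0, 5), 1))))
})

test_that("bi-exponential fit recovers noiseless parameters", {
  m <- decayModel(c(500, 500), c(0.3, 3.4))
  fit <- fitBiexp(expHist(m, 10.2, 51))
  expect_true(fit$valid)
  expect_false(fit$degenerate)
  expect_equal(fit$tau1, 0.3, tolerance = 1e-4)
  expect_equal(fit$tau2, 3.4, tolerance = 1e-4)
  expect_equal(fit$A1, 500, tolerance = 1e-3)
  expect_equal(fit$A2, 500, tolerance = 1e-3)
  expect_equal(fit$tauAve, 1.85, tolerance = 1e-4)

  # single-exponential input is flagged degenerate
  fit1 <- fitBiexp(expHist(singleExp(tau = 2), 10, 64))
  expect_true(fit1$degenerate)
  # photon floor
  starved <- decayHistogram(rep(1, 16), 0.5)
  expect_false(fitBiexp(starved)$valid)
})

test_that("histogram-to-gate aggregation is exact on aligned boundaries", {
  N <- counts(expHist(singleExp(tau = 1.5), 8, 32))
  hist <- decayHistogram(N, 0.25)
  # R = 2: half-window gates align with bin 16
  gc <- gateCountsFromHistogram(hist, 1, 2)
  expect_equal(gc@n1, sum(N[1:16]))
  expect_equal(gc@n2, sum(N[17:32]))
  expect_equal(binWidth(gc), 4)
  # fractional boundaries conserve the total
  gc2 <- gateCountsFromHistogram(hist, 0.2, 3.2)
  expect_equal(gc2@n1 + gc2@n2 - gc2@nOverlap, sum(N), tolerance = 1e-9)
})
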