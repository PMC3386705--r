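test_that("photon sampling is reproducible and respects the window", {
  sp <- simSpec(singleExp(tau = 1), binnedConfig(8, 256), 5000, seed = 11)
  a <- samplePhotons(sp)
  b <- samplePhotons(sp)
  expect_identical(a@codes, b@codes)
  expect_length(a@codes, 5000L)
  expect_true(all(a@codes >= 0L & a@codes < 256L))

  # Poisson law varies the total around the mean
  totals <- vapply(1:8, function(s) {
    spP <- simSpec(singleExp(tau = 1), binnedConfig(8, 256), 5000,
                   law = "poisson", seed = s)
    length(samplePhotons(spP)@codes)
  }, integer(1))
  expect_gt(stats::sd(totals), 0)
  expect_lt(abs(mean(totals) - 5000), 5 * sqrt(5000 / 8))
})

test_that("background-dominated sampling is uniform over codes", {
  m <- decayModel(1e-9, 1, background = 1000)
  sp <- simSpec(m, binnedConfig(8, 64), 1e5, seed = 21)
  cnt <- counts(samplePhotons(sp))
  gof <- stats::chisq.test(cnt)
  expect_gt(gof$p.value, 0.01)
})

test_that("sampled code frequencies match the expected decay histogram", {
  m <- singleExp(tau = 1)
  cfg <- binnedConfig(8, 256)
  sp <- simSpec(m, cfg, 1e6, seed = 31)
  obs <- counts(samplePhotons(sp))
  expReal <- counts(expectedBinCounts(m, cfg))
  expCnt <- 1e6 * expReal / sum(expReal)
  z <- abs(obs - expCnt) / sqrt(pmax(expCnt, 1))
  expect_gte(mean(z <= 4), 0.99)
})

test_that("gate-count sampling honours the partition and the overlap law", {
  m <- singleExp(tau = 1)
  spC <- simSpec(m, gatedConfig(1, 0.2, 3.2, correlated = TRUE),
                 1000, replicates = 2000L, seed = 41)
  g <- sampleGateCounts(spC, replicates = 2000L)
  # correlated: N1 + N2 - Nov equals the window total
  expect_equal(g$n1 + g$n2 - g$nOverlap, g$nc)
  # under shot-noise (Poisson) counting, overlap sharing induces
  # positive correlation between the gates: Cov(N1, N2) = Var(Nov) > 0
  spCP <- simSpec(m, gatedConfig(1, 0.2, 3.2, correlated = TRUE),
                  1000, law = "poisson", replicates = 2000L, seed = 44)
  gp <- sampleGateCounts(spCP, replicates = 2000L)
  ct <- stats::cor.test(gp$n1, gp$n2, alternative = "greater")
  expect_lt(ct$p.value, 0.01)

  spU <- simSpec(m, gatedConfig(1, 0.2, 3.2, correlated = FALSE),
                 1000, replicates = 2000L, seed = 42)
  gu <- sampleGateCounts(spU, replicates = 2000L)
  expect_lt(abs(stats::cor(gu$n1, gu$n2)), 3 / sqrt(2000))

  # single replicate returns a GateCounts object
  g1 <- sampleGateCounts(simSpec(m, gatedConfig(1, 0.2, 3.2), 500,
                                 seed = 43))
  expect_s4_class(g1, "GateCounts")
  expect_error(sampleGateCounts(simSpec(m, binnedConfig(8, 64), 500)),
               "scheme")
})

test_that("Poisson-law counters are Poisson-consistent", {
  m <- singleExp(tau = 1)
  sp <- simSpec(m, gatedConfig(1, 0.2, 3.2), 1000, law = "poisson",
                replicates = 10000L, seed = 51)
  g <- sampleGateCounts(sp, replicates = 10000L)
  for (v in list(g$n1, g$n2)) {
    expect_gte(mean(v), 100)
    expect_gt(stats::var(v) / mean(v), 0.9)
    expect_lt(stats::var(v) / mean(v), 1.1)
  }
})

test_that("the default phantom encodes the two-region bi-decay scene", {
  ph <- defaultPhantom()
  expect_setequal(unique(as.vector(ph@labels)), c(1L, 2L))
  # both regions share the bi-exponential fit components
  for (m in ph@models)
    expect_equal(lifetimes(m), c(0.3, 3.4))
  # amplitude-weighted means of the two regions
  expect_equal(tauAve(ph@models[[1]]), 0.92, tolerance = 1e-12)
  expect_equal(tauAve(ph@models[[2]]), 2.78, tolerance = 1e-12)
  # fraction 1 in both regions degenerates to single-exponential 0.3 ns
  ph1 <- defaultPhantom(fractions = c(1, 1))
  for (m in ph1@models) {
    w <- amplitudes(m) / sum(amplitudes(m))
    expect_equal(sum(w * lifetimes(m)), 0.3)
  }
})

test_that("image stacks are reproducible, labelled and zero-safe", {
  ph <- defaultPhantom(size = 8L, meanCounts = 200)
  cfg <- binnedConfig(8, 17)
  a <- simulateImageStack(ph, cfg, seed = 61)
  b <- simulateImageStack(ph, cfg, seed = 61)
  expect_identical(counts(a), counts(b))
  expect_identical(dim(counts(a)), c(8L, 8L, 17L))

  # a (near) zero-expected-count pixel yields an all-zero histogram
  ph0 <- ph
  ph0@expectedCounts[3, 5] <- 1e-12
  st <- simulateImageStack(ph0, cfg, seed = 62)
  expect_equal(sum(counts(st)[3, 5, ]), 0)
})

test_that("two-region stacks order region means correctly for every estimator", {
  ph <- defaultPhantom(size = 24L, meanCounts = 2000)
  st <- simulateImageStack(ph, binnedConfig(8, 51), seed = 63)
  for (meth in c("rld2", "grld", "iem", "cmm")) {
    img <- mapEstimator(st, meth, lut = sharedLUT)
    s <- regionStats(img, ph@labels)$summary
    expect_lt(s$mean[s$label == 1], s$mean[s$label == 2])
  }
})

test_that("uniform-phantom lifetime spread is consistent with F theory", {
  # one-label single-exponential phantom; per-pixel RLD-2 spread should
  # match the closed-form photon economy at the per-pixel count
  tauTrue <- 1
  nc <- 1000
  ph <- new("Phantom", labels = matrix(1L, 32, 32),
            models = list(singleExp(tau = tauTrue)),
            expectedCounts = matrix(nc, 32, 32))
  Tw <- 4.8   # h = 2.4 tau per gate
  st <- simulateImageStack(ph, binnedConfig(Tw, 32), seed = 64)
  img <- mapEstimator(st, "rld2")
  taus <- tauMap(img)[validMask(img)]
  Fhat <- sqrt(mean(intensityMap(img))) * stats::sd(taus) / tauTrue
  Fth <- fValueRLD2(Tw / 2 / tauTrue)
  expect_lt(abs(Fhat - Fth) / Fth, 0.2)
})
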