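test_that("the gating F-curves form an identity lattice", {
  # 400-point grid; at S=1, R=2 and M=2 everything collapses to RLD-2
  tt <- exp(seq(log(0.02), log(2), length.out = 400L))
  u <- 1 / (2 * tt)    # h/tau for the two-equal-gate geometry
  f0 <- fValueRLD2(u)
  expect_equal(fValueGRLD(tt, 1, 2, correlated = TRUE), f0,
               tolerance = 1e-10)
  expect_equal(fValueGRLD(tt, 1, 2, correlated = FALSE), f0,
               tolerance = 1e-10)
  expect_equal(fValueRLDM(u, 2L), f0, tolerance = 1e-10)
})

test_that("RLD-2 F-curve has the textbook optimum and diverges at the edges", {
  opt <- optimizeSetting("rld2")
  # stationarity condition (u/2) tanh(u/2) = 1 at the reported optimum
  u <- opt$hOverTau
  expect_equal((u / 2) * tanh(u / 2), 1, tolerance = 1e-6)
  expect_equal(opt$hOverTau, 2.3994, tolerance = 1e-4)
  expect_equal(opt$minF, 1.5089, tolerance = 1e-4)
  expect_gt(fValueRLD2(1e-4), 1e3)
  expect_gt(fValueRLD2(50), 1e3)
})

test_that("gate overlap correlation never hurts: k2 <= k1 everywhere", {
  x <- seq(0.01, 0.99, length.out = 200)
  for (S in c(0.1, 0.25, 0.5, 1)) {
    for (R in c(2.1, 3.2, 12.25)) {
      k1 <- flimtd:::.grldK1(x, S, R)
      k2 <- flimtd:::.grldK2(x, S, R)
      expect_true(all(k2 <= k1 + 1e-12))
      expect_true(all(fValueGRLD(seq(0.05, 1, by = 0.05), S, R, TRUE) <=
                      fValueGRLD(seq(0.05, 1, by = 0.05), S, R, FALSE) +
                      1e-9))
    }
  }
})

test_that("RLD-M minima saturate with bin count and only win near T ~ tau", {
  minAt <- function(M)
    stats::optimize(function(u) fValueRLDM(u, M), c(0.01, 4))$objective
  m8 <- minAt(8L)
  m16 <- minAt(16L)
  expect_lt(abs(m8 - m16) / m8, 0.02)
  # the multi-gate minimum never beats the two-gate one
  expect_gte(m8, 0.99 * optimizeSetting("rld2")$minF)
  # near T ~ tau the multi-gate estimator is the better gating option
  expect_lt(fValueRLDM(1 / 8, 8L), fValueRLD2(1 / 2))
})

test_that("Fisher baseline matches its closed-form anchors and lower-bounds", {
  # M = 2 two-bin sufficiency: Fisher F equals the RLD-2 F
  for (tt in c(0.1, 0.2083, 0.4))
    expect_equal(fValueFisherMLE(tt, 2L), fValueRLD2(1 / (2 * tt)),
                 tolerance = 1e-9)
  # continuous-limit oracle: truncated-exponential information integral
  fisherCont <- function(v) {
    cc <- v * exp(-v) / (1 - exp(-v))
    E2 <- stats::integrate(function(t) (t - 1 + cc)^2 * exp(-t) /
                             (1 - exp(-v)), 0, v, rel.tol = 1e-10)$value
    1 / sqrt(E2)
  }
  # 256 bins sit within a small finite-binning penalty of the continuum
  for (tt in c(0.05, 0.1, 0.3, 0.5))
    expect_equal(fValueFisherMLE(tt, 256L), fisherCont(1 / tt),
                 tolerance = 1e-3)
  # near-ideal photon economy over the fine-binned long-window band
  tt <- seq(0.05, 0.2, by = 0.01)
  Fv <- fValueFisherMLE(tt, 256L)
  expect_true(all(Fv >= 1 & Fv <= 1.1))
  # Cramer-Rao: the bound never exceeds any estimator curve
  for (tt in c(0.1, 0.2, 0.5)) {
    expect_lte(fValueFisherMLE(tt, 2L),
               fValueRLD2(1 / (2 * tt)) * (1 + 1e-9))
    expect_lte(fValueFisherMLE(tt, 8L),
               fValueRLDM(1 / (8 * tt), 8L) * (1 + 1e-9))
    expect_lte(fValueFisherMLE(tt, 256L) * (1 - 1e-9),
               min(fValueGRLD(tt, 0.2, 3.2, TRUE),
                   fValueGRLD(tt, 0.2, 3.2, FALSE)))
  }
})

test_that("setting optimization handles constraints and degenerate regions", {
  opt <- optimizeSetting("cgrld", "deltaR", deltaR = 3,
                         sGrid = seq(0.3, 0.7, by = 0.05))
  expect_equal(opt$gateStart, 0.5, tolerance = 0.05)
  # degenerate one-point region returns that point
  opt1 <- optimizeSetting("cgrld", "deltaR", deltaR = 3, sGrid = 0.2,
                          refine = FALSE)
  expect_equal(opt1$gateStart, 0.2)
  expect_error(optimizeSetting("cgrld", "deltaR", sGrid = numeric(0)),
               "empty")
  # fixed-S scan picks a finite optimum
  opt2 <- optimizeSetting("cgrld", "S", gateStart = 0.2,
                          rGrid = seq(2.2, 6.2, by = 1))
  expect_true(opt2$gateEnd %in% seq(2.2, 6.2, by = 1))
})

test_that("Monte-Carlo F agrees with closed forms for the gating estimators", {
  m <- singleExp(tau = 1)
  # RLD-2 at its optimum
  sp <- simSpec(m, gatedConfig(2.4), 1000, replicates = 3000L, seed = 71)
  r <- mcFValue(sp, "rld2")
  half <- (r$ci[2] - r$ci[1]) / 2
  expect_lt(abs(r$fvalue - fValueRLD2(2.4)), 3 * half)
  expect_lt(r$invalidFraction, 0.01)

  # CGRLD at its optimal tau/T
  ttOpt <- fValueCurve("cgrld", gateStart = 0.2,
                       gateEnd = 3.2)@minTauOverT
  h <- 1 / (3.2 * ttOpt)
  spc <- simSpec(m, gatedConfig(h, 0.2, 3.2), 1000, law = "poisson",
                 replicates = 3000L, seed = 72)
  rc <- mcFValue(spc, "grld")
  expect_lt(abs(rc$fvalue - fValueGRLD(ttOpt, 0.2, 3.2, TRUE)),
            3 * (rc$ci[2] - rc$ci[1]) / 2)

  # correlated beats uncorrelated at identical settings; compared where
  # the overlap carries a sizeable share of the photons (tau ~ window)
  h3 <- 1 / (3.2 * 0.3)
  spc3 <- simSpec(m, gatedConfig(h3, 0.2, 3.2), 1000, law = "poisson",
                  replicates = 4000L, seed = 76)
  spu3 <- simSpec(m, gatedConfig(h3, 0.2, 3.2, correlated = FALSE), 1000,
                  law = "poisson", replicates = 4000L, seed = 73)
  expect_lt(mcFValue(spc3, "grld")$fvalue, mcFValue(spu3, "grld")$fvalue)

  # a constant estimator has zero photon economy spread
  spb <- simSpec(m, binnedConfig(8, 32), 1000, replicates = 200L,
                 seed = 74)
  r0 <- mcFValue(spb, function(cnt, h) rep(1, ncol(cnt)))
  expect_equal(r0$fvalue, 0)
})

test_that("Monte-Carlo MLE precision approaches the Fisher bound", {
  m <- singleExp(tau = 1)
  sp <- simSpec(m, binnedConfig(8, 64), 1024, replicates = 400L,
                seed = 75)
  r <- mcFValue(sp, "mle")
  expect_lt(abs(r$fvalue - fValueFisherMLE(1 / 8, 64L)) /
              fValueFisherMLE(1 / 8, 64L), 0.1)
})
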