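test_that("per-pixel mapping equals the scalar estimators on every pixel", {
  ph <- defaultPhantom(size = 8L, meanCounts = 800)
  st <- simulateImageStack(ph, binnedConfig(8, 51), seed = 81)
  h <- binWidth(st)
  for (meth in c("rldm", "iem", "cmm", "mle")) {
    img <- mapEstimator(st, meth, minCounts = 0, lut = sharedLUT)
    for (px in list(c(1, 1), c(3, 7), c(8, 8))) {
      hist <- decayHistogram(counts(st)[px[1], px[2], ], h)
      scalar <- switch(meth,
                       rldm = fitRLDM(hist), iem = fitIEM(hist),
                       cmm = fitCMM(hist, sharedLUT), mle = fitMLE(hist))
      if (isValid(scalar))
        expect_equal(tauMap(img)[px[1], px[2]], tau(scalar),
                     tolerance = 1e-9)
      else
        expect_true(is.na(tauMap(img)[px[1], px[2]]))
    }
  }
  # gate methods against the histogram aggregation path
  img2 <- mapEstimator(st, "grld", gateStart = 0.2, gateEnd = 3.2,
                       minCounts = 0)
  hist <- decayHistogram(counts(st)[2, 5, ], h)
  gc <- gateCountsFromHistogram(hist, 0.2, 3.2)
  expect_equal(tauMap(img2)[2, 5], tau(fitGRLD(gc)), tolerance = 1e-5)
})

test_that("grld at S=1, R=2 and rld2 maps are identical", {
  ph <- defaultPhantom(size = 8L, meanCounts = 400)
  st <- simulateImageStack(ph, binnedConfig(8, 16), seed = 82)
  a <- mapEstimator(st, "rld2")
  b <- mapEstimator(st, "grld", gateStart = 1, gateEnd = 2)
  expect_equal(tauMap(a), tauMap(b), tolerance = 1e-9)
})

test_that("masking excludes starved, invalid and all-zero pixels", {
  ph <- defaultPhantom(size = 6L, meanCounts = 400)
  ph@expectedCounts[2, 2] <- 1e-12   # dead pixel
  st <- simulateImageStack(ph, binnedConfig(8, 17), seed = 83)
  img <- mapEstimator(st, "cmm", minCounts = 50, lut = sharedLUT)
  expect_false(validMask(img)[2, 2])
  expect_true(is.na(tauMap(img)[2, 2]))
  expect_equal(intensityMap(img)[2, 2], 0)
  # summaries ignore masked pixels
  s <- regionStats(img, ph@labels)$summary
  expect_equal(sum(s$nValid), sum(validMask(img)))
})

test_that("pixel order does not leak into the maps", {
  ph <- defaultPhantom(size = 8L, meanCounts = 500)
  st <- simulateImageStack(ph, binnedConfig(8, 17), seed = 84)
  img <- mapEstimator(st, "iem")
  # permute pixels, map, unpermute: identical result
  set.seed(1)
  perm <- sample(64L)
  arr <- counts(st)
  dim(arr) <- c(64L, 17L)
  arrP <- arr[perm, ]
  stP <- histogramStack(array(arrP, c(8L, 8L, 17L)), binWidth(st))
  imgP <- mapEstimator(stP, "iem")
  back <- matrix(NA_real_, 8L, 8L)
  back[perm] <- tauMap(imgP)
  expect_equal(as.vector(back), as.vector(tauMap(img)))
})

test_that("region statistics and empty labels behave", {
  ph <- defaultPhantom(size = 10L, meanCounts = 600)
  st <- simulateImageStack(ph, binnedConfig(8, 17), seed = 85)
  img <- mapEstimator(st, "cmm", lut = sharedLUT)
  labs <- ph@labels
  labs[1, 1] <- 3L   # (nearly) empty third label
  img@valid[1, 1] <- FALSE
  img@tau[1, 1] <- NA
  rs <- regionStats(img, labs)
  expect_true(is.na(rs$summary$mean[rs$summary$label == 3]))
  expect_equal(nrow(rs$summary), 3L)
  expect_length(rs$histograms, 3L)
})

test_that("rebinning aggregates pages exactly", {
  ph <- defaultPhantom(size = 4L, meanCounts = 300)
  st <- simulateImageStack(ph, binnedConfig(8, 16), seed = 86)
  rb <- rebinStack(st, 4L)
  expect_equal(nBins(rb), 4L)
  expect_equal(binWidth(rb), 4 * binWidth(st))
  expect_equal(counts(rb)[2, 3, 1], sum(counts(st)[2, 3, 1:4]))
  expect_equal(sum(counts(rb)), sum(counts(st)))
  expect_error(rebinStack(st, 3L), "divide")
})

test_that("contrast report flags identical and distinct maps", {
  ph <- defaultPhantom(size = 12L, meanCounts = 1500)
  st <- simulateImageStack(ph, binnedConfig(8, 51), seed = 87)
  img <- mapEstimator(st, "iem")
  cr <- contrastReport(list(a = img, b = img), ph@labels)
  expect_equal(cr$pairs$correlation, 1)
  expect_equal(cr$pairs$slope, 1)
  # vessel mean below extra-vascular mean for distinct estimators too
  img2 <- mapEstimator(st, "cmm", lut = sharedLUT)
  cr2 <- contrastReport(list(iem = img, cmm = img2), ph@labels)
  expect_true(all(cr2$contrast$mean1 < cr2$contrast$mean2))
  expect_error(contrastReport(list(img, img2), matrix(1L, 12, 12)),
               "two labels")
})
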