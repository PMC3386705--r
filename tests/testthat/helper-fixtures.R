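# shared fixtures built in code

singleExp <- function(A = 1000, tau = 1, b = 0) decayModel(A, tau, b)

# expected histogram of a single/bi-exponential model
expHist <- function(model, window, bins)
  expectedBinCounts(model, binnedConfig(window, bins))

# random strictly positive decreasing-ish count pairs / histograms
randomCountPair <- function() {
  n2 <- stats::runif(1, 1, 1e4)
  c(n2 * stats::runif(1, 1.01, 20), n2)
}

sharedLUT <- buildOmegaLUT()
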