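#' Sample a photon time-tag list
#'
#' Draws photon arrival times i.i.d. from the window-truncated decay
#' density \eqn{f(t)/\int_0^T f} — a mixture of truncated exponentials
#' plus a uniform background, with mixture weights proportional to each
#' component's expected window count — and emits the TDC codes
#' \eqn{D_i = \lfloor t_i/h \rfloor}. The total count is either exactly
#' `nPhotons` (`law = "fixed"`) or Poisson with that mean
#' (`law = "poisson"`); in both cases it counts photons inside
#' \eqn{[0, T)}, consistent with the photon-economy normalization.
#'
#' @param spec A [SimSpec-class] with a binned configuration.
#' @return A [PhotonList-class]; identical for identical specs (all
#'   randomness flows from `spec@seed`).
#' @examples
#' sp <- simSpec(decayModel(1000, 1), binnedConfig(8, 256), 1000, seed = 7)
#' samplePhotons(sp)
#' @export
samplePhotons <- function(spec) {
  stopifnot(is(spec, "SimSpec"))
  cfg <- spec@config
  if (is.na(cfg@bins))
    stop("samplePhotons requires a binned configuration")
  set.seed(spec@seed)
  t <- .sampleArrivalTimes(spec@model, cfg@window, .drawN(spec))
  photonList(floor(t / cfg@binWidth), cfg@bins, cfg@binWidth)
}

.drawN <- function(spec) {
  if (spec@law == "fixed") as.integer(round(spec@nPhotons))
  else stats::rpois(1L, spec@nPhotons)
}

# i.i.d. arrival times on [0, T) via component choice + inverse CDF of the
# window-truncated exponential (background component is uniform).
.sampleArrivalTimes <- function(model, window, n) {
  if (n == 0L) return(numeric(0))
  A <- model@amplitudes
  tauk <- model@lifetimes
  w <- A * tauk * (1 - exp(-window / tauk))
  wb <- model@background * window
  comp <- sample.int(length(w) + 1L, n, replace = TRUE,
                     prob = c(w, wb))
  t <- numeric(n)
  for (k in seq_along(w)) {
    idx <- comp == k
    nk <- sum(idx)
    if (nk) {
      u <- stats::runif(nk)
      t[idx] <- -tauk[k] * log1p(-u * (1 - exp(-window / tauk[k])))
    }
  }
  idx <- comp == length(w) + 1L
  if (any(idx)) t[idx] <- stats::runif(sum(idx), 0, window)
  pmin(t, window * (1 - 1e-12))
}

#' Sample a decay histogram
#'
#' Convenience wrapper: samples photons per [samplePhotons()] and bins
#' them.
#'
#' @param spec A [SimSpec-class] with a binned configuration.
#' @return A [DecayHistogram-class].
#' @export
sampleHistogram <- function(spec) {
  pl <- samplePhotons(spec)
  decayHistogram(counts(pl), pl@binWidth)
}

# Replicate sampler for binned acquisitions: bins x replicates matrix.
# Fixed law -> multinomial; Poisson law -> independent Poisson bins
# (exact thinning of a Poisson stream).
.sampleHistReps <- function(model, config, nPhotons, law, reps) {
  p <- counts(expectedBinCounts(model, config))
  p <- p / sum(p)
  M <- length(p)
  if (law == "fixed") {
    stats::rmultinom(reps, as.integer(round(nPhotons)), p)
  } else {
    matrix(stats::rpois(M * reps, nPhotons * p), nrow = M)
  }
}

# Replicate sampler for the two-gate geometries. Correlated: one photon
# stream over [0, Rh), region counts over the partition
# {[0,Sh), [Sh,h), [h,Rh)}; gate counts share the overlap region.
# Uncorrelated: two independent streams of the same duration, one per
# gate. Returns n1, n2, nOverlap (NA if uncorrelated) and nc, the
# window total used for F normalization.
.sampleGateReps <- function(model, config, nPhotons, law, reps) {
  S <- config@gateStart
  R <- config@gateEnd
  if (is.na(S)) stop("gated sampling requires a gated configuration")
  h <- config@binWidth
  bounds <- if (S < 1) c(0, S * h, h, R * h) else c(0, h, S * h, R * h)
  lam <- .expectedInterval(model, bounds[-length(bounds)], bounds[-1])
  p <- lam / sum(lam)
  correlated <- config@scheme != "uncorrelated-gates"
  if (correlated) {
    cnt <- if (law == "fixed")
      stats::rmultinom(reps, as.integer(round(nPhotons)), p)
    else
      matrix(stats::rpois(length(p) * reps, nPhotons * p),
             nrow = length(p))
    if (S < 1) {
      list(n1 = cnt[1, ] + cnt[2, ], n2 = cnt[2, ] + cnt[3, ],
           nOverlap = cnt[2, ], nc = colSums(cnt))
    } else {
      list(n1 = cnt[1, ], n2 = cnt[3, ], nOverlap = rep(0, reps),
           nc = colSums(cnt))
    }
  } else {
    p1 <- if (S < 1) p[1] + p[2] else p[1]
    p2 <- if (S < 1) p[2] + p[3] else p[3]
    if (law == "fixed") {
      n <- as.integer(round(nPhotons))
      list(n1 = stats::rbinom(reps, n, p1),
           n2 = stats::rbinom(reps, n, p2),
           nOverlap = rep(NA_real_, reps), nc = rep(n, reps))
    } else {
      list(n1 = stats::rpois(reps, nPhotons * p1),
           n2 = stats::rpois(reps, nPhotons * p2),
           nOverlap = rep(NA_real_, reps),
           nc = stats::rpois(reps, nPhotons))
    }
  }
}

#' Sample two-gate counts
#'
#' Simulates one acquisition of the generalized two-gate geometry. In the
#' correlated scheme a single photon stream over \eqn{[0, Rh)} feeds both
#' gates, so overlap photons increment both counters and \eqn{N_1} and
#' \eqn{N_2} are positively correlated across replicates. In the
#' uncorrelated scheme each gate sees its own independent stream of the
#' same duration.
#'
#' @param spec A [SimSpec-class] with a gated configuration.
#' @param replicates Optional override of `spec@replicates`; when the
#'   result is more than one replicate a list of vectors
#'   (`n1`, `n2`, `nOverlap`, `nc`) is returned instead of a single
#'   [GateCounts-class].
#' @return A [GateCounts-class] (single replicate) or a list of count
#'   vectors.
#' @export
sampleGateCounts <- function(spec, replicates = NULL) {
  stopifnot(is(spec, "SimSpec"))
  if (!(spec@config@scheme %in% GATED_SCHEMES))
    stop("sampleGateCounts requires a correlated-gates or ",
         "uncorrelated-gates scheme")
  reps <- if (is.null(replicates)) spec@replicates else as.integer(replicates)
  set.seed(spec@seed)
  g <- .sampleGateReps(spec@model, spec@config, spec@nPhotons, spec@law,
                       reps)
  if (reps == 1L) {
    gateCounts(g$n1, g$n2, spec@config@gateStart, spec@config@gateEnd,
               spec@config@binWidth,
               correlated = spec@config@scheme == "correlated-gates",
               nOverlap = g$nOverlap)
  } else g
}

#' Two-region synthetic FLIM phantom
#'
#' A 64 x 64 (by default) scene with a branching "vessel" region V and an
#' "extra-vascular" region E. Both regions share the same bi-exponential
#' lifetime pair — 0.3 ns and 3.4 ns by default — and differ only in the
#' short-component amplitude fraction \eqn{A_1/(A_1+A_2)} (defaults 0.8
#' in V and 0.2 in E), so the vessel's amplitude-weighted mean lifetime
#' (0.92 ns at defaults) is below the extra-vascular one (2.78 ns).
#'
#' @param size Image side length in pixels.
#' @param fractions Length-2 short-component amplitude fractions for
#'   regions V and E.
#' @param lifetimes Length-2 lifetime pair \eqn{(\tau_1, \tau_2)} (ns).
#' @param meanCounts Expected total photon count per pixel.
#' @param totalRate Total amplitude scale \eqn{A_1 + A_2} (photons/ns);
#'   only the per-pixel expected count matters downstream.
#' @return A [Phantom-class]; label 1 is the vessel region.
#' @examples
#' ph <- defaultPhantom(size = 16)
#' table(ph@labels)
#' @export
defaultPhantom <- function(size = 64L, fractions = c(0.8, 0.2),
                           lifetimes = c(0.3, 3.4), meanCounts = 500,
                           totalRate = 1000) {
  stopifnot(size >= 4L, length(fractions) == 2L, length(lifetimes) == 2L)
  x <- matrix(rep(seq_len(size), each = size), size)
  y <- matrix(rep(seq_len(size), times = size), size)
  # a vessel-rich field: trunk, two parallel vessels, one branch
  trunk <- abs(x - y) <= size / 8
  v2 <- abs(x - y + round(size / 2.5)) <= size / 10
  v3 <- abs(x - y - round(size / 2.5)) <= size / 10
  branch <- abs(y - round(0.75 * size)) <= size / 16 & x >= size / 4
  labels <- matrix(2L, size, size)
  labels[trunk | v2 | v3 | branch] <- 1L
  models <- lapply(fractions, function(f)
    decayModel(totalRate * c(f, 1 - f), lifetimes))
  new("Phantom", labels = labels, models = models,
      expectedCounts = matrix(meanCounts, size, size))
}

#' Simulate a per-pixel histogram image stack
#'
#' Samples every pixel's decay histogram independently from its label's
#' model. Per-pixel totals are Poisson with the phantom's expected count
#' (`law = "poisson"`, the default, samples every bin as an independent
#' Poisson variate — the exact law of a thinned Poisson photon stream) or
#' exactly the rounded expected count (`law = "fixed"`). Pixels are
#' filled in a fixed column-major order from a single seeded stream, so
#' identical inputs give identical stacks.
#'
#' @param phantom A [Phantom-class].
#' @param config A binned [AcquisitionConfig-class].
#' @param seed Integer seed.
#' @param law `"poisson"` or `"fixed"` per-pixel total-count law.
#' @return A [HistogramStack-class].
#' @export
simulateImageStack <- function(phantom, config, seed = 1L,
                               law = c("poisson", "fixed")) {
  stopifnot(is(phantom, "Phantom"), is(config, "AcquisitionConfig"))
  law <- match.arg(law)
  if (is.na(config@bins))
    stop("simulateImageStack requires a binned configuration")
  set.seed(seed)
  M <- config@bins
  d <- dim(phantom@labels)
  stack <- array(0, c(d[1], d[2], M))
  for (lab in sort(unique(as.vector(phantom@labels)))) {
    idx <- which(phantom@labels == lab)
    if (!length(idx)) next
    p <- counts(expectedBinCounts(phantom@models[[lab]], config))
    p <- p / sum(p)
    lamTot <- phantom@expectedCounts[idx]
    if (law == "poisson") {
      cnt <- matrix(stats::rpois(M * length(idx), outer(p, lamTot)),
                    nrow = M)
    } else {
      cnt <- matrix(0, M, length(idx))
      for (i in seq_along(idx))
        cnt[, i] <- stats::rmultinom(1L, as.integer(round(lamTot[i])), p)
    }
    for (jbin in seq_len(M)) {
      page <- stack[, , jbin]
      page[idx] <- cnt[jbin, ]
      stack[, , jbin] <- page
    }
  }
  histogramStack(stack, config@binWidth)
}
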