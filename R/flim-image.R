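#' Apply a lifetime estimator to every pixel of a histogram stack
#'
#' Runs one estimator independently per pixel and assembles a lifetime
#' map, an intensity (total-count) map and a validity mask. Pixels whose
#' total count falls below `minCounts` — where the gating estimators'
#' invalid fraction explodes — or where the estimator itself flags an
#' invalid result are masked, never imputed.
#'
#' For the gate-based methods the per-pixel histogram is first aggregated
#' into two gates spanning the full window (see
#' [gateCountsFromHistogram()]): `"rld2"` uses two half-window gates and
#' `"grld"` the \eqn{S}/\eqn{R} geometry with gate width \eqn{T/R}.
#' `"ave"` reports the amplitude-weighted mean lifetime of a per-pixel
#' bi-exponential fit ([fitBiexp()]).
#'
#' @param stack A [HistogramStack-class].
#' @param method One of `"rld2"`, `"grld"`, `"rldm"`, `"iem"`, `"cmm"`,
#'   `"mle"`, `"ave"`.
#' @param gateStart,gateEnd Gate geometry for `"grld"`.
#' @param lut [OmegaLUT-class] for `"cmm"` (built on demand).
#' @param minCounts Minimum per-pixel total count (default 50).
#' @param rebin Integer page-aggregation factor applied before
#'   estimation (default 1, no rebinning); the bin count must be
#'   divisible by it.
#' @return A [LifetimeImage-class].
#' @examples
#' ph <- defaultPhantom(size = 8)
#' st <- simulateImageStack(ph, binnedConfig(10.2, 51), seed = 1)
#' mapEstimator(st, "cmm")
#' @export
mapEstimator <- function(stack,
                         method = c("rld2", "grld", "rldm", "iem", "cmm",
                                    "mle", "ave"),
                         gateStart = 0.2, gateEnd = 3.2, lut = NULL,
                         minCounts = 50, rebin = 1L) {
  stopifnot(is(stack, "HistogramStack"), minCounts >= 0)
  method <- match.arg(method)
  if (rebin > 1L) stack <- rebinStack(stack, rebin)
  d <- dim(stack@counts)
  M <- d[3]
  h <- stack@binWidth
  cnt <- matrix(aperm(stack@counts, c(3, 1, 2)), nrow = M)  # bins x pixels
  tot <- colSums(cnt)
  taus <- switch(method,
    rld2 = {
      b <- M / 2   # two half-window gates; fractional boundary allowed
      n1 <- .cumAtVec(cnt, b)
      n2 <- tot - n1
      .rld2Vec(n1, n2, b * h)
    },
    grld = {
      .checkGrldGeometry(gateStart, gateEnd)
      b <- M / gateEnd
      n1 <- .cumAtVec(cnt, b)
      n2 <- tot - .cumAtVec(cnt, gateStart * b)
      inv <- .grldInverse(gateStart, gateEnd)
      ratio <- ifelse(n1 > 0, n2 / n1, NA_real_)
      b * h * inv(ratio)
    },
    rldm = .rldmVec(cnt, h),
    iem = {
      if (M %% 2L == 0L)
        stop("IEM requires an odd bin count; rebin or truncate the stack")
      .iemVec(cnt, h)
    },
    cmm = .cmmVec(cnt, h, if (is.null(lut)) buildOmegaLUT() else lut),
    mle = apply(cnt, 2, function(N) {
      if (sum(N) < 1) return(NA_real_)
      e <- fitMLE(decayHistogram(N, h))
      if (e@valid) e@tau else NA_real_
    }),
    ave = apply(cnt, 2, function(N) {
      if (sum(N) < 100) return(NA_real_)
      f <- fitBiexp(decayHistogram(N, h))
      if (isTRUE(f$valid)) f$tauAve else NA_real_
    }))
  valid <- is.finite(taus) & taus > 0 & tot >= minCounts
  taus[!valid] <- NA_real_
  new("LifetimeImage",
      tau = matrix(taus, d[1], d[2]),
      intensity = matrix(tot, d[1], d[2]),
      valid = matrix(valid, d[1], d[2]),
      method = method,
      settings = list(gateStart = if (method == "grld") gateStart else NA,
                      gateEnd = if (method == "grld") gateEnd else NA,
                      minCounts = minCounts, binWidth = h, bins = M,
                      rebin = as.integer(rebin)))
}

# cumulative counts of each column up to fractional bin position b
# (uniform-within-bin apportionment), vectorized over pixels
.cumAtVec <- function(cnt, b) {
  M <- nrow(cnt)
  b <- min(max(b, 0), M)
  i <- floor(b)
  base <- if (i == 0L) 0 else colSums(cnt[seq_len(i), , drop = FALSE])
  if (i < M) base <- base + (b - i) * cnt[i + 1L, ]
  base
}

#' Aggregate stack pages by an integer factor
#'
#' Sums consecutive groups of `factor` time-bin pages, producing a stack
#' with `M/factor` coarser bins of width `factor * h`.
#'
#' @param stack A [HistogramStack-class].
#' @param factor Integer divisor of the bin count.
#' @return A [HistogramStack-class].
#' @export
rebinStack <- function(stack, factor) {
  stopifnot(is(stack, "HistogramStack"))
  factor <- as.integer(factor)
  M <- dim(stack@counts)[3]
  if (factor < 1L || M %% factor != 0L)
    stop("rebin factor must divide the bin count")
  if (factor == 1L) return(stack)
  d <- dim(stack@counts)
  Mnew <- M %/% factor
  out <- array(0, c(d[1], d[2], Mnew))
  for (j in seq_len(Mnew)) {
    idx <- ((j - 1L) * factor + 1L):(j * factor)
    out[, , j] <- apply(stack@counts[, , idx, drop = FALSE], c(1, 2), sum)
  }
  histogramStack(out, stack@binWidth * factor)
}

#' Per-region summaries of a lifetime image
#'
#' Mean, standard deviation, pixel counts and a fixed-width histogram of
#' the valid lifetimes in each labelled region. Histogram binning spans
#' the 1st-99th percentile of all valid lifetimes in the image.
#'
#' @param img A [LifetimeImage-class].
#' @param labels Integer label matrix matching the image extent.
#' @param histBins Number of histogram bins (default 32).
#' @return A list with a `summary` data frame (columns `label`, `nValid`,
#'   `nTotal`, `mean`, `sd`, `median`) and a `histograms` list of
#'   per-label `hist`-style lists (`breaks`, `counts`).
#' @export
regionStats <- function(img, labels, histBins = 32L) {
  stopifnot(is(img, "LifetimeImage"),
            identical(dim(labels), dim(img@tau)))
  allTau <- img@tau[img@valid]
  breaks <- if (length(allTau) >= 2L) {
    q <- stats::quantile(allTau, c(0.01, 0.99), names = FALSE)
    if (q[2] <= q[1]) q[2] <- q[1] + 1e-9
    seq(q[1], q[2], length.out = histBins + 1L)
  } else c(0, 1)
  labs <- sort(unique(as.vector(labels)))
  rows <- list()
  hists <- list()
  for (lab in labs) {
    sel <- labels == lab & img@valid
    tv <- img@tau[sel]
    rows[[as.character(lab)]] <- data.frame(
      label = lab, nValid = length(tv), nTotal = sum(labels == lab),
      mean = if (length(tv)) mean(tv) else NA_real_,
      sd = if (length(tv) > 1L) stats::sd(tv) else NA_real_,
      median = if (length(tv)) stats::median(tv) else NA_real_)
    tc <- tv[tv >= breaks[1] & tv <= breaks[length(breaks)]]
    hists[[as.character(lab)]] <- list(
      breaks = breaks,
      counts = if (length(tc))
        graphics::hist(tc, breaks = breaks, plot = FALSE)$counts
      else rep(0L, length(breaks) - 1L))
  }
  list(summary = do.call(rbind, c(rows, make.row.names = FALSE)),
       histograms = hists)
}

#' Inter-region contrast and between-method agreement
#'
#' For each lifetime image of the same scene, reports the two-region
#' contrast (difference of region means over the pooled standard
#' deviation) and, for every image pair, the pixelwise correlation and
#' the least-squares slope of the second method's lifetimes on the
#' first's over jointly valid pixels.
#'
#' @param imgs Named list of [LifetimeImage-class] objects on the same
#'   scene (at least 2).
#' @param labels Integer label matrix with exactly two labels.
#' @return A list with `contrast` (per-method data frame: region means,
#'   pooled sd, contrast) and `pairs` (per-pair data frame: correlation,
#'   slope of method 2 on method 1).
#' @export
contrastReport <- function(imgs, labels) {
  stopifnot(is.list(imgs), length(imgs) >= 2L)
  if (is.null(names(imgs)))
    names(imgs) <- vapply(imgs, function(i) i@method, character(1))
  labs <- sort(unique(as.vector(labels)))
  if (length(labs) != 2L) stop("contrastReport needs exactly two labels")
  contrast <- do.call(rbind, lapply(names(imgs), function(nm) {
    img <- imgs[[nm]]
    t1 <- img@tau[labels == labs[1] & img@valid]
    t2 <- img@tau[labels == labs[2] & img@valid]
    pooled <- sqrt(((length(t1) - 1) * stats::var(t1) +
                    (length(t2) - 1) * stats::var(t2)) /
                   (length(t1) + length(t2) - 2))
    data.frame(method = nm, mean1 = mean(t1), mean2 = mean(t2),
               pooledSD = pooled,
               contrast = abs(mean(t2) - mean(t1)) / pooled)
  }))
  pairIdx <- utils::combn(names(imgs), 2L)
  pairs <- do.call(rbind, lapply(seq_len(ncol(pairIdx)), function(i) {
    a <- imgs[[pairIdx[1, i]]]
    b <- imgs[[pairIdx[2, i]]]
    sel <- a@valid & b@valid
    xa <- a@tau[sel]
    xb <- b@tau[sel]
    sl <- stats::cov(xa, xb) / stats::var(xa)
    data.frame(method1 = pairIdx[1, i], method2 = pairIdx[2, i],
               nPixels = sum(sel), correlation = stats::cor(xa, xb),
               slope = sl)
  }))
  list(contrast = contrast, pairs = pairs)
}
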