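#' @import methods
NULL

SCHEMES <- c("sequential", "correlated-gates", "uncorrelated-gates", "tcspc")
GATED_SCHEMES <- c("correlated-gates", "uncorrelated-gates")

#' Multi-exponential fluorescence decay model
#'
#' Describes an impulse-response fluorescence decay
#' \eqn{f(t) = \sum_k A_k \exp(-t/\tau_k) + b} on \eqn{t \ge 0}: a sum of
#' exponential components plus a uniform background rate. The instrument
#' response is treated as a delta function, so \eqn{t = 0} is the moment of
#' excitation.
#'
#' @slot amplitudes Numeric vector of component amplitudes \eqn{A_k}
#'   (photons per unit time at \eqn{t = 0}), all non-negative with at least
#'   one positive entry.
#' @slot lifetimes Numeric vector of component lifetimes \eqn{\tau_k} (ns),
#'   strictly positive, same length as `amplitudes`.
#' @slot background Uniform background rate \eqn{b} (photons per unit time
#'   across the measurement window), non-negative scalar.
#' @seealso [decayModel()], [expectedBinCounts()], [expectedTotal()]
#' @export
setClass("DecayModel",
  representation(amplitudes = "numeric", lifetimes = "numeric",
                 background = "numeric"),
  prototype(background = 0),
  validity = function(object) {
    msg <- character()
    if (length(object@amplitudes) != length(object@lifetimes))
      msg <- c(msg, "amplitudes and lifetimes must have equal length")
    if (length(object@amplitudes) < 1L)
      msg <- c(msg, "at least one decay component is required")
    if (any(!is.finite(object@lifetimes)) || any(object@lifetimes <= 0))
      msg <- c(msg, "all lifetimes must be finite and > 0")
    if (any(!is.finite(object@amplitudes)) || any(object@amplitudes < 0))
      msg <- c(msg, "all amplitudes must be finite and >= 0")
    if (length(object@amplitudes) >= 1L && all(object@amplitudes == 0))
      msg <- c(msg, "at least one amplitude must be > 0")
    if (length(object@background) != 1L || !is.finite(object@background) ||
        object@background < 0)
      msg <- c(msg, "background must be a single non-negative number")
    if (length(msg)) msg else TRUE
  })

#' Construct a decay model
#'
#' @param amplitudes Component amplitudes \eqn{A_k} (photons/ns).
#' @param lifetimes Component lifetimes \eqn{\tau_k} (ns).
#' @param background Uniform background rate (photons/ns), default 0.
#' @return A [DecayModel-class] object.
#' @examples
#' decayModel(1000, 2.5)
#' decayModel(c(800, 200), c(0.3, 3.4))
#' @export
decayModel <- function(amplitudes, lifetimes, background = 0) {
  new("DecayModel", amplitudes = as.numeric(amplitudes),
      lifetimes = as.numeric(lifetimes),
      background = as.numeric(background))
}

#' Acquisition configuration
#'
#' Describes how photons are collected after each excitation pulse: the
#' measurement window \eqn{T}, the number of time bins \eqn{M} of width
#' \eqn{h = T/M} (for binned schemes), or the two-gate geometry for gated
#' schemes. In the generalized two-gate geometry, gate 1 spans
#' \eqn{[0, h)} and gate 2 spans \eqn{[S h, R h)}; the gates overlap when
#' \eqn{S < 1}. For gated schemes the measurement window is \eqn{T = R h}.
#'
#' @slot window Measurement window \eqn{T} (ns).
#' @slot bins Number of time bins \eqn{M} (integer, `NA` for gated schemes).
#' @slot binWidth Bin or gate width \eqn{h} (ns).
#' @slot gateStart Gate-2 start \eqn{S} in units of \eqn{h} (`NA` if unused).
#' @slot gateEnd Gate-2 end \eqn{R} in units of \eqn{h} (`NA` if unused).
#' @slot scheme One of `"sequential"`, `"correlated-gates"`,
#'   `"uncorrelated-gates"`, `"tcspc"`.
#' @seealso [binnedConfig()], [gatedConfig()]
#' @export
setClass("AcquisitionConfig",
  representation(window = "numeric", bins = "integer", binWidth = "numeric",
                 gateStart = "numeric", gateEnd = "numeric",
                 scheme = "character"),
  prototype(bins = NA_integer_, gateStart = NA_real_, gateEnd = NA_real_,
            scheme = "tcspc"),
  validity = function(object) {
    msg <- character()
    if (!(object@scheme %in% SCHEMES))
      msg <- c(msg, paste("scheme must be one of:",
                          paste(SCHEMES, collapse = ", ")))
    if (!is.finite(object@binWidth) || object@binWidth <= 0)
      msg <- c(msg, "binWidth must be > 0")
    if (!is.finite(object@window) || object@window <= 0)
      msg <- c(msg, "window must be > 0")
    gated <- object@scheme %in% GATED_SCHEMES
    if (gated) {
      S <- object@gateStart; R <- object@gateEnd
      if (is.na(S) || is.na(R)) {
        msg <- c(msg, "gated schemes require gateStart and gateEnd")
      } else {
        if (!(S > 0 && S <= 1 && R > 1))
          msg <- c(msg, "gate geometry requires 0 < S <= 1 < R")
        if (abs(object@window - R * object@binWidth) >
            1e-9 * object@window)
          msg <- c(msg, "gated schemes require window == gateEnd * binWidth")
      }
    } else {
      M <- object@bins
      if (is.na(M) || M < 2L)
        msg <- c(msg, "binned schemes require bins >= 2")
      else if (abs(object@window - M * object@binWidth) >
               1e-9 * object@window)
        msg <- c(msg, "window must equal bins * binWidth")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a binned (histogram / TCSPC) acquisition configuration
#'
#' @param window Measurement window \eqn{T} (ns).
#' @param bins Number of equal time bins \eqn{M}.
#' @param scheme `"tcspc"` (default) or `"sequential"`.
#' @return An [AcquisitionConfig-class].
#' @examples
#' binnedConfig(window = 8, bins = 256)
#' @export
binnedConfig <- function(window, bins, scheme = c("tcspc", "sequential")) {
  scheme <- match.arg(scheme)
  bins <- as.integer(bins)
  new("AcquisitionConfig", window = as.numeric(window), bins = bins,
      binWidth = as.numeric(window) / bins, scheme = scheme)
}

#' Construct a two-gate acquisition configuration
#'
#' Gate 1 covers \eqn{[0, h)}; gate 2 covers \eqn{[S h, R h)}. The
#' measurement window is \eqn{T = R h}. `gateStart = 1, gateEnd = 2`
#' reproduces the classic two-equal-gate geometry.
#'
#' @param binWidth Gate width \eqn{h} (ns).
#' @param gateStart Gate-2 start \eqn{S} (units of \eqn{h}), \eqn{0 < S \le 1}.
#' @param gateEnd Gate-2 end \eqn{R} (units of \eqn{h}), \eqn{R > 1}.
#' @param correlated Logical; `TRUE` when both gates see the same photon
#'   stream (overlap counts are shared events), `FALSE` when the two gates
#'   are independent acquisitions.
#' @return An [AcquisitionConfig-class].
#' @examples
#' gatedConfig(binWidth = 1, gateStart = 0.2, gateEnd = 3.2)
#' @export
gatedConfig <- function(binWidth, gateStart = 1, gateEnd = 2,
                        correlated = TRUE) {
  new("AcquisitionConfig",
      window = as.numeric(gateEnd) * as.numeric(binWidth),
      binWidth = as.numeric(binWidth),
      gateStart = as.numeric(gateStart), gateEnd = as.numeric(gateEnd),
      scheme = if (correlated) "correlated-gates" else "uncorrelated-gates")
}

#' Binned decay histogram
#'
#' Photon counts per time bin. Bin \eqn{j} (0-based) covers
#' \eqn{[j h, (j+1) h)}. Counts may be real-valued (expected counts) or
#' integer (observed).
#'
#' @slot counts Non-negative numeric vector of per-bin counts.
#' @slot binWidth Bin width \eqn{h} (ns).
#' @export
setClass("DecayHistogram",
  representation(counts = "numeric", binWidth = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@counts) < 1L) msg <- c(msg, "counts must be non-empty")
    if (any(!is.finite(object@counts)) || any(object@counts < 0))
      msg <- c(msg, "counts must be finite and >= 0")
    if (!is.finite(object@binWidth) || object@binWidth <= 0)
      msg <- c(msg, "binWidth must be > 0")
    if (length(msg)) msg else TRUE
  })

#' @rdname DecayHistogram-class
#' @param counts Per-bin photon counts.
#' @param binWidth Bin width (ns).
#' @return A [DecayHistogram-class].
#' @export
decayHistogram <- function(counts, binWidth) {
  new("DecayHistogram", counts = as.numeric(counts),
      binWidth = as.numeric(binWidth))
}

#' Photon time-tag list
#'
#' Discrete photon arrival codes, one per detected photon: code
#' \eqn{D_i = \lfloor t_i/h \rfloor \in \{0, \dots, M-1\}} as produced by a
#' time-to-digital converter with \eqn{M} bins of width \eqn{h}.
#'
#' @slot codes Integer vector of per-photon bin codes.
#' @slot bins Number of bins \eqn{M}.
#' @slot binWidth Bin width \eqn{h} (ns).
#' @export
setClass("PhotonList",
  representation(codes = "integer", bins = "integer", binWidth = "numeric"),
  validity = function(object) {
    msg <- character()
    if (is.na(object@bins) || object@bins < 1L)
      msg <- c(msg, "bins must be >= 1")
    if (length(object@codes) &&
        (min(object@codes) < 0L || max(object@codes) >= object@bins))
      msg <- c(msg, "codes must lie in [0, bins - 1]")
    if (!is.finite(object@binWidth) || object@binWidth <= 0)
      msg <- c(msg, "binWidth must be > 0")
    if (length(msg)) msg else TRUE
  })

#' @rdname PhotonList-class
#' @param codes Integer photon codes in `[0, bins - 1]`.
#' @param bins Number of TDC bins.
#' @param binWidth Bin width (ns).
#' @return A [PhotonList-class].
#' @export
photonList <- function(codes, bins, binWidth) {
  new("PhotonList", codes = as.integer(codes), bins = as.integer(bins),
      binWidth = as.numeric(binWidth))
}

#' Two-gate photon counts
#'
#' Counts collected by the two gates of the generalized rapid lifetime
#' determination geometry: \eqn{N_1} over \eqn{[0, h)} and \eqn{N_2} over
#' \eqn{[S h, R h)}. When the gates overlap (\eqn{S < 1}) and the
#' acquisition is correlated, the overlap count \eqn{N_{ov}} is shared
#' between both gates.
#'
#' @slot n1 Gate-1 count \eqn{N_1}.
#' @slot n2 Gate-2 count \eqn{N_2}.
#' @slot nOverlap Overlap count \eqn{N_{ov}} (`NA` when unknown or
#'   meaningless, e.g. uncorrelated acquisition).
#' @slot gateStart Gate-2 start \eqn{S} in units of \eqn{h}.
#' @slot gateEnd Gate-2 end \eqn{R} in units of \eqn{h}.
#' @slot binWidth Gate width \eqn{h} (ns).
#' @slot correlated Logical overlap-sharing flag.
#' @export
setClass("GateCounts",
  representation(n1 = "numeric", n2 = "numeric", nOverlap = "numeric",
                 gateStart = "numeric", gateEnd = "numeric",
                 binWidth = "numeric", correlated = "logical"),
  prototype(nOverlap = NA_real_, correlated = TRUE),
  validity = function(object) {
    msg <- character()
    if (object@n1 < 0 || object@n2 < 0)
      msg <- c(msg, "gate counts must be >= 0")
    S <- object@gateStart; R <- object@gateEnd
    if (!(S > 0 && S <= 1 && R > 1))
      msg <- c(msg, "gate geometry requires 0 < S <= 1 < R")
    if (!is.finite(object@binWidth) || object@binWidth <= 0)
      msg <- c(msg, "binWidth must be > 0")
    if (length(msg)) msg else TRUE
  })

#' @rdname GateCounts-class
#' @param n1,n2 Gate counts.
#' @param gateStart,gateEnd Gate-2 geometry \eqn{S}, \eqn{R}.
#' @param binWidth Gate width (ns).
#' @param correlated Logical; shared photon stream in the overlap.
#' @param nOverlap Overlap count (optional).
#' @return A [GateCounts-class].
#' @export
gateCounts <- function(n1, n2, gateStart = 1, gateEnd = 2, binWidth,
                       correlated = TRUE, nOverlap = NA_real_) {
  new("GateCounts", n1 = as.numeric(n1), n2 = as.numeric(n2),
      nOverlap = as.numeric(nOverlap), gateStart = as.numeric(gateStart),
      gateEnd = as.numeric(gateEnd), binWidth = as.numeric(binWidth),
      correlated = isTRUE(correlated))
}

#' Lifetime estimate
#'
#' Result of a non-iterative or reference lifetime estimator. Invalid
#' estimates (non-decaying counts, saturated centroid, zero bins, ...) are
#' flagged rather than raised, so per-pixel application stays robust.
#'
#' @slot tau Estimated lifetime \eqn{\hat\tau} (ns); `NA` when invalid.
#' @slot method Estimator name.
#' @slot valid Logical validity flag.
#' @slot diagnostics Named list of method-specific diagnostics.
#' @export
setClass("LifetimeEstimate",
  representation(tau = "numeric", method = "character", valid = "logical",
                 diagnostics = "list"),
  prototype(diagnostics = list()),
  validity = function(object) {
    if (object@valid && (!is.finite(object@tau) || object@tau <= 0))
      "valid estimates must have finite tau > 0"
    else TRUE
  })

.estimate <- function(tau, method, valid = TRUE, diagnostics = list()) {
  if (!valid) tau <- NA_real_
  new("LifetimeEstimate", tau = as.numeric(tau), method = method,
      valid = valid, diagnostics = diagnostics)
}

#' Centre-of-mass truncation-calibration lookup table
#'
#' Tabulates the forward truncation map
#' \eqn{g(u) = u - e^{-1/u} / (1 - e^{-1/u})} relating the true
#' normalized lifetime \eqn{u = \tau/T} to the normalized first moment
#' (centroid) of the window-truncated decay. The calibration
#' \eqn{\Omega = g^{-1}} is evaluated by monotone cubic interpolation of
#' the tabulated pairs. Centroids at or above the saturation value 1/2
#' (the uniform-distribution limit) are not invertible.
#'
#' @slot tauOverT Log-spaced grid of \eqn{\tau/T} values.
#' @slot centroid Corresponding \eqn{g(\tau/T)} values (strictly increasing).
#' @seealso [buildOmegaLUT()], [omegaCalibrate()], [fitCMM()]
#' @export
setClass("OmegaLUT",
  representation(tauOverT = "numeric", centroid = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@tauOverT) < 256L)
      msg <- c(msg, "LUT needs at least 256 grid points")
    if (length(object@tauOverT) != length(object@centroid))
      msg <- c(msg, "grid and centroid lengths differ")
    if (any(diff(object@centroid) <= 0))
      msg <- c(msg, "centroid values must be strictly increasing")
    if (length(msg)) msg else TRUE
  })

#' Photon-economy curve
#'
#' F-value (photon economy figure of merit,
#' \eqn{F = \sqrt{N_c}\,\sigma_\tau/\tau}) of a lifetime estimator as a
#' function of the normalized lifetime \eqn{\tau/T}.
#'
#' @slot method Estimator name.
#' @slot settings Named list of estimator settings (S, R, M, ...).
#' @slot tauOverT Grid of \eqn{\tau/T} values.
#' @slot fvalue F-values on the grid.
#' @slot minTauOverT Location of the refined minimum.
#' @slot minF Value of the refined minimum.
#' @export
setClass("FValueCurve",
  representation(method = "character", settings = "list",
                 tauOverT = "numeric", fvalue = "numeric",
                 minTauOverT = "numeric", minF = "numeric"))

#' Monte-Carlo simulation specification
#'
#' Bundles a decay model, an acquisition configuration, the photon budget
#' and its law, a replicate count and a seed, so that simulation runs are
#' fully reproducible.
#'
#' @slot model A [DecayModel-class].
#' @slot config An [AcquisitionConfig-class].
#' @slot nPhotons Target total count \eqn{N_c} in the measurement window.
#' @slot law `"fixed"` (exactly `nPhotons` per replicate) or `"poisson"`
#'   (Poisson with mean `nPhotons`).
#' @slot replicates Number of independent replicates.
#' @slot seed Integer RNG seed.
#' @export
setClass("SimSpec",
  representation(model = "DecayModel", config = "AcquisitionConfig",
                 nPhotons = "numeric", law = "character",
                 replicates = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nPhotons < 1) msg <- c(msg, "nPhotons must be >= 1")
    if (!(object@law %in% c("fixed", "poisson")))
      msg <- c(msg, "law must be 'fixed' or 'poisson'")
    if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' @rdname SimSpec-class
#' @param model A [DecayModel-class].
#' @param config An [AcquisitionConfig-class].
#' @param nPhotons Target window count \eqn{N_c}.
#' @param law `"fixed"` or `"poisson"` total-count law.
#' @param replicates Replicate count.
#' @param seed Integer seed.
#' @return A [SimSpec-class].
#' @export
simSpec <- function(model, config, nPhotons, law = c("fixed", "poisson"),
                    replicates = 1L, seed = 1L) {
  law <- match.arg(law)
  new("SimSpec", model = model, config = config,
      nPhotons = as.numeric(nPhotons), law = law,
      replicates = as.integer(replicates), seed = as.integer(seed))
}

#' Labelled synthetic scene for image simulation
#'
#' A 2-D integer label image, one decay model per label, and a per-pixel
#' expected total photon count.
#'
#' @slot labels Integer matrix of region labels (1-based).
#' @slot models List of [DecayModel-class], one per label.
#' @slot expectedCounts Numeric matrix of per-pixel expected total counts.
#' @seealso [defaultPhantom()], [simulateImageStack()]
#' @export
setClass("Phantom",
  representation(labels = "matrix", models = "list",
                 expectedCounts = "matrix"),
  validity = function(object) {
    msg <- character()
    labs <- sort(unique(as.vector(object@labels)))
    if (length(object@models) < max(labs))
      msg <- c(msg, "every label needs a model")
    if (!all(vapply(object@models, is, logical(1), "DecayModel")))
      msg <- c(msg, "models must all be DecayModel objects")
    if (!identical(dim(object@labels), dim(object@expectedCounts)))
      msg <- c(msg, "labels and expectedCounts must share extent")
    if (any(object@expectedCounts <= 0))
      msg <- c(msg, "expected counts must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Per-pixel histogram image stack
#'
#' A 3-D photon count array (rows x cols x time bins) with its bin width;
#' page \eqn{j} holds the counts of time bin \eqn{j}.
#'
#' @slot counts 3-D numeric array of counts.
#' @slot binWidth Bin width \eqn{h} (ns).
#' @export
setClass("HistogramStack",
  representation(counts = "array", binWidth = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@counts)) != 3L)
      msg <- c(msg, "counts must be a 3-D array (rows x cols x bins)")
    if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
    if (!is.finite(object@binWidth) || object@binWidth <= 0)
      msg <- c(msg, "binWidth must be > 0")
    if (length(msg)) msg else TRUE
  })

#' @rdname HistogramStack-class
#' @param counts 3-D count array (rows x cols x bins).
#' @param binWidth Bin width (ns).
#' @return A [HistogramStack-class].
#' @export
histogramStack <- function(counts, binWidth) {
  new("HistogramStack", counts = counts, binWidth = as.numeric(binWidth))
}

#' Lifetime image
#'
#' Per-pixel lifetime map with intensity and validity companions. Invalid
#' pixels carry `NA` in the lifetime map and are excluded from all summary
#' statistics.
#'
#' @slot tau Numeric matrix of estimated lifetimes (ns, `NA` when invalid).
#' @slot intensity Numeric matrix of per-pixel total counts.
#' @slot valid Logical matrix of per-pixel validity.
#' @slot method Estimator name.
#' @slot settings Named list of estimator settings used.
#' @export
setClass("LifetimeImage",
  representation(tau = "matrix", intensity = "matrix", valid = "matrix",
                 method = "character", settings = "list"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@tau), dim(object@intensity)) ||
        !identical(dim(object@tau), dim(object@valid)))
      msg <- c(msg, "tau, intensity and valid must share extent")
    if (any(object@valid & !is.finite(object@tau)))
      msg <- c(msg, "valid pixels must have finite lifetimes")
    if (length(msg)) msg else TRUE
  })
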