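#' Amplitude-weighted mean lifetime of a multi-exponential decay
#'
#' \deqn{\tau_{ave} = \frac{\sum_k A_k \tau_k}{\sum_k A_k}.}
#' This is the customary reference an ideal "average lifetime" readout
#' should approach; the single-exponential estimators applied to
#' bi-exponential data each deviate from it in their own systematic way.
#'
#' @param model A [DecayModel-class] (background ignored).
#' @return Amplitude-weighted mean lifetime (ns).
#' @examples
#' tauAve(decayModel(c(1, 1), c(2, 4)))  # 3
#' @export
tauAve <- function(model) {
  stopifnot(is(model, "DecayModel"))
  sum(model@amplitudes * model@lifetimes) / sum(model@amplitudes)
}

#' Predicted IEM readout on a multi-exponential decay
#'
#' What the Simpson-weighted integral estimator reports when fed the
#' noise-free expected bin counts of a multi-exponential decay over
#' window \eqn{T} with \eqn{M} bins. The exact form applies [fitIEM()]
#' to [expectedBinCounts()]; the large-\eqn{M} approximation is
#' \deqn{\tau_{IEM} \approx \frac{\sum_k A_k\tau_k(1 - x_k^{M-1})}
#'       {\sum_k A_k (1 - x_k^{M-1})}, \qquad x_k = e^{-h/\tau_k},}
#' which tends to [tauAve()] as \eqn{M \to \infty} with \eqn{T} fixed
#' well above the longest lifetime.
#'
#' @param model A [DecayModel-class].
#' @param window Measurement window \eqn{T} (ns).
#' @param bins Bin count \eqn{M} (odd for the exact form).
#' @param exact Logical; exact Simpson form (default) or the
#'   large-\eqn{M} approximation.
#' @return Predicted lifetime readout (ns).
#' @export
tauIEMPred <- function(model, window, bins = 7L, exact = TRUE) {
  stopifnot(is(model, "DecayModel"))
  if (exact) {
    est <- fitIEM(expectedBinCounts(model, binnedConfig(window, bins)))
    return(est@tau)
  }
  h <- window / bins
  xk <- exp(-h / model@lifetimes)
  A <- model@amplitudes
  tk <- model@lifetimes
  sum(A * tk * (1 - xk^(bins - 1))) / sum(A * (1 - xk^(bins - 1)))
}

#' Predicted RLD-2 readout on a multi-exponential decay
#'
#' The two-equal-gate estimator applied to the noise-free half-window
#' integrals:
#' \deqn{\tau_{RLD2} = \frac{0.5\,T}
#'       {\ln\left(\int_0^{T/2} f \,\big/ \int_{T/2}^{T} f\right)}.}
#' Exact for a single exponential; for mixtures the log-ratio convexity
#' pushes the readout above [tauAve()].
#'
#' @param model A [DecayModel-class].
#' @param window Measurement window \eqn{T} (ns).
#' @return Predicted lifetime readout (ns).
#' @export
tauRLD2Pred <- function(model, window) {
  stopifnot(is(model, "DecayModel"))
  n1 <- .expectedInterval(model, 0, window / 2)
  n2 <- .expectedInterval(model, window / 2, window)
  0.5 * window / log(n1 / n2)
}

#' Predicted CMM readout on a multi-exponential decay
#'
#' The centre-of-mass estimator applied to the noise-free first-moment
#' ratio of the window-truncated mixture,
#' \deqn{\frac{E[t]}{T} = \frac{\sum_k A_k\tau_k^2
#'       \left(1 - e^{-T/\tau_k} - (T/\tau_k)e^{-T/\tau_k}\right)}
#'       {T \sum_k A_k\tau_k (1 - e^{-T/\tau_k})},}
#' then calibrated through \eqn{\Omega}. The \eqn{\tau_k^2} moment
#' weighting over-represents the long component, inflating the readout
#' above [tauAve()] for mixtures.
#'
#' @param model A [DecayModel-class].
#' @param window Measurement window \eqn{T} (ns).
#' @param lut An [OmegaLUT-class] (built on demand when `NULL`).
#' @return Predicted lifetime readout (ns); `NA` if the centroid
#'   saturates.
#' @export
tauCMMPred <- function(model, window, lut = NULL) {
  stopifnot(is(model, "DecayModel"))
  A <- model@amplitudes
  tk <- model@lifetimes
  v <- window / tk
  num <- sum(A * tk^2 * (1 - exp(-v) - v * exp(-v)))
  den <- window * sum(A * tk * (1 - exp(-v)))
  u <- omegaCalibrate(num / den, lut)
  u * window
}

#' Predicted generalized-gate readout on a multi-exponential decay
#'
#' Forms the noise-free gate-count ratio of the generalized two-gate
#' geometry for a mixture,
#' \deqn{\frac{N_2}{N_1} = \frac{\sum_k A_k\tau_k (x_k^S - x_k^R)}
#'       {\sum_k A_k\tau_k (1 - x_k)}, \qquad x_k = e^{-h/\tau_k},}
#' solves the single-exponential gate-ratio equation for \eqn{x}, and
#' returns \eqn{-h/\ln x}. The gate width defaults to
#' \eqn{h = T/(S + R)} when a window is given instead.
#'
#' @param model A [DecayModel-class].
#' @param gateStart,gateEnd Gate geometry \eqn{S}, \eqn{R} (with the
#'   GRLD integer constraints).
#' @param binWidth Gate width \eqn{h} (ns); alternatively give `window`.
#' @param window Measurement window \eqn{T} (ns), mapped to
#'   \eqn{h = T/(S+R)}.
#' @return Predicted lifetime readout (ns); `NA` when the ratio leaves
#'   the estimator's range.
#' @export
tauCGRLDPred <- function(model, gateStart = 0.2, gateEnd = 3.2,
                         binWidth = NULL, window = NULL) {
  stopifnot(is(model, "DecayModel"))
  .checkGrldGeometry(gateStart, gateEnd)
  if (is.null(binWidth)) {
    if (is.null(window)) stop("give either binWidth or window")
    binWidth <- window / (gateStart + gateEnd)
  }
  gc <- expectedGateCounts(model,
                           gatedConfig(binWidth, gateStart, gateEnd))
  est <- fitGRLD(gc)
  est@tau
}

#' Average-lifetime curves across amplitude fractions
#'
#' Evaluates the five average-lifetime readouts — the amplitude-weighted
#' mean and the RLD-2, CMM, IEM and generalized-gate predictions — on a
#' fixed bi-exponential lifetime pair as the short-component amplitude
#' fraction \eqn{A_1/(A_1+A_2)} sweeps \eqn{[0, 1]}.
#'
#' @param tau1,tau2 Lifetime pair (ns), \eqn{\tau_1 < \tau_2}.
#' @param window Measurement window \eqn{T} (ns).
#' @param fractions Vector of short-component amplitude fractions.
#' @param binsIEM Bin count for the IEM prediction (odd).
#' @param gateStart,gateEnd Generalized-gate geometry.
#' @param lut An [OmegaLUT-class] (built on demand when `NULL`).
#' @return A data frame with columns `fraction`, `tauAve`, `tauRLD2`,
#'   `tauCMM`, `tauIEM`, `tauCGRLD`.
#' @examples
#' head(biexpCurve(0.33, 3.3, 8, fractions = seq(0.1, 0.9, 0.2)))
#' @export
biexpCurve <- function(tau1, tau2, window,
                       fractions = seq(0, 1, length.out = 101L),
                       binsIEM = 7L, gateStart = 0.2, gateEnd = 3.2,
                       lut = NULL) {
  stopifnot(tau1 > 0, tau2 > 0, window > 0)
  if (is.null(lut)) lut <- buildOmegaLUT()
  rows <- lapply(fractions, function(f) {
    # endpoints handled as single-exponential models
    m <- if (f <= 0) decayModel(1, tau2)
         else if (f >= 1) decayModel(1, tau1)
         else decayModel(c(f, 1 - f), c(tau1, tau2))
    data.frame(fraction = f,
               tauAve = tauAve(m),
               tauRLD2 = tauRLD2Pred(m, window),
               tauCMM = tauCMMPred(m, window, lut),
               tauIEM = tauIEMPred(m, window, binsIEM),
               tauCGRLD = tauCGRLDPred(m, gateStart, gateEnd,
                                       window = window))
  })
  do.call(rbind, rows)
}
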