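#' Expected total count in a measurement window
#'
#' Closed-form mean number of photons collected in \eqn{[0, T)}:
#' \deqn{E[N_c] = \sum_k A_k \tau_k (1 - e^{-T/\tau_k}) + b\,T.}
#'
#' @param model A [DecayModel-class].
#' @param window Measurement window \eqn{T} (ns), \eqn{T > 0}. May be `Inf`
#'   when the background rate is zero.
#' @return Expected count (numeric scalar).
#' @examples
#' expectedTotal(decayModel(1000, 1), 1)   # 1000 * (1 - exp(-1))
#' @export
expectedTotal <- function(model, window) {
  stopifnot(is(model, "DecayModel"), window > 0)
  A <- model@amplitudes
  tauk <- model@lifetimes
  decay <- sum(A * tauk * (1 - exp(-window / tauk)))
  if (model@background > 0) decay + model@background * window else decay
}

# Expected counts of f on arbitrary intervals [lo, hi) (vectorized);
# exact antiderivative, shared by bin, gate and region calculations.
.expectedInterval <- function(model, lo, hi) {
  A <- model@amplitudes
  tauk <- model@lifetimes
  out <- numeric(length(lo))
  for (k in seq_along(A))
    out <- out + A[k] * tauk[k] * (exp(-lo / tauk[k]) - exp(-hi / tauk[k]))
  out + model@background * (hi - lo)
}

#' Expected per-bin counts
#'
#' Integrates the decay model over each of the \eqn{M} half-open bins
#' \eqn{[j h, (j+1) h)}:
#' \deqn{N_j = \sum_k A_k \tau_k\, x_k^j (1 - x_k) + b h, \qquad
#'       x_k = e^{-h/\tau_k}.}
#'
#' @param model A [DecayModel-class].
#' @param config A binned [AcquisitionConfig-class] (slots `bins`,
#'   `binWidth` used).
#' @return A real-valued [DecayHistogram-class] of expected counts.
#' @examples
#' h <- expectedBinCounts(decayModel(1000, 1), binnedConfig(8, 64))
#' sum(counts(h))  # equals expectedTotal(model, 8)
#' @export
expectedBinCounts <- function(model, config) {
  stopifnot(is(model, "DecayModel"), is(config, "AcquisitionConfig"))
  M <- config@bins
  if (is.na(M)) stop("expectedBinCounts requires a binned configuration")
  h <- config@binWidth
  j <- seq_len(M) - 1
  decayHistogram(.expectedInterval(model, j * h, (j + 1) * h), h)
}

#' Expected two-gate counts
#'
#' Expected counts of the generalized two-gate geometry: gate 1 over
#' \eqn{[0, h)}, gate 2 over \eqn{[S h, R h)}, and their overlap
#' \eqn{[S h, h)} (empty when \eqn{S \ge 1}).
#'
#' @param model A [DecayModel-class].
#' @param config A gated [AcquisitionConfig-class].
#' @return A real-valued [GateCounts-class] with the overlap count in
#'   `nOverlap`.
#' @examples
#' expectedGateCounts(decayModel(1000, 1),
#'                    gatedConfig(1, gateStart = 0.2, gateEnd = 3.2))
#' @export
expectedGateCounts <- function(model, config) {
  stopifnot(is(model, "DecayModel"), is(config, "AcquisitionConfig"))
  S <- config@gateStart
  R <- config@gateEnd
  if (is.na(S) || is.na(R))
    stop("expectedGateCounts requires a gated configuration")
  h <- config@binWidth
  n1 <- .expectedInterval(model, 0, h)
  n2 <- .expectedInterval(model, S * h, R * h)
  nov <- if (S < 1) .expectedInterval(model, S * h, h) else 0
  gateCounts(n1, n2, S, R, h,
             correlated = config@scheme != "uncorrelated-gates",
             nOverlap = nov)
}

#' Serialize a decay model and acquisition configuration to flat JSON
#'
#' Writes (or reads) a single flat JSON document with keys `amplitudes`,
#' `lifetimes`, `background`, `T`, `M`, `h`, `S`, `R`, `scheme`, so that
#' simulation inputs can be exchanged with other tools.
#'
#' @param model A [DecayModel-class].
#' @param config An [AcquisitionConfig-class].
#' @param path File path to write to.
#' @return `writeFlimJSON` returns `path` invisibly; `readFlimJSON`
#'   returns `list(model =, config =)`.
#' @examples
#' tf <- tempfile(fileext = ".json")
#' writeFlimJSON(decayModel(1000, 2), binnedConfig(10, 64), tf)
#' readFlimJSON(tf)$model
#' @export
writeFlimJSON <- function(model, config, path) {
  stopifnot(is(model, "DecayModel"), is(config, "AcquisitionConfig"))
  doc <- list(amplitudes = model@amplitudes,
              lifetimes = model@lifetimes,
              background = model@background,
              T = config@window,
              M = config@bins,
              h = config@binWidth,
              S = config@gateStart,
              R = config@gateEnd,
              scheme = config@scheme)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writeFlimJSON
#' @export
readFlimJSON <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- decayModel(doc$amplitudes, doc$lifetimes,
                      if (is.null(doc$background)) 0 else doc$background)
  scheme <- if (is.null(doc$scheme)) "tcspc" else doc$scheme
  config <- if (scheme %in% GATED_SCHEMES) {
    gatedConfig(doc$h, doc$S, doc$R,
                correlated = scheme == "correlated-gates")
  } else {
    binnedConfig(doc$T, doc$M, scheme = scheme)
  }
  list(model = model, config = config)
}
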