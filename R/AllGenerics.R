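#' Accessor generics
#'
#' Small accessor generics for the package's S4 classes: per-bin counts,
#' bin width, bin number, measurement window, gate geometry, estimated
#' lifetime and validity, and the maps of a lifetime image.
#'
#' @param object An object of the matching class.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))
#' @rdname accessors
#' @export
setGeneric("binWidth", function(object) standardGeneric("binWidth"))
#' @rdname accessors
#' @export
setGeneric("nBins", function(object) standardGeneric("nBins"))
#' @rdname accessors
#' @export
setGeneric("measurementWindow",
           function(object) standardGeneric("measurementWindow"))
#' @rdname accessors
#' @export
setGeneric("gateStart", function(object) standardGeneric("gateStart"))
#' @rdname accessors
#' @export
setGeneric("gateEnd", function(object) standardGeneric("gateEnd"))
#' @rdname accessors
#' @export
setGeneric("lifetimes", function(object) standardGeneric("lifetimes"))
#' @rdname accessors
#' @export
setGeneric("amplitudes", function(object) standardGeneric("amplitudes"))
#' @rdname accessors
#' @export
setGeneric("background", function(object) standardGeneric("background"))
#' @rdname accessors
#' @export
setGeneric("tau", function(object) standardGeneric("tau"))
#' @rdname accessors
#' @export
setGeneric("isValid", function(object) standardGeneric("isValid"))
#' @rdname accessors
#' @export
setGeneric("tauMap", function(object) standardGeneric("tauMap"))
#' @rdname accessors
#' @export
setGeneric("intensityMap", function(object) standardGeneric("intensityMap"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))

#' @rdname accessors
setMethod("counts", "DecayHistogram", function(object) object@counts)
#' @rdname accessors
setMethod("counts", "PhotonList", function(object) {
  tabulate(object@codes + 1L, nbins = object@bins)
})
#' @rdname accessors
setMethod("counts", "HistogramStack", function(object) object@counts)

#' @rdname accessors
setMethod("binWidth", "DecayHistogram", function(object) object@binWidth)
#' @rdname accessors
setMethod("binWidth", "PhotonList", function(object) object@binWidth)
#' @rdname accessors
setMethod("binWidth", "AcquisitionConfig", function(object) object@binWidth)
#' @rdname accessors
setMethod("binWidth", "GateCounts", function(object) object@binWidth)
#' @rdname accessors
setMethod("binWidth", "HistogramStack", function(object) object@binWidth)

#' @rdname accessors
setMethod("nBins", "DecayHistogram", function(object) length(object@counts))
#' @rdname accessors
setMethod("nBins", "PhotonList", function(object) object@bins)
#' @rdname accessors
setMethod("nBins", "AcquisitionConfig", function(object) object@bins)
#' @rdname accessors
setMethod("nBins", "HistogramStack", function(object) dim(object@counts)[3L])

#' @rdname accessors
setMethod("measurementWindow", "AcquisitionConfig",
          function(object) object@window)
#' @rdname accessors
setMethod("measurementWindow", "DecayHistogram",
          function(object) length(object@counts) * object@binWidth)
#' @rdname accessors
setMethod("measurementWindow", "PhotonList",
          function(object) object@bins * object@binWidth)
#' @rdname accessors
setMethod("measurementWindow", "GateCounts",
          function(object) object@gateEnd * object@binWidth)
#' @rdname accessors
setMethod("measurementWindow", "HistogramStack",
          function(object) dim(object@counts)[3L] * object@binWidth)

#' @rdname accessors
setMethod("gateStart", "AcquisitionConfig", function(object) object@gateStart)
#' @rdname accessors
setMethod("gateStart", "GateCounts", function(object) object@gateStart)
#' @rdname accessors
setMethod("gateEnd", "AcquisitionConfig", function(object) object@gateEnd)
#' @rdname accessors
setMethod("gateEnd", "GateCounts", function(object) object@gateEnd)

#' @rdname accessors
setMethod("lifetimes", "DecayModel", function(object) object@lifetimes)
#' @rdname accessors
setMethod("amplitudes", "DecayModel", function(object) object@amplitudes)
#' @rdname accessors
setMethod("background", "DecayModel", function(object) object@background)

#' @rdname accessors
setMethod("tau", "LifetimeEstimate", function(object) object@tau)
#' @rdname accessors
setMethod("isValid", "LifetimeEstimate", function(object) object@valid)

#' @rdname accessors
setMethod("tauMap", "LifetimeImage", function(object) object@tau)
#' @rdname accessors
setMethod("intensityMap", "LifetimeImage", function(object) object@intensity)
#' @rdname accessors
setMethod("validMask", "LifetimeImage", function(object) object@valid)

setMethod("show", "DecayModel", function(object) {
  k <- length(object@amplitudes)
  cat(sprintf("DecayModel with %d component%s\n", k, if (k > 1) "s" else ""))
  for (i in seq_len(k))
    cat(sprintf("  A%d = %g photons/ns, tau%d = %g ns\n",
                i, object@amplitudes[i], i, object@lifetimes[i]))
  if (object@background > 0)
    cat(sprintf("  background = %g photons/ns\n", object@background))
  invisible(object)
})

setMethod("show", "AcquisitionConfig", function(object) {
  cat(sprintf("AcquisitionConfig (%s): window T = %g ns, h = %g ns",
              object@scheme, object@window, object@binWidth))
  if (!is.na(object@bins)) cat(sprintf(", M = %d bins", object@bins))
  if (!is.na(object@gateStart))
    cat(sprintf(", gates S = %g, R = %g", object@gateStart, object@gateEnd))
  cat("\n")
  invisible(object)
})

setMethod("show", "DecayHistogram", function(object) {
  cat(sprintf("DecayHistogram: %d bins of %g ns, %g total counts\n",
              length(object@counts), object@binWidth, sum(object@counts)))
  invisible(object)
})

setMethod("show", "PhotonList", function(object) {
  cat(sprintf("PhotonList: %d photons, %d TDC bins of %g ns\n",
              length(object@codes), object@bins, object@binWidth))
  invisible(object)
})

setMethod("show", "GateCounts", function(object) {
  cat(sprintf(
    "GateCounts (%s): N1 = %g, N2 = %g, S = %g, R = %g, h = %g ns\n",
    if (object@correlated) "correlated" else "uncorrelated",
    object@n1, object@n2, object@gateStart, object@gateEnd,
    object@binWidth))
  invisible(object)
})

setMethod("show", "LifetimeEstimate", function(object) {
  if (object@valid)
    cat(sprintf("LifetimeEstimate [%s]: tau = %.6g ns\n",
                object@method, object@tau))
  else
    cat(sprintf("LifetimeEstimate [%s]: invalid (%s)\n", object@method,
                if (is.null(object@diagnostics$reason)) "unspecified"
                else object@diagnostics$reason))
  invisible(object)
})

setMethod("show", "FValueCurve", function(object) {
  st <- paste(names(object@settings),
              vapply(object@settings, format, character(1)),
              sep = " = ", collapse = ", ")
  cat(sprintf("FValueCurve [%s%s]: %d points, min F = %.4g at tau/T = %.4g\n",
              object@method, if (nzchar(st)) paste0("; ", st) else "",
              length(object@tauOverT), object@minF, object@minTauOverT))
  invisible(object)
})

setMethod("show", "Phantom", function(object) {
  cat(sprintf("Phantom: %d x %d pixels, %d labels\n",
              nrow(object@labels), ncol(object@labels),
              length(unique(as.vector(object@labels)))))
  invisible(object)
})

setMethod("show", "HistogramStack", function(object) {
  d <- dim(object@counts)
  cat(sprintf("HistogramStack: %d x %d pixels, %d bins of %g ns\n",
              d[1], d[2], d[3], object@binWidth))
  invisible(object)
})

setMethod("show", "LifetimeImage", function(object) {
  v <- mean(object@valid)
  cat(sprintf(
    "LifetimeImage [%s]: %d x %d pixels, %.1f%% valid, median tau = %.3g ns\n",
    object@method, nrow(object@tau), ncol(object@tau), 100 * v,
    stats::median(object@tau[object@valid])))
  invisible(object)
})
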