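#' Write / read a histogram image stack as multi-page TIFF
#'
#' Pages are time bins stored as 16-bit unsigned integers (exact for
#' per-bin counts below 65536); acquisition metadata (`h_ns`, `M`,
#' `T_ns`, and anything passed through `extra`) goes to a JSON sidecar
#' next to the TIFF (same path with `.json` appended).
#'
#' @param stack A [HistogramStack-class].
#' @param path Output TIFF path.
#' @param extra Named list merged into the sidecar (seed, phantom
#'   description, ...).
#' @return `writeStackTIFF` returns `path` invisibly; `readStackTIFF`
#'   returns a [HistogramStack-class].
#' @export
writeStackTIFF <- function(stack, path, extra = list()) {
  stopifnot(is(stack, "HistogramStack"))
  if (max(stack@counts) > 65535)
    stop("per-bin counts exceed the 16-bit storage range")
  M <- dim(stack@counts)[3]
  pages <- lapply(seq_len(M),
                  function(j) stack@counts[, , j] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  side <- c(list(h_ns = stack@binWidth, M = M,
                 T_ns = M * stack@binWidth), extra)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeStackTIFF
#' @export
readStackTIFF <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("missing JSON sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  stack <- array(0, c(d[1], d[2], length(pages)))
  for (j in seq_along(pages)) stack[, , j] <- pages[[j]]
  if (length(pages) != meta$M)
    stop("page count disagrees with sidecar M")
  histogramStack(stack, meta$h_ns)
}

#' Write a lifetime image to TIFF + sidecar + CSV
#'
#' The lifetime map is stored as a 32-bit float TIFF normalized by a
#' scale recorded in the JSON sidecar (`tau_scale_ns`; stored value x
#' scale = lifetime in ns, invalid pixels stored as 0 and listed in the
#' sidecar's validity count); the intensity map goes to a second page
#' normalized by `intensity_scale`. Estimator provenance (method,
#' settings) is recorded in the sidecar.
#'
#' @param img A [LifetimeImage-class].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
writeLifetimeImage <- function(img, path) {
  stopifnot(is(img, "LifetimeImage"))
  tauScale <- max(img@tau[img@valid], 1e-9)
  intScale <- max(img@intensity, 1)
  tauPage <- img@tau / tauScale
  tauPage[!img@valid] <- 0
  tiff::writeTIFF(list(tauPage, img@intensity / intScale), path,
                  bits.per.sample = 32L, compression = "none")
  side <- list(tau_scale_ns = tauScale, intensity_scale = intScale,
               method = img@method, settings = img@settings,
               n_valid = sum(img@valid), n_pixels = length(img@valid))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Histogram, photon-list and gate-count CSV formats
#'
#' Small plain-text interchange formats: histograms as `bin,count` with
#' the bin width in a comment header; photon lists as `code`; gate
#' counts as `n1,n2,s,r,h,correlated`.
#'
#' @param hist A [DecayHistogram-class].
#' @param path File path.
#' @return Readers return the matching object; writers return `path`
#'   invisibly.
#' @name flimCSV
#' @export
writeHistogramCSV <- function(hist, path) {
  stopifnot(is(hist, "DecayHistogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# h_ns=%.17g", hist@binWidth), con)
  utils::write.csv(data.frame(bin = seq_along(hist@counts) - 1L,
                              count = hist@counts),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname flimCSV
#' @param binWidth Bin width override when the file has no header
#'   comment.
#' @export
readHistogramCSV <- function(path, binWidth = NULL) {
  first <- readLines(path, n = 1L)
  if (grepl("^# h_ns=", first)) {
    if (is.null(binWidth))
      binWidth <- as.numeric(sub("^# h_ns=", "", first))
    df <- utils::read.csv(path, comment.char = "#")
  } else {
    df <- utils::read.csv(path)
  }
  if (is.null(binWidth))
    stop("bin width not found in file header; pass binWidth")
  df <- df[order(df$bin), ]
  decayHistogram(df$count, binWidth)
}

#' @rdname flimCSV
#' @param pl A [PhotonList-class].
#' @export
writePhotonsCSV <- function(pl, path) {
  stopifnot(is(pl, "PhotonList"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# h_ns=%.17g M=%d", pl@binWidth, pl@bins), con)
  utils::write.csv(data.frame(code = pl@codes), con, row.names = FALSE)
  invisible(path)
}

#' @rdname flimCSV
#' @export
readPhotonsCSV <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^# h_ns=", first))
    stop("photon CSV requires the '# h_ns=<h> M=<M>' header")
  h <- as.numeric(sub("^# h_ns=([^ ]+) M=.*$", "\\1", first))
  M <- as.integer(sub("^.* M=", "", first))
  df <- utils::read.csv(path, comment.char = "#")
  photonList(df$code, M, h)
}

#' @rdname flimCSV
#' @param gc A [GateCounts-class].
#' @export
writeGateCountsCSV <- function(gc, path) {
  stopifnot(is(gc, "GateCounts"))
  utils::write.csv(data.frame(n1 = gc@n1, n2 = gc@n2, s = gc@gateStart,
                              r = gc@gateEnd, h = gc@binWidth,
                              correlated = gc@correlated),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname flimCSV
#' @export
readGateCountsCSV <- function(path) {
  df <- utils::read.csv(path)
  gateCounts(df$n1[1], df$n2[1], df$s[1], df$r[1], df$h[1],
             correlated = as.logical(df$correlated[1]))
}

#' Write an F-value curve as CSV
#'
#' Columns `tau_over_T`, `F`.
#'
#' @param curve An [FValueCurve-class].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
writeCurveCSV <- function(curve, path) {
  stopifnot(is(curve, "FValueCurve"))
  utils::write.csv(data.frame(tau_over_T = curve@tauOverT,
                              F = curve@fvalue),
                   path, row.names = FALSE)
  invisible(path)
}
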