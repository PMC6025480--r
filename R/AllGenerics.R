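#' @rdname accessors
#' @export
setGeneric("pdffMap", function(x) standardGeneric("pdffMap"))

#' @rdname accessors
#' @export
setGeneric("fieldMap", function(x) standardGeneric("fieldMap"))

#' @rdname accessors
#' @export
setGeneric("r2sMap", function(x) standardGeneric("r2sMap"))

#' @rdname accessors
#' @export
setGeneric("residualMap", function(x) standardGeneric("residualMap"))

#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname accessors
#' @export
setGeneric("echoTimes", function(x) standardGeneric("echoTimes"))

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname accessors
#' @export
setGeneric("voxelVolumeCm3", function(x) standardGeneric("voxelVolumeCm3"))

#' Accessors for batwfi objects
#'
#' Getter functions for the imaging containers: \code{pdffMap},
#' \code{fieldMap} (psi, Hz), \code{r2sMap} (1/s), \code{residualMap} (RMS
#' fit error), \code{validMask}, \code{echoTimes} (s), \code{voxelSpacing}
#' (mm) and \code{voxelVolumeCm3}.
#'
#' @param x a \code{FitMaps}, \code{EchoSeries}, \code{Protocol} or
#'   \code{GroundTruthMaps} object (as applicable).
#' @return The requested array or numeric value.
#' @name accessors
NULL

setMethod("pdffMap", "FitMaps", function(x) x@pdff)
setMethod("fieldMap", "FitMaps", function(x) x@psi)
setMethod("fieldMap", "GroundTruthMaps", function(x) x@psi)
setMethod("r2sMap", "FitMaps", function(x) {
  if (!length(x@r2s)) stop("no R2* map: fit method '", x@method,
                           "' does not estimate R2*")
  x@r2s
})
setMethod("r2sMap", "GroundTruthMaps", function(x) x@r2s)
setMethod("residualMap", "FitMaps", function(x) x@residual)
setMethod("validMask", "FitMaps", function(x) x@valid)
setMethod("echoTimes", "EchoSeries", function(x) x@teS)
setMethod("echoTimes", "Protocol", function(x) x@teS)
setMethod("voxelSpacing", "EchoSeries", function(x) x@spacingMm)
setMethod("voxelSpacing", "FitMaps", function(x) x@spacingMm)
setMethod("voxelSpacing", "GroundTruthMaps", function(x) x@spacingMm)
setMethod("voxelSpacing", "Protocol", function(x) x@acqVoxelMm)
setMethod("voxelVolumeCm3", "FitMaps", function(x) prod(x@spacingMm) / 1000)
setMethod("voxelVolumeCm3", "EchoSeries", function(x) prod(x@spacingMm) / 1000)
setMethod("voxelVolumeCm3", "Protocol", function(x) prod(x@acqVoxelMm) / 1000)

# show methods ----------------------------------------------------------------

setMethod("show", "FatSpectrum", function(object) {
  cat(sprintf("FatSpectrum: %d peak(s) at %.5g T (gamma %.4g MHz/T)\n",
              length(object@shiftsPpm), object@fieldStrengthT,
              object@gammaMHzT))
  df <- data.frame(shift_ppm = object@shiftsPpm,
                   amplitude = object@amplitudes,
                   freq_Hz = round(peakFrequencies(object), 2))
  print(df, row.names = FALSE)
})

setMethod("show", "GroundTruthMaps", function(object) {
  d <- dim(object@rhoW)
  cat(sprintf("GroundTruthMaps: %d x %d x %d cells at %.3g mm\n",
              d[1], d[2], d[3], object@spacingMm[1]))
  tab <- table(factor(object@labels, levels = 0:length(object@labelNames),
                      labels = c("background", object@labelNames)))
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  cat(sprintf("  max |psi| = %.1f Hz, seed = %d\n",
              max(abs(object@psi)), object@seed))
})

setMethod("show", "EchoSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "EchoSeries '%s' (%s): %d x %d x %d voxels, %d echo(es)\n",
    object@protocolName, object@orientation, d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel %.2f x %.2f x %.2f mm, TE %s ms\n",
              object@spacingMm[1], object@spacingMm[2], object@spacingMm[3],
              paste(format(object@teS * 1000), collapse = ", ")))
})

setMethod("show", "FitMaps", function(object) {
  d <- dim(object@pdff)
  cat(sprintf("FitMaps (%s): %d x %d x %d voxels, %d valid\n",
              object@method, d[1], d[2], d[3], sum(object@valid)))
  if (any(object@valid)) {
    p <- object@pdff[object@valid]
    cat(sprintf("  PDFF range %.1f-%.1f%%, median %.1f%%\n",
                min(p), max(p), stats::median(p)))
  }
})

setMethod("show", "VolumeCurve", function(object) {
  cat(sprintf(
    "VolumeCurve: %d thresholds, total VOI volume %.3f cm^3\n",
    length(object@thresholdsPct), object@totalVolumeCm3))
})

setMethod("show", "Protocol", function(object) {
  cat(sprintf("Protocol '%s': %d echoes, voxel %.2f x %.2f x %.2f mm (%.2f mm^3), snr %s\n",
              object@name, length(object@teS), object@acqVoxelMm[1],
              object@acqVoxelMm[2], object@acqVoxelMm[3],
              prod(object@acqVoxelMm), format(object@snr)))
})
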