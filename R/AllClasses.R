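#' @import methods
NULL

#' Multipeak fat resonance spectrum
#'
#' Represents the fat signal as a weighted sum of spectral resonances.
#' Chemical shifts are stored in ppm relative to water (negative for the
#' dominant methylene peak under the clinical sign convention); relative
#' amplitudes are nonnegative and sum to one.
#'
#' @slot shiftsPpm numeric, chemical shift of each peak relative to water (ppm).
#' @slot amplitudes numeric, relative weight of each peak (sums to 1).
#' @slot fieldStrengthT main field strength in Tesla.
#' @slot gammaMHzT gyromagnetic ratio in MHz/T.
#' @export
setClass("FatSpectrum",
  representation(
    shiftsPpm = "numeric",
    amplitudes = "numeric",
    fieldStrengthT = "numeric",
    gammaMHzT = "numeric"
  )
)

setValidity("FatSpectrum", function(object) {
  msgs <- character()
  if (length(object@shiftsPpm) < 1L)
    msgs <- c(msgs, "at least one peak is required")
  if (length(object@shiftsPpm) != length(object@amplitudes))
    msgs <- c(msgs, "shiftsPpm and amplitudes must have equal length")
  if (!all(is.finite(object@shiftsPpm)))
    msgs <- c(msgs, "peak shifts must be finite")
  if (any(object@amplitudes < 0))
    msgs <- c(msgs, "amplitudes must be nonnegative")
  if (length(object@amplitudes) &&
      abs(sum(object@amplitudes) - 1) > 1e-9)
    msgs <- c(msgs, "amplitudes must sum to 1 (within 1e-9)")
  if (length(object@fieldStrengthT) != 1L || object@fieldStrengthT <= 0)
    msgs <- c(msgs, "fieldStrengthT must be a positive scalar")
  if (length(object@gammaMHzT) != 1L || object@gammaMHzT <= 0)
    msgs <- c(msgs, "gammaMHzT must be a positive scalar")
  if (length(msgs)) msgs else TRUE
})

#' Tissue model for phantom ground truth
#'
#' Per-tissue PDFF and R2* distributions used when assigning ground-truth
#' fields: each fine-grid cell of a tissue draws its PDFF (percent, truncated
#' to [0, 100]) and R2* (1/s, truncated at 0) from independent normals.
#'
#' @slot name tissue name.
#' @slot pdffMeanPct,pdffSdPct PDFF distribution in percent.
#' @slot r2sMeanPerS,r2sSdPerS R2* distribution in 1/s.
#' @slot totalDensity total proton density rho_w + rho_f (arbitrary units).
#' @export
setClass("TissueModel",
  representation(
    name = "character",
    pdffMeanPct = "numeric",
    pdffSdPct = "numeric",
    r2sMeanPerS = "numeric",
    r2sSdPerS = "numeric",
    totalDensity = "numeric"
  )
)

setValidity("TissueModel", function(object) {
  msgs <- character()
  if (object@pdffMeanPct < 0 || object@pdffMeanPct > 100)
    msgs <- c(msgs, "pdffMeanPct must lie in [0, 100]")
  if (object@pdffSdPct < 0 || object@r2sSdPerS < 0)
    msgs <- c(msgs, "standard deviations must be >= 0")
  if (object@r2sMeanPerS < 0)
    msgs <- c(msgs, "r2sMeanPerS must be >= 0")
  if (object@totalDensity <= 0)
    msgs <- c(msgs, "totalDensity must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Cylindrical tube specification
#'
#' Geometry and composition of one sample tube inside the phantom box.
#' The axis is one of the phantom coordinate axes.
#'
#' @slot radiusMm,lengthMm cylinder dimensions in mm.
#' @slot centerMm length-3 center in phantom coordinates (mm).
#' @slot axis axis name: "x", "y" or "z".
#' @slot composition named numeric of tissue volume fractions (sums to 1).
#' @slot clumpScaleMm characteristic mixing length of tissue pieces (mm).
#' @slot analyzedVolumeCm3 target VOI volume in cm^3 (NA = use full tube).
#' @slot packing "clumped" or "layered" realization of the composition.
#' @export
setClass("TubeSpec",
  representation(
    radiusMm = "numeric",
    lengthMm = "numeric",
    centerMm = "numeric",
    axis = "character",
    composition = "numeric",
    clumpScaleMm = "numeric",
    analyzedVolumeCm3 = "numeric",
    packing = "character"
  )
)

setValidity("TubeSpec", function(object) {
  msgs <- character()
  if (object@radiusMm <= 0 || object@lengthMm <= 0)
    msgs <- c(msgs, "radius and length must be positive")
  if (length(object@centerMm) != 3L)
    msgs <- c(msgs, "centerMm must have length 3")
  if (!object@axis %in% c("x", "y", "z"))
    msgs <- c(msgs, "axis must be one of x, y, z")
  if (is.null(names(object@composition)) || any(!nzchar(names(object@composition))))
    msgs <- c(msgs, "composition must be named by tissue")
  if (any(object@composition < 0))
    msgs <- c(msgs, "composition fractions must be nonnegative")
  if (abs(sum(object@composition) - 1) > 1e-9)
    msgs <- c(msgs, "composition fractions must sum to 1 (within 1e-9)")
  if (object@clumpScaleMm <= 0)
    msgs <- c(msgs, "clumpScaleMm must be positive")
  if (!is.na(object@analyzedVolumeCm3)) {
    tubeVol <- pi * object@radiusMm^2 * object@lengthMm / 1000
    if (object@analyzedVolumeCm3 > tubeVol + 1e-9)
      msgs <- c(msgs, "analyzedVolumeCm3 exceeds geometric tube volume")
  }
  if (!object@packing %in% c("clumped", "layered"))
    msgs <- c(msgs, "packing must be 'clumped' or 'layered'")
  if (length(msgs)) msgs else TRUE
})

#' Phantom specification
#'
#' Geometry of the water box and tubes plus the smooth B0 field-map model
#' and the fine ground-truth grid spacing.
#'
#' @slot boxMm outer box dimensions (x, y, z) in mm.
#' @slot fineVoxelMm isotropic ground-truth grid spacing in mm.
#' @slot marginMm margin kept around the tubes when cropping the simulated
#'   region out of the box (mm).
#' @slot tubes list of \code{TubeSpec}.
#' @slot fieldMap list of smooth field-map parameters (see
#'   \code{\link{smoothFieldMap}}).
#' @export
setClass("PhantomSpec",
  representation(
    boxMm = "numeric",
    fineVoxelMm = "numeric",
    marginMm = "numeric",
    tubes = "list",
    fieldMap = "list"
  )
)

setValidity("PhantomSpec", function(object) {
  msgs <- character()
  if (length(object@boxMm) != 3L || any(object@boxMm <= 0))
    msgs <- c(msgs, "boxMm must be 3 positive dimensions")
  if (object@fineVoxelMm <= 0)
    msgs <- c(msgs, "fineVoxelMm must be positive")
  if (!all(vapply(object@tubes, function(t) is(t, "TubeSpec"), logical(1))))
    msgs <- c(msgs, "tubes must be a list of TubeSpec")
  # tubes inside box, pairwise non-overlapping (axis-aligned cylinders)
  for (t in object@tubes) {
    lo <- t@centerMm - tubeHalfExtent(t)
    hi <- t@centerMm + tubeHalfExtent(t)
    if (any(lo < -1e-9) || any(hi > object@boxMm + 1e-9))
      msgs <- c(msgs, sprintf("tube at (%s) extends outside the box",
                              paste(t@centerMm, collapse = ", ")))
  }
  if (length(object@tubes) > 1L) {
    for (i in seq_along(object@tubes)[-1L]) {
      for (j in seq_len(i - 1L)) {
        if (tubesOverlap(object@tubes[[i]], object@tubes[[j]]))
          msgs <- c(msgs, sprintf("tubes %d and %d overlap", j, i))
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Ground-truth phantom maps on the fine grid
#'
#' Per-cell water/fat proton densities, R2*, B0 field offset and tissue
#' labels on the fine isotropic grid. Label 0 is background (Gd-doped water).
#'
#' @slot spacingMm,originMm grid geometry (mm); cell centers are at
#'   \code{origin + (i - 0.5) * spacing}.
#' @slot rhoW,rhoF,r2s,psi numeric 3-D arrays.
#' @slot labels integer 3-D array of tissue codes.
#' @slot labelNames character vector naming codes 1..n (0 = background).
#' @slot seed integer seed used to build the phantom.
#' @export
setClass("GroundTruthMaps",
  representation(
    spacingMm = "numeric",
    originMm = "numeric",
    rhoW = "array",
    rhoF = "array",
    r2s = "array",
    psi = "array",
    labels = "array",
    labelNames = "character",
    seed = "integer"
  )
)

setValidity("GroundTruthMaps", function(object) {
  msgs <- character()
  d <- dim(object@rhoW)
  if (length(d) != 3L)
    msgs <- c(msgs, "maps must be 3-D arrays")
  for (s in c("rhoF", "r2s", "psi", "labels")) {
    if (!identical(dim(slot(object, s)), d))
      msgs <- c(msgs, sprintf("%s dims differ from rhoW", s))
  }
  if (any(object@rhoW < 0) || any(object@rhoF < 0))
    msgs <- c(msgs, "densities must be nonnegative")
  if (any(object@r2s < 0))
    msgs <- c(msgs, "r2s must be nonnegative")
  if (length(object@spacingMm) != 3L || any(object@spacingMm <= 0))
    msgs <- c(msgs, "spacingMm must be 3 positive values")
  if (length(msgs)) msgs else TRUE
})

#' Acquisition protocol
#'
#' Echo train, voxel geometry and noise level of one imaging protocol.
#' TR, flip angle and NSA are carried as metadata only: the signal model has
#' no T1 term (low flip angle), and signal averaging folds into \code{snr}.
#'
#' @slot name protocol identifier.
#' @slot teS echo times in seconds, strictly increasing.
#' @slot acqVoxelMm acquisition voxel (in-plane, in-plane, slab) in mm.
#' @slot reconVoxelMm nominal reconstructed voxel (metadata; analysis runs on
#'   the acquisition grid).
#' @slot trMs,flipDeg,nsa sequence metadata.
#' @slot snr background-water signal magnitude divided by the complex noise
#'   SD per channel; \code{Inf} = noiseless.
#' @export
setClass("Protocol",
  representation(
    name = "character",
    teS = "numeric",
    acqVoxelMm = "numeric",
    reconVoxelMm = "numeric",
    trMs = "numeric",
    flipDeg = "numeric",
    nsa = "numeric",
    snr = "numeric"
  )
)

setValidity("Protocol", function(object) {
  msgs <- character()
  if (length(object@teS) < 1L)
    msgs <- c(msgs, "echo train must be nonempty")
  if (any(object@teS <= 0) || is.unsorted(object@teS, strictly = TRUE))
    msgs <- c(msgs, "echo times must be positive and strictly increasing")
  if (length(object@acqVoxelMm) != 3L || any(object@acqVoxelMm <= 0))
    msgs <- c(msgs, "acqVoxelMm must be 3 positive values")
  if (length(object@reconVoxelMm) == 3L &&
      any(object@acqVoxelMm < object@reconVoxelMm - 1e-9))
    msgs <- c(msgs, "acquisition voxel must be >= reconstructed voxel")
  if (object@snr <= 0)
    msgs <- c(msgs, "snr must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Complex multiecho volume series
#'
#' Complex echo images on an acquisition grid, one volume per echo time.
#' The acquisition axes may be a permutation of the phantom axes (orientation
#' is simulated as an axis permutation); \code{axes[k]} gives the phantom
#' axis imaged along acquisition axis k, with the slab (slice) direction
#' always the third acquisition axis.
#'
#' @slot data complex 4-D array (x, y, z, echo).
#' @slot teS echo times in seconds.
#' @slot spacingMm,originMm acquisition grid geometry (mm).
#' @slot axes integer permutation mapping acquisition to phantom axes.
#' @slot protocolName protocol identifier.
#' @slot orientation "coronal" or "sagittal".
#' @slot seed noise seed used.
#' @export
setClass("EchoSeries",
  representation(
    data = "array",
    teS = "numeric",
    spacingMm = "numeric",
    originMm = "numeric",
    axes = "integer",
    protocolName = "character",
    orientation = "character",
    seed = "integer"
  )
)

setValidity("EchoSeries", function(object) {
  msgs <- character()
  d <- dim(object@data)
  if (length(d) != 4L)
    msgs <- c(msgs, "data must be a 4-D array (x, y, z, echo)")
  if (!is.complex(object@data))
    msgs <- c(msgs, "data must be complex")
  if (length(d) == 4L && d[4L] != length(object@teS))
    msgs <- c(msgs, "4th dim must equal the number of echoes")
  if (!identical(sort(object@axes), 1:3))
    msgs <- c(msgs, "axes must be a permutation of 1:3")
  if (length(msgs)) msgs else TRUE
})

#' Per-voxel water-fat fit results
#'
#' PDFF, field-map and (for the T2*-corrected fit) R2* maps on the
#' acquisition grid, with fitted amplitude magnitudes, RMS residual and a
#' validity mask (all-zero voxels are invalid).
#'
#' @slot pdff,psi,r2s,rhoW,rhoF,residual numeric 3-D arrays (r2s is a
#'   0-length array for the uncorrected fit).
#' @slot valid logical 3-D array.
#' @slot spacingMm,originMm,axes grid geometry as in \code{EchoSeries}.
#' @slot method "quantitative" or "uncorrected".
#' @export
setClass("FitMaps",
  representation(
    pdff = "array",
    psi = "array",
    r2s = "array",
    rhoW = "array",
    rhoF = "array",
    residual = "array",
    valid = "array",
    spacingMm = "numeric",
    originMm = "numeric",
    axes = "integer",
    method = "character"
  )
)

setValidity("FitMaps", function(object) {
  msgs <- character()
  d <- dim(object@pdff)
  if (length(d) != 3L)
    msgs <- c(msgs, "pdff must be a 3-D array")
  p <- object@pdff[object@valid]
  if (length(p) && (min(p) < -1e-9 || max(p) > 100 + 1e-9))
    msgs <- c(msgs, "pdff must lie in [0, 100] on valid voxels")
  if (length(object@r2s) && any(object@r2s[object@valid] < 0))
    msgs <- c(msgs, "r2s must be >= 0")
  if (any(object@residual[object@valid] < 0))
    msgs <- c(msgs, "residual must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Threshold-volume curve
#'
#' Integral tissue volume inside a VOI as a function of the PDFF threshold:
#' \code{volume(t) = #\{valid VOI voxels with PDFF <= t\} * voxel volume}.
#'
#' @slot thresholdsPct threshold grid over [0, 100].
#' @slot volumeCm3 volume at each threshold (cm^3), nondecreasing.
#' @slot totalVolumeCm3 total VOI volume (value at threshold 100).
#' @export
setClass("VolumeCurve",
  representation(
    thresholdsPct = "numeric",
    volumeCm3 = "numeric",
    totalVolumeCm3 = "numeric"
  )
)

setValidity("VolumeCurve", function(object) {
  msgs <- character()
  if (length(object@thresholdsPct) != length(object@volumeCm3))
    msgs <- c(msgs, "thresholds and volumes must have equal length")
  if (is.unsorted(object@thresholdsPct))
    msgs <- c(msgs, "thresholds must be sorted")
  if (any(diff(object@volumeCm3) < -1e-12))
    msgs <- c(msgs, "volume must be nondecreasing in threshold")
  if (any(object@volumeCm3 < 0))
    msgs <- c(msgs, "volumes must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

# internal geometry helpers used by validity ---------------------------------

tubeAxisIndex <- function(tube) match(tube@axis, c("x", "y", "z"))

tubeHalfExtent <- function(tube) {
  h <- rep(tube@radiusMm, 3)
  h[tubeAxisIndex(tube)] <- tube@lengthMm / 2
  h
}

tubesOverlap <- function(a, b) {
  # conservative bounding-box test for axis-aligned cylinders
  loA <- a@centerMm - tubeHalfExtent(a); hiA <- a@centerMm + tubeHalfExtent(a)
  loB <- b@centerMm - tubeHalfExtent(b); hiB <- b@centerMm + tubeHalfExtent(b)
  all(loA < hiB - 1e-9) && all(loB < hiA - 1e-9)
}
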