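#' VOI statistics of a PDFF map
#'
#' Mean, SD (sample convention, n - 1, by default), minimum and maximum of
#' PDFF over the valid voxels of a mask, plus the voxel count and voxel
#' volume.
#'
#' @param pdff numeric 3-D PDFF array (percent).
#' @param mask logical array selecting the VOI.
#' @param valid optional logical array of valid voxels (default all).
#' @param voxelVolumeCm3 voxel volume in cm^3 (for bookkeeping).
#' @param sdType "sample" (n - 1) or "population" (n).
#' @return A list of class \code{VOIStats}: \code{mean}, \code{sd},
#'   \code{min}, \code{max} (percent), \code{n}, \code{voxelVolumeCm3}.
#' @export
voiStats <- function(pdff, mask, valid = NULL, voxelVolumeCm3 = NA_real_,
                     sdType = c("sample", "population")) {
  sdType <- match.arg(sdType)
  if (is.null(valid)) valid <- !is.na(pdff)
  sel <- mask & valid & !is.na(pdff)
  v <- pdff[sel]
  if (!length(v)) stop("empty VOI: no valid voxels under the mask")
  s <- if (length(v) > 1L) stats::sd(v) else 0
  if (sdType == "population" && length(v) > 1L)
    s <- s * sqrt((length(v) - 1) / length(v))
  structure(list(mean = mean(v), sd = s, min = min(v), max = max(v),
                 n = length(v), voxelVolumeCm3 = voxelVolumeCm3),
            class = "VOIStats")
}

#' Restrict a mask to central slices
#'
#' Keeps the n central slices of the mask's occupied extent along the slab
#' (third) axis, with ties toward the lower slice index when parity prevents
#' exact centering. Mirrors the analysis restriction to the central slices
#' showing the fewest artifacts (four slices for the pure-tissue
#' experiments, eight for the mixture experiment); slices near the tube
#' tips are the ones dropped.
#'
#' @param mask logical 3-D array.
#' @param nSlices number of central slices to keep (> 0).
#' @param axis slab axis (default 3).
#' @return The restricted mask.
#' @export
centralSliceMask <- function(mask, nSlices, axis = 3L) {
  d <- dim(mask)
  if (nSlices <= 0) stop("nSlices must be positive")
  occ <- which(apply(mask, axis, any))
  if (!length(occ)) return(mask)
  lo <- occ[1]; nZ <- occ[length(occ)] - lo + 1L
  n <- min(nSlices, nZ)
  start <- lo + floor((nZ - n) / 2)
  keep <- seq.int(start, start + n - 1L)
  out <- mask
  drop <- setdiff(seq_len(d[axis]), keep)
  if (length(drop)) {
    if (axis == 3L) out[, , drop] <- FALSE
    else if (axis == 2L) out[, drop, ] <- FALSE
    else out[drop, , ] <- FALSE
  }
  out
}

#' PDFF histogram over a VOI
#'
#' Counts valid VOI voxels in bins of width \code{binWidthPct} over
#' [0, 100]; bins are left-closed, right-open except the last, which is
#' closed ([lo, 100]). Counts sum to the number of valid masked voxels.
#'
#' @inheritParams voiStats
#' @param binWidthPct bin width in percent; must divide 100.
#' @return A data.frame with \code{lo}, \code{hi}, \code{mid} and
#'   \code{count}.
#' @export
pdffHistogram <- function(pdff, mask, binWidthPct = 1, valid = NULL) {
  if (abs(100 / binWidthPct - round(100 / binWidthPct)) > 1e-9)
    stop("binWidthPct must divide 100")
  if (is.null(valid)) valid <- !is.na(pdff)
  v <- pdff[mask & valid & !is.na(pdff)]
  nb <- as.integer(round(100 / binWidthPct))
  edges <- seq(0, 100, length.out = nb + 1L)
  b <- findInterval(v, edges, rightmost.closed = TRUE, left.open = FALSE)
  b <- pmin(pmax(b, 1L), nb)
  data.frame(lo = edges[-(nb + 1L)], hi = edges[-1L],
             mid = (edges[-(nb + 1L)] + edges[-1L]) / 2,
             count = tabulate(b, nbins = nb))
}

#' Tissue volume below a PDFF threshold
#'
#' The BAT-volume metric: count of valid VOI voxels with PDFF less than or
#' equal to \code{tPct} (inclusive threshold) times the voxel volume.
#'
#' @inheritParams voiStats
#' @param tPct threshold in percent, in [0, 100].
#' @return Volume in cm^3.
#' @export
volUnderThreshold <- function(pdff, mask, tPct, voxelVolumeCm3,
                              valid = NULL) {
  stopifnot(tPct >= 0, tPct <= 100)
  if (is.null(valid)) valid <- !is.na(pdff)
  sel <- mask & valid & !is.na(pdff)
  sum(pdff[sel] <= tPct) * voxelVolumeCm3
}

#' Threshold-volume curve
#'
#' Evaluates \code{\link{volUnderThreshold}} on a grid of thresholds. At a
#' histogram bin edge the curve equals the cumulative histogram count times
#' the voxel volume.
#'
#' @inheritParams volUnderThreshold
#' @param thresholdsPct sorted threshold grid (default 0..100 by 1).
#' @return A \code{\link{VolumeCurve}}.
#' @export
volumeCurve <- function(pdff, mask, voxelVolumeCm3,
                        thresholdsPct = seq(0, 100, by = 1), valid = NULL) {
  stopifnot(!is.unsorted(thresholdsPct))
  if (is.null(valid)) valid <- !is.na(pdff)
  sel <- mask & valid & !is.na(pdff)
  v <- sort(pdff[sel])
  counts <- findInterval(thresholdsPct, v, rightmost.closed = FALSE)
  # findInterval gives #{v <= t} directly since v is sorted
  vol <- counts * voxelVolumeCm3
  new("VolumeCurve", thresholdsPct = as.numeric(thresholdsPct),
      volumeCm3 = vol, totalVolumeCm3 = length(v) * voxelVolumeCm3)
}

#' Aggregate results over acquisitions
#'
#' Combines per-acquisition VOI statistics and threshold-volume curves:
#' mean and SD (sample convention) of the VOI means, and the pointwise
#' mean/min/max envelope of the curves.
#'
#' @param statsList list of \code{VOIStats} (>= 2).
#' @param curveList optional list of \code{\link{VolumeCurve}} on identical
#'   threshold grids.
#' @return A list of class \code{AcquisitionAggregate} with
#'   \code{meanOfMeans}, \code{sdOfMeans}, \code{n}, and (when curves are
#'   given) \code{thresholdsPct}, \code{curveMean}, \code{curveMin},
#'   \code{curveMax} in cm^3.
#' @export
aggregateAcquisitions <- function(statsList, curveList = NULL) {
  stopifnot(length(statsList) >= 2L)
  means <- vapply(statsList, function(s) s$mean, numeric(1))
  out <- list(meanOfMeans = mean(means), sdOfMeans = stats::sd(means),
              n = length(means), means = means)
  if (!is.null(curveList)) {
    thr <- curveList[[1]]@thresholdsPct
    for (cv in curveList)
      if (!isTRUE(all.equal(cv@thresholdsPct, thr)))
        stop("mismatched threshold grids across acquisitions")
    V <- vapply(curveList, function(cv) cv@volumeCm3, numeric(length(thr)))
    out$thresholdsPct <- thr
    out$curveMean <- rowMeans(V)
    out$curveMin <- apply(V, 1, min)
    out$curveMax <- apply(V, 1, max)
  }
  structure(out, class = "AcquisitionAggregate")
}

#' Programmatic tube VOI on an acquisition grid
#'
#' Builds the analysis mask for one tube on the grid of a fitted map or
#' echo series: voxels whose centers lie inside the tube (with a small
#' radial wall margin), restricted to the n central slices along the slab
#' axis, and - when the tube specifies an analyzed volume - truncated to the
#' \code{round(volume / voxel volume)} voxels closest to the tube axis.
#'
#' @param x a \code{\link{FitMaps}} or \code{\link{EchoSeries}} providing
#'   the grid geometry.
#' @param tube a \code{\link{TubeSpec}} in phantom coordinates.
#' @param nCentralSlices number of central slices to keep (NULL = all).
#' @param wallMarginMm radial margin inside the tube wall excluded from the
#'   VOI (default: half the largest in-plane voxel dimension).
#' @return A logical array over the grid.
#' @export
tubeVOI <- function(x, tube, nCentralSlices = NULL, wallMarginMm = NULL) {
  sp <- x@spacingMm; or <- x@originMm; axes <- x@axes
  dims <- if (is(x, "FitMaps")) dim(x@pdff) else dim(x@data)[1:3]
  if (is.null(wallMarginMm)) wallMarginMm <- max(sp[1:2]) / 2
  # voxel centers in phantom coordinates: acquisition axis k images phantom
  # axis axes[k]
  centers <- list(cellCenters(dims[1], sp[1], or[1]),
                  cellCenters(dims[2], sp[2], or[2]),
                  cellCenters(dims[3], sp[3], or[3]))
  phantomCoord <- function(phAxis) {
    k <- match(phAxis, axes)
    arr <- array(0, dims)
    if (k == 1L) arr[] <- centers[[1]]
    else if (k == 2L) arr[] <- rep(centers[[2]], each = dims[1])
    else arr[] <- rep(centers[[3]], each = dims[1] * dims[2])
    arr
  }
  px <- phantomCoord(1L); py <- phantomCoord(2L); pz <- phantomCoord(3L)
  ax <- tubeAxisIndex(tube)
  coords <- list(px, py, pz)
  perp <- setdiff(1:3, ax)
  d2 <- (coords[[perp[1]]] - tube@centerMm[perp[1]])^2 +
    (coords[[perp[2]]] - tube@centerMm[perp[2]])^2
  inTube <- d2 <= (tube@radiusMm - wallMarginMm)^2 &
    abs(coords[[ax]] - tube@centerMm[ax]) <= tube@lengthMm / 2
  if (!is.null(nCentralSlices))
    inTube <- centralSliceMask(inTube, nCentralSlices)
  if (!is.na(tube@analyzedVolumeCm3)) {
    voxVol <- prod(sp) / 1000
    nTarget <- round(tube@analyzedVolumeCm3 / voxVol)
    idx <- which(inTube)
    if (length(idx) > nTarget) {
      ord <- order(d2[idx])
      inTube[] <- FALSE
      inTube[idx[ord[seq_len(nTarget)]]] <- TRUE
    }
  }
  inTube
}
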