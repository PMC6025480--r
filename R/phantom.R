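#' Construct a tissue model
#'
#' @param name tissue name.
#' @param pdffMeanPct,pdffSdPct per-cell PDFF distribution (percent); draws
#'   are truncated to [0, 100].
#' @param r2sMeanPerS,r2sSdPerS per-cell R2* distribution (1/s), truncated
#'   at 0.
#' @param totalDensity total proton density rho_w + rho_f (arbitrary units).
#' @return A \code{\link{TissueModel}}.
#' @export
tissueModel <- function(name, pdffMeanPct, pdffSdPct = 0,
                        r2sMeanPerS = 30, r2sSdPerS = 0, totalDensity = 1) {
  new("TissueModel", name = name, pdffMeanPct = pdffMeanPct,
      pdffSdPct = pdffSdPct, r2sMeanPerS = r2sMeanPerS,
      r2sSdPerS = r2sSdPerS, totalDensity = totalDensity)
}

#' Default tissue models
#'
#' Ground-truth tissue distributions for the tube replicas: brown adipose
#' tissue (BAT, PDFF 23 +/- 6 %), perigonadal white adipose tissue
#' (WAT_peri, 88 +/- 7 %), subcutaneous WAT (WAT_sub, 91 +/- 5 %) and the
#' gadolinium-doped water background (PDFF 0). BAT is assigned a higher R2*
#' than WAT, reflecting its higher intracellular water and mitochondrial
#' iron content.
#'
#' @return Named list of \code{\link{TissueModel}} objects, with the
#'   background model first (named \code{water}).
#' @export
defaultTissueModels <- function() {
  list(
    water = tissueModel("water", 0, 0, r2sMeanPerS = 20, r2sSdPerS = 3),
    BAT = tissueModel("BAT", 23, 6, r2sMeanPerS = 60, r2sSdPerS = 10),
    WAT_peri = tissueModel("WAT_peri", 88, 7, r2sMeanPerS = 35, r2sSdPerS = 8),
    WAT_sub = tissueModel("WAT_sub", 91, 5, r2sMeanPerS = 35, r2sSdPerS = 8)
  )
}

#' Construct a tube specification
#'
#' @param radiusMm,lengthMm cylinder geometry in mm.
#' @param centerMm length-3 center in phantom (box) coordinates, mm.
#' @param axis cylinder axis: "x", "y" or "z".
#' @param composition named numeric vector of tissue volume fractions
#'   (must sum to 1).
#' @param clumpScaleMm characteristic size of tissue pieces (mm).
#' @param analyzedVolumeCm3 target analyzed VOI volume in cm^3 (NA to use the
#'   full tube cross-section).
#' @param packing "clumped" (default) or "layered" realization.
#' @return A \code{\link{TubeSpec}}.
#' @export
tubeSpec <- function(radiusMm, lengthMm, centerMm, axis = "y",
                     composition, clumpScaleMm = 1.5,
                     analyzedVolumeCm3 = NA_real_, packing = "clumped") {
  new("TubeSpec", radiusMm = radiusMm, lengthMm = lengthMm,
      centerMm = as.numeric(centerMm), axis = axis,
      composition = composition, clumpScaleMm = clumpScaleMm,
      analyzedVolumeCm3 = as.numeric(analyzedVolumeCm3), packing = packing)
}

#' Construct a phantom specification
#'
#' @param boxMm outer box dimensions (x, y, z) in mm.
#' @param tubes list of \code{\link{TubeSpec}}.
#' @param fineVoxelMm isotropic ground-truth grid spacing (mm).
#' @param marginMm margin around the tubes kept when cropping the simulated
#'   region out of the box (mm).
#' @param fieldMap list of field-map parameters (see
#'   \code{\link{smoothFieldMap}}).
#' @return A \code{\link{PhantomSpec}}.
#' @export
phantomSpec <- function(boxMm = c(55, 75, 40), tubes, fineVoxelMm = 0.25,
                        marginMm = 5, fieldMap = defaultFieldMapParams()) {
  new("PhantomSpec", boxMm = as.numeric(boxMm), fineVoxelMm = fineVoxelMm,
      marginMm = marginMm, tubes = tubes, fieldMap = fieldMap)
}

#' Default smooth field-map parameters
#'
#' A low-order polynomial plus a long-wavelength sinusoidal ripple, rescaled
#' so the maximum off-resonance magnitude never exceeds \code{maxHz}.
#'
#' @param poly coefficients (constant, x, y, z) in Hz over coordinates
#'   normalized to [-1, 1] across the simulated region.
#' @param rippleHz ripple amplitude in Hz.
#' @param wavelengthMm ripple wavelength in mm.
#' @param maxHz cap on max |psi| (Hz).
#' @return A parameter list.
#' @export
defaultFieldMapParams <- function(poly = c(10, 15, 10, 8), rippleHz = 20,
                                  wavelengthMm = 60, maxHz = 60) {
  list(poly = poly, rippleHz = rippleHz, wavelengthMm = wavelengthMm,
       maxHz = maxHz)
}

#' Phantom specifications replicating the three tube experiments
#'
#' Experiments 1 and 2 hold near-pure BAT and perigonadal WAT in two
#' separate tubes; experiment 3 holds graded mixtures (60/40 BAT/WAT and
#' 40/60) plus a pure subcutaneous-WAT tube, with an analyzed VOI volume of
#' 0.6 cm^3 per tube. The \code{"paper"} profile uses full-size geometry
#' (tube radius 4 mm, length 30 mm, fine grid 0.25 mm inside the
#' 55 x 75 x 40 mm box); the \code{"small"} profile shrinks the tubes and
#' simulated region for fast replicas while keeping all tissue and protocol
#' parameters identical.
#'
#' @param experiment 1, 2 or 3.
#' @param profile "paper" (default) or "small".
#' @return A \code{\link{PhantomSpec}}.
#' @export
experimentPhantomSpec <- function(experiment = 1, profile = c("paper", "small")) {
  profile <- match.arg(profile)
  stopifnot(experiment %in% 1:3)
  if (profile == "paper") {
    r <- 4; len <- 30; yc <- 37.5; zc <- 20
    box <- c(55, 75, 40); margin <- 5
    xs3 <- c(15.5, 27.5, 39.5); xs2 <- c(21.5, 33.5)
    voi3 <- 0.6
  } else {
    r <- 3; len <- 14; yc <- 12; zc <- 9
    box <- c(32, 24, 18); margin <- 3
    xs3 <- c(7, 16, 25); xs2 <- c(10.5, 19.5)
    voi3 <- 0.15
  }
  tubes <- if (experiment %in% c(1, 2)) {
    list(
      tubeSpec(r, len, c(xs2[1], yc, zc), composition = c(BAT = 1)),
      tubeSpec(r, len, c(xs2[2], yc, zc), composition = c(WAT_peri = 1))
    )
  } else {
    list(
      tubeSpec(r, len, c(xs3[1], yc, zc),
               composition = c(BAT = 0.6, WAT_peri = 0.4),
               analyzedVolumeCm3 = voi3),
      tubeSpec(r, len, c(xs3[2], yc, zc),
               composition = c(BAT = 0.4, WAT_peri = 0.6),
               analyzedVolumeCm3 = voi3),
      tubeSpec(r, len, c(xs3[3], yc, zc),
               composition = c(WAT_sub = 1),
               analyzedVolumeCm3 = voi3)
    )
  }
  phantomSpec(boxMm = box, tubes = tubes, fineVoxelMm = 0.25,
              marginMm = margin)
}

# simulated-region grid for a spec: bounding box of tubes +/- margin,
# clipped to the box, snapped to whole fine cells
phantomGrid <- function(spec) {
  lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
  for (t in spec@tubes) {
    lo <- pmin(lo, t@centerMm - tubeHalfExtent(t))
    hi <- pmax(hi, t@centerMm + tubeHalfExtent(t))
  }
  lo <- pmax(lo - spec@marginMm, 0)
  hi <- pmin(hi + spec@marginMm, spec@boxMm)
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / spec@fineVoxelMm - 1e-9)))
  list(dims = dims, originMm = lo, spacingMm = rep(spec@fineVoxelMm, 3))
}

#' Pack a tissue mixture into tube cells
#'
#' Realizes a target composition over the cells of a tube, emulating
#' manually placed pieces of excised tissue. In \code{"clumped"} mode a
#' smooth random field (white noise on a grid at the clump scale,
#' trilinearly interpolated to the cells) is thresholded at the exact
#' quantiles matching the cumulative target fractions, so achieved per-tissue
#' fractions match the target to well within 1 percentage point. In
#' \code{"layered"} mode cells are split into contiguous layers along the
#' tube axis at the same quantile positions.
#'
#' @param coordsMm n x 3 matrix of cell-center coordinates (mm).
#' @param composition named numeric vector of volume fractions (sums to 1).
#' @param clumpScaleMm characteristic mixing length (mm); must be at least
#'   the fine grid spacing.
#' @param seed integer seed.
#' @param fineSpacingMm fine grid spacing (mm), used to validate the clump
#'   scale.
#' @param packing "clumped" or "layered".
#' @param axis tube axis ("x", "y" or "z"), used by layered packing.
#' @return Integer vector of indices into \code{names(composition)}.
#' @export
packMixture <- function(coordsMm, composition, clumpScaleMm, seed,
                        fineSpacingMm = NULL, packing = "clumped",
                        axis = "y") {
  stopifnot(abs(sum(composition) - 1) <= 1e-9, all(composition >= 0))
  n <- nrow(coordsMm)
  if (length(composition) == 1L) return(rep(1L, n))
  if (!is.null(fineSpacingMm) && clumpScaleMm < fineSpacingMm)
    stop("clumpScaleMm must not be smaller than the fine grid spacing")
  field <- if (packing == "layered") {
    coordsMm[, match(axis, c("x", "y", "z"))]
  } else {
    withSeed(seed, clumpField(coordsMm, clumpScaleMm))
  }
  cum <- cumsum(composition)
  cuts <- stats::quantile(field, cum[-length(cum)], names = FALSE, type = 7)
  findInterval(field, cuts, left.open = TRUE) + 1L
}

# smooth random field: white noise on a coarse grid at the clump scale,
# trilinearly interpolated to the cell coordinates
clumpField <- function(coordsMm, scaleMm) {
  lo <- apply(coordsMm, 2, min) - scaleMm
  hi <- apply(coordsMm, 2, max) + scaleMm
  nk <- pmax(2L, as.integer(ceiling((hi - lo) / scaleMm)) + 1L)
  g <- array(stats::rnorm(prod(nk)), dim = nk)
  u <- sweep(sweep(coordsMm, 2, lo), 2, scaleMm, "/")  # grid units, >= 0
  i0 <- pmin(pmax(floor(u[, 1]) + 1L, 1L), nk[1] - 1L)
  j0 <- pmin(pmax(floor(u[, 2]) + 1L, 1L), nk[2] - 1L)
  k0 <- pmin(pmax(floor(u[, 3]) + 1L, 1L), nk[3] - 1L)
  fx <- u[, 1] - (i0 - 1L); fy <- u[, 2] - (j0 - 1L); fz <- u[, 3] - (k0 - 1L)
  idx <- function(i, j, k) i + nk[1] * ((j - 1L) + nk[2] * (k - 1L))
  g[idx(i0, j0, k0)] * (1 - fx) * (1 - fy) * (1 - fz) +
    g[idx(i0 + 1L, j0, k0)] * fx * (1 - fy) * (1 - fz) +
    g[idx(i0, j0 + 1L, k0)] * (1 - fx) * fy * (1 - fz) +
    g[idx(i0 + 1L, j0 + 1L, k0)] * fx * fy * (1 - fz) +
    g[idx(i0, j0, k0 + 1L)] * (1 - fx) * (1 - fy) * fz +
    g[idx(i0 + 1L, j0, k0 + 1L)] * fx * (1 - fy) * fz +
    g[idx(i0, j0 + 1L, k0 + 1L)] * (1 - fx) * fy * fz +
    g[idx(i0 + 1L, j0 + 1L, k0 + 1L)] * fx * fy * fz
}

#' Draw per-cell tissue fields
#'
#' For every cell, draws PDFF from the truncated normal of its tissue model
#' and splits the tissue's total density into fat and water densities
#' (\code{rho_F = density * PDFF/100}, \code{rho_W = density - rho_F}); R2*
#' is drawn truncated-normal at >= 0.
#'
#' @param labels integer vector/array of tissue codes (indices into
#'   \code{tissues}; 0 is allowed and must be mapped by the caller).
#' @param tissues list of \code{\link{TissueModel}} indexed by code.
#' @param seed integer seed.
#' @return List with numeric components \code{rhoW}, \code{rhoF}, \code{r2s}
#'   shaped like \code{labels}.
#' @export
assignTissueFields <- function(labels, tissues, seed) {
  codes <- sort(unique(as.integer(labels)))
  if (any(!codes %in% seq_along(tissues)))
    stop("missing tissue model for label code(s): ",
         paste(setdiff(codes, seq_along(tissues)), collapse = ", "))
  n <- length(labels)
  pdff <- numeric(n); r2s <- numeric(n); dens <- numeric(n)
  withSeed(seed, {
    for (code in codes) {
      tm <- tissues[[code]]
      idx <- which(labels == code)
      pdff[idx] <- rtruncnorm(length(idx), tm@pdffMeanPct, tm@pdffSdPct,
                              0, 100)
      r2s[idx] <- rtruncnorm(length(idx), tm@r2sMeanPerS, tm@r2sSdPerS,
                             0, Inf)
      dens[idx] <- tm@totalDensity
    }
  })
  rhoF <- dens * pdff / 100
  out <- list(rhoW = dens - rhoF, rhoF = rhoF, r2s = r2s)
  if (!is.null(dim(labels)))
    out <- lapply(out, array, dim = dim(labels))
  out
}

#' Smooth B0 field map
#'
#' Low-order polynomial plus a long-wavelength sinusoidal ripple (random
#' phase), rescaled so that \code{max |psi| <= maxHz}.
#'
#' @param dims grid dimensions.
#' @param spacingMm,originMm grid geometry (mm).
#' @param params parameter list from \code{\link{defaultFieldMapParams}}.
#' @param seed integer seed (ripple phases).
#' @return Numeric 3-D array of field offsets in Hz.
#' @export
smoothFieldMap <- function(dims, spacingMm, originMm, params, seed) {
  x <- cellCenters(dims[1], spacingMm[1], originMm[1])
  y <- cellCenters(dims[2], spacingMm[2], originMm[2])
  z <- cellCenters(dims[3], spacingMm[3], originMm[3])
  norm1 <- function(v) if (length(v) > 1L && diff(range(v)) > 0)
    2 * (v - min(v)) / diff(range(v)) - 1 else rep(0, length(v))
  u <- norm1(x); v <- norm1(y); w <- norm1(z)
  p <- params$poly
  psi <- p[1] +
    outer(outer(p[2] * u, p[3] * v, "+"), p[4] * w, "+")
  if (params$rippleHz != 0) {
    ph <- withSeed(seed, stats::runif(2, 0, 2 * pi))
    k <- 2 * pi / params$wavelengthMm
    rip <- params$rippleHz *
      outer(outer(sin(k * x + ph[1]), cos(k * y + ph[2])), rep(1, dims[3]))
    psi <- psi + rip
  }
  m <- max(abs(psi))
  if (m > params$maxHz && m > 0) psi <- psi * (params$maxHz / m)
  array(psi, dim = dims)
}

#' Build a ground-truth phantom
#'
#' Rasterizes the tubes onto the fine grid, packs each tube's composition
#' (\code{\link{packMixture}}), draws per-cell tissue fields
#' (\code{\link{assignTissueFields}}) and adds a smooth field map. Background
#' cells get the water-only background tissue (PDFF 0). Deterministic for a
#' given seed; stage seeds are derived per tube and stage.
#'
#' @param spec a \code{\link{PhantomSpec}}.
#' @param tissues named list of \code{\link{TissueModel}} (must contain
#'   \code{backgroundTissue} and every tissue named in tube compositions).
#' @param seed integer master seed for the phantom stage.
#' @param backgroundTissue name of the background tissue model.
#' @return A \code{\link{GroundTruthMaps}}.
#' @export
buildPhantom <- function(spec, tissues = defaultTissueModels(), seed = 1L,
                         backgroundTissue = "water") {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  g <- phantomGrid(spec)
  dims <- g$dims
  labelNames <- names(tissues)
  if (!backgroundTissue %in% labelNames)
    stop("background tissue '", backgroundTissue, "' not in tissue list")
  x <- cellCenters(dims[1], g$spacingMm[1], g$originMm[1])
  y <- cellCenters(dims[2], g$spacingMm[2], g$originMm[2])
  z <- cellCenters(dims[3], g$spacingMm[3], g$originMm[3])
  labels <- array(0L, dim = dims)
  for (ti in seq_along(spec@tubes)) {
    tube <- spec@tubes[[ti]]
    missing <- setdiff(names(tube@composition), labelNames)
    if (length(missing))
      stop("no tissue model for: ", paste(missing, collapse = ", "))
    inside <- tubeCellIndex(tube, x, y, z)
    coords <- cbind(x[inside$i], y[inside$j], z[inside$k])
    packed <- packMixture(coords, tube@composition, tube@clumpScaleMm,
                          seed = deriveSeed(seed, paste0("pack:", ti)),
                          fineSpacingMm = spec@fineVoxelMm,
                          packing = tube@packing, axis = tube@axis)
    labels[inside$lin] <- match(names(tube@composition), labelNames)[packed]
  }
  # assign fields: background shares the background-tissue code for drawing
  codeMap <- labels
  codeMap[codeMap == 0L] <- match(backgroundTissue, labelNames)
  fields <- assignTissueFields(codeMap, tissues,
                               seed = deriveSeed(seed, "fields"))
  psi <- smoothFieldMap(dims, g$spacingMm, g$originMm, spec@fieldMap,
                        seed = deriveSeed(seed, "fieldmap"))
  new("GroundTruthMaps", spacingMm = g$spacingMm, originMm = g$originMm,
      rhoW = fields$rhoW, rhoF = fields$rhoF, r2s = fields$r2s, psi = psi,
      labels = labels, labelNames = labelNames, seed = as.integer(seed))
}

# linear + per-axis indices of fine cells inside a tube
tubeCellIndex <- function(tube, x, y, z) {
  ax <- tubeAxisIndex(tube)
  cc <- tube@centerMm
  coords <- list(x, y, z)
  perp <- setdiff(1:3, ax)
  inAxis <- abs(coords[[ax]] - cc[ax]) <= tube@lengthMm / 2
  d1 <- coords[[perp[1]]] - cc[perp[1]]
  d2 <- coords[[perp[2]]] - cc[perp[2]]
  dims <- c(length(x), length(y), length(z))
  perpOK <- outer(d1^2, d2^2, "+") <= tube@radiusMm^2
  # expand along the axis dimension in the right orientation
  inside <- if (ax == 1L) {
    array(outer(inAxis, perpOK, "&"), dims)
  } else if (ax == 2L) {
    aperm(outer(inAxis, perpOK, "&"), c(2, 1, 3))
  } else {
    aperm(outer(inAxis, perpOK, "&"), c(2, 3, 1))
  }
  lin <- which(inside)
  ijk <- arrayInd(lin, dims)
  list(lin = lin, i = ijk[, 1], j = ijk[, 2], k = ijk[, 3])
}
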