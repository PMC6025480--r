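#' Imaging protocols
#'
#' \code{quantitativeProtocol}: six-echo 3-D gradient echo
#' (TE = 1.5 + n x 1.3 ms, n = 0..5) at 1.1 x 1.1 x 2.2 mm^3 acquired voxels
#' (2.66 mm^3), TR 14 ms, flip 3 deg, NSA 8 - the T2*-corrected multipeak
#' ("quantitative") low-resolution protocol.
#' \code{highresProtocol}: four sequential single-echo acquisitions
#' (TE = 3.8, 4.8, 5.8, 6.8 ms) at 0.5 x 0.5 x 2.2 mm^3 voxels (0.55 mm^3),
#' TR 10 ms, flip 3 deg, NSA 6 - the uncorrected high-resolution protocol.
#' TR/flip/NSA are metadata: the low flip angle minimizes T1 weighting, and
#' signal averaging is folded into \code{snr}.
#'
#' @param snr background-water signal magnitude over complex noise SD per
#'   channel (default 80; \code{Inf} = noiseless).
#' @return A \code{\link{Protocol}}.
#' @export
quantitativeProtocol <- function(snr = 80) {
  new("Protocol", name = "quantitative_lowres", teS = quantitativeEchoes(),
      acqVoxelMm = c(1.1, 1.1, 2.2), reconVoxelMm = c(0.39, 0.39, 1.1),
      trMs = 14, flipDeg = 3, nsa = 8, snr = snr)
}

#' @rdname quantitativeProtocol
#' @export
highresProtocol <- function(snr = 80) {
  new("Protocol", name = "highres_uncorrected", teS = highresEchoes(),
      acqVoxelMm = c(0.5, 0.5, 2.2), reconVoxelMm = c(0.39, 0.39, 1.1),
      trMs = 10, flipDeg = 3, nsa = 6, snr = snr)
}

orientationPerm <- function(orientation) {
  switch(orientation,
         coronal = c(1L, 2L, 3L),   # slab along phantom z
         sagittal = c(3L, 2L, 1L),  # slab along phantom x
         stop("unknown orientation: ", orientation))
}

#' Forward-simulate one acquisition
#'
#' Synthesizes the complex gradient-echo signal of every fine ground-truth
#' cell at each echo time and box-averages it onto the acquisition grid (the
#' complex mean over the fine cells whose centers fall inside each
#' acquisition voxel - this voxel averaging is the partial-volume mechanism),
#' then adds circular complex Gaussian noise with per-channel SD equal to
#' the background-water signal magnitude divided by \code{protocol@@snr}.
#' Orientation is realized as an axis permutation of the ground truth, with
#' the slab (slice) axis always the third acquisition axis.
#'
#' @param gt a \code{\link{GroundTruthMaps}}.
#' @param protocol a \code{\link{Protocol}}.
#' @param seed integer noise seed.
#' @param orientation "coronal" or "sagittal".
#' @param spectrum fat spectrum used for signal synthesis.
#' @return An \code{\link{EchoSeries}}.
#' @export
acquire <- function(gt, protocol, seed = 1L, orientation = "coronal",
                    spectrum = defaultFatSpectrum()) {
  stopifnot(is(gt, "GroundTruthMaps"), is(protocol, "Protocol"))
  perm <- orientationPerm(orientation)
  if (any(gt@spacingMm[perm] > protocol@acqVoxelMm / 2 + 1e-9))
    stop("ground-truth grid too coarse for this protocol: fine spacing ",
         "must be at most half the acquisition voxel in every dimension")
  rhoW <- aperm(gt@rhoW, perm); rhoF <- aperm(gt@rhoF, perm)
  r2s <- aperm(gt@r2s, perm); psi <- aperm(gt@psi, perm)
  fineSp <- gt@spacingMm[perm]
  fineOr <- gt@originMm[perm]
  dimsF <- dim(rhoW)
  vox <- protocol@acqVoxelMm
  nAcq <- pmax(1L, as.integer(floor(dimsF * fineSp / vox + 1e-9)))
  # bin index of each fine cell along each axis (cells past the last full
  # voxel are dropped)
  binOf <- function(nF, sp, v, nA) {
    b <- floor(cellCenters(nF, sp) / v) + 1L
    b[b > nA] <- NA_integer_
    as.integer(b)
  }
  bx <- binOf(dimsF[1], fineSp[1], vox[1], nAcq[1])
  by <- binOf(dimsF[2], fineSp[2], vox[2], nAcq[2])
  bz <- binOf(dimsF[3], fineSp[3], vox[3], nAcq[3])
  lin <- bx + nAcq[1] * ((rep(by, each = dimsF[1]) - 1L))
  lin <- lin + nAcq[1] * nAcq[2] *
    (rep(bz, each = dimsF[1] * dimsF[2]) - 1L)
  keep <- !is.na(lin)
  lin <- lin[keep]
  counts <- tabulate(lin, nbins = prod(nAcq))
  te <- protocol@teS
  nE <- length(te)
  cte <- fatPhasor(te, spectrum)
  w <- as.vector(rhoW)[keep]; f <- as.vector(rhoF)[keep]
  r <- as.vector(r2s)[keep]; p <- as.vector(psi)[keep]
  out <- array(0i, dim = c(nAcq, nE))
  for (e in seq_len(nE)) {
    s <- (w + f * cte[e]) * exp((2i * pi * p - r) * te[e])
    sums <- rowsum(cbind(Re(s), Im(s)), lin)
    occ <- as.integer(rownames(sums))
    re <- numeric(prod(nAcq)); im <- numeric(prod(nAcq))
    re[occ] <- sums[, 1]; im[occ] <- sums[, 2]
    avg <- complex(real = re, imaginary = im) / pmax(counts, 1L)
    out[, , , e] <- avg
  }
  if (is.finite(protocol@snr)) {
    sdN <- backgroundSignal(gt) / protocol@snr
    nz <- prod(nAcq) * nE
    noise <- withSeed(seed, complex(real = stats::rnorm(nz, 0, sdN),
                                    imaginary = stats::rnorm(nz, 0, sdN)))
    out <- out + array(noise, dim = c(nAcq, nE))
  }
  new("EchoSeries", data = out, teS = te, spacingMm = vox,
      originMm = fineOr, axes = perm, protocolName = protocol@name,
      orientation = orientation, seed = as.integer(seed))
}

# TE -> 0 signal magnitude of the background compartment (noise reference)
backgroundSignal <- function(gt) {
  bg <- gt@labels == 0L
  if (!any(bg)) bg <- rep(TRUE, length(gt@labels))
  mean(gt@rhoW[bg] + gt@rhoF[bg])
}

#' Simulate the full four-acquisition set
#'
#' Runs both protocols in both orthogonal orientations (coronal and
#' sagittal), with independent noise seeds derived deterministically from
#' the master seed.
#'
#' @param gt a \code{\link{GroundTruthMaps}}.
#' @param protocols list of \code{\link{Protocol}} objects (default: the
#'   quantitative and high-resolution protocols).
#' @param seed integer master seed.
#' @param spectrum fat spectrum used for signal synthesis.
#' @return Named list of four \code{\link{EchoSeries}} (name =
#'   "protocol.orientation").
#' @export
buildAcquisitionSet <- function(gt, protocols = list(quantitativeProtocol(),
                                                     highresProtocol()),
                                seed = 1L, spectrum = defaultFatSpectrum()) {
  out <- list()
  for (pr in protocols) {
    for (ori in c("coronal", "sagittal")) {
      key <- paste0("acq:", pr@name, ":", ori)
      out[[paste(pr@name, ori, sep = ".")]] <-
        acquire(gt, pr, seed = deriveSeed(seed, key), orientation = ori,
                spectrum = spectrum)
    }
  }
  out
}
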