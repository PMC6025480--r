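# shared fixtures and independent oracles for the test suite

# wrap an nEcho x nVoxel complex signal matrix into an EchoSeries laid out
# along the x axis
seriesFromSignals <- function(S, te, spacingMm = c(1, 1, 1)) {
  S <- as.matrix(S)
  n <- ncol(S)
  new("EchoSeries", data = array(t(S), c(n, 1, 1, nrow(S))), teS = te,
      spacingMm = spacingMm, originMm = c(0, 0, 0), axes = 1:3,
      protocolName = "test", orientation = "coronal", seed = 1L)
}

# hand-built uniform ground truth for acquisition tests
uniformGroundTruth <- function(dims, spacing, pdffPct = 0, r2s = 0,
                               psi = 0, density = 1, label = 0L) {
  rhoF <- array(density * pdffPct / 100, dims)
  new("GroundTruthMaps", spacingMm = rep(spacing, 3),
      originMm = c(0, 0, 0), rhoW = array(density, dims) - rhoF,
      rhoF = rhoF, r2s = array(r2s, dims), psi = array(psi, dims),
      labels = array(as.integer(label), dims),
      labelNames = c("water", "BAT", "WAT_peri", "WAT_sub"), seed = 1L)
}

# independent brute-force water-fat objective: dense grid search solving the
# 2x2 normal equations at every (psi, r2s) candidate; returns the minimal
# residual energy per voxel. Deliberately a different code path from the
# package's Gram-Schmidt projection.
bruteForceObjective <- function(S, te, spectrum, psiGrid, r2sGrid) {
  df <- peakFrequencies(spectrum)
  cn <- drop(exp(outer(te, df, function(t, f) 2i * pi * f * t)) %*%
               spectrum@amplitudes)
  N <- ncol(S)
  tot <- colSums(Mod(S)^2)
  best <- rep(Inf, N)
  for (r in r2sGrid) {
    d <- exp(-r * te)
    for (p in psiGrid) {
      b1 <- d * exp(2i * pi * p * te)
      b2 <- cn * b1
      a11 <- sum(Mod(b1)^2); a22 <- sum(Mod(b2)^2)
      a12 <- sum(Conj(b1) * b2)
      det <- a11 * a22 - Mod(a12)^2
      y1 <- Conj(b1) %*% S   # 1 x N
      y2 <- Conj(b2) %*% S
      if (Mod(det) < 1e-14 * a11 * a22) {
        # rank-deficient basis: project onto b1 alone
        proj <- Mod(y1[1, ])^2 / a11
      } else {
        x1 <- (a22 * y1 - a12 * y2) / det
        x2 <- (a11 * y2 - Conj(a12) * y1) / det
        proj <- Re(Conj(x1[1, ]) * y1[1, ] + Conj(x2[1, ]) * y2[1, ])
      }
      resid <- tot - proj
      best <- pmin(best, resid)
    }
  }
  pmax(best, 0)
}

# independent geometric tube mask on the fine grid of a GroundTruthMaps
tubeMaskOracle <- function(gt, tube) {
  d <- dim(gt@labels)
  cc <- function(k) gt@originMm[k] + (seq_len(d[k]) - 0.5) * gt@spacingMm[k]
  x <- array(cc(1), d)
  y <- array(rep(cc(2), each = d[1]), d)
  z <- array(rep(cc(3), each = d[1] * d[2]), d)
  coords <- list(x, y, z)
  ax <- match(tube@axis, c("x", "y", "z"))
  perp <- setdiff(1:3, ax)
  d2 <- (coords[[perp[1]]] - tube@centerMm[perp[1]])^2 +
    (coords[[perp[2]]] - tube@centerMm[perp[2]])^2
  d2 <= tube@radiusMm^2 &
    abs(coords[[ax]] - tube@centerMm[ax]) <= tube@lengthMm / 2
}

# memoised small experiment runs shared within a test file
.runCache <- new.env(parent = emptyenv())
runSmallExperiment <- function(experiment, seed, protocols = "both") {
  key <- paste(experiment, seed, protocols, sep = "_")
  if (is.null(.runCache[[key]])) {
    cfg <- experimentConfig(experiment, seed = seed, profile = "small",
                            protocols = protocols)
    .runCache[[key]] <- runExperiment(cfg)
  }
  .runCache[[key]]
}
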