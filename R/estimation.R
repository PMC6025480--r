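#' Fit options for the water-fat estimators
#'
#' Controls the variable-projection search: the coarse field-map grid, the
#' R2* grid/bounds (quantitative fit only), local refinement and the fit
#' mode.
#'
#' @param psiSearchHz c(min, max, step) of the coarse field-map grid in Hz.
#' @param r2sBoundsPerS c(min, max, step) of the coarse R2* grid in 1/s.
#' @param refine logical: run bounded local refinement from the best coarse
#'   candidate.
#' @param convergenceTol relative tolerance on the objective decrease at
#'   which the local refinement stops (default: machine-precision level).
#' @param maxIterations iteration cap for the local refinement.
#' @param fitMode "complex" (default) or "magnitude".
#' @return A list of class \code{fitOptions}.
#' @export
fitOptions <- function(psiSearchHz = c(-200, 200, 2),
                       r2sBoundsPerS = c(0, 250, 5),
                       refine = TRUE, convergenceTol = 2e-15,
                       maxIterations = 200L,
                       fitMode = c("complex", "magnitude")) {
  stopifnot(psiSearchHz[1] < psiSearchHz[2], psiSearchHz[3] > 0,
            r2sBoundsPerS[1] <= r2sBoundsPerS[2], r2sBoundsPerS[3] > 0)
  structure(list(psiSearchHz = psiSearchHz, r2sBoundsPerS = r2sBoundsPerS,
                 refine = refine, convergenceTol = convergenceTol,
                 maxIterations = as.integer(maxIterations),
                 fitMode = match.arg(fitMode)),
            class = "fitOptions")
}

# orthonormal basis of span{b1, b2} by Gram-Schmidt; returns 2 x nE matrix
# of conjugated rows (so proj energy = |Q %*% s|^2), handling rank 1
gsBasisH <- function(b1, b2) {
  n1 <- sqrt(sum(Mod(b1)^2))
  q1 <- b1 / n1
  v <- b2 - q1 * sum(Conj(q1) * b2)
  n2 <- sqrt(sum(Mod(v)^2))
  if (n2 < 1e-12 * sqrt(sum(Mod(b2)^2))) {
    rbind(Conj(q1), rep(0i, length(b1)))
  } else {
    rbind(Conj(q1), Conj(v / n2))
  }
}

# residual energy of one voxel at (psi, r2s) given demodulated-by-nothing
# signal s; cn is the fat phasor. Returns list(obj, rhoW, rhoF).
varproVoxel <- function(s, te, cn, psi, r2s, solve = FALSE) {
  ph <- exp(2i * pi * psi * te)
  d <- exp(-r2s * te)
  b1 <- d * ph
  b2 <- cn * b1
  Qh <- gsBasisH(b1, b2)
  proj <- Qh %*% s
  obj <- sum(Mod(s)^2) - sum(Mod(proj)^2)
  if (!solve) return(list(obj = max(obj, 0)))
  A <- cbind(b1, b2)
  co <- tryCatch(qr.coef(qr(A), s), error = function(e) c(0i, 0i))
  co[is.na(co)] <- 0i
  list(obj = max(obj, 0), rhoW = co[1], rhoF = co[2])
}

# vectorized coarse grid search over (psi, r2s) for an nE x N signal matrix;
# returns best candidate indices and objectives per voxel
coarseSearch <- function(S, te, cn, psiGrid, r2sGrid) {
  nE <- nrow(S); N <- ncol(S)
  R <- length(r2sGrid)
  Qh <- matrix(0i, 2L * R, nE)
  for (ri in seq_len(R)) {
    d <- exp(-r2sGrid[ri] * te)
    Qh[(2L * ri - 1L):(2L * ri), ] <- gsBasisH(d, cn * d)
  }
  tot <- colSums(Mod(S)^2)
  bestE <- rep(-Inf, N)
  bestPsi <- rep(1L, N); bestR <- rep(1L, N)
  oddRows <- seq(1L, 2L * R, by = 2L)
  for (gi in seq_along(psiGrid)) {
    dem <- exp(-2i * pi * psiGrid[gi] * te)
    Tm <- Qh %*% (dem * S)                     # 2R x N
    E2 <- Mod(Tm)^2
    E <- E2[oddRows, , drop = FALSE] + E2[oddRows + 1L, , drop = FALSE]
    mr <- max.col(t(E), ties.method = "first")
    mv <- E[cbind(mr, seq_len(N))]
    upd <- mv > bestE
    if (any(upd)) {
      bestE[upd] <- mv[upd]
      bestPsi[upd] <- gi
      bestR[upd] <- mr[upd]
    }
  }
  list(psiIdx = bestPsi, r2sIdx = bestR, obj = pmax(tot - bestE, 0))
}

# full per-voxel fit driver shared by both estimators
fitVoxelMatrix <- function(S, te, spectrum, opts, estimateR2s) {
  nE <- nrow(S); N <- ncol(S)
  cn <- fatPhasor(te, spectrum)
  psiGrid <- seq(opts$psiSearchHz[1], opts$psiSearchHz[2],
                 by = opts$psiSearchHz[3])
  r2sGrid <- if (estimateR2s)
    seq(opts$r2sBoundsPerS[1], opts$r2sBoundsPerS[2],
        by = opts$r2sBoundsPerS[3]) else 0
  valid <- colSums(Mod(S)) > 0
  psi <- numeric(N); r2s <- numeric(N)
  rhoW <- complex(N); rhoF <- complex(N); obj <- numeric(N)
  converged <- rep(TRUE, N)
  if (any(valid)) {
    Sv <- S[, valid, drop = FALSE]
    cs <- coarseSearch(Sv, te, cn, psiGrid, r2sGrid)
    psiV <- psiGrid[cs$psiIdx]; r2sV <- r2sGrid[cs$r2sIdx]
    objV <- cs$obj
    convV <- rep(TRUE, length(psiV))
    if (opts$refine) {
      psiLim <- opts$psiSearchHz[1:2]
      r2sLim <- opts$r2sBoundsPerS[1:2]
      for (vi in seq_len(ncol(Sv))) {
        s <- Sv[, vi]
        # recompute the coarse objective on the refinement path so the
        # accept test is not confounded by accumulation-order rounding
        objV[vi] <- varproVoxel(s, te, cn, psiV[vi], r2sV[vi])$obj
        if (estimateR2s) {
          fn <- function(par) varproVoxel(s, te, cn, par[1], par[2])$obj
          res <- tryCatch(
            stats::optim(c(psiV[vi], r2sV[vi]), fn, method = "L-BFGS-B",
                         lower = c(psiLim[1], r2sLim[1]),
                         upper = c(psiLim[2], r2sLim[2]),
                         control = list(
                           factr = opts$convergenceTol /
                             .Machine$double.eps,
                           maxit = opts$maxIterations)),
            error = function(e) NULL)
        } else {
          half <- opts$psiSearchHz[3]
          o <- stats::optimize(function(p) varproVoxel(s, te, cn, p, 0)$obj,
                               lower = max(psiLim[1], psiV[vi] - half),
                               upper = min(psiLim[2], psiV[vi] + half),
                               tol = 1e-7)
          res <- list(par = c(o$minimum, 0), value = o$objective,
                      convergence = 0L)
        }
        if (is.null(res)) {
          # optimizer failure: keep the coarse-grid optimum, flag the voxel
          convV[vi] <- FALSE
        } else {
          improved <- res$value <= objV[vi]
          if (improved) {
            psiV[vi] <- res$par[1]; r2sV[vi] <- res$par[2]
            objV[vi] <- res$value
          }
          # an "abnormal termination" at the coarse optimum (line search
          # stuck at machine precision) is convergence, not failure
          convV[vi] <- improved || is.null(res$convergence) ||
            res$convergence == 0L
        }
      }
    }
    # solve amplitudes at the selected (psi, r2s)
    for (vi in seq_len(ncol(Sv))) {
      sol <- varproVoxel(Sv[, vi], te, cn, psiV[vi], r2sV[vi], solve = TRUE)
      idx <- which(valid)[vi]
      rhoW[idx] <- sol$rhoW; rhoF[idx] <- sol$rhoF
    }
    psi[valid] <- psiV; r2s[valid] <- r2sV; obj[valid] <- objV
    converged[valid] <- convV
  }
  list(psi = psi, r2s = r2s, rhoW = rhoW, rhoF = rhoF, obj = obj,
       valid = valid, converged = converged)
}

# magnitude-mode fit: |s| against |rho_w + rho_f c(te)| e^{-r2s te}; the
# field map drops out of magnitudes, so psi is reported as 0
magnitudeFitMatrix <- function(S, te, spectrum, opts, estimateR2s) {
  cn <- fatPhasor(te, spectrum)
  N <- ncol(S)
  valid <- colSums(Mod(S)) > 0
  psi <- numeric(N); r2s <- numeric(N)
  rhoW <- complex(N); rhoF <- complex(N); obj <- numeric(N)
  shape <- function(ff, r) Mod((1 - ff) + ff * cn) * exp(-r * te)
  for (idx in which(valid)) {
    m <- Mod(S[, idx])
    fn <- function(par) {
      g <- shape(par[1], if (estimateR2s) par[2] else 0)
      a <- sum(m * g) / sum(g^2)
      sum((m - a * g)^2)
    }
    start <- c(0.5, if (estimateR2s) 50 else NULL)
    lower <- c(0, if (estimateR2s) opts$r2sBoundsPerS[1] else NULL)
    upper <- c(1, if (estimateR2s) opts$r2sBoundsPerS[2] else NULL)
    res <- stats::optim(start, fn, method = "L-BFGS-B", lower = lower,
                        upper = upper, control = list(factr = 100))
    g <- shape(res$par[1], if (estimateR2s) res$par[2] else 0)
    a <- sum(m * g) / sum(g^2)
    rhoF[idx] <- a * res$par[1]; rhoW[idx] <- a * (1 - res$par[1])
    r2s[idx] <- if (estimateR2s) res$par[2] else 0
    obj[idx] <- res$value
  }
  list(psi = psi, r2s = r2s, rhoW = rhoW, rhoF = rhoF, obj = obj,
       valid = valid, converged = valid)
}

assembleFitMaps <- function(fit, dims, nE, series, method, estimateR2s) {
  arr <- function(v) array(v, dim = dims)
  pdff <- pdffPercent(fit$rhoW, fit$rhoF)
  pdff[!fit$valid] <- NA_real_
  # a fitted voxel with both amplitudes exactly zero has no defined PDFF
  fit$valid <- fit$valid & !is.na(pdff)
  pdff[!fit$valid] <- 0
  new("FitMaps",
      pdff = arr(pdff), psi = arr(fit$psi),
      r2s = if (estimateR2s) arr(fit$r2s) else array(numeric(0)),
      rhoW = arr(Mod(fit$rhoW)), rhoF = arr(Mod(fit$rhoF)),
      residual = arr(sqrt(fit$obj / nE)),
      valid = arr(fit$valid & fit$converged),
      spacingMm = series@spacingMm, originMm = series@originMm,
      axes = series@axes, method = method)
}

#' T2*-corrected multipeak water-fat fit
#'
#' Inverts the six-echo signal model per voxel by variable projection: for
#' each (psi, R2*) candidate on a coarse grid the complex water/fat
#' amplitudes are the solution of a linear least-squares subproblem, and the
#' best candidate seeds a bounded local refinement of
#' \eqn{\sum_n |s_n - model(TE_n)|^2}. PDFF is computed from the fitted
#' amplitude magnitudes and clamped to [0, 100]. All-zero voxels are masked
#' invalid; voxels whose refinement fails keep the coarse-grid optimum and
#' are flagged in the valid mask.
#'
#' @param series an \code{\link{EchoSeries}} with at least 6 echoes.
#' @param spectrum fat spectrum assumed by the fit (default: the six-peak
#'   model).
#' @param opts a \code{\link{fitOptions}} list.
#' @param mask optional logical array restricting which voxels are fitted
#'   (others are marked invalid); used to confine expensive fits to a VOI.
#' @return A \code{\link{FitMaps}} with PDFF, field-map, R2*, amplitude and
#'   residual maps.
#' @export
fitQuantitative <- function(series, spectrum = defaultFatSpectrum(),
                            opts = fitOptions(), mask = NULL) {
  stopifnot(is(series, "EchoSeries"))
  if (length(series@teS) < 6L)
    stop("the quantitative fit requires at least 6 echoes for full ",
         "(rho_w, rho_f, psi, R2*) identifiability")
  fitSeries(series, spectrum, opts, mask, estimateR2s = TRUE,
            method = "quantitative")
}

#' Uncorrected single-peak water-fat fit
#'
#' The fat-fraction estimator applied to the high-resolution series: same
#' variable-projection machinery but with R2* fixed at 0 and a single fat
#' resonance at -3.40 ppm. With signals generated by the full model
#' (multipeak fat, nonzero R2*), this estimator is biased - T2* decay tends
#' to reduce the apparent fat fraction at high fat content.
#'
#' @param series an \code{\link{EchoSeries}} with at least 3 echoes.
#' @param spectrum fat model assumed by the fit (default single peak).
#' @inheritParams fitQuantitative
#' @return A \code{\link{FitMaps}} without an R2* map.
#' @export
fitUncorrected <- function(series, spectrum = singlePeakSpectrum(),
                           opts = fitOptions(), mask = NULL) {
  stopifnot(is(series, "EchoSeries"))
  if (length(series@teS) < 3L)
    stop("the uncorrected fit requires at least 3 echoes")
  fitSeries(series, spectrum, opts, mask, estimateR2s = FALSE,
            method = "uncorrected")
}

fitSeries <- function(series, spectrum, opts, mask, estimateR2s, method) {
  dims <- dim(series@data)[1:3]
  nE <- dim(series@data)[4]
  S <- matrix(series@data, nrow = prod(dims), ncol = nE)
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dims))
    S[!as.vector(mask), ] <- 0i
  }
  S <- t(S)
  fit <- if (opts$fitMode == "magnitude")
    magnitudeFitMatrix(S, series@teS, spectrum, opts, estimateR2s)
  else
    fitVoxelMatrix(S, series@teS, spectrum, opts, estimateR2s)
  assembleFitMaps(fit, dims, nE, series, method, estimateR2s)
}

#' Resolve water-fat swaps
#'
#' For each valid voxel, evaluates the swapped solution branch (field map
#' shifted by +/- the dominant fat frequency, amplitudes re-solved, which
#' exchanges the water and fat roles) and keeps whichever branch has the
#' lower residual. Near-ties are broken toward the branch whose field-map
#' value is closer to the median field map of the 3 x 3 x 3 neighborhood.
#'
#' @param fitmaps a \code{\link{FitMaps}}.
#' @param series the \code{\link{EchoSeries}} the maps were fitted from.
#' @param spectrum the fat spectrum used in the fit.
#' @param tieTol relative residual difference below which the neighborhood
#'   vote decides.
#' @return A list with the corrected \code{maps} (\code{FitMaps}) and
#'   \code{nSwapped}, the number of voxels changed.
#' @export
swapCheck <- function(fitmaps, series, spectrum = defaultFatSpectrum(),
                      tieTol = 1e-6) {
  stopifnot(is(fitmaps, "FitMaps"), is(series, "EchoSeries"))
  dims <- dim(fitmaps@pdff)
  te <- series@teS
  cn <- fatPhasor(te, spectrum)
  dfDom <- peakFrequencies(spectrum)[which.max(spectrum@amplitudes)]
  estimateR2s <- length(fitmaps@r2s) > 0
  nE <- length(te)
  pdff <- fitmaps@pdff; psi <- fitmaps@psi; resid <- fitmaps@residual
  rhoW <- fitmaps@rhoW; rhoF <- fitmaps@rhoF
  valid <- fitmaps@valid
  nSwapped <- 0L
  idxAll <- which(valid)
  for (lin in idxAll) {
    ijk <- arrayInd(lin, dims)
    s <- series@data[ijk[1], ijk[2], ijk[3], ]
    r2sHere <- if (estimateR2s) fitmaps@r2s[lin] else 0
    cur <- varproVoxel(s, te, cn, psi[lin], r2sHere, solve = TRUE)
    cands <- psi[lin] + c(dfDom, -dfDom)
    alt <- lapply(cands, function(p)
      c(list(psi = p), varproVoxel(s, te, cn, p, r2sHere, solve = TRUE)))
    altBest <- alt[[which.min(vapply(alt, `[[`, numeric(1), "obj"))]]
    scale2 <- sum(Mod(s)^2)
    relDiff <- (cur$obj - altBest$obj) / max(scale2, 1e-30)
    takeAlt <- relDiff > tieTol
    if (abs(relDiff) <= tieTol) {
      medPsi <- neighborhoodMedianPsi(fitmaps@psi, valid, ijk, dims)
      if (!is.na(medPsi))
        takeAlt <- abs(altBest$psi - medPsi) < abs(psi[lin] - medPsi)
    }
    if (takeAlt) {
      psi[lin] <- altBest$psi
      rhoW[lin] <- Mod(altBest$rhoW); rhoF[lin] <- Mod(altBest$rhoF)
      p <- pdffPercent(altBest$rhoW, altBest$rhoF)
      pdff[lin] <- if (is.na(p)) 0 else p
      resid[lin] <- sqrt(altBest$obj / nE)
      nSwapped <- nSwapped + 1L
    }
  }
  out <- fitmaps
  out@pdff <- pdff; out@psi <- psi; out@residual <- resid
  out@rhoW <- rhoW; out@rhoF <- rhoF
  list(maps = out, nSwapped = nSwapped)
}

neighborhoodMedianPsi <- function(psiArr, valid, ijk, dims) {
  rng <- function(c, n) max(1L, c - 1L):min(n, c + 1L)
  block <- psiArr[rng(ijk[1], dims[1]), rng(ijk[2], dims[2]),
                  rng(ijk[3], dims[3])]
  vb <- valid[rng(ijk[1], dims[1]), rng(ijk[2], dims[2]),
              rng(ijk[3], dims[3])]
  vals <- block[vb]
  if (!length(vals)) return(NA_real_)
  stats::median(vals)
}
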