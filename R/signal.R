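#' Echo trains of the two imaging protocols
#'
#' \code{quantitativeEchoes} returns the six-echo train TE = 1.5 + n * 1.3 ms
#' (n = 0..5) of the T2*-corrected protocol; \code{highresEchoes} returns the
#' four single-echo times TE = 3.8, 4.8, 5.8, 6.8 ms of the high-resolution
#' protocol. Values are in seconds.
#'
#' @return Numeric vector of echo times in seconds.
#' @export
quantitativeEchoes <- function() (1.5 + (0:5) * 1.3) / 1000

#' @rdname quantitativeEchoes
#' @export
highresEchoes <- function() c(3.8, 4.8, 5.8, 6.8) / 1000

#' Chemical-shift-encoded gradient-echo signal
#'
#' Forward signal equation evaluated at each echo time:
#' \deqn{s(TE) = (\rho_W + \rho_F \sum_p \alpha_p e^{i 2\pi \Delta f_p TE})
#'   \, e^{i 2\pi \psi TE} \, e^{-R_2^* TE}}
#' Water resonates at 0 Hz; the field offset \eqn{\psi} affects phase only;
#' \eqn{R_2^*} decay is common to water and fat. Inputs are vectorized over
#' voxels; the result is an \code{nEcho x nVoxel} complex matrix (a plain
#' complex vector when a single voxel is given).
#'
#' @param rhoW,rhoF water and fat proton densities (>= 0, arbitrary units).
#' @param teS echo times in seconds.
#' @param spectrum a \code{\link{FatSpectrum}}.
#' @param psiHz B0 field offset in Hz (per voxel).
#' @param r2sPerS R2* in 1/s (per voxel, >= 0).
#' @return Complex matrix \code{length(teS) x n} (dropped to a vector for
#'   n = 1).
#' @examples
#' s <- simulateSignal(1, 0, quantitativeEchoes(), defaultFatSpectrum())
#' stopifnot(all(s == 1 + 0i))  # pure water, no decay, no off-resonance
#' @export
simulateSignal <- function(rhoW, rhoF, teS, spectrum, psiHz = 0, r2sPerS = 0) {
  n <- max(length(rhoW), length(rhoF), length(psiHz), length(r2sPerS))
  rhoW <- rep_len(rhoW, n); rhoF <- rep_len(rhoF, n)
  psiHz <- rep_len(psiHz, n); r2sPerS <- rep_len(r2sPerS, n)
  if (any(rhoW < 0) || any(rhoF < 0))
    stop("densities must be nonnegative")
  if (any(r2sPerS < 0))
    stop("r2sPerS must be nonnegative")
  cte <- fatPhasor(teS, spectrum)                    # nE
  amp <- outer(cte, rhoF) + rep(rhoW, each = length(teS))  # nE x n
  phase <- exp(outer(teS, psiHz, function(t, p) 2i * pi * p * t))
  decay <- exp(-outer(teS, r2sPerS))
  out <- amp * phase * decay
  if (n == 1L) as.complex(out) else out
}

#' Proton density fat fraction in percent
#'
#' \code{100 |rho_F| / (|rho_W| + |rho_F|)}, clamped to [0, 100]. Magnitudes
#' are used so complex fitted amplitudes can be passed directly. A voxel with
#' both densities zero has no defined fat fraction and returns \code{NA}
#' (such voxels are excluded from statistics rather than counted as 0).
#'
#' @param rhoW,rhoF water and fat amplitudes (numeric or complex; vectorized).
#' @return Numeric vector of PDFF in percent, \code{NA} where undefined.
#' @examples
#' pdffPercent(1, 0)      # 0
#' pdffPercent(0.5, 0.5)  # 50
#' @export
pdffPercent <- function(rhoW, rhoF) {
  w <- Mod(rhoW); f <- Mod(rhoF)
  tot <- w + f
  out <- ifelse(tot > 0, 100 * f / tot, NA_real_)
  pmin(pmax(out, 0), 100)
}
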