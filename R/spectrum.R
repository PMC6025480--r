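#' Construct a fat spectrum
#'
#' @param shiftsPpm chemical shifts relative to water in ppm (negative for
#'   the dominant methylene resonance).
#' @param amplitudes relative peak weights; normalized to sum to 1 must hold
#'   on input (within 1e-9).
#' @param fieldStrengthT main field in Tesla (default 3).
#' @param gammaMHzT gyromagnetic ratio in MHz/T (default 42.577).
#' @return A \code{\link{FatSpectrum}}.
#' @examples
#' fatSpectrum(-3.4, 1)             # single-peak model
#' defaultFatSpectrum()             # six-peak triglyceride model
#' @export
fatSpectrum <- function(shiftsPpm, amplitudes,
                        fieldStrengthT = 3, gammaMHzT = 42.577) {
  new("FatSpectrum", shiftsPpm = as.numeric(shiftsPpm),
      amplitudes = as.numeric(amplitudes),
      fieldStrengthT = fieldStrengthT, gammaMHzT = gammaMHzT)
}

#' Default six-peak triglyceride spectrum
#'
#' A widely used six-resonance triglyceride model with the dominant
#' methylene peak at -3.40 ppm. Amplitudes sum to 1.
#'
#' @inheritParams fatSpectrum
#' @return A \code{\link{FatSpectrum}}.
#' @export
defaultFatSpectrum <- function(fieldStrengthT = 3, gammaMHzT = 42.577) {
  sh <- c(-3.80, -3.40, -2.60, -1.94, -0.39, 0.60)
  am <- c(0.087, 0.693, 0.128, 0.004, 0.039, 0.048)
  fatSpectrum(sh, am / sum(am), fieldStrengthT, gammaMHzT)
}

#' Single-peak fat model
#'
#' One resonance at -3.40 ppm; this is the fat model assumed by the
#' uncorrected fitting route.
#'
#' @inheritParams fatSpectrum
#' @return A \code{\link{FatSpectrum}}.
#' @export
singlePeakSpectrum <- function(fieldStrengthT = 3, gammaMHzT = 42.577) {
  fatSpectrum(-3.40, 1, fieldStrengthT, gammaMHzT)
}

#' Peak frequency offsets in Hz
#'
#' Chemical-shift relation: the frequency offset of peak p is
#' \code{shift_ppm_p * gamma_MHz/T * B0_T} Hz (ppm times MHz = Hz).
#'
#' @param spectrum a \code{\link{FatSpectrum}}.
#' @return Numeric vector of offsets in Hz, in peak order.
#' @export
peakFrequencies <- function(spectrum) {
  stopifnot(is(spectrum, "FatSpectrum"))
  spectrum@shiftsPpm * spectrum@gammaMHzT * spectrum@fieldStrengthT
}

#' Composite fat phasor at given echo times
#'
#' The amplitude-weighted sum of peak phasors,
#' \code{c(TE) = sum_p alpha_p exp(i 2 pi df_p TE)}, which multiplies the
#' fat density in the signal equation.
#'
#' @param teS echo times in seconds.
#' @param spectrum a \code{\link{FatSpectrum}}.
#' @return Complex vector, one value per echo time.
#' @export
fatPhasor <- function(teS, spectrum) {
  df <- peakFrequencies(spectrum)
  ph <- exp(outer(teS, df, function(t, f) 2i * pi * f * t))
  as.complex(ph %*% spectrum@amplitudes)
}

#' Read or write spectrum/protocol constants as YAML
#'
#' \code{writeSpectrumConfig} serializes a \code{FatSpectrum} to a YAML file;
#' \code{readSpectrumConfig} reads one back.
#'
#' @param spectrum a \code{\link{FatSpectrum}}.
#' @param path file path.
#' @return \code{readSpectrumConfig} returns a \code{FatSpectrum};
#'   \code{writeSpectrumConfig} returns \code{path} invisibly.
#' @export
writeSpectrumConfig <- function(spectrum, path) {
  yaml::write_yaml(list(
    shifts_ppm = spectrum@shiftsPpm,
    amplitudes = spectrum@amplitudes,
    field_strength_T = spectrum@fieldStrengthT,
    gamma_MHz_per_T = spectrum@gammaMHzT
  ), path, precision = 12L)
  invisible(path)
}

#' @rdname writeSpectrumConfig
#' @export
readSpectrumConfig <- function(path) {
  x <- yaml::read_yaml(path)
  am <- as.numeric(x$amplitudes)
  if (any(am < 0) || sum(am) <= 0)
    stop("spectrum config: amplitudes must be nonnegative with positive sum")
  # renormalize: serialized text may carry limited precision
  fatSpectrum(x$shifts_ppm, am / sum(am), x$field_strength_T,
              x$gamma_MHz_per_T)
}
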