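#' Write and read complex echo series as NIfTI
#'
#' An \code{\link{EchoSeries}} is stored as a pair of 4-D NIfTI-1 float32
#' files (magnitude and phase, echo along the fourth axis) plus a JSON
#' sidecar carrying echo times (s), protocol name, orientation, axes
#' permutation, grid origin and noise seed.
#'
#' @param series an \code{\link{EchoSeries}}.
#' @param prefix output path prefix; writes \code{<prefix>_mag.nii},
#'   \code{<prefix>_phase.nii} and \code{<prefix>.json}.
#' @return \code{readEchoSeries} returns an \code{EchoSeries};
#'   \code{writeEchoSeries} returns \code{prefix} invisibly.
#' @export
writeEchoSeries <- function(series, prefix) {
  stopifnot(is(series, "EchoSeries"))
  writeVolume(Mod(series@data), series@spacingMm,
              paste0(prefix, "_mag.nii"))
  writeVolume(Arg(series@data), series@spacingMm,
              paste0(prefix, "_phase.nii"))
  jsonlite::write_json(list(
    te_s = series@teS, protocol = series@protocolName,
    orientation = series@orientation, axes = series@axes,
    origin_mm = series@originMm, spacing_mm = series@spacingMm,
    seed = series@seed
  ), paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname writeEchoSeries
#' @export
readEchoSeries <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  mag <- readVolume(paste0(prefix, "_mag.nii"))
  ph <- readVolume(paste0(prefix, "_phase.nii"))
  data <- array(complex(modulus = as.vector(mag$data),
                        argument = as.vector(ph$data)),
                dim = dim(mag$data))
  new("EchoSeries", data = data, teS = as.numeric(meta$te_s),
      spacingMm = as.numeric(meta$spacing_mm),
      originMm = as.numeric(meta$origin_mm),
      axes = as.integer(meta$axes), protocolName = meta$protocol,
      orientation = meta$orientation, seed = as.integer(meta$seed))
}

#' Write and read fitted maps as NIfTI
#'
#' Each map (pdff, psi, r2s when present, rhoW, rhoF, residual, valid) is
#' written as one float32 NIfTI-1 volume with correct voxel spacing, plus a
#' JSON sidecar with the grid origin, axes permutation and fit method.
#'
#' @param maps a \code{\link{FitMaps}}.
#' @param prefix output path prefix.
#' @return \code{readFitMaps} returns a \code{FitMaps};
#'   \code{writeFitMaps} returns \code{prefix} invisibly.
#' @export
writeFitMaps <- function(maps, prefix) {
  stopifnot(is(maps, "FitMaps"))
  vols <- list(pdff = maps@pdff, psi = maps@psi, rhoW = maps@rhoW,
               rhoF = maps@rhoF, residual = maps@residual,
               valid = maps@valid * 1)
  if (length(maps@r2s)) vols$r2s <- maps@r2s
  for (nm in names(vols))
    writeVolume(vols[[nm]], maps@spacingMm,
                paste0(prefix, "_", nm, ".nii"))
  jsonlite::write_json(list(
    method = maps@method, origin_mm = maps@originMm,
    spacing_mm = maps@spacingMm, axes = maps@axes,
    has_r2s = length(maps@r2s) > 0
  ), paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname writeFitMaps
#' @export
readFitMaps <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  rd <- function(nm) readVolume(paste0(prefix, "_", nm, ".nii"))$data
  new("FitMaps", pdff = rd("pdff"), psi = rd("psi"),
      r2s = if (isTRUE(meta$has_r2s)) rd("r2s") else array(numeric(0)),
      rhoW = rd("rhoW"), rhoF = rd("rhoF"), residual = rd("residual"),
      valid = array(rd("valid") > 0.5, dim = dim(rd("valid"))),
      spacingMm = as.numeric(meta$spacing_mm),
      originMm = as.numeric(meta$origin_mm),
      axes = as.integer(meta$axes), method = meta$method)
}

#' Write ground-truth maps as NIfTI
#'
#' One float32 NIfTI-1 file per field (rhoW, rhoF, r2s, psi, labels) with
#' correct spacing, plus a JSON provenance sidecar recording origin, label
#' names and the phantom seed.
#'
#' @param gt a \code{\link{GroundTruthMaps}}.
#' @param prefix output path prefix.
#' @return \code{prefix}, invisibly.
#' @export
writeGroundTruth <- function(gt, prefix) {
  stopifnot(is(gt, "GroundTruthMaps"))
  for (nm in c("rhoW", "rhoF", "r2s", "psi", "labels"))
    writeVolume(slot(gt, nm) * 1, gt@spacingMm,
                paste0(prefix, "_", nm, ".nii"))
  jsonlite::write_json(list(
    origin_mm = gt@originMm, spacing_mm = gt@spacingMm,
    label_names = gt@labelNames, seed = gt@seed
  ), paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

# low-level NIfTI helpers -----------------------------------------------------

writeVolume <- function(arr, spacingMm, path) {
  d <- dim(arr)
  if (is.null(d)) d <- length(arr)
  if (length(d) < 3L) d <- c(d, rep(1L, 3L - length(d)))
  img <- RNifti::asNifti(array(arr * 1, dim = d))
  RNifti::`pixdim<-`(img, c(spacingMm, rep(1, length(d) - 3L))) -> img
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

readVolume <- function(path) {
  if (!file.exists(path)) stop("missing NIfTI file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  # NIfTI readers drop trailing singleton dimensions; restore 3-D shape
  if (length(d) < 3L) d <- c(d, rep(1L, 3L - length(d)))
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L) sp <- c(sp, rep(1, 3L - length(sp)))
  list(data = array(as.numeric(img), dim = d), spacingMm = sp[1:3])
}
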