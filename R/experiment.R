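#' Build an experiment configuration
#'
#' Bundles everything one replica run needs: phantom spec, tissue models,
#' protocols, SNR, analysis options and the master seed. All defaults
#' resolve without network access.
#'
#' @param experiment 1, 2 or 3.
#' @param seed integer master seed.
#' @param profile "paper" (full-size geometry) or "small" (fast replica).
#' @param snr background signal over noise SD (default 80).
#' @param protocols "both", "quantitative" or "highres".
#' @param nCentralSlices central slices analyzed (default: 4 for
#'   experiments 1-2, 8 for experiment 3 at paper size, 4 at small size).
#' @param binWidthPct histogram bin width in percent.
#' @param thresholdPct PDFF segmentation threshold for the volume metric
#'   (default 50).
#' @param fitOpts \code{\link{fitOptions}} for the estimators.
#' @return A list of class \code{ExperimentConfig}.
#' @export
experimentConfig <- function(experiment = 1, seed = 1L,
                             profile = c("paper", "small"), snr = 80,
                             protocols = c("both", "quantitative", "highres"),
                             nCentralSlices = NULL, binWidthPct = 1,
                             thresholdPct = 50, fitOpts = NULL) {
  profile <- match.arg(profile)
  protocols <- match.arg(protocols)
  if (!experiment %in% 1:3)
    stop("config error at $experiment: must be 1, 2 or 3")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("config error at $seed: must be a finite integer")
  if (!is.numeric(snr) || snr <= 0)
    stop("config error at $snr: must be positive")
  if (is.null(nCentralSlices))
    nCentralSlices <- if (experiment == 3 && profile == "paper") 8L else 4L
  if (nCentralSlices <= 0)
    stop("config error at $nCentralSlices: must be positive")
  if (is.null(fitOpts))
    fitOpts <- if (profile == "small")
      fitOptions(psiSearchHz = c(-120, 120, 3), r2sBoundsPerS = c(0, 200, 8))
    else fitOptions()
  structure(list(
    experiment = as.integer(experiment), seed = as.integer(seed),
    profile = profile, snr = snr, protocols = protocols,
    phantom = experimentPhantomSpec(experiment, profile),
    tissues = defaultTissueModels(),
    spectrum = defaultFatSpectrum(),
    nCentralSlices = as.integer(nCentralSlices),
    binWidthPct = binWidthPct, thresholdPct = thresholdPct,
    fitOpts = fitOpts
  ), class = "ExperimentConfig")
}

configProtocols <- function(config) {
  switch(config$protocols,
         both = list(quantitativeProtocol(config$snr),
                     highresProtocol(config$snr)),
         quantitative = list(quantitativeProtocol(config$snr)),
         highres = list(highresProtocol(config$snr)))
}

#' Run a full experiment replica
#'
#' End-to-end pipeline: ground-truth phantom, four forward-simulated
#' acquisitions (two protocols x two orientations), per-voxel water-fat
#' fitting (T2*-corrected multipeak for the quantitative series, single-peak
#' uncorrected for the high-resolution series) with swap correction, then
#' per-tube VOI statistics, PDFF histograms, threshold-volume curves and
#' aggregation over acquisitions. Deterministic for a given master seed.
#'
#' @param config an \code{\link{experimentConfig}}.
#' @param keepMaps logical: include the FitMaps objects in the result.
#' @return A list of class \code{ExperimentReport} with elements
#'   \code{tubes} (per-tube per-acquisition stats, volume metric and
#'   aggregate), \code{provenance}, and optionally \code{maps} and
#'   \code{phantom}.
#' @export
runExperiment <- function(config, keepMaps = FALSE) {
  stopifnot(inherits(config, "ExperimentConfig"))
  gt <- buildPhantom(config$phantom, config$tissues,
                     seed = deriveSeed(config$seed, "phantom"))
  series <- buildAcquisitionSet(gt, configProtocols(config),
                                seed = config$seed,
                                spectrum = config$spectrum)
  maps <- list()
  for (nm in names(series)) {
    ser <- series[[nm]]
    fm <- if (ser@protocolName == "quantitative_lowres")
      fitQuantitative(ser, config$spectrum, config$fitOpts)
    else
      fitUncorrected(ser, opts = config$fitOpts)
    maps[[nm]] <- swapCheck(fm, ser, spectrum = if (ser@protocolName ==
      "quantitative_lowres") config$spectrum else singlePeakSpectrum())$maps
  }
  thrGrid <- seq(0, 100, by = config$binWidthPct)
  tubes <- list()
  for (ti in seq_along(config$phantom@tubes)) {
    tube <- config$phantom@tubes[[ti]]
    perAcq <- list()
    for (nm in names(maps)) {
      fm <- maps[[nm]]
      voi <- tubeVOI(fm, tube, nCentralSlices = config$nCentralSlices)
      vv <- voxelVolumeCm3(fm)
      st <- voiStats(fm@pdff, voi, valid = fm@valid, voxelVolumeCm3 = vv)
      cv <- volumeCurve(fm@pdff, voi, vv, thresholdsPct = thrGrid,
                        valid = fm@valid)
      vol <- volUnderThreshold(fm@pdff, voi, config$thresholdPct, vv,
                               valid = fm@valid)
      hist <- pdffHistogram(fm@pdff, voi, config$binWidthPct,
                            valid = fm@valid)
      perAcq[[nm]] <- list(stats = st, curve = cv, volAtThreshold = vol,
                           histogram = hist)
    }
    agg <- if (length(perAcq) >= 2L)
      aggregateAcquisitions(lapply(perAcq, `[[`, "stats"),
                            lapply(perAcq, `[[`, "curve"))
    else NULL
    tubes[[paste0("tube", ti)]] <- list(
      composition = tube@composition, perAcquisition = perAcq,
      aggregate = agg,
      volAtThresholdMean = mean(vapply(perAcq, `[[`, numeric(1),
                                       "volAtThreshold")),
      volAtThresholdRange = range(vapply(perAcq, `[[`, numeric(1),
                                         "volAtThreshold")))
  }
  report <- list(
    tubes = tubes,
    provenance = list(seed = config$seed, experiment = config$experiment,
                      profile = config$profile,
                      configHash = rlang::hash(config),
                      thresholdPct = config$thresholdPct,
                      version = as.character(utils::packageVersion("batwfi")))
  )
  if (keepMaps) {
    report$maps <- maps
    report$phantom <- gt
  }
  structure(report, class = "ExperimentReport")
}

#' Serialize an experiment report
#'
#' \code{writeReport} writes the report as deterministic JSON (no
#' timestamps) plus per-tube CSV tables of VOI statistics and the
#' threshold-volume curve envelope.
#'
#' @param report an \code{ExperimentReport}.
#' @param dir output directory (created if needed).
#' @return The JSON path, invisibly.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  js <- reportAsList(report)
  jsonPath <- file.path(dir, "report.json")
  jsonlite::write_json(js, jsonPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  statRows <- list()
  for (tn in names(report$tubes)) {
    tb <- report$tubes[[tn]]
    for (an in names(tb$perAcquisition)) {
      s <- tb$perAcquisition[[an]]$stats
      statRows[[length(statRows) + 1L]] <- data.frame(
        tube = tn, acquisition = an, mean_pct = s$mean, sd_pct = s$sd,
        min_pct = s$min, max_pct = s$max, n_voxels = s$n,
        vol_at_threshold_cm3 = tb$perAcquisition[[an]]$volAtThreshold)
    }
    agg <- tb$aggregate
    if (!is.null(agg) && !is.null(agg$thresholdsPct)) {
      utils::write.csv(
        data.frame(threshold_pct = agg$thresholdsPct,
                   volume_mean_cm3 = agg$curveMean,
                   volume_min_cm3 = agg$curveMin,
                   volume_max_cm3 = agg$curveMax),
        file.path(dir, paste0("curve_", tn, ".csv")), row.names = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, statRows),
                   file.path(dir, "voi_stats.csv"), row.names = FALSE)
  invisible(jsonPath)
}

reportAsList <- function(report) {
  tubes <- lapply(report$tubes, function(tb) {
    list(
      composition = as.list(tb$composition),
      perAcquisition = lapply(tb$perAcquisition, function(pa) {
        list(stats = unclass(pa$stats), volAtThreshold = pa$volAtThreshold)
      }),
      aggregate = if (!is.null(tb$aggregate)) list(
        meanOfMeans = tb$aggregate$meanOfMeans,
        sdOfMeans = tb$aggregate$sdOfMeans,
        n = tb$aggregate$n) else NULL,
      volAtThresholdMean = tb$volAtThresholdMean,
      volAtThresholdRange = tb$volAtThresholdRange)
  })
  list(tubes = tubes, provenance = report$provenance)
}
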