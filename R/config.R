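#' @include AllClasses.R
NULL

#' Build a pipeline configuration
#'
#' Constructs a validated \linkS4class{PipelineConfig} with the study
#' defaults: dive-detection threshold 1 m (ten times the 0.1 m depth
#' resolution), single-dive foraging-trip threshold 18.1 m (the
#' across-year median maximum dive depth), 5-minute post-dive interval
#' for bouts, 130 km environmental radius, 800 m kernel grid, 50% and
#' 95% isopleths, activity energy rates 32 / 532.8 / 100.8 / 97.2 kJ/h
#' for colony / flying / swimming / diving, VIF threshold 5, GVIF
#' threshold 2.2 and Kaiser eigenvalue 1.
#'
#' @param colonyLonLat numeric(2) colony longitude, latitude. Defaults to
#'   the Coats Island colony (62.95 N, 82.01 W).
#' @param diveDepthThresholdM,singleDiveTripThresholdM,boutPdiMin,envRadiusKm,kdeGridM
#'   thresholds; see slot documentation.
#' @param udIsopleths isopleth fractions.
#' @param energyRatesKjPerH named kJ/h rates for the four behaviours.
#' @param vifThreshold,gvifThreshold,kaiserEigenvalue statistical cutoffs.
#' @param rngSeed integer seed recorded for provenance.
#' @return a \linkS4class{PipelineConfig}.
#' @examples
#' cfg <- pipelineConfig()
#' cfg@energyRatesKjPerH
#' @export
pipelineConfig <- function(colonyLonLat = c(-82.01, 62.95),
                           diveDepthThresholdM = 1.0,
                           singleDiveTripThresholdM = 18.1,
                           boutPdiMin = 5.0,
                           envRadiusKm = 130,
                           kdeGridM = 800,
                           udIsopleths = c(0.50, 0.95),
                           energyRatesKjPerH = c(COLONY = 32.0,
                                                 FLY = 532.8,
                                                 SWIM = 100.8,
                                                 DIVE = 97.2),
                           vifThreshold = 5,
                           gvifThreshold = 2.2,
                           kaiserEigenvalue = 1.0,
                           rngSeed = 1L) {
  new("PipelineConfig",
      colonyLonLat = as.numeric(colonyLonLat),
      diveDepthThresholdM = diveDepthThresholdM,
      singleDiveTripThresholdM = singleDiveTripThresholdM,
      boutPdiMin = boutPdiMin,
      envRadiusKm = envRadiusKm,
      kdeGridM = kdeGridM,
      udIsopleths = udIsopleths,
      energyRatesKjPerH = energyRatesKjPerH,
      vifThreshold = vifThreshold,
      gvifThreshold = gvifThreshold,
      kaiserEigenvalue = kaiserEigenvalue,
      rngSeed = as.integer(rngSeed))
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file whose keys match the arguments of
#' \code{\link{pipelineConfig}}; absent keys keep their defaults.
#'
#' @param path YAML file path.
#' @return a \linkS4class{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  if (!is.null(vals$energyRatesKjPerH))
    vals$energyRatesKjPerH <- unlist(vals$energyRatesKjPerH)
  do.call(pipelineConfig, vals)
}
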