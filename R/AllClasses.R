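#' @import methods
NULL

#' Behaviour state labels
#'
#' The four behaviours classified from biologger streams, in the fixed
#' decoding order used throughout the package: resting at the colony,
#' flying, swimming on the water surface, and diving.
#'
#' @export
BEHAVIOR_STATES <- c("COLONY", "FLY", "SWIM", "DIVE")

#' Pipeline configuration
#'
#' Holds every tunable threshold of the analysis chain: the colony
#' location, dive-detection and single-dive trip-classification depth
#' thresholds, the post-dive interval defining dive bouts, the radius for
#' environmental averaging, kernel grid size and isopleth fractions,
#' activity-specific energy rates, and the collinearity and component
#' retention thresholds of the statistical layer.
#'
#' @slot colonyLonLat numeric(2), colony longitude and latitude (degrees).
#' @slot diveDepthThresholdM metres; minimum depth for dive detection.
#' @slot singleDiveTripThresholdM metres; a single dive deeper than this
#'   marks a trip as foraging (default 18.1, the across-year median
#'   maximum dive depth).
#' @slot boutPdiMin minutes; post-dive interval separating dive bouts.
#' @slot envRadiusKm kilometres; radius around the colony for
#'   environmental averaging (default 130, the maximum foraging range).
#' @slot kdeGridM metres; kernel density grid cell size (default 800).
#' @slot udIsopleths fractions in (0,1); utilization-distribution
#'   isopleths reported (default 0.50 core, 0.95 overall).
#' @slot energyRatesKjPerH named numeric(4); kJ per hour for COLONY, FLY,
#'   SWIM, DIVE (defaults 32, 532.8, 100.8, 97.2).
#' @slot vifThreshold variance inflation factor cutoff (default 5).
#' @slot gvifThreshold GVIF^(1/(2 df)) cutoff for multi-df terms
#'   (default 2.2).
#' @slot kaiserEigenvalue eigenvalue retention threshold (default 1).
#' @slot rngSeed integer seed recorded for provenance.
#' @export
setClass("PipelineConfig",
  representation(
    colonyLonLat = "numeric",
    diveDepthThresholdM = "numeric",
    singleDiveTripThresholdM = "numeric",
    boutPdiMin = "numeric",
    envRadiusKm = "numeric",
    kdeGridM = "numeric",
    udIsopleths = "numeric",
    energyRatesKjPerH = "numeric",
    vifThreshold = "numeric",
    gvifThreshold = "numeric",
    kaiserEigenvalue = "numeric",
    rngSeed = "integer"
  )
)

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (length(object@colonyLonLat) != 2L ||
      any(!is.finite(object@colonyLonLat)))
    msg <- c(msg, "colonyLonLat must be two finite degrees (lon, lat)")
  pos <- c(diveDepthThresholdM = object@diveDepthThresholdM,
           singleDiveTripThresholdM = object@singleDiveTripThresholdM,
           boutPdiMin = object@boutPdiMin,
           envRadiusKm = object@envRadiusKm,
           kdeGridM = object@kdeGridM,
           vifThreshold = object@vifThreshold,
           gvifThreshold = object@gvifThreshold,
           kaiserEigenvalue = object@kaiserEigenvalue)
  if (any(!is.finite(pos)) || any(pos <= 0))
    msg <- c(msg, paste("thresholds must be strictly positive:",
                        paste(names(pos)[!is.finite(pos) | pos <= 0],
                              collapse = ", ")))
  if (any(object@udIsopleths <= 0 | object@udIsopleths >= 1))
    msg <- c(msg, "udIsopleths must lie in (0, 1)")
  er <- object@energyRatesKjPerH
  if (length(er) != 4L || !setequal(names(er), BEHAVIOR_STATES))
    msg <- c(msg, "energyRatesKjPerH must name exactly COLONY, FLY, SWIM, DIVE")
  else if (any(er < 0)) msg <- c(msg, "energy rates must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Hidden Markov model specification
#'
#' Parameters of the four-state behaviour HMM: initial distribution,
#' row-stochastic transition matrix, and per-state emission distributions
#' for the four observation channels. Non-negative channels (wing-beat
#' frequency, depth, distance from colony) use zero-inflated gamma
#' emissions; pitch uses a normal emission. Channels are conditionally
#' independent given the state.
#'
#' @slot states character, state labels in decoding order.
#' @slot init numeric initial state probabilities.
#' @slot trans row-stochastic transition matrix.
#' @slot emissions list, one element per state; each a list with
#'   components \code{wingbeat}, \code{depth}, \code{dist} (each
#'   \code{c(pi0, shape, rate)}) and \code{pitch} (\code{c(mean, sd)}).
#' @export
setClass("HMMSpec",
  representation(
    states = "character",
    init = "numeric",
    trans = "matrix",
    emissions = "list"
  )
)

setValidity("HMMSpec", function(object) {
  msg <- character()
  S <- length(object@states)
  if (S < 2L) msg <- c(msg, "need at least two states")
  if (length(object@init) != S || abs(sum(object@init) - 1) > 1e-10 ||
      any(object@init < 0))
    msg <- c(msg, "init must be a probability vector summing to 1")
  if (!all(dim(object@trans) == c(S, S)))
    msg <- c(msg, "trans must be square, states x states")
  else if (any(abs(rowSums(object@trans) - 1) > 1e-10) ||
           any(object@trans < 0))
    msg <- c(msg, "rows of trans must sum to 1 (within 1e-10)")
  if (length(object@emissions) != S)
    msg <- c(msg, "one emission set per state required")
  for (e in object@emissions) {
    for (ch in c("wingbeat", "depth", "dist")) {
      p <- e[[ch]]
      if (is.null(p) || length(p) != 3L || any(!is.finite(p)) ||
          p[1] < 0 || p[1] > 1 || p[2] <= 0 || p[3] <= 0) {
        msg <- c(msg, sprintf(
          "channel %s needs c(pi0 in [0,1], shape > 0, rate > 0)", ch))
        break
      }
    }
    p <- e[["pitch"]]
    if (is.null(p) || length(p) != 2L || any(!is.finite(p)) || p[2] <= 0)
      msg <- c(msg, "pitch channel needs c(mean, sd > 0)")
  }
  if (length(msg)) unique(msg) else TRUE
})

#' One biologger deployment
#'
#' A single bird-deployment: identity and breeding metadata plus the
#' ordered fix table (time, position, depth, wing-beat frequency, pitch,
#' and distance from the colony) and, when simulated or detected, the
#' table of individual dives.
#'
#' @slot birdId character bird identifier.
#' @slot sex one of "M", "F", "UNKNOWN".
#' @slot stage one of "INCUBATION", "CHICK_REARING".
#' @slot chickAgeD mean chick age over the deployment (days; NA during
#'   incubation).
#' @slot startT,endT POSIXct deployment window (UTC).
#' @slot fixes data.frame with columns t, lon, lat, depth, wingbeatHz,
#'   pitch, distColonyKm; times strictly increasing.
#' @slot dives data.frame of dive events (startT, endT, maxDepthM),
#'   possibly empty.
#' @slot massPreG,massPostG body mass at deployment and retrieval (g; NA
#'   if unmeasured).
#' @slot timeAtColonyH hours at the colony before the post-deployment
#'   blood sample (NA if unknown).
#' @export
setClass("MurreDeployment",
  representation(
    birdId = "character",
    sex = "character",
    stage = "character",
    chickAgeD = "numeric",
    startT = "POSIXct",
    endT = "POSIXct",
    fixes = "data.frame",
    dives = "data.frame",
    massPreG = "numeric",
    massPostG = "numeric",
    timeAtColonyH = "numeric"
  )
)

setValidity("MurreDeployment", function(object) {
  msg <- character()
  if (!object@sex %in% c("M", "F", "UNKNOWN"))
    msg <- c(msg, "sex must be M, F or UNKNOWN")
  if (!object@stage %in% c("INCUBATION", "CHICK_REARING"))
    msg <- c(msg, "stage must be INCUBATION or CHICK_REARING")
  if (object@stage == "INCUBATION" && !is.na(object@chickAgeD))
    msg <- c(msg, "chickAgeD must be NA during incubation")
  if (object@stage == "CHICK_REARING" && is.na(object@chickAgeD))
    msg <- c(msg, "chickAgeD required during chick rearing")
  if (as.numeric(object@endT) <= as.numeric(object@startT))
    msg <- c(msg, "deployment duration must be positive")
  fx <- object@fixes
  need <- c("t", "lon", "lat", "depth", "wingbeatHz", "pitch",
            "distColonyKm")
  miss <- setdiff(need, names(fx))
  if (length(miss))
    msg <- c(msg, paste("fixes missing column(s):",
                        paste(miss, collapse = ", ")))
  else {
    if (nrow(fx) == 0L) msg <- c(msg, "deployment has zero fixes")
    if (nrow(fx) > 1L && any(diff(as.numeric(fx$t)) <= 0))
      msg <- c(msg, "fix times must be strictly increasing")
    if (any(fx$depth < 0, na.rm = TRUE))
      msg <- c(msg, "depth must be non-negative")
    if (any(fx$distColonyKm < 0, na.rm = TRUE))
      msg <- c(msg, "distColonyKm must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Decoded behaviour sequence
#'
#' Per-fix behaviour labels produced by Viterbi decoding, together with
#' the forward-algorithm marginal log-likelihood and the model that
#' produced them.
#'
#' @slot deploymentId deployment (bird) identifier.
#' @slot states character vector of per-fix labels.
#' @slot logLik forward log-likelihood of the observations (nats).
#' @slot spec the \linkS4class{HMMSpec} used for decoding.
#' @export
setClass("BehaviorSequence",
  representation(
    deploymentId = "character",
    states = "character",
    logLik = "numeric",
    spec = "HMMSpec"
  )
)

setValidity("BehaviorSequence", function(object) {
  msg <- character()
  if (!is.finite(object@logLik))
    msg <- c(msg, "log-likelihood must be finite")
  if (!all(object@states %in% object@spec@states))
    msg <- c(msg, "states contain labels absent from the model")
  if (length(msg)) msg else TRUE
})

#' Utilization distribution on a planar grid
#'
#' A kernel-density utilization distribution (UD) evaluated on a regular
#' grid in a local azimuthal-equidistant plane centred on the colony.
#' Density integrates to 1 over the grid (sum of density times cell
#' area).
#'
#' @slot x,y cell-centre coordinates (metres, projected).
#' @slot density matrix (length(x) rows by length(y) columns) of density
#'   per square metre, all non-negative.
#' @slot cellM grid cell size (metres).
#' @slot crsNote free-text projection descriptor.
#' @export
setClass("UtilizationDistribution",
  representation(
    x = "numeric",
    y = "numeric",
    density = "matrix",
    cellM = "numeric",
    crsNote = "character"
  )
)

setValidity("UtilizationDistribution", function(object) {
  msg <- character()
  if (!all(dim(object@density) == c(length(object@x), length(object@y))))
    msg <- c(msg, "density must be length(x) by length(y)")
  if (any(object@density < 0))
    msg <- c(msg, "density must be non-negative")
  tot <- sum(object@density) * object@cellM^2
  if (abs(tot - 1) > 1e-6)
    msg <- c(msg, sprintf("density must integrate to 1 (got %.8f)", tot))
  if (length(msg)) msg else TRUE
})

#' Gridded environmental field
#'
#' A daily time series of lon/lat rasters of one environmental variable
#' (sea ice concentration in percent, or sea surface temperature in
#' degrees Celsius).
#'
#' @slot variable "ICE_PCT" or "SST_C".
#' @slot lon,lat cell-centre coordinates (degrees).
#' @slot times Date vector, one per raster layer.
#' @slot values array, dim (lon, lat, time); NA marks missing cells.
#' @slot units "%" or "degC".
#' @export
setClass("EnvField",
  representation(
    variable = "character",
    lon = "numeric",
    lat = "numeric",
    times = "Date",
    values = "array",
    units = "character"
  )
)

setValidity("EnvField", function(object) {
  msg <- character()
  if (!object@variable %in% c("ICE_PCT", "SST_C"))
    msg <- c(msg, "variable must be ICE_PCT or SST_C")
  d <- dim(object@values)
  if (length(d) != 3L || d[1] != length(object@lon) ||
      d[2] != length(object@lat) || d[3] != length(object@times))
    msg <- c(msg, "values must have dim (lon, lat, time)")
  if (object@variable == "ICE_PCT" &&
      any(object@values < 0 | object@values > 100, na.rm = TRUE))
    msg <- c(msg, "ice concentration must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' Principal component analysis result
#'
#' Correlation-matrix PCA of a deployment metric table with Kaiser
#' retention and optional varimax rotation, carrying the loadings,
#' rotation, per-bird component scores and the standardization needed to
#' score new data.
#'
#' @slot variables variable names in fitting order.
#' @slot eigenvalues all eigenvalues of the correlation matrix,
#'   non-increasing.
#' @slot loadings variables x retained-components loading matrix
#'   (rotated when \code{rotated} is TRUE).
#' @slot rotated logical; TRUE when a varimax rotation was applied.
#' @slot rotation orthonormal rotation matrix applied to the unrotated
#'   loadings (identity when unrotated).
#' @slot scores rows x retained-components score matrix
#'   (regression-method scores, mean zero on the fitting sample).
#' @slot varExplainedPct percent of total variance carried by the
#'   retained components.
#' @slot center,scaleV per-variable standardization used at fit time.
#' @slot corMatrix correlation matrix of the fitting data (used for
#'   regression scores).
#' @export
setClass("PCAResult",
  representation(
    variables = "character",
    eigenvalues = "numeric",
    loadings = "matrix",
    rotated = "logical",
    rotation = "matrix",
    scores = "matrix",
    varExplainedPct = "numeric",
    center = "numeric",
    scaleV = "numeric",
    corMatrix = "matrix"
  )
)

setValidity("PCAResult", function(object) {
  msg <- character()
  ev <- object@eigenvalues
  if (any(diff(ev) > 1e-8)) msg <- c(msg, "eigenvalues must be non-increasing")
  if (abs(sum(ev) - length(object@variables)) > 1e-6)
    msg <- c(msg, "eigenvalues of a correlation PCA must sum to the number of variables")
  R <- object@rotation
  if (nrow(R) > 0 &&
      max(abs(crossprod(R) - diag(ncol(R)))) > 1e-10)
    msg <- c(msg, "rotation must be orthonormal (within 1e-10)")
  if (length(msg)) msg else TRUE
})

#' Synthetic biologging scenario
#'
#' Parameters of the seeded generator: fleet size and sampling protocol,
#' the ground-truth behaviour model, trip and dive structure, planted
#' covariate effects, and biomarker noise. Identical seeds give
#' bit-identical output.
#'
#' @slot nBirds number of deployments.
#' @slot sexRatio fraction male.
#' @slot stage breeding stage for all birds.
#' @slot days deployment length in days (study protocol: about 2).
#' @slot fixIntervalS GPS fix interval, 60 or 180 s.
#' @slot depthHz depth sampling rate (Hz) used when rendering traces.
#' @slot hmmTruth \linkS4class{HMMSpec} generating within-trip behaviour
#'   and observation channels.
#' @slot colonyLonLat colony longitude/latitude (degrees).
#' @slot tripRatePerDay expected foraging trips per day.
#' @slot tripMeanDurH mean trip duration (hours).
#' @slot diveDepthMeanM median maximum dive depth (metres; lognormal
#'   log-location is \code{log(diveDepthMeanM)}).
#' @slot diveDepthSdM spread of maximum dive depth (metres; converted to
#'   a log-scale SD as \code{diveDepthSdM / diveDepthMeanM}).
#' @slot boutSizeMean mean dives per bout.
#' @slot iceEffect,sstEffect,sexEffect,chickageEffect planted
#'   standardized effects on behaviour (trip rate) and biomarker change.
#' @slot noiseSd biomarker log-scale residual SD.
#' @slot seed integer RNG seed.
#' @export
setClass("SimScenario",
  representation(
    nBirds = "integer",
    sexRatio = "numeric",
    stage = "character",
    days = "numeric",
    fixIntervalS = "numeric",
    depthHz = "numeric",
    hmmTruth = "HMMSpec",
    colonyLonLat = "numeric",
    tripRatePerDay = "numeric",
    tripMeanDurH = "numeric",
    diveDepthMeanM = "numeric",
    diveDepthSdM = "numeric",
    boutSizeMean = "numeric",
    iceEffect = "numeric",
    sstEffect = "numeric",
    sexEffect = "numeric",
    chickageEffect = "numeric",
    noiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("SimScenario", function(object) {
  msg <- character()
  if (object@sexRatio < 0 || object@sexRatio > 1)
    msg <- c(msg, "sexRatio must lie in [0, 1]")
  if (!object@fixIntervalS %in% c(60, 180))
    msg <- c(msg, "fixIntervalS must be 60 or 180 seconds")
  nonneg <- c(object@days, object@tripRatePerDay, object@tripMeanDurH,
              object@diveDepthMeanM, object@diveDepthSdM,
              object@boutSizeMean, object@noiseSd, object@depthHz)
  if (any(!is.finite(nonneg)) || any(nonneg < 0))
    msg <- c(msg, "rates, durations and SDs must be non-negative")
  if (!object@stage %in% c("INCUBATION", "CHICK_REARING"))
    msg <- c(msg, "stage must be INCUBATION or CHICK_REARING")
  if (length(msg)) msg else TRUE
})
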