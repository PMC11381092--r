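#' @include AllClasses.R hmm.R
NULL

#' Build a synthetic biologging scenario
#'
#' Defaults follow the study protocol: ~2-day deployments, a GPS fix
#' every 3 minutes (60 s also allowed), 1 Hz depth, a colony at 62.95 N
#' / 82.01 W, about two foraging trips per day of ~6 h, lognormal
#' maximum dive depths with median 18 m, and dive bouts of ~8 dives
#' separated by surface intervals shorter than the 5-minute post-dive
#' interval. Planted effects act multiplicatively on the per-bird trip
#' rate and additively on log-scale biomarker change.
#'
#' @param nBirds,sexRatio,stage,days,fixIntervalS,depthHz see
#'   \linkS4class{SimScenario}.
#' @param hmmTruth generating behaviour model.
#' @param colonyLonLat colony (lon, lat).
#' @param tripRatePerDay,tripMeanDurH trip structure.
#' @param diveDepthMeanM,diveDepthSdM,boutSizeMean dive structure.
#' @param iceEffect,sstEffect,sexEffect,chickageEffect planted
#'   standardized effect sizes.
#' @param noiseSd biomarker log-scale residual SD.
#' @param seed integer seed; identical seeds give identical output.
#' @return a validated \linkS4class{SimScenario}.
#' @export
simScenario <- function(nBirds = 20, sexRatio = 0.5,
                        stage = "CHICK_REARING", days = 2,
                        fixIntervalS = 180, depthHz = 1,
                        hmmTruth = defaultHMMSpec(),
                        colonyLonLat = c(-82.01, 62.95),
                        tripRatePerDay = 2, tripMeanDurH = 6,
                        diveDepthMeanM = 18, diveDepthSdM = 9,
                        boutSizeMean = 8,
                        iceEffect = 0, sstEffect = 0, sexEffect = 0,
                        chickageEffect = 0,
                        noiseSd = 0.2, seed = 1L) {
  new("SimScenario", nBirds = as.integer(nBirds), sexRatio = sexRatio,
      stage = stage, days = days, fixIntervalS = fixIntervalS,
      depthHz = depthHz, hmmTruth = hmmTruth,
      colonyLonLat = as.numeric(colonyLonLat),
      tripRatePerDay = tripRatePerDay, tripMeanDurH = tripMeanDurH,
      diveDepthMeanM = diveDepthMeanM, diveDepthSdM = diveDepthSdM,
      boutSizeMean = boutSizeMean, iceEffect = iceEffect,
      sstEffect = sstEffect, sexEffect = sexEffect,
      chickageEffect = chickageEffect, noiseSd = noiseSd,
      seed = as.integer(seed))
}

## season origin (June 15) and length used by the seasonal curves
SEASON_START <- as.Date("2018-06-15")
SEASON_DAYS <- 61

## deterministic seasonal curves at the colony: ice declines, SST rises
seasonalIce <- function(dayOfSeason) {
  pmin(100, pmax(0, 85 - 1.5 * dayOfSeason))
}
seasonalSst <- function(dayOfSeason) -0.5 + 0.12 * dayOfSeason

## standardized seasonal covariate of a deployment window
seasonZ <- function(curve, day0, days) {
  grid <- curve(0:SEASON_DAYS)
  win <- mean(curve(seq(day0, day0 + days, by = 0.25)))
  (win - mean(grid)) / stats::sd(grid)
}

#' Simulate biologger deployments
#'
#' Generates seeded central-place foraging deployments: each bird
#' alternates colony attendance (forced through its sex-specific diel
#' window, in local solar time) with foraging trips; within a trip the
#' bird commutes out in flight, then switches between swimming and
#' diving following the scenario's Markov chain, then flies home. Dive
#' events fill diving periods with surface gaps shorter than the bout
#' criterion, and maximum dive depths are lognormal with median
#' \code{diveDepthMeanM}. Wing-beat frequency and pitch are drawn from
#' the generating HMM's per-state emissions; depth and distance follow
#' the simulated dives and positions.
#'
#' @param scenario a \linkS4class{SimScenario}.
#' @return list with \code{deployments} (list of
#'   \linkS4class{MurreDeployment}), \code{truth} (list of per-fix
#'   ground-truth label vectors) and \code{birds} (per-bird covariate
#'   data.frame: sex, chick age, standardized seasonal ice and SST of
#'   the deployment window, realized trip count).
#' @export
simulateDeployments <- function(scenario) {
  validObject(scenario)
  set.seed(scenario@seed)
  nFix <- round(scenario@days * 86400 / scenario@fixIntervalS)
  fixInt <- scenario@fixIntervalS
  colony <- scenario@colonyLonLat
  spec <- scenario@hmmTruth
  stateIdx <- stats::setNames(seq_along(spec@states), spec@states)

  deployments <- vector("list", scenario@nBirds)
  truth <- vector("list", scenario@nBirds)
  birds <- data.frame(bird_id = sprintf("bird%03d", seq_len(scenario@nBirds)),
                      sex = NA_character_, chick_age_d = NA_real_,
                      ice_z = NA_real_, sst_z = NA_real_,
                      n_trips = NA_integer_, deployment_dur_h = NA_real_,
                      start_date = as.Date(NA),
                      stringsAsFactors = FALSE)

  for (b in seq_len(scenario@nBirds)) {
    sex <- if (stats::runif(1) < scenario@sexRatio) "M" else "F"
    day0 <- if (scenario@stage == "INCUBATION")
      sample(0:25, 1) else sample(33:55, 1)
    startT <- as.POSIXct(SEASON_START, tz = "UTC") + day0 * 86400 +
      round(stats::runif(1, 0, 86400 / fixInt)) * fixInt
    tFix <- startT + (seq_len(nFix) - 1) * fixInt
    iceZ <- seasonZ(seasonalIce, day0, scenario@days)
    sstZ <- seasonZ(seasonalSst, day0, scenario@days)
    chickAge <- if (scenario@stage == "CHICK_REARING")
      stats::runif(1, 1, 20) else NA_real_
    chickZ <- if (is.na(chickAge)) 0 else (chickAge - 10.5) / 5.5
    rate <- scenario@tripRatePerDay *
      exp(scenario@iceEffect * iceZ + scenario@sstEffect * sstZ +
            scenario@sexEffect * (sex == "M") +
            scenario@chickageEffect * chickZ)

    sched <- scheduleTrips(tFix, fixInt, sex, colony[1], rate,
                           scenario@tripMeanDurH)
    states <- buildStates(sched, spec, stateIdx)
    pos <- buildPositions(states, sched, colony, fixInt, spec)
    dv <- buildDives(states, tFix, fixInt, scenario)
    obsWb <- drawChannel(states, spec, "wingbeat")
    obsPitch <- drawPitch(states, spec)
    depth <- fixDepth(states, tFix, fixInt, dv)

    fx <- data.frame(t = tFix, lon = pos$lon, lat = pos$lat,
                     depth = depth, wingbeatHz = obsWb,
                     pitch = obsPitch,
                     distColonyKm = haversineKm(colony[1], colony[2],
                                                pos$lon, pos$lat))
    deployments[[b]] <- new("MurreDeployment",
      birdId = birds$bird_id[b], sex = sex, stage = scenario@stage,
      chickAgeD = chickAge, startT = tFix[1],
      endT = tFix[nFix] + fixInt, fixes = fx, dives = dv,
      massPreG = stats::rnorm(1, 980, 60),
      massPostG = NA_real_,
      timeAtColonyH = stats::runif(1, 0.5, 6))
    truth[[b]] <- spec@states[states]
    birds$sex[b] <- sex
    birds$chick_age_d[b] <- chickAge
    birds$ice_z[b] <- iceZ
    birds$sst_z[b] <- sstZ
    birds$n_trips[b] <- sched$nTrips
    birds$deployment_dur_h[b] <- nFix * fixInt / 3600
    birds$start_date[b] <- as.Date(startT)
  }
  list(deployments = deployments, truth = truth, birds = birds)
}

## renewal-process trip schedule honouring the sex diel attendance window.
## Colony gaps are exponential with mean chosen so the realized rate
## matches the nominal trips/day after accounting for trip duration and
## the expected delay when a start lands in the attendance window.
scheduleTrips <- function(tFix, fixInt, sex, lon, ratePerDay,
                          tripMeanDurH) {
  n <- length(tFix)
  solar <- localSolarHour(tFix, lon)
  inWindow <- if (sex == "F") (solar >= 23.5 | solar < 3.5)
              else (solar >= 11.5 & solar < 15.5)
  tripId <- integer(n)                      # 0 = colony
  if (ratePerDay <= 0)
    return(list(tripId = tripId, inWindow = inWindow, nTrips = 0L))
  windowDelay <- 4 / 24 * 2                 # E(delay) ~ P(hit) * E(remain)
  gapMeanH <- max(0.3, 24 / ratePerDay - tripMeanDurH - windowDelay)
  cursor <- 1L
  nTrips <- 0L
  totalH <- n * fixInt / 3600
  while (TRUE) {
    gap <- stats::rexp(1, 1 / gapMeanH)
    cursor <- cursor + max(1L, round(gap * 3600 / fixInt))
    if (cursor > n) break
    while (cursor <= n && inWindow[cursor]) cursor <- cursor + 1L
    if (cursor > n) break
    durH <- stats::rlnorm(1, log(tripMeanDurH) - 0.3^2 / 2, 0.3)
    len <- max(3L, round(durH * 3600 / fixInt))
    end <- min(n, cursor + len - 1L)
    ## the bird must be back on the nest for its attendance window
    windowAhead <- which(inWindow[cursor:end])
    if (length(windowAhead)) end <- cursor + windowAhead[1] - 2L
    if (end - cursor + 1L < 3L) { cursor <- end + 1L; next }
    nTrips <- nTrips + 1L
    tripId[cursor:end] <- nTrips
    cursor <- end + 1L
  }
  list(tripId = tripId, inWindow = inWindow, nTrips = nTrips,
       totalH = totalH)
}

## within-trip behaviour: forced FLY commute legs bracketing a middle
## phase that alternates SWIM/DIVE by the truth chain
buildStates <- function(sched, spec, stateIdx) {
  n <- length(sched$tripId)
  states <- rep(stateIdx[["COLONY"]], n)
  if (sched$nTrips == 0L) return(states)
  pSwimDive <- spec@trans[c("SWIM", "DIVE"), c("SWIM", "DIVE")]
  pSwimDive <- pSwimDive / rowSums(pSwimDive)
  for (k in seq_len(sched$nTrips)) {
    idx <- which(sched$tripId == k)
    len <- length(idx)
    nCommute <- max(1L, min(floor((len - 1) / 2), round(0.2 * len)))
    mid <- if (len > 2 * nCommute)
      (nCommute + 1):(len - nCommute) else integer(0)
    st <- rep(stateIdx[["FLY"]], len)
    if (length(mid)) {
      cur <- 1L                                    # 1 = SWIM, 2 = DIVE
      for (i in mid) {
        st[i] <- if (cur == 1L) stateIdx[["SWIM"]] else stateIdx[["DIVE"]]
        cur <- sample.int(2L, 1L, prob = pSwimDive[cur, ])
      }
    }
    states[idx] <- st
  }
  states
}

buildPositions <- function(states, sched, colony, fixInt, spec) {
  n <- length(states)
  lon <- rep(colony[1], n)
  lat <- rep(colony[2], n)
  eCol <- spec@emissions[[which(spec@states == "COLONY")]]$dist
  atColony <- sched$tripId == 0L
  jitter <- stats::runif(sum(atColony)) >= eCol[1]
  if (any(jitter)) {
    d <- stats::rgamma(sum(jitter), shape = eCol[2], rate = eCol[3])
    az <- stats::runif(sum(jitter), 0, 2 * pi)
    p <- destPoint(colony[1], colony[2], az, d)
    lon[atColony][jitter] <- p$lon
    lat[atColony][jitter] <- p$lat
  }
  flyIdx <- which(spec@states == "FLY")
  if (sched$nTrips > 0L) for (k in seq_len(sched$nTrips)) {
    idx <- which(sched$tripId == k)
    len <- length(idx)
    bear <- stats::runif(1, 0, 2 * pi)
    tripH <- len * fixInt / 3600
    dest <- min(stats::runif(1, 15, 60), 0.4 * tripH * 65)
    fly <- states[idx] == flyIdx
    r <- rle(fly)
    lead <- if (r$values[1]) r$lengths[1] else 0L
    tail_ <- if (r$values[length(r$values)]) r$lengths[length(r$values)]
             else 0L
    dvec <- numeric(len)
    if (lead + tail_ >= len) {       # trip too short for a middle phase
      half <- ceiling(len / 2)
      dvec <- dest * c(seq_len(half) / half,
                       (rev(seq_len(len - half)) - 1) / max(1, len - half))
    } else {
      dvec[seq_len(lead)] <- dest * seq_len(lead) / lead
      mid <- (lead + 1):(len - tail_)
      wob <- cumsum(stats::rnorm(length(mid), 0, 0.3))  # drift at sea (km)
      dvec[mid] <- pmax(0.5, dest + wob)
      tl <- (len - tail_ + 1):len
      dvec[tl] <- dest * (rev(seq_len(tail_)) - 1) / tail_
    }
    p <- destPoint(colony[1], colony[2], bear, dvec)
    lon[idx] <- p$lon
    lat[idx] <- p$lat
  }
  list(lon = lon, lat = lat)
}

## fill DIVE-state runs with dive events; gaps inside a run stay under
## the 5-minute bout criterion
buildDives <- function(states, tFix, fixInt, scenario) {
  diveState <- which(scenario@hmmTruth@states == "DIVE")
  isDive <- states == diveState
  if (!any(isDive)) return(emptyDiveTable())
  r <- rle(isDive)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  sdlog <- scenario@diveDepthSdM / scenario@diveDepthMeanM
  out <- list()
  for (ri in runs) {
    w0 <- as.numeric(tFix[starts[ri]])
    w1 <- as.numeric(tFix[ends[ri]]) + fixInt
    cur <- w0 + stats::runif(1, 0, 15)
    while (cur < w1 - 25) {
      maxDepth <- stats::rlnorm(1, log(scenario@diveDepthMeanM), sdlog)
      dur <- 20 + 2 * maxDepth
      end <- min(cur + dur, w1)
      out[[length(out) + 1L]] <- c(cur, end, maxDepth)
      cur <- end + stats::runif(1, 20, 100)
    }
  }
  if (!length(out)) return(emptyDiveTable())
  m <- do.call(rbind, out)
  data.frame(startT = as.POSIXct(m[, 1], origin = "1970-01-01", tz = "UTC"),
             endT = as.POSIXct(m[, 2], origin = "1970-01-01", tz = "UTC"),
             maxDepthM = round(m[, 3], 1))
}

drawChannel <- function(states, spec, channel) {
  n <- length(states)
  out <- numeric(n)
  for (s in seq_along(spec@states)) {
    idx <- which(states == s)
    if (!length(idx)) next
    p <- spec@emissions[[s]][[channel]]
    z <- stats::runif(length(idx)) < p[1]
    v <- stats::rgamma(length(idx), shape = p[2], rate = p[3])
    v[z] <- 0
    out[idx] <- v
  }
  out
}

drawPitch <- function(states, spec) {
  n <- length(states)
  out <- numeric(n)
  for (s in seq_along(spec@states)) {
    idx <- which(states == s)
    if (!length(idx)) next
    p <- spec@emissions[[s]]$pitch
    out[idx] <- stats::rnorm(length(idx), p[1], p[2])
  }
  out
}

## per-fix depth summary: maximum dive depth intersecting the interval
fixDepth <- function(states, tFix, fixInt, dv) {
  n <- length(tFix)
  depth <- numeric(n)
  if (!nrow(dv)) return(depth)
  t0 <- as.numeric(tFix[1])
  s <- as.numeric(dv$startT); e <- as.numeric(dv$endT)
  i0 <- pmax(1L, pmin(n, floor((s - t0) / fixInt) + 1L))
  i1 <- pmax(1L, pmin(n, ceiling((e - t0) / fixInt)))
  for (i in seq_len(nrow(dv))) {
    idx <- i0[i]:i1[i]
    depth[idx] <- pmax(depth[idx], dv$maxDepthM[i])
  }
  depth
}

#' Render a 1 Hz depth trace for a deployment
#'
#' Expands the deployment's dive events into a 1 Hz depth series with a
#' symmetric V profile per dive (linear descent to the maximum depth at
#' the dive midpoint, linear ascent back), zero at the surface; the
#' trace is rounded to the 0.1 m sensor resolution.
#'
#' @param deployment a \linkS4class{MurreDeployment}.
#' @param from,to POSIXct window (defaults: whole deployment).
#' @return data.frame with columns t (POSIXct) and depth (m).
#' @export
renderDepthTrace <- function(deployment, from = deployment@startT,
                             to = deployment@endT) {
  tSec <- seq(as.numeric(from), as.numeric(to))
  depth <- numeric(length(tSec))
  dv <- deployment@dives
  if (nrow(dv)) for (i in seq_len(nrow(dv))) {
    s <- as.numeric(dv$startT[i]); e <- as.numeric(dv$endT[i])
    idx <- which(tSec >= s & tSec <= e)
    if (!length(idx)) next
    mid <- (s + e) / 2
    half <- max((e - s) / 2, 0.5)
    depth[idx] <- pmax(depth[idx],
                       dv$maxDepthM[i] * (1 - abs(tSec[idx] - mid) / half))
  }
  data.frame(t = as.POSIXct(tSec, origin = "1970-01-01", tz = "UTC"),
             depth = round(pmax(depth, 0), 1))
}

#' Simulate environmental raster fields
#'
#' Daily sea ice concentration and SST rasters over a box extending at
#' least 130 km past the colony, following the deterministic seasonal
#' curves used for the planted covariates (ice declines, SST rises over
#' the season) plus a weak north-south gradient and seeded cell noise.
#'
#' @param scenario a \linkS4class{SimScenario}.
#' @param noiseSd cell noise SD (ice %; SST uses a tenth of it).
#' @return list with elements \code{ice} and \code{sst}, each an
#'   \linkS4class{EnvField} spanning June 15 to August 15.
#' @export
simulateEnv <- function(scenario, noiseSd = 3) {
  set.seed(scenario@seed + 1L)
  colony <- scenario@colonyLonLat
  lon <- seq(colony[1] - 4, colony[1] + 4, by = 0.25)
  lat <- seq(colony[2] - 1.6, colony[2] + 1.6, by = 0.125)
  times <- SEASON_START + 0:SEASON_DAYS
  nT <- length(times)
  latDev <- outer(rep(1, length(lon)), lat - colony[2])
  ice <- array(0, c(length(lon), length(lat), nT))
  sst <- array(0, c(length(lon), length(lat), nT))
  for (k in seq_len(nT)) {
    d <- k - 1
    ice[, , k] <- pmin(100, pmax(0,
      seasonalIce(d) + 5 * latDev +
        matrix(stats::rnorm(length(lon) * length(lat), 0, noiseSd),
               length(lon))))
    sst[, , k] <- seasonalSst(d) - 0.5 * latDev +
      matrix(stats::rnorm(length(lon) * length(lat), 0, noiseSd / 10),
             length(lon))
  }
  list(
    ice = new("EnvField", variable = "ICE_PCT", lon = lon, lat = lat,
              times = times, values = ice, units = "%"),
    sst = new("EnvField", variable = "SST_C", lon = lon, lat = lat,
              times = times, values = sst, units = "degC"))
}

#' Simulate pre/post biomarker panels
#'
#' Draws positive pre-foraging values per analyte and sets
#' \code{log(post) = log(pre) + sum(effect * covariate) + N(0, noiseSd)},
#' so the log-ratio change score carries the planted standardized
#' effects exactly on average.
#'
#' @param deployments list of \linkS4class{MurreDeployment}.
#' @param scenario a \linkS4class{SimScenario}.
#' @param covariates data.frame with one row per bird: \code{bird_id}
#'   plus standardized \code{ice_z}, \code{sst_z}, \code{chick_age_d}
#'   and \code{sex} columns (as from \code{simulateDeployments()$birds}).
#' @return data.frame with columns bird_id, analyte, pre, post, delta,
#'   time_at_colony_h.
#' @export
simulateBiomarkers <- function(deployments, scenario, covariates) {
  set.seed(scenario@seed + 2L)
  baselines <- c(MASS = 980, TRIG = 1.5, BCORT = 10, BOH = 0.5,
                 NEFA = 0.8)
  rows <- list()
  for (d in deployments) {
    cv <- covariates[covariates$bird_id == d@birdId, , drop = FALSE]
    if (nrow(cv) != 1L)
      stop("missing covariate row for bird ", d@birdId)
    chickZ <- if (is.na(cv$chick_age_d)) 0 else
      (cv$chick_age_d - 10.5) / 5.5
    mu <- scenario@iceEffect * cv$ice_z +
      scenario@sstEffect * cv$sst_z +
      scenario@sexEffect * (cv$sex == "M") +
      scenario@chickageEffect * chickZ
    for (an in names(baselines)) {
      pre <- stats::rlnorm(1, log(baselines[[an]]), 0.15)
      delta <- mu + stats::rnorm(1, 0, scenario@noiseSd)
      rows[[length(rows) + 1L]] <- data.frame(
        bird_id = d@birdId, analyte = an, pre = pre,
        post = pre * exp(delta), delta = delta,
        time_at_colony_h = d@timeAtColonyH)
    }
  }
  do.call(rbind, rows)
}
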