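#' @include AllClasses.R geo.R
NULL

#' Detect dives in a depth trace
#'
#' A dive is a maximal run of samples at or below the detection depth
#' (default 1 m, ten times the 0.1 m sensor resolution); runs separated
#' by at least one surface sample are distinct dives. Duration is the
#' run length at the sampling rate; maximum depth is the run maximum.
#'
#' @param depth numeric depth series (m, non-negative) or a data.frame
#'   with columns \code{t} (POSIXct) and \code{depth}.
#' @param times POSIXct sample times (required when \code{depth} is a
#'   bare vector; defaults to 1 Hz from \code{startT}).
#' @param minDepthM detection threshold (m).
#' @param startT trace start used when \code{times} is NULL.
#' @param hz sampling rate used when \code{times} is NULL.
#' @return data.frame with columns startT, endT, durationMin, maxDepthM.
#' @export
detectDives <- function(depth, times = NULL, minDepthM = 1,
                        startT = as.POSIXct("2018-07-01", tz = "UTC"),
                        hz = 1) {
  if (is.data.frame(depth)) {
    times <- depth$t
    depth <- depth$depth
  }
  if (any(depth < 0, na.rm = TRUE)) stop("negative depth in trace")
  if (is.null(times)) times <- startT + (seq_along(depth) - 1) / hz
  wet <- !is.na(depth) & depth >= minDepthM
  if (!any(wet))
    return(data.frame(startT = as.POSIXct(numeric(0), tz = "UTC",
                                          origin = "1970-01-01"),
                      endT = as.POSIXct(numeric(0), tz = "UTC",
                                        origin = "1970-01-01"),
                      durationMin = numeric(0), maxDepthM = numeric(0)))
  r <- rle(wet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  step <- if (length(times) > 1)
    stats::median(diff(as.numeric(times))) else 1
  data.frame(
    startT = times[starts[runs]],
    endT = times[ends[runs]] + step,
    durationMin = r$lengths[runs] * step / 60,
    maxDepthM = vapply(runs, function(i)
      max(depth[starts[i]:ends[i]]), numeric(1)))
}

#' Group dives into bouts by post-dive interval
#'
#' A new bout begins when the surface gap (next dive start minus
#' previous dive end) exceeds the post-dive interval; a gap exactly
#' equal to it stays within the bout.
#'
#' @param dives data.frame of time-ordered dives (columns startT, endT
#'   and typically maxDepthM).
#' @param pdiMin post-dive interval (minutes, default 5).
#' @return list with \code{dives} (input plus a \code{bout} id column)
#'   and \code{bouts} (one row per bout: bout, nDives, startT, endT).
#' @export
groupBouts <- function(dives, pdiMin = 5) {
  if (!nrow(dives)) {
    dives$bout <- integer(0)
    return(list(dives = dives,
                bouts = data.frame(bout = integer(0), nDives = integer(0))))
  }
  s <- as.numeric(dives$startT)
  e <- as.numeric(dives$endT)
  if (is.unsorted(s)) stop("dives must be time-ordered")
  gaps <- (s[-1] - e[-length(e)]) / 60
  if (any(gaps < 0)) stop("overlapping dives in input")
  bout <- cumsum(c(1L, as.integer(gaps > pdiMin)))
  dives$bout <- bout
  first <- which(!duplicated(bout))
  last <- c(first[-1] - 1L, length(bout))
  bouts <- data.frame(bout = bout[first], nDives = tabulate(bout),
                      startT = dives$startT[first],
                      endT = dives$endT[last])
  list(dives = dives, bouts = bouts)
}

#' Segment a deployment into trips
#'
#' A trip is a maximal interval of non-colony behaviour between leaving
#' and re-entering the COLONY state. Trips cut by the deployment edges
#' are flagged truncated (they contribute dives and distance but are
#' excluded from duration-based means downstream). Departure is the
#' first away fix, return the first colony fix after the trip (for a
#' truncated end, the last fix).
#'
#' @param sequence a \linkS4class{BehaviorSequence} (or character vector
#'   of per-fix states).
#' @param deployment the matching \linkS4class{MurreDeployment}.
#' @return data.frame with one row per trip: trip, departT, returnT,
#'   durationH, maxDistKm, totalDistKm, truncated.
#' @export
segmentTrips <- function(sequence, deployment) {
  states <- if (is.character(sequence)) sequence else sequence@states
  fx <- deployment@fixes
  stopifnot(length(states) == nrow(fx))
  away <- states != "COLONY"
  empty <- data.frame(trip = integer(0), departT = fx$t[0],
                      returnT = fx$t[0], durationH = numeric(0),
                      maxDistKm = numeric(0), totalDistKm = numeric(0),
                      truncated = logical(0))
  if (!any(away)) return(empty)
  r <- rle(away)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  out <- lapply(seq_along(runs), function(k) {
    i0 <- starts[runs[k]]; i1 <- ends[runs[k]]
    truncated <- i0 == 1L || i1 == nrow(fx)
    ## include the bracketing colony fixes in the travelled path
    p0 <- max(1L, i0 - 1L); p1 <- min(nrow(fx), i1 + 1L)
    seg <- fx[p0:p1, , drop = FALSE]
    stepKm <- haversineKm(seg$lon[-nrow(seg)], seg$lat[-nrow(seg)],
                          seg$lon[-1], seg$lat[-1])
    departT <- fx$t[i0]
    returnT <- if (i1 < nrow(fx)) fx$t[i1 + 1L] else fx$t[i1]
    data.frame(trip = k, departT = departT, returnT = returnT,
               durationH = as.numeric(returnT - departT, units = "hours"),
               maxDistKm = max(fx$distColonyKm[i0:i1]),
               totalDistKm = sum(stepKm), truncated = truncated)
  })
  do.call(rbind, out)
}

#' Assign dives to trips
#'
#' @param trips data.frame from \code{\link{segmentTrips}}.
#' @param dives dive table (columns startT, endT, maxDepthM).
#' @return dives with a \code{trip} column (NA when outside all trips).
#' @export
assignDivesToTrips <- function(trips, dives) {
  if (!nrow(dives)) {
    dives$trip <- integer(0)
    return(dives)
  }
  dives$trip <- NA_integer_
  if (!nrow(trips)) return(dives)
  for (k in seq_len(nrow(trips))) {
    hit <- as.numeric(dives$startT) >= as.numeric(trips$departT[k]) &
      as.numeric(dives$startT) < as.numeric(trips$returnT[k])
    dives$trip[hit] <- trips$trip[k]
  }
  dives
}

#' Classify trips as foraging or non-foraging
#'
#' A trip is a foraging trip if it contains more than one dive, or a
#' single dive deeper than the single-dive threshold (default 18.1 m,
#' the across-year median maximum dive depth, which filters single
#' preening dives near the colony). Everything else is non-foraging.
#'
#' @param trips data.frame from \code{\link{segmentTrips}}.
#' @param dives dive table with a \code{trip} column
#'   (\code{\link{assignDivesToTrips}}).
#' @param config a \linkS4class{PipelineConfig}.
#' @return trips with columns nDives, maxDiveDepthM and isForaging added.
#' @export
classifyForaging <- function(trips, dives, config = pipelineConfig()) {
  trips$nDives <- 0L
  trips$maxDiveDepthM <- NA_real_
  if (nrow(dives)) for (k in seq_len(nrow(trips))) {
    d <- dives[!is.na(dives$trip) & dives$trip == trips$trip[k], ,
               drop = FALSE]
    trips$nDives[k] <- nrow(d)
    if (nrow(d)) trips$maxDiveDepthM[k] <- max(d$maxDepthM)
  }
  thr <- config@singleDiveTripThresholdM
  trips$isForaging <- trips$nDives > 1L |
    (trips$nDives == 1L & !is.na(trips$maxDiveDepthM) &
       trips$maxDiveDepthM > thr)
  trips
}

#' Summarize one deployment
#'
#' Collapses classified trips and their dives into the per-deployment
#' metric row used by the statistical layer: five foraging metrics over
#' foraging trips (truncated trips excluded from duration-based means),
#' eight diving metrics over dives within foraging trips, daily energy
#' expenditure, and covariates. Per-day rates divide by deployment days;
#' metrics are NA (not zero) when there are no foraging trips or dives.
#'
#' @param deployment a \linkS4class{MurreDeployment}.
#' @param trips classified trips (\code{\link{classifyForaging}}).
#' @param dives dive table with trip assignment.
#' @param dee daily energy expenditure (kJ/day) from \code{\link{dee}},
#'   or NA.
#' @param config a \linkS4class{PipelineConfig}.
#' @param divesFrom compute diving metrics over dives in foraging trips
#'   only (default) or over all dives ("foraging" or "all").
#' @return one-row data.frame of deployment metrics and covariates.
#' @export
summarizeDeployment <- function(deployment, trips, dives, dee = NA_real_,
                                config = pipelineConfig(),
                                divesFrom = c("foraging", "all")) {
  divesFrom <- match.arg(divesFrom)
  durH <- as.numeric(deployment@endT - deployment@startT, units = "hours")
  if (durH <= 0) stop("zero-duration deployment")
  days <- durH / 24
  ft <- trips[trips$isForaging, , drop = FALSE]
  ftFull <- ft[!ft$truncated, , drop = FALSE]
  dv <- if (divesFrom == "foraging") {
    dives[!is.na(dives$trip) & dives$trip %in% ft$trip, , drop = FALSE]
  } else dives
  db <- groupBouts(dv[order(dv$startT), , drop = FALSE],
                   config@boutPdiMin)
  nb <- nrow(db$bouts)
  diveDurMin <- if (nrow(dv))
    as.numeric(dv$endT - dv$startT, units = "mins") else numeric(0)
  statOr <- function(x, f) if (length(x)) f(x) else NA_real_
  data.frame(
    bird_id = deployment@birdId,
    ## foraging metrics (foraging trips only)
    max_dist_km = statOr(ft$maxDistKm, max),
    mean_daily_dist_km = if (nrow(ft)) sum(ft$totalDistKm) / days
                         else NA_real_,
    mean_trip_dist_km = statOr(ft$totalDistKm, mean),
    mean_trip_dur_h = statOr(ftFull$durationH, mean),
    trips_per_day = nrow(ft) / days,
    ## diving metrics
    max_dive_depth_m = statOr(dv$maxDepthM, max),
    mean_dive_depth_m = statOr(dv$maxDepthM, mean),
    max_dive_dur_min = statOr(diveDurMin, max),
    mean_dive_dur_min = statOr(diveDurMin, mean),
    mean_dives_per_bout = if (nb) nrow(dv) / nb else NA_real_,
    dives_per_day = if (nrow(dv)) nrow(dv) / days else
      if (nrow(ft)) 0 else NA_real_,
    bouts_per_day = if (nb) nb / days else NA_real_,
    time_diving_per_day_h = if (nrow(dv)) sum(diveDurMin) / 60 / days
                            else NA_real_,
    dee_kj_per_day = dee,
    ## covariates
    sex = deployment@sex,
    stage = deployment@stage,
    chick_age_d = deployment@chickAgeD,
    deployment_dur_h = durH,
    stringsAsFactors = FALSE)
}

#' Behavioural sexing from colony attendance
#'
#' Applies the diel attendance rule: females sit on the nest
#' consistently between 23:30 and 03:30, males between 11:30 and 15:30
#' (local solar time, computed as UTC plus longitude / 15). A bird is
#' assigned a sex when, on every observed night (or midday), at least
#' \code{consistency} of its fixes in that sex's window are COLONY and
#' the opposite window fails the same test. Ambiguous birds (both or
#' neither window satisfied) and deployments under 24 h are
#' UNDETERMINED.
#'
#' @param sequence a \linkS4class{BehaviorSequence} or per-fix state
#'   vector.
#' @param deployment the matching \linkS4class{MurreDeployment}.
#' @param consistency minimum COLONY fraction per window occurrence
#'   (default 0.8).
#' @param minFixes minimum fixes for a window occurrence to count.
#' @return "F", "M" or "UNDETERMINED".
#' @export
sexFromAttendance <- function(sequence, deployment, consistency = 0.8,
                              minFixes = 3L) {
  states <- if (is.character(sequence)) sequence else sequence@states
  fx <- deployment@fixes
  if (as.numeric(deployment@endT - deployment@startT,
                 units = "hours") < 24) {
    warning("deployment shorter than 24 h: sex undetermined")
    return("UNDETERMINED")
  }
  solar <- localSolarHour(fx$t, fx$lon)
  atColony <- states == "COLONY"
  ## group window fixes into occurrences (nights / middays)
  consistent <- function(inWin, offsetH) {
    if (!any(inWin)) return(FALSE)
    occ <- as.Date(fx$t[inWin] - offsetH * 3600)
    frac <- tapply(atColony[inWin], occ, mean)
    n <- tapply(atColony[inWin], occ, length)
    frac <- frac[n >= minFixes]
    length(frac) > 0 && all(frac >= consistency)
  }
  fWin <- solar >= 23.5 | solar < 3.5
  mWin <- solar >= 11.5 & solar < 15.5
  isF <- consistent(fWin, offsetH = 3.5)   # group nights by morning end
  isM <- consistent(mWin, offsetH = 0)
  if (isF && !isM) "F" else if (isM && !isF) "M" else "UNDETERMINED"
}
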