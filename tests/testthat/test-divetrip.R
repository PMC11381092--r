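test_that("dive detection reads maximal wet runs from the trace", {
  expect_equal(nrow(detectDives(rep(0, 100))), 0L)
  ## 0,2,10,18,10,2,0 at 1 Hz with threshold 1: one 5-sample dive to 18 m
  d <- detectDives(c(0, 2, 10, 18, 10, 2, 0), minDepthM = 1)
  expect_equal(nrow(d), 1L)
  expect_equal(d$maxDepthM, 18)
  expect_equal(d$durationMin, 5 / 60)
  ## one surface second separates two dives
  d2 <- detectDives(c(0, 5, 5, 0, 5, 5, 0), minDepthM = 1)
  expect_equal(nrow(d2), 2L)
  expect_error(detectDives(c(0, -1, 3)), "negative")
})

test_that("detected dives match the simulator's dive events", {
  sim <- simulateDeployments(simScenario(nBirds = 1, seed = 13))
  d <- sim$deployments[[1]]
  trace <- renderDepthTrace(d)
  det <- detectDives(trace, minDepthM = 1)
  expect_equal(nrow(det), nrow(dives(d)))
  expect_equal(det$maxDepthM, dives(d)$maxDepthM, tolerance = 0.02)
})

test_that("bout grouping follows the post-dive interval rule", {
  ## dives with gaps 2, 3, 10 min and 5-min criterion: bouts of 3 and 1
  dv <- makeDives(startMin = c(0, 3, 7, 18), durMin = 1,
                  maxDepth = c(10, 12, 9, 11))
  g <- groupBouts(dv, pdiMin = 5)
  expect_equal(g$bouts$nDives, c(3L, 1L))
  ## single dive is its own bout
  g1 <- groupBouts(makeDives(0, 1, 10), pdiMin = 5)
  expect_equal(g1$bouts$nDives, 1L)
  ## a gap of exactly 5 minutes stays in-bout
  dv5 <- makeDives(startMin = c(0, 6), durMin = 1, maxDepth = 10)
  expect_equal(nrow(groupBouts(dv5, pdiMin = 5)$bouts), 1L)
  ## overlap is a data error
  bad <- makeDives(startMin = c(0, 0.5), durMin = 1, maxDepth = 10)
  expect_error(groupBouts(bad, pdiMin = 5), "overlap")
})

test_that("bout structure is monotone in the interval and partitions dives", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    starts <- cumsum(runif(n, 1.2, 12))
    dv <- makeDives(starts, durMin = 1, maxDepth = runif(n, 2, 40))
    counts <- vapply(c(1, 2, 5, 8, 15), function(pdi)
      nrow(groupBouts(dv, pdi)$bouts), integer(1))
    expect_true(all(diff(counts) <= 0))
    g <- groupBouts(dv, 5)
    expect_equal(sum(g$bouts$nDives), n)
    expect_equal(sort(unique(g$dives$bout)), g$bouts$bout)
  }
})

test_that("trip segmentation finds away intervals and distances", {
  expect_equal(nrow(segmentTrips(rep("COLONY", 50), makeDeployment(50))),
               0L)
  ## one 6-hour away block at 1-min fixes
  n <- 10 * 60
  states <- rep("COLONY", n)
  states[121:(120 + 360)] <- "SWIM"
  tr <- segmentTrips(states, makeDeployment(n, intervalS = 60))
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$durationH, 6, tolerance = 1e-9)
  expect_false(tr$truncated)
})

test_that("out-and-back track yields max 50 and total 100 km", {
  ## 11 fixes stepped 10 km north then back along a meridian
  stepDeg <- 10 / (2 * pi * 6371 / 360)
  latSeq <- COLONY[2] + c(0:5, 4:0) * stepDeg
  states <- c("COLONY", rep("FLY", 9), "COLONY")
  d <- makeDeployment(11, intervalS = 600, lat = latSeq)
  tr <- segmentTrips(states, d)
  expect_equal(tr$maxDistKm, 50, tolerance = 1e-6)
  expect_equal(tr$totalDistKm, 100, tolerance = 1e-6)
})

test_that("trips cut by deployment edges are flagged truncated", {
  states <- c(rep("FLY", 10), rep("COLONY", 20), rep("SWIM", 10))
  tr <- segmentTrips(states, makeDeployment(40))
  expect_equal(tr$truncated, c(TRUE, TRUE))
})

test_that("foraging classification follows the dive-count and depth rules", {
  cfg <- pipelineConfig()
  trips <- data.frame(trip = 1:4,
                      departT = T0 + c(0, 100, 200, 300) * 60,
                      returnT = T0 + c(90, 190, 290, 390) * 60,
                      durationH = 1.5, maxDistKm = 10, totalDistKm = 20,
                      truncated = FALSE)
  dv <- rbind(
    makeDives(c(10, 20), 1, c(3, 3)),       # trip 1: two shallow dives
    makeDives(150, 1, 20),                  # trip 2: one 20 m dive
    makeDives(250, 1, 5))                   # trip 3: one 5 m dive
  dv <- assignDivesToTrips(trips, dv)
  out <- classifyForaging(trips, dv, cfg)
  expect_equal(out$isForaging, c(TRUE, TRUE, FALSE, FALSE))
  ## exactly at the threshold is NOT foraging (rule is strictly greater)
  dvEq <- assignDivesToTrips(trips, makeDives(150, 1, 18.1))
  expect_false(classifyForaging(trips[2, ], dvEq, cfg)$isForaging)
})

test_that("deployment summary arithmetic matches hand computation", {
  n <- 48 * 60
  states <- rep("COLONY", n)
  states[601:(600 + 240)] <- "SWIM"          # 4 h trip
  states[1501:(1500 + 360)] <- "SWIM"        # 6 h trip
  d <- makeDeployment(n, intervalS = 60)
  dv <- rbind(makeDives(620, 1, 10), makeDives(630, 3, 20),
              makeDives(1520, 1, 15), makeDives(1530, 2, 25))
  d@dives <- dv
  tr <- segmentTrips(states, d)
  dv <- assignDivesToTrips(tr, dv)
  tr <- classifyForaging(tr, dv)
  s <- summarizeDeployment(d, tr, dv)
  expect_equal(s$trips_per_day, 1)
  expect_equal(s$mean_trip_dur_h, 5)
  expect_equal(s$max_dive_depth_m, 25)
  expect_equal(s$mean_dive_depth_m, 17.5)
  expect_equal(s$max_dive_dur_min, 3)
  expect_equal(s$mean_dive_dur_min, 1.75)
  expect_equal(s$dives_per_day, 2)
  expect_equal(s$time_diving_per_day_h, 7 / 60 / 2)
})

test_that("deployments without dives get missing diving metrics", {
  n <- 24 * 60
  states <- rep("COLONY", n)
  states[301:400] <- "FLY"
  d <- makeDeployment(n, intervalS = 60)
  tr <- segmentTrips(states, d)
  dv <- assignDivesToTrips(tr, dives(d))
  tr <- classifyForaging(tr, dv)
  s <- summarizeDeployment(d, tr, dv)
  expect_equal(s$trips_per_day, 0)
  expect_true(is.na(s$max_dive_depth_m))
  expect_true(is.na(s$mean_dives_per_bout))
  expect_true(is.na(s$mean_trip_dur_h))
})

test_that("total distance dominates maximum distance on simulated trips", {
  sim <- simulateDeployments(simScenario(nBirds = 5, seed = 41))
  for (b in seq_along(sim$deployments)) {
    tr <- segmentTrips(sim$truth[[b]], sim$deployments[[b]])
    if (nrow(tr))
      expect_true(all(tr$totalDistKm >= tr$maxDistKm - 1e-9))
  }
})

test_that("behavioural sexing recovers stereotyped attendance schedules", {
  ## 48 h at 10-min fixes; colony longitude makes solar = UTC - 5.467 h
  n <- 48 * 6
  d <- makeDeployment(n, intervalS = 600)
  solar <- localSolarHour(fixes(d)$t, fixes(d)$lon)
  fWin <- solar >= 23.5 | solar < 3.5
  mWin <- solar >= 11.5 & solar < 15.5
  femaleStates <- ifelse(mWin, "SWIM", "COLONY")
  maleStates <- ifelse(fWin, "SWIM", "COLONY")
  expect_equal(sexFromAttendance(femaleStates, d), "F")
  expect_equal(sexFromAttendance(maleStates, d), "M")
  ## always at the colony satisfies both windows: undetermined
  expect_equal(sexFromAttendance(rep("COLONY", n), d), "UNDETERMINED")
  short <- makeDeployment(12, intervalS = 600)
  expect_warning(
    expect_equal(sexFromAttendance(rep("COLONY", 12), short),
                 "UNDETERMINED"), "24 h")
})
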