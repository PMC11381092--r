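test_that("identical seeds give identical deployments", {
  sc <- simScenario(nBirds = 3, seed = 123)
  a <- simulateDeployments(sc)
  b <- simulateDeployments(sc)
  expect_identical(lapply(a$deployments, fixes),
                   lapply(b$deployments, fixes))
  expect_identical(lapply(a$deployments, dives),
                   lapply(b$deployments, dives))
  expect_identical(a$truth, b$truth)
  expect_identical(a$birds, b$birds)
})

test_that("a zero trip rate pins the bird to the colony", {
  sc <- simScenario(nBirds = 2, tripRatePerDay = 0, seed = 3)
  sim <- simulateDeployments(sc)
  for (i in 1:2) {
    expect_true(all(sim$truth[[i]] == "COLONY"))
    expect_true(all(fixes(sim$deployments[[i]])$depth == 0))
    expect_equal(nrow(dives(sim$deployments[[i]])), 0L)
  }
})

test_that("physical ranges hold across a simulated fleet", {
  sim <- simulateDeployments(simScenario(nBirds = 10, seed = 31))
  for (d in sim$deployments) {
    fx <- fixes(d)
    expect_true(all(fx$depth >= 0))
    expect_true(all(fx$wingbeatHz >= 0))
    expect_true(all(fx$distColonyKm >= 0))
    expect_true(all(diff(as.numeric(fx$t)) > 0))
    dv <- dives(d)
    if (nrow(dv))
      expect_true(all(as.numeric(dv$endT) > as.numeric(dv$startT)))
  }
})

test_that("only 1- and 3-minute fix intervals are accepted", {
  expect_error(simScenario(fixIntervalS = 120), "60 or 180")
})

test_that("simulated maximum dive depths have the configured median", {
  ## lognormal with log-location log(18): median 18 m
  sc <- simScenario(nBirds = 120, seed = 77)
  sim <- simulateDeployments(sc)
  depths <- unlist(lapply(sim$deployments,
                          function(d) dives(d)$maxDepthM))
  expect_gt(length(depths), 10000)
  expect_lt(abs(median(depths) / 18 - 1), 0.02)
})

test_that("ground-truth labels reproduce the scenario trip rate", {
  sc <- simScenario(nBirds = 50, seed = 19)
  sim <- simulateDeployments(sc)
  perBird <- vapply(seq_len(50), function(b) {
    tr <- segmentTrips(sim$truth[[b]], sim$deployments[[b]])
    nrow(tr) / sc@days
  }, numeric(1))
  se <- sd(perBird) / sqrt(length(perBird))
  expect_lt(abs(mean(perBird) - sc@tripRatePerDay), 2 * se + 0.05)
})

test_that("dives inside a trip cluster into bouts under the 5-min criterion", {
  sim <- simulateDeployments(simScenario(nBirds = 5, seed = 23))
  for (b in 1:5) {
    dv <- dives(sim$deployments[[b]])
    if (nrow(dv) < 2) next
    g <- groupBouts(dv, pdiMin = 5)
    expect_equal(sum(g$bouts$nDives), nrow(dv))
    ## multi-dive bouts exist: within-run surface gaps are short
    expect_gt(max(g$bouts$nDives), 1)
  }
})

test_that("attendance windows separate the sexes without mislabeling", {
  sim <- simulateDeployments(simScenario(nBirds = 20, seed = 29))
  for (b in 1:20) {
    inferred <- suppressWarnings(
      sexFromAttendance(sim$truth[[b]], sim$deployments[[b]]))
    if (inferred != "UNDETERMINED")
      expect_equal(inferred, sim$deployments[[b]]@sex)
  }
})

test_that("biomarker deltas are exactly the planted linear predictor at zero noise", {
  sc0 <- simScenario(nBirds = 10, noiseSd = 0, seed = 5)
  sim <- simulateDeployments(sc0)
  bm0 <- simulateBiomarkers(sim$deployments, sc0, sim$birds)
  expect_equal(bm0$delta, rep(0, nrow(bm0)))
  expect_equal(bm0$post, bm0$pre)
  ## planted ice effect, zero noise: delta = 0.5 * ice_z exactly
  scI <- simScenario(nBirds = 10, noiseSd = 0, iceEffect = 0.5,
                     stage = "INCUBATION", seed = 5)
  simI <- simulateDeployments(scI)
  bmI <- simulateBiomarkers(simI$deployments, scI, simI$birds)
  merged <- merge(bmI, simI$birds, by = "bird_id")
  expect_equal(merged$delta, 0.5 * merged$ice_z, tolerance = 1e-12)
  ## a missing covariate row names the bird
  expect_error(simulateBiomarkers(sim$deployments, sc0,
                                  sim$birds[-1, ]),
               sim$deployments[[1]]@birdId)
})

test_that("rendered depth traces honour dive timing and sensor resolution", {
  sim <- simulateDeployments(simScenario(nBirds = 1, seed = 59))
  d <- sim$deployments[[1]]
  tr <- renderDepthTrace(d)
  expect_true(all(tr$depth >= 0))
  expect_equal(tr$depth, round(tr$depth, 1))
  dv <- dives(d)
  outside <- rep(TRUE, nrow(tr))
  for (i in seq_len(nrow(dv))) {
    inside <- tr$t >= dv$startT[i] & tr$t <= dv$endT[i]
    outside[inside] <- FALSE
  }
  expect_true(all(tr$depth[outside] == 0))
})
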