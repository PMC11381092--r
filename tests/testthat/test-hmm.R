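test_that("forward log-likelihood matches closed form on one fix", {
  set.seed(21)
  spec <- randomSpec(3)
  obs <- simulateHMMSeq(spec, 1)$obs
  logE <- murreforage:::emissionLogMatrix(obs, spec)
  expect_equal(forwardLogLik(obs, spec),
               log(sum(spec@init * exp(logE[1, ]))), tolerance = 1e-12)
})

test_that("forward and Viterbi match exhaustive enumeration on short sequences", {
  set.seed(22)
  for (i in 1:30) {
    S <- sample(2:4, 1)
    n <- sample(2:8, 1)
    spec <- randomSpec(S)
    obs <- simulateHMMSeq(spec, n)$obs
    oracle <- enumeratePaths(spec, obs)
    expect_equal(forwardLogLik(obs, spec), oracle$logLik,
                 tolerance = 1e-9)
    got <- murreforage:::viterbiPath(
      murreforage:::emissionLogMatrix(obs, spec), spec@init, spec@trans)
    expect_equal(got, oracle$bestPath)
  }
})

test_that("decoding is invariant to state relabeling", {
  set.seed(23)
  spec <- randomSpec(4)
  obs <- simulateHMMSeq(spec, 200)$obs
  perm <- c(3, 1, 4, 2)
  permSpec <- hmmSpec(spec@states[perm], spec@init[perm],
                      spec@trans[perm, perm], spec@emissions[perm])
  p1 <- murreforage:::viterbiPath(
    murreforage:::emissionLogMatrix(obs, spec), spec@init, spec@trans)
  p2 <- murreforage:::viterbiPath(
    murreforage:::emissionLogMatrix(obs, permSpec), permSpec@init,
    permSpec@trans)
  expect_equal(spec@states[p1], permSpec@states[p2])
})

test_that("an observation impossible in every state is an error", {
  spec <- defaultHMMSpec()
  ## pi0 = 0 for wingbeat in every state makes an exact zero impossible
  em <- lapply(spec@emissions, function(e) {
    e$wingbeat[1] <- 0
    e
  })
  spec0 <- hmmSpec(spec@states, spec@init, spec@trans, em)
  obs <- cbind(wingbeat = 0, depth = 0, pitch = 10, dist = 0.1)
  expect_error(forwardLogLik(obs, spec0), "impossible")
})

test_that("all-missing fixes decode from transition structure alone", {
  spec <- defaultHMMSpec()
  d <- makeDeployment(10, depth = NA_real_, wingbeat = NA_real_,
                      pitch = NA_real_)
  d@fixes$distColonyKm <- NA_real_
  bs <- decodeBehavior(d, spec)
  expect_length(stateLabels(bs), 10)
  ## COLONY has the largest initial probability and strong persistence
  expect_true(all(stateLabels(bs) == "COLONY"))
})

test_that("well-separated emissions give >= 90% decoding accuracy", {
  spec <- defaultHMMSpec()
  sim <- simulateHMMSeq(spec, 10000, seed = 99)
  d <- makeDeployment(10000)
  d@fixes$wingbeatHz <- sim$obs[, "wingbeat"]
  d@fixes$depth <- sim$obs[, "depth"]
  d@fixes$pitch <- sim$obs[, "pitch"]
  d@fixes$distColonyKm <- sim$obs[, "dist"]
  bs <- decodeBehavior(d, spec)
  expect_gte(mean(stateLabels(bs) == sim$labels), 0.90)
})

test_that("EM log-likelihood is monotone and near-stationary at the truth", {
  spec <- defaultHMMSpec()
  obsList <- lapply(1:2, function(i) simulateHMMSeq(spec, 800,
                                                    seed = 30 + i)$obs)
  fit <- fitHMM(obsList, spec, maxIter = 50, tol = 0)
  expect_true(all(diff(fit$logLikTrace) >= -1e-6))
  gain <- fit$logLik - fit$logLikTrace[1]
  expect_lt(gain, 0.01 * abs(fit$logLikTrace[1]))
})

test_that("single-state-support data forces COLONY self-transition to 1", {
  ## every fix looks like colony: zero wingbeat and depth, upright
  ## pitch, at the colony. A two-state model whose FLY state overlaps
  ## the data weakly (so it is not fully starved) must concentrate the
  ## COLONY self-transition at 1.
  d <- makeDeployment(400, depth = 0, wingbeat = 0, pitch = 60)
  spec2 <- hmmSpec(
    c("COLONY", "FLY"), init = c(0.6, 0.4),
    trans = matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2, byrow = TRUE),
    emissions = list(
      COLONY = list(wingbeat = c(0.7, 2, 2), depth = c(0.9, 2, 1),
                    pitch = c(60, 15), dist = c(0.6, 1.5, 10)),
      FLY = list(wingbeat = c(0.3, 5, 1), depth = c(0.9, 2, 1),
                 pitch = c(0, 15), dist = c(0.3, 2, 0.5))))
  fit <- fitHMM(list(d), spec2, maxIter = 10, tol = 1e-8)
  expect_gte(fit$spec@trans[1, 1], 0.99)
})

test_that("a starved state raises a degenerate-state error", {
  spec <- defaultHMMSpec()
  ## make DIVE unreachable and impossible: no mass anywhere near its
  ## emissions and zero transition into it
  em <- spec@emissions
  em$DIVE$pitch <- c(1e5, 0.01)
  em$DIVE$depth <- c(1e-6, 500, 0.01)
  trans <- spec@trans
  trans[, 4] <- 0
  trans <- trans / rowSums(trans)
  init <- c(0.5, 0.3, 0.2, 0)
  spec2 <- hmmSpec(spec@states, init, trans, em)
  d <- makeDeployment(100, depth = 0, wingbeat = 0, pitch = 60)
  expect_error(fitHMM(list(d), spec2, maxIter = 5), "DIVE")
})

test_that("k-means initialization labels the four behaviours correctly", {
  sim <- simulateDeployments(simScenario(nBirds = 4, seed = 17))
  sp <- initialSpecKmeans(sim$deployments, seed = 1)
  expect_equal(sp@states, BEHAVIOR_STATES)
  ## DIVE carries the deep depths, FLY the high wing-beat
  expect_gt(sp@emissions$DIVE$depth[2] / sp@emissions$DIVE$depth[3], 5)
  expect_gt(sp@emissions$FLY$wingbeat[2] / sp@emissions$FLY$wingbeat[3], 5)
  expect_lt(sp@emissions$FLY$wingbeat[1], 0.2)
})
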