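## shared fixtures: hand-built deployments and exhaustive HMM oracles

T0 <- as.POSIXct("2018-07-10 00:00:00", tz = "UTC")
COLONY <- c(-82.01, 62.95)

## deployment with explicit per-fix channels; positions default to the
## colony unless lon/lat given
makeDeployment <- function(n, intervalS = 60, lon = NULL, lat = NULL,
                           depth = 0, wingbeat = 0, pitch = 0,
                           birdId = "testbird", sex = "UNKNOWN",
                           stage = "CHICK_REARING", chickAge = 5,
                           startT = T0, dives = NULL) {
  t <- startT + (seq_len(n) - 1) * intervalS
  if (is.null(lon)) lon <- rep(COLONY[1], n)
  if (is.null(lat)) lat <- rep(COLONY[2], n)
  fx <- data.frame(
    t = t, lon = lon, lat = lat,
    depth = rep_len(depth, n),
    wingbeatHz = rep_len(wingbeat, n),
    pitch = rep_len(pitch, n),
    distColonyKm = murreforage::haversineKm(COLONY[1], COLONY[2], lon, lat))
  new("MurreDeployment", birdId = birdId, sex = sex, stage = stage,
      chickAgeD = if (stage == "INCUBATION") NA_real_ else chickAge,
      startT = t[1], endT = t[n] + intervalS, fixes = fx,
      dives = if (is.null(dives)) murreforage:::emptyDiveTable() else dives,
      massPreG = NA_real_, massPostG = NA_real_,
      timeAtColonyH = NA_real_)
}

## dive table from start offsets (minutes from T0), durations (min), depths
makeDives <- function(startMin, durMin, maxDepth) {
  data.frame(startT = T0 + startMin * 60,
             endT = T0 + (startMin + durMin) * 60,
             maxDepthM = maxDepth)
}

## absolute cosine similarity between all column pairs of two matrices
colCongruence <- function(M1, M2) {
  n1 <- sweep(M1, 2, sqrt(colSums(M1^2)), "/")
  n2 <- sweep(M2, 2, sqrt(colSums(M2^2)), "/")
  abs(crossprod(n1, n2))
}

## random HMM spec over S states with the package's channel structure
randomSpec <- function(S) {
  rdir <- function(k) { g <- stats::rgamma(k, 1); g / sum(g) }
  trans <- t(vapply(seq_len(S), function(i) rdir(S), numeric(S)))
  em <- lapply(seq_len(S), function(s) list(
    wingbeat = c(runif(1, 0.1, 0.9), runif(1, 0.5, 5), runif(1, 0.2, 3)),
    depth = c(runif(1, 0.1, 0.9), runif(1, 0.5, 5), runif(1, 0.2, 3)),
    pitch = c(runif(1, -50, 50), runif(1, 3, 15)),
    dist = c(runif(1, 0.1, 0.9), runif(1, 0.5, 5), runif(1, 0.2, 3))))
  murreforage::hmmSpec(paste0("S", seq_len(S)), rdir(S), trans, em)
}

## exhaustive enumeration over all S^T state paths: marginal likelihood
## and the maximum-probability path
enumeratePaths <- function(spec, obs) {
  S <- length(spec@states)
  T_ <- nrow(obs)
  logE <- murreforage:::emissionLogMatrix(obs, spec)
  paths <- as.matrix(expand.grid(replicate(T_, seq_len(S),
                                           simplify = FALSE)))
  lp <- log(spec@init)[paths[, 1]]
  if (T_ > 1) for (t in 2:T_) {
    lp <- lp + log(spec@trans)[cbind(paths[, t - 1], paths[, t])]
  }
  for (t in seq_len(T_)) lp <- lp + logE[cbind(t, paths[, t])]
  m <- max(lp)
  list(logLik = m + log(sum(exp(lp - m))),
       bestPath = unname(paths[which.max(lp), ]))
}
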