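#' @include AllClasses.R
NULL

## ---- spec construction -------------------------------------------------

#' Construct an HMM specification
#'
#' @param states character state labels (decoding order; ties in Viterbi
#'   break toward the earlier label).
#' @param init initial state probabilities.
#' @param trans row-stochastic transition matrix.
#' @param emissions per-state emission parameter lists; see
#'   \linkS4class{HMMSpec}.
#' @return a validated \linkS4class{HMMSpec}.
#' @export
hmmSpec <- function(states, init, trans, emissions) {
  dimnames(trans) <- list(states, states)
  new("HMMSpec", states = states, init = init, trans = trans,
      emissions = emissions)
}

emis <- function(wingbeat, depth, pitch, dist) {
  list(wingbeat = wingbeat, depth = depth, pitch = pitch, dist = dist)
}

#' Default four-state behaviour model
#'
#' A hand-specified starting model for the four murre behaviours.
#' Colony: zero wing-beat and depth, upright pitch, distance pinned near
#' zero. Flight: ~8.5 Hz wing-beat, level pitch. Swimming: zero
#' wing-beat and depth, slightly negative pitch, offshore distances.
#' Diving: steep negative pitch and positive depth. Used as the EM
#' starting point and as the generating truth of the synthetic scenario.
#'
#' @return an \linkS4class{HMMSpec}.
#' @export
defaultHMMSpec <- function() {
  trans <- matrix(c(
    0.96, 0.04, 0.00, 0.00,
    0.05, 0.85, 0.10, 0.00,
    0.00, 0.05, 0.75, 0.20,
    0.00, 0.01, 0.39, 0.60), 4, 4, byrow = TRUE)
  hmmSpec(
    states = BEHAVIOR_STATES,
    init = c(0.7, 0.1, 0.1, 0.1),
    trans = trans,
    emissions = list(
      COLONY = emis(wingbeat = c(0.95, 2, 2), depth = c(0.995, 2, 1),
                    pitch = c(60, 10), dist = c(0.60, 1.5, 10)),
      FLY    = emis(wingbeat = c(0.02, 50, 50 / 8.5), depth = c(0.995, 2, 1),
                    pitch = c(5, 10), dist = c(0.01, 2, 0.12)),
      SWIM   = emis(wingbeat = c(0.95, 2, 2), depth = c(0.98, 2, 1),
                    pitch = c(-10, 10), dist = c(0.01, 2, 0.12)),
      DIVE   = emis(wingbeat = c(0.95, 2, 2), depth = c(0.02, 4, 4 / 18),
                    pitch = c(-40, 15), dist = c(0.01, 2, 0.12))))
}

## ---- observation channels ----------------------------------------------

#' Observation channel matrix of a deployment
#'
#' Extracts the four HMM observation channels from the fix table:
#' wing-beat frequency (Hz), per-fix depth (m), pitch (degrees) and
#' distance from colony (km).
#'
#' @param deployment a \linkS4class{MurreDeployment}.
#' @return numeric matrix with columns wingbeat, depth, pitch, dist.
#' @export
obsChannels <- function(deployment) {
  fx <- deployment@fixes
  cbind(wingbeat = fx$wingbeatHz, depth = fx$depth, pitch = fx$pitch,
        dist = fx$distColonyKm)
}

## zero-inflated gamma log density; NA contributes 0 (channel skipped)
ziGammaLogDens <- function(x, p) {
  out <- numeric(length(x))
  zero <- !is.na(x) & x == 0
  pos <- !is.na(x) & x > 0
  out[zero] <- log(p[1])
  out[pos] <- log1p(-p[1]) +
    stats::dgamma(x[pos], shape = p[2], rate = p[3], log = TRUE)
  out
}

#' Per-fix emission log-likelihood matrix
#'
#' @param obs observation matrix from \code{\link{obsChannels}}.
#' @param spec an \linkS4class{HMMSpec}.
#' @return T x S matrix of log emission densities; missing channel
#'   values contribute zero to their row.
#' @keywords internal
emissionLogMatrix <- function(obs, spec) {
  S <- length(spec@states)
  out <- matrix(0, nrow(obs), S)
  for (s in seq_len(S)) {
    e <- spec@emissions[[s]]
    ll <- ziGammaLogDens(obs[, "wingbeat"], e$wingbeat) +
      ziGammaLogDens(obs[, "depth"], e$depth) +
      ziGammaLogDens(obs[, "dist"], e$dist)
    pch <- obs[, "pitch"]
    ok <- !is.na(pch)
    ll[ok] <- ll[ok] +
      stats::dnorm(pch[ok], e$pitch[1], e$pitch[2], log = TRUE)
    out[, s] <- ll
  }
  out
}

## scaled forward pass; returns alphaHat, scale logs, total loglik
forwardPass <- function(logE, init, trans) {
  T_ <- nrow(logE); S <- ncol(logE)
  shift <- apply(logE, 1, max)
  if (any(!is.finite(shift)))
    stop("observation impossible in every state: forward likelihood is zero")
  E <- exp(logE - shift)
  alpha <- matrix(0, T_, S)
  logc <- numeric(T_)
  a <- init * E[1, ]
  c1 <- sum(a)
  if (c1 <= 0)
    stop("observation impossible in every state: forward likelihood is zero")
  alpha[1, ] <- a / c1; logc[1] <- log(c1)
  if (T_ > 1) for (t in 2:T_) {
    a <- as.vector(alpha[t - 1, ] %*% trans) * E[t, ]
    ct <- sum(a)
    if (ct <= 0)
      stop("observation impossible in every state: forward likelihood is zero")
    alpha[t, ] <- a / ct; logc[t] <- log(ct)
  }
  list(alpha = alpha, logc = logc, E = E, shift = shift,
       logLik = sum(logc) + sum(shift))
}

#' Forward-algorithm log-likelihood
#'
#' Marginal log-likelihood of a deployment's observations under an HMM,
#' summing over all state paths (scaled forward recursion).
#'
#' @param deployment a \linkS4class{MurreDeployment}, or an observation
#'   matrix from \code{\link{obsChannels}}.
#' @param spec an \linkS4class{HMMSpec}.
#' @return log-likelihood in nats.
#' @export
forwardLogLik <- function(deployment, spec) {
  obs <- if (is.matrix(deployment)) deployment else obsChannels(deployment)
  validObject(spec)
  if (any(!vapply(spec@emissions,
                  function(e) all(is.finite(unlist(e))), logical(1))))
    stop("non-finite emission parameter")
  logE <- emissionLogMatrix(obs, spec)
  forwardPass(logE, spec@init, spec@trans)$logLik
}

## ---- Viterbi -----------------------------------------------------------

viterbiPath <- function(logE, init, trans) {
  T_ <- nrow(logE); S <- ncol(logE)
  logT <- log(trans)
  delta <- log(init) + logE[1, ]
  ptr <- matrix(1L, T_, S)
  if (T_ > 1) for (t in 2:T_) {
    m <- delta + logT                 # m[i, j] = delta[i] + logT[i, j]
    best <- max.col(t(m), ties.method = "first")
    delta <- m[cbind(best, seq_len(S))] + logE[t, ]
    ptr[t, ] <- best
  }
  path <- integer(T_)
  path[T_] <- which.max(delta)        # first max: lower index wins ties
  if (T_ > 1) for (t in (T_ - 1):1) path[t] <- ptr[t + 1, path[t + 1]]
  path
}

#' Viterbi decoding of a deployment
#'
#' Maximum a posteriori joint state path with ties broken toward the
#' earlier state label, plus the forward marginal log-likelihood.
#' All-missing fix rows carry no emission information and are assigned
#' by the transition structure alone.
#'
#' @param deployment a \linkS4class{MurreDeployment}.
#' @param spec an \linkS4class{HMMSpec}.
#' @return a \linkS4class{BehaviorSequence}.
#' @export
decodeBehavior <- function(deployment, spec) {
  validObject(spec)
  obs <- obsChannels(deployment)
  logE <- emissionLogMatrix(obs, spec)
  path <- viterbiPath(logE, spec@init, spec@trans)
  ll <- forwardPass(logE, spec@init, spec@trans)$logLik
  new("BehaviorSequence", deploymentId = deployment@birdId,
      states = spec@states[path], logLik = ll, spec = spec)
}

#' Decode a fleet of equal-length deployments at once
#'
#' Identical to calling \code{\link{decodeBehavior}} per deployment, but
#' the Viterbi and forward recursions run over all birds simultaneously,
#' which is much faster for fleets of deployments sharing one fix count
#' (the usual case for a common sampling protocol).
#'
#' @param deployments list of \linkS4class{MurreDeployment} with equal
#'   numbers of fixes.
#' @param spec an \linkS4class{HMMSpec}.
#' @return list of \linkS4class{BehaviorSequence}.
#' @export
decodeFleet <- function(deployments, spec) {
  validObject(spec)
  nFix <- vapply(deployments, function(d) nrow(d@fixes), integer(1))
  if (length(unique(nFix)) != 1L)
    return(lapply(deployments, decodeBehavior, spec = spec))
  B <- length(deployments); T_ <- nFix[1]; S <- length(spec@states)
  E3 <- array(0, c(B, S, T_))
  for (b in seq_len(B)) {
    logE <- emissionLogMatrix(obsChannels(deployments[[b]]), spec)
    E3[b, , ] <- t(logE)
  }
  logT <- log(spec@trans)
  ## joint Viterbi over birds
  delta <- matrix(log(spec@init), B, S, byrow = TRUE) + E3[, , 1]
  ptr <- array(1L, c(T_, B, S))
  if (T_ > 1) for (t in 2:T_) {
    newDelta <- matrix(0, B, S)
    for (j in seq_len(S)) {
      cand <- delta + matrix(logT[, j], B, S, byrow = TRUE)
      best <- max.col(cand, ties.method = "first")
      ptr[t, , j] <- best
      newDelta[, j] <- cand[cbind(seq_len(B), best)]
    }
    delta <- newDelta + E3[, , t]
  }
  paths <- matrix(0L, T_, B)
  paths[T_, ] <- max.col(delta, ties.method = "first")
  if (T_ > 1) for (t in (T_ - 1):1)
    paths[t, ] <- ptr[cbind(t + 1L, seq_len(B), paths[t + 1, ])]
  ## joint scaled forward pass
  shift <- apply(E3, c(1, 3), max)                  # B x T
  if (any(!is.finite(shift)))
    stop("observation impossible in every state: forward likelihood is zero")
  ll <- rowSums(shift)
  alpha <- matrix(spec@init, B, S, byrow = TRUE) *
    exp(E3[, , 1] - shift[, 1])
  cs <- rowSums(alpha)
  ll <- ll + log(cs); alpha <- alpha / cs
  if (T_ > 1) for (t in 2:T_) {
    alpha <- (alpha %*% spec@trans) * exp(E3[, , t] - shift[, t])
    cs <- rowSums(alpha)
    if (any(cs <= 0))
      stop("observation impossible in every state: forward likelihood is zero")
    ll <- ll + log(cs); alpha <- alpha / cs
  }
  lapply(seq_len(B), function(b)
    new("BehaviorSequence", deploymentId = deployments[[b]]@birdId,
        states = spec@states[paths[, b]], logLik = ll[b], spec = spec))
}

## ---- Baum-Welch --------------------------------------------------------

## weighted gamma MLE: solve log(shape) - digamma(shape) = s by Newton,
## iterated to convergence so the M-step is an exact maximizer (EM
## monotonicity depends on it)
gammaMleFromStats <- function(wSum, xSum, logxSum, fallback) {
  if (wSum <= 0 || xSum <= 0) return(fallback)
  mu <- xSum / wSum
  s <- log(mu) - logxSum / wSum
  if (!is.finite(s)) return(fallback)
  ## the shape is capped: a near-zero-spread channel would otherwise
  ## spike the density without bound. Given the cap, rate = shape/mu is
  ## still the profile maximizer, so EM stays monotone within the
  ## constrained family.
  cap <- c(1e-4, 1e4)
  if (s <= 1e-12) return(c(cap[2], cap[2] / mu))
  shape <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  shape <- min(max(shape, cap[1]), cap[2])
  for (i in 1:50) {
    f <- log(shape) - digamma(shape) - s
    if (abs(f) < 1e-13) break
    step <- f / (1 / shape - trigamma(shape))
    shapeNew <- shape - step
    if (!is.finite(shapeNew) || shapeNew <= 0) shapeNew <- shape / 2
    shape <- min(max(shapeNew, cap[1]), cap[2])
  }
  c(shape, shape / mu)
}

mstepZiGamma <- function(W, W0, Sx, Slx, prev) {
  pi0 <- if (W > 0) min(max(W0 / W, 1e-6), 1 - 1e-6) else prev[1]
  g <- gammaMleFromStats(W - W0, Sx, Slx, prev[2:3])
  c(pi0, g)
}

#' Fit the behaviour HMM by Baum-Welch EM
#'
#' Expectation-maximization for the multivariate four-channel HMM.
#' Multiple deployments are treated as independent sequences sharing one
#' parameter set. The total log-likelihood is checked to be
#' non-decreasing at every iteration; fitting stops when the improvement
#' drops below \code{tol} or after \code{maxIter} iterations. Optional
#' random restarts perturb the starting emissions and keep the best
#' final likelihood.
#'
#' @param deployments list of \linkS4class{MurreDeployment} (or
#'   observation matrices).
#' @param initSpec starting \linkS4class{HMMSpec}; see
#'   \code{\link{initialSpecKmeans}} for a data-driven start.
#' @param maxIter maximum EM iterations.
#' @param tol log-likelihood improvement (nats) below which EM stops.
#' @param nRestarts number of perturbed restarts in addition to
#'   \code{initSpec} itself.
#' @param seed integer seed for the restarts.
#' @return list with \code{spec} (fitted \linkS4class{HMMSpec}),
#'   \code{logLik}, and \code{logLikTrace}.
#' @export
fitHMM <- function(deployments, initSpec, maxIter = 100, tol = 1e-4,
                   nRestarts = 0, seed = 1L) {
  if (!length(deployments)) stop("need at least one deployment")
  obsList <- lapply(deployments, function(d)
    if (is.matrix(d)) d else obsChannels(d))
  runs <- list(emFit(obsList, initSpec, maxIter, tol))
  if (nRestarts > 0) {
    set.seed(seed)
    for (r in seq_len(nRestarts)) {
      sp <- perturbSpec(initSpec)
      runs[[r + 1]] <- tryCatch(emFit(obsList, sp, maxIter, tol),
                                error = function(e) NULL)
    }
    runs <- Filter(Negate(is.null), runs)
  }
  best <- which.max(vapply(runs, `[[`, numeric(1), "logLik"))
  runs[[best]]
}

perturbSpec <- function(spec) {
  em <- lapply(spec@emissions, function(e) {
    list(wingbeat = c(e$wingbeat[1],
                      e$wingbeat[2:3] * exp(stats::rnorm(2, 0, 0.3))),
         depth = c(e$depth[1], e$depth[2:3] * exp(stats::rnorm(2, 0, 0.3))),
         pitch = c(e$pitch[1] + stats::rnorm(1, 0, 5),
                   e$pitch[2] * exp(stats::rnorm(1, 0, 0.2))),
         dist = c(e$dist[1], e$dist[2:3] * exp(stats::rnorm(2, 0, 0.3))))
  })
  hmmSpec(spec@states, spec@init, spec@trans, em)
}

emFit <- function(obsList, spec, maxIter, tol) {
  S <- length(spec@states)
  logEs <- lapply(obsList, emissionLogMatrix, spec = spec)
  prevLL <- -Inf
  trace <- numeric(0)
  for (iter in seq_len(maxIter)) {
    initAcc <- numeric(S)
    transNum <- matrix(0, S, S)
    stateW <- numeric(S)
    ## per state x channel sufficient statistics
    zi <- array(0, c(S, 3, 3),
                dimnames = list(NULL, c("wingbeat", "depth", "dist"),
                                c("W", "W0", "Sx")))
    ziLog <- matrix(0, S, 3,
                    dimnames = list(NULL, c("wingbeat", "depth", "dist")))
    pitchW <- numeric(S); pitchSx <- numeric(S); pitchSxx <- numeric(S)
    totalLL <- 0
    for (k in seq_along(obsList)) {
      obs <- obsList[[k]]
      logE <- logEs[[k]]
      fw <- forwardPass(logE, spec@init, spec@trans)
      totalLL <- totalLL + fw$logLik
      T_ <- nrow(logE)
      beta <- matrix(0, T_, S)
      beta[T_, ] <- 1
      if (T_ > 1) for (t in (T_ - 1):1) {
        b <- spec@trans %*% (fw$E[t + 1, ] * beta[t + 1, ])
        beta[t, ] <- b / exp(fw$logc[t + 1])
      }
      g <- fw$alpha * beta
      g <- g / rowSums(g)
      initAcc <- initAcc + g[1, ]
      if (T_ > 1) for (t in 1:(T_ - 1)) {
        xi <- (fw$alpha[t, ] %o% (fw$E[t + 1, ] * beta[t + 1, ])) *
          spec@trans / exp(fw$logc[t + 1])
        transNum <- transNum + xi / sum(xi)
      }
      stateW <- stateW + colSums(g)
      for (ch in c("wingbeat", "depth", "dist")) {
        x <- obs[, ch]
        ok <- !is.na(x)
        zero <- ok & x == 0
        pos <- ok & x > 0
        zi[, ch, "W"] <- zi[, ch, "W"] + colSums(g[ok, , drop = FALSE])
        zi[, ch, "W0"] <- zi[, ch, "W0"] + colSums(g[zero, , drop = FALSE])
        zi[, ch, "Sx"] <- zi[, ch, "Sx"] +
          colSums(g[pos, , drop = FALSE] * x[pos])
        ziLog[, ch] <- ziLog[, ch] +
          colSums(g[pos, , drop = FALSE] * log(x[pos]))
      }
      p <- obs[, "pitch"]
      ok <- !is.na(p)
      pitchW <- pitchW + colSums(g[ok, , drop = FALSE])
      pitchSx <- pitchSx + colSums(g[ok, , drop = FALSE] * p[ok])
      pitchSxx <- pitchSxx + colSums(g[ok, , drop = FALSE] * p[ok]^2)
    }
    trace <- c(trace, totalLL)
    if (totalLL < prevLL - 1e-6)
      stop(sprintf("EM log-likelihood decreased (%.6f -> %.6f)",
                   prevLL, totalLL))
    starved <- stateW < 1e-8
    if (any(starved))
      stop("degenerate state (no responsibility): ",
           paste(spec@states[starved], collapse = ", "))
    converged <- is.finite(prevLL) && (totalLL - prevLL) < tol
    if (converged) break
    prevLL <- totalLL
    ## M step
    init <- initAcc / sum(initAcc)
    trans <- transNum / rowSums(transNum)
    em <- spec@emissions
    for (s in seq_len(S)) {
      for (ch in c("wingbeat", "depth", "dist")) {
        em[[s]][[ch]] <- mstepZiGamma(zi[s, ch, "W"], zi[s, ch, "W0"],
                                      zi[s, ch, "Sx"], ziLog[s, ch],
                                      em[[s]][[ch]])
      }
      if (pitchW[s] > 0) {
        m <- pitchSx[s] / pitchW[s]
        v <- pitchSxx[s] / pitchW[s] - m^2
        em[[s]]$pitch <- c(m, sqrt(max(v, 1e-6)))
      }
    }
    spec <- hmmSpec(spec@states, init, trans, em)
    logEs <- lapply(obsList, emissionLogMatrix, spec = spec)
  }
  list(spec = spec, logLik = trace[length(trace)], logLikTrace = trace,
       iterations = length(trace))
}

## ---- data-driven initialization ----------------------------------------

#' K-means starting model for the behaviour HMM
#'
#' Clusters complete observation rows into four groups with k-means and
#' labels them by channel signatures (deepest mean depth is DIVE,
#' highest wing-beat is FLY, smallest distance among the rest is COLONY,
#' the remainder SWIM); moment-matched emissions and empirical cluster
#' transitions give the starting HMM.
#'
#' @param deployments list of \linkS4class{MurreDeployment} (or
#'   observation matrices).
#' @param seed k-means seed.
#' @return an \linkS4class{HMMSpec}.
#' @export
initialSpecKmeans <- function(deployments, seed = 1L) {
  obs <- do.call(rbind, lapply(deployments, function(d)
    if (is.matrix(d)) d else obsChannels(d)))
  ok <- stats::complete.cases(obs)
  X <- scale(obs[ok, , drop = FALSE])
  set.seed(seed)
  km <- stats::kmeans(X, centers = 4, nstart = 5)
  cl <- km$cluster
  raw <- obs[ok, , drop = FALSE]
  mDepth <- tapply(raw[, "depth"], cl, mean)
  mWb <- tapply(raw[, "wingbeat"], cl, mean)
  mDist <- tapply(raw[, "dist"], cl, mean)
  lab <- rep(NA_character_, 4)
  lab[which.max(mDepth)] <- "DIVE"
  remaining <- which(is.na(lab))
  lab[remaining[which.max(mWb[remaining])]] <- "FLY"
  remaining <- which(is.na(lab))
  lab[remaining[which.min(mDist[remaining])]] <- "COLONY"
  lab[is.na(lab)] <- "SWIM"
  em <- vector("list", 4)
  names(em) <- BEHAVIOR_STATES
  for (s in seq_along(BEHAVIOR_STATES)) {
    k <- which(lab == BEHAVIOR_STATES[s])
    sub <- raw[cl == k, , drop = FALSE]
    em[[s]] <- list(
      wingbeat = momentZiGamma(sub[, "wingbeat"]),
      depth = momentZiGamma(sub[, "depth"]),
      pitch = c(mean(sub[, "pitch"]), max(stats::sd(sub[, "pitch"]), 1)),
      dist = momentZiGamma(sub[, "dist"]))
  }
  stateSeq <- match(lab[cl], BEHAVIOR_STATES)
  trans <- matrix(1, 4, 4)          # Laplace smoothing
  for (t in seq_len(length(stateSeq) - 1))
    trans[stateSeq[t], stateSeq[t + 1]] <-
      trans[stateSeq[t], stateSeq[t + 1]] + 1
  trans <- trans / rowSums(trans)
  init <- tabulate(stateSeq, 4) + 1
  hmmSpec(BEHAVIOR_STATES, init / sum(init), trans, em)
}

momentZiGamma <- function(x) {
  x <- x[!is.na(x)]
  pi0 <- min(max(mean(x == 0), 1e-6), 1 - 1e-6)
  xp <- x[x > 0]
  if (length(xp) < 2) return(c(pi0, 2, 2))
  m <- mean(xp); v <- max(stats::var(xp), 1e-8)
  c(pi0, m^2 / v, m / v)
}

## ---- simulation from a spec --------------------------------------------

#' Simulate observations from an HMM specification
#'
#' Draws a state path from the Markov chain and channel observations
#' from the per-state emission distributions. Used for parameter
#' recovery and decoding-accuracy checks.
#'
#' @param spec an \linkS4class{HMMSpec}.
#' @param n sequence length.
#' @param seed integer seed.
#' @return list with \code{states} (integer indices), \code{labels},
#'   and \code{obs} (observation matrix).
#' @export
simulateHMMSeq <- function(spec, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  S <- length(spec@states)
  states <- integer(n)
  states[1] <- sample.int(S, 1, prob = spec@init)
  if (n > 1) for (t in 2:n)
    states[t] <- sample.int(S, 1, prob = spec@trans[states[t - 1], ])
  drawZi <- function(p, k) {
    z <- stats::runif(k) < p[1]
    out <- stats::rgamma(k, shape = p[2], rate = p[3])
    out[z] <- 0
    out
  }
  obs <- matrix(NA_real_, n, 4,
                dimnames = list(NULL, c("wingbeat", "depth", "pitch",
                                        "dist")))
  for (s in seq_len(S)) {
    idx <- which(states == s)
    if (!length(idx)) next
    e <- spec@emissions[[s]]
    obs[idx, "wingbeat"] <- drawZi(e$wingbeat, length(idx))
    obs[idx, "depth"] <- drawZi(e$depth, length(idx))
    obs[idx, "pitch"] <- stats::rnorm(length(idx), e$pitch[1], e$pitch[2])
    obs[idx, "dist"] <- drawZi(e$dist, length(idx))
  }
  list(states = states, labels = spec@states[states], obs = obs)
}
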