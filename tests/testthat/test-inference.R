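test_that("AICc matches hand arithmetic and limits", {
  expect_equal(aicc(-50, 5, 25), 100 + 10 + 60 / 19, tolerance = 1e-12)
  expect_equal(aicc(-50, 0, 10), 100)
  ## large-n limit: correction vanishes
  expect_lt(abs(aicc(-100, 5, 1e6) - (200 + 10)), 1e-3)
  expect_error(aicc(-10, 5, 6), "undefined")
})

test_that("Akaike weights normalize and survive loglik shifts", {
  a <- c(100, 102, 110)
  w <- akaikeWeights(a)
  expect_equal(sum(w), 1)
  expect_equal(akaikeWeights(a + 37), w)
  expect_true(all(diff(w) < 0))
})

test_that("VIF screening keeps orthogonal designs and drops collinear pairs", {
  set.seed(101)
  n <- 200
  z <- matrix(rnorm(n * 3), n, 3)
  q <- qr.Q(qr(z))
  d0 <- data.frame(x1 = q[, 1], x2 = q[, 2], x3 = q[, 3])
  out <- vifScreen(d0, c("x1", "x2", "x3"))
  expect_setequal(out$retained, c("x1", "x2", "x3"))
  expect_true(all(abs(out$report$measure - 1) < 0.05))
  ## near-duplicate predictor is removed
  d1 <- data.frame(x1 = rnorm(n))
  d1$x2 <- d1$x1 + rnorm(n, 0, 1e-4)
  d1$x3 <- rnorm(n)
  out1 <- vifScreen(d1, c("x1", "x2", "x3"))
  expect_length(out1$removed, 1)
  expect_true(out1$removed %in% c("x1", "x2"))
})

test_that("a correlation of 0.9 gives VIF 1/(1-0.81) and triggers removal", {
  set.seed(102)
  n <- 500
  a <- rnorm(n); b <- rnorm(n)
  ## Gram-Schmidt for an exact sample correlation of 0.9
  a <- as.vector(scale(a))
  b <- as.vector(scale(residuals(lm(b ~ a))))
  x2 <- 0.9 * a + sqrt(1 - 0.81) * b
  d <- data.frame(x1 = a, x2 = x2)
  out <- vifScreen(d, c("x1", "x2"))
  expect_equal(max(out$report$measure), 1 / (1 - 0.81), tolerance = 1e-6)
  expect_length(out$removed, 1)
})

test_that("interactions are removed before main effects", {
  set.seed(103)
  n <- 150
  ## x1 concentrated near 1 makes the x1:x2 product nearly collinear
  ## with x2: both fail the screen, the interaction must go first
  d <- data.frame(x1 = rnorm(n, 1, 0.1), x2 = rnorm(n))
  out <- vifScreen(d, c("x1", "x2", "x1:x2"))
  expect_equal(out$removed, "x1:x2")
  expect_setequal(out$retained, c("x1", "x2"))
})

test_that("a constant response ranks the null model first", {
  set.seed(104)
  d <- data.frame(y = rnorm(60, 10, 1e-8), x = rnorm(60),
                  bird_id = paste0("b", 1:60))
  out <- fitCandidates(d, "y", c("1", "x"), random = "NONE")
  expect_equal(out$table$formula[1], "1")
  slope <- coef(out$fits[["x"]])[["x"]]
  expect_lt(abs(slope), 1e-6)
})

test_that("planted slopes are recovered and beat the null on AICc", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 150
    d <- data.frame(ice = rnorm(n), dur = rnorm(n),
                    bird_id = paste0("b", 1:n))
    d$y <- 0.5 * d$ice + rnorm(n, 0, 0.3)
    out <- fitCandidates(d, "y", c("dur", "ice + dur"), random = "NONE")
    expect_equal(out$table$formula[1], "ice + dur")
    expect_lt(abs(coef(out$fits[["ice + dur"]])[["ice"]] - 0.5), 0.1)
  }
})

test_that("random-intercept variance is recovered in a repeated design", {
  set.seed(105)
  nBird <- 60; reps <- 3
  bird <- rep(paste0("b", 1:nBird), each = reps)
  u <- rep(rnorm(nBird, 0, 0.5), each = reps)
  d <- data.frame(bird_id = bird, x = rnorm(nBird * reps))
  d$y <- 0.3 * d$x + u + rnorm(nBird * reps, 0, 0.4)
  out <- fitCandidates(d, "y", c("1", "x"), random = "BIRD_ID")
  fit <- out$fits[["x"]]
  expect_s4_class(fit, "merMod")
  sdHat <- sqrt(lme4::VarCorr(fit)$bird_id[1, 1])
  expect_lt(abs(sdHat - 0.5), 0.15)
  expect_equal(out$table$random_effect[1], "BIRD_ID")
  ## k counts fixed effects + random-intercept SD + residual SD
  expect_equal(out$table$k[out$table$formula == "x"], 4)
})

test_that("likelihood-ratio comparison handles identical and nested fits", {
  set.seed(106)
  d <- data.frame(y = rnorm(80), x = rnorm(80))
  f0 <- lm(y ~ 1, data = d)
  f1 <- lm(y ~ x, data = d)
  same <- compareToNull(f0, f0)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  cmp <- compareToNull(f1, f0)
  expect_equal(cmp$df, 1)
  expect_equal(cmp$statistic,
               2 * (as.numeric(logLik(f1)) - as.numeric(logLik(f0))),
               tolerance = 1e-10)
  expect_error(compareToNull(f0, f1), "nested")
})

test_that("Nakagawa R2 components behave as constructed", {
  set.seed(107)
  d <- data.frame(y = rnorm(100), x = rnorm(100))
  d$y <- 0.8 * d$x + rnorm(100, 0, 0.5)
  fit <- lm(y ~ x, data = d)
  r2 <- r2Nakagawa(fit)
  expect_equal(r2$r2m, r2$r2c)           # no random variance
  fitNull <- lm(y ~ 1, data = d)
  expect_equal(r2Nakagawa(fitNull)$r2m, 0, tolerance = 1e-12)
  ## equal fixed, random and residual variances: r2m ~ 1/3, r2c ~ 2/3
  ## (averaged over simulations to tame finite-sample variance noise)
  nBird <- 100; reps <- 3
  r2ms <- r2cs <- numeric(8)
  for (s in seq_along(r2ms)) {
    set.seed(400 + s)
    bird <- rep(paste0("b", 1:nBird), each = reps)
    u <- rep(rnorm(nBird, 0, 1), each = reps)
    dd <- data.frame(bird_id = bird, x = rnorm(nBird * reps))
    dd$y <- dd$x + u + rnorm(nBird * reps, 0, 1)
    fitM <- lme4::lmer(y ~ x + (1 | bird_id), data = dd, REML = FALSE)
    r2 <- r2Nakagawa(fitM)
    r2ms[s] <- r2$r2m; r2cs[s] <- r2$r2c
    expect_gte(r2$r2c, r2$r2m)
  }
  expect_equal(mean(r2ms), 1 / 3, tolerance = 0.05)
  expect_equal(mean(r2cs), 2 / 3, tolerance = 0.05)
})

test_that("REML refit matches OLS without random effects and classical ANOVA with", {
  set.seed(108)
  d <- data.frame(y = rnorm(50), x = rnorm(50))
  fit <- lm(y ~ x, data = d)
  out <- refitREML(fit)
  expect_equal(out$coefficients$estimate, unname(coef(fit)))
  expect_false(out$singular)
  ## balanced one-way design: REML variance components equal the
  ## closed-form ANOVA estimators
  g <- 12; m <- 6
  bird <- rep(paste0("b", 1:g), each = m)
  set.seed(109)
  u <- rep(rnorm(g, 0, 1.2), each = m)
  y <- 5 + u + rnorm(g * m, 0, 0.7)
  dd <- data.frame(bird_id = bird, y = y)
  fitM <- lme4::lmer(y ~ 1 + (1 | bird_id), data = dd, REML = FALSE)
  out2 <- refitREML(fitM)
  gm <- tapply(y, bird, mean)
  msb <- m * var(gm)
  msw <- sum((y - rep(gm[unique(bird)], each = m))^2) / (g * (m - 1))
  vc <- lme4::VarCorr(out2$fit)
  expect_equal(attr(vc, "sc")^2, msw, tolerance = 1e-6)
  expect_equal(vc$bird_id[1, 1], (msb - msw) / m, tolerance = 1e-6)
  expect_true(all(c("df", "t", "p") %in% names(out2$coefficients)))
})

test_that("null slopes rarely exceed |t| = 2", {
  hits <- 0
  for (seed in 1:100) {
    set.seed(200 + seed)
    d <- data.frame(y = rnorm(200), x = rnorm(200))
    tval <- summary(lm(y ~ x, data = d))$coefficients["x", "t value"]
    if (abs(tval) < 2) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("planted biomarker effects propagate through the simulator to OLS", {
  sc <- simScenario(nBirds = 200, stage = "INCUBATION", iceEffect = 0.5,
                    noiseSd = 0.3, seed = 7)
  sim <- simulateDeployments(sc)
  bm <- simulateBiomarkers(sim$deployments, sc, sim$birds)
  trig <- bm[bm$analyte == "TRIG", ]
  d <- merge(trig, sim$birds, by = "bird_id")
  fit <- lm(delta ~ ice_z, data = d)
  expect_lt(abs(coef(fit)[["ice_z"]] - 0.5), 0.1)
})
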