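test_that("foraging points keep only DIVE fixes, projected about the colony", {
  n <- 10
  lat <- COLONY[2] + seq(0, 0.5, length.out = n)
  d <- makeDeployment(n, lat = lat)
  states <- c(rep("FLY", 7), rep("DIVE", 3))
  pts <- foragingPoints(list(states), list(d))
  expect_equal(nrow(pts), 3)
  ## a DIVE fix at the colony projects to the origin
  d2 <- makeDeployment(2)
  pts2 <- foragingPoints(list(c("DIVE", "DIVE")), list(d2))
  expect_equal(pts2$x, c(0, 0))
  expect_equal(pts2$y, c(0, 0))
  expect_error(foragingPoints(list(rep("SWIM", n)), list(d)),
               "empty point set")
})

test_that("href follows the ad hoc reference formula", {
  ## sd_x = sd_y = 1 exactly, n = 64: h = 64^(-1/6) = 1/2
  set.seed(61)
  x <- as.vector(scale(rnorm(64)))
  y <- as.vector(scale(rnorm(64)))
  pts <- cbind(x = x, y = y)
  expect_equal(hrefBandwidth(pts), 0.5, tolerance = 1e-12)
  ## homogeneity of degree one in the coordinates
  expect_equal(hrefBandwidth(pts * 37.5), 0.5 * 37.5, tolerance = 1e-12)
  ## strictly decreasing in n at fixed spread
  h128 <- ((1 + 1) / 2) * 128^(-1 / 6)
  expect_lt(h128, 0.5)
  expect_error(hrefBandwidth(cbind(x = rep(1, 5), y = rep(2, 5))),
               "degenerate")
})

test_that("kernel UDs are normalized, symmetric and split mass between clusters", {
  set.seed(62)
  for (i in 1:5) {
    pts <- cbind(x = rnorm(50, 0, 3000), y = rnorm(50, 0, 3000))
    ud <- kdeUD(pts, h = 800, cellM = 400)
    expect_equal(sum(udDensity(ud)) * udCellM(ud)^2, 1, tolerance = 1e-6)
    expect_true(all(udDensity(ud) >= 0))
  }
  ## single point: maximum at the nearest cell, symmetric density
  ud1 <- kdeUD(cbind(x = 0, y = 0), h = 1000, cellM = 250)
  dens <- udDensity(ud1)
  peak <- which(dens == max(dens), arr.ind = TRUE)
  expect_equal(abs(ud1@x[peak[1, 1]]), min(abs(ud1@x)))
  expect_equal(dens, dens[rev(seq_len(nrow(dens))), rev(seq_len(ncol(dens)))],
               tolerance = 1e-9)
  ## two distant clusters of equal size: half the mass each
  two <- rbind(cbind(x = rnorm(100, -30000, 500), y = rnorm(100, 0, 500)),
               cbind(x = rnorm(100, 30000, 500), y = rnorm(100, 0, 500)))
  colnames(two) <- c("x", "y")
  ud2 <- kdeUD(two, h = 800, cellM = 400)
  left <- sum(udDensity(ud2)[ud2@x < 0, ]) * udCellM(ud2)^2
  expect_equal(left, 0.5, tolerance = 0.01)
  expect_error(kdeUD(cbind(x = c(0, 10), y = c(0, 10)), h = 1,
                     cellM = 1e6), "cell larger")
})

test_that("isopleth areas are ranked-cell cumulative areas, nested in fraction", {
  ## uniform over 100 cells of 1 km^2: the 50% area is 50 km^2
  ud <- uniformBlockUD(10, 10, 1, 10, 1, 10, cellM = 1000)
  expect_equal(isoplethArea(ud, 0.5), 50)
  set.seed(63)
  pts <- cbind(x = rnorm(200, 0, 2000), y = rnorm(200, 0, 2000))
  udr <- kdeUD(pts, h = 500, cellM = 200)
  expect_lte(isoplethArea(udr, 0.5), isoplethArea(udr, 0.95))
  fr <- c(0.2, 0.5, 0.8, 0.95)
  areas <- vapply(fr, function(f) isoplethArea(udr, f), numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("a single Gaussian kernel recovers the analytic 95% circle area", {
  ## UD of one point with h = 1 km is exactly bivariate normal:
  ## 95% area = pi * h^2 * qchisq(0.95, 2)
  ud <- kdeUD(cbind(x = 0, y = 0), h = 1000, cellM = 100, pad = 4)
  expect_equal(isoplethArea(ud, 0.95), pi * qchisq(0.95, 2),
               tolerance = 0.05)
})

test_that("Bhattacharyya affinity has unit self-affinity and zero on disjoint UDs", {
  set.seed(64)
  pts <- cbind(x = rnorm(100, 0, 2000), y = rnorm(100, 0, 2000))
  ud <- kdeUD(pts, h = 800, cellM = 800)
  expect_equal(bhattacharyya(ud, ud), 1, tolerance = 1e-6)
  a <- uniformBlockUD(10, 10, 1, 3, 1, 3)
  b <- uniformBlockUD(10, 10, 7, 9, 7, 9)
  expect_equal(bhattacharyya(a, b), 0)
  ## uniform on {A,B} vs uniform on {B,C}: BA = sqrt(1/2 * 1/2) = 1/2
  ab <- uniformBlockUD(3, 1, 1, 2, 1, 1)
  bc <- uniformBlockUD(3, 1, 2, 3, 1, 1)
  expect_equal(bhattacharyya(ab, bc), 0.5, tolerance = 1e-12)
})

test_that("affinity between different grids goes through resampling", {
  set.seed(65)
  pts <- cbind(x = rnorm(150, 0, 2500), y = rnorm(150, 0, 2500))
  ud1 <- kdeUD(pts, h = 700, cellM = 400)
  ud2 <- kdeUD(pts, h = 700, cellM = 800)
  expect_error(bhattacharyya(ud1, ud2, resample = FALSE),
               "different grids")
  ba <- bhattacharyya(ud1, ud2)
  expect_gt(ba, 0.95)
  expect_lte(ba, 1)
})

test_that("the KDE converges to the generating density", {
  set.seed(66)
  n <- 2000
  pts <- cbind(x = rnorm(n, 0, 1000), y = rnorm(n, 0, 1000))
  h <- hrefBandwidth(pts)
  ud <- kdeUD(pts, h, cellM = 200)
  analytic <- udDensity(ud)
  for (j in seq_along(ud@y))
    analytic[, j] <- dnorm(ud@x, 0, 1000) * dnorm(ud@y[j], 0, 1000)
  analytic <- analytic / (sum(analytic) * udCellM(ud)^2)
  ud2 <- methods::initialize(ud, density = analytic)
  expect_gt(bhattacharyya(ud, ud2, maskFraction = NULL), 0.95)
})

test_that("kernel density agrees with the MASS reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(68)
  pts <- cbind(x = rnorm(60, 0, 2000), y = rnorm(60, 0, 1500))
  h <- 700
  ud <- kdeUD(pts, h = h, cellM = 250)
  ## MASS::kde2d uses a kernel SD of h/4, evaluated on an inclusive grid
  ref <- MASS::kde2d(pts[, "x"], pts[, "y"], h = 4 * h,
                     n = c(length(ud@x), length(ud@y)),
                     lims = c(range(ud@x), range(ud@y)))
  refDens <- ref$z / (sum(ref$z) * udCellM(ud)^2)
  expect_equal(udDensity(ud), refDens, tolerance = 1e-6)
})

test_that("masking to an isopleth renormalizes and shrinks support", {
  set.seed(67)
  pts <- cbind(x = rnorm(300, 0, 3000), y = rnorm(300, 0, 3000))
  ud <- kdeUD(pts, h = 600, cellM = 300)
  m <- maskToIsopleth(ud, 0.95)
  expect_equal(sum(udDensity(m)) * udCellM(m)^2, 1, tolerance = 1e-9)
  expect_lt(sum(udDensity(m) > 0), sum(udDensity(ud) > 0))
})
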