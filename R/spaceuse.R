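#' @include AllClasses.R geo.R
NULL

#' Foraging locations in projected metres
#'
#' Retains only DIVE-state fixes (locations associated with swimming,
#' flying or resting at the colony are excluded) and projects them to a
#' local azimuthal-equidistant plane centred on the colony.
#'
#' @param sequences list of \linkS4class{BehaviorSequence}.
#' @param deployments matching list of \linkS4class{MurreDeployment}.
#' @param colonyLonLat projection centre (lon, lat).
#' @return data.frame with columns x, y (metres) and bird_id.
#' @export
foragingPoints <- function(sequences, deployments,
                           colonyLonLat = pipelineConfig()@colonyLonLat) {
  pts <- mapply(function(sq, dep) {
    states <- if (is.character(sq)) sq else sq@states
    fx <- dep@fixes[states == "DIVE", , drop = FALSE]
    if (!nrow(fx)) return(NULL)
    p <- projectAeqd(fx$lon, fx$lat, colonyLonLat)
    p$bird_id <- dep@birdId
    p
  }, sequences, deployments, SIMPLIFY = FALSE)
  out <- do.call(rbind, pts)
  if (is.null(out) || !nrow(out))
    stop("no DIVE-state fixes in this stratum: empty point set")
  out
}

#' Reference bandwidth (href)
#'
#' The ad hoc bivariate-normal reference smoothing parameter:
#' h = ((sd_x + sd_y) / 2) * n^(-1/6).
#'
#' @param points data.frame or matrix with columns x, y (metres).
#' @return bandwidth in metres.
#' @export
hrefBandwidth <- function(points) {
  x <- points[, "x"]; y <- points[, "y"]
  n <- length(x)
  if (n < 2) stop("need at least two points for href")
  sdx <- stats::sd(x); sdy <- stats::sd(y)
  if (sdx + sdy <= 0) stop("degenerate point set: no spread")
  (sdx + sdy) / 2 * n^(-1 / 6)
}

#' Kernel-density utilization distribution
#'
#' Isotropic bivariate normal kernel of SD \code{h} per point, evaluated
#' on a regular grid of \code{cellM} cells padded at least \code{pad}
#' bandwidths beyond the point bounding box, then renormalized so the
#' density integrates to exactly 1 over the grid.
#'
#' @param points data.frame or matrix with columns x, y (metres).
#' @param h bandwidth (metres).
#' @param cellM grid cell size (metres, default 800).
#' @param pad padding in bandwidths (default 3).
#' @return a \linkS4class{UtilizationDistribution}.
#' @export
kdeUD <- function(points, h, cellM = 800, pad = 3) {
  px <- points[, "x"]; py <- points[, "y"]
  if (h <= 0) stop("bandwidth must be positive")
  x0 <- min(px) - pad * h; x1 <- max(px) + pad * h
  y0 <- min(py) - pad * h; y1 <- max(py) + pad * h
  if (cellM >= max(x1 - x0, y1 - y0))
    stop("grid cell larger than the padded domain")
  gx <- seq(x0 + cellM / 2, x1, by = cellM)
  gy <- seq(y0 + cellM / 2, y1, by = cellM)
  ## separable kernel: density = A %*% t(B) summed over points
  A <- outer(gx, px, function(g, p) stats::dnorm(g, p, h))
  B <- outer(gy, py, function(g, p) stats::dnorm(g, p, h))
  dens <- tcrossprod(A, B) / length(px)
  dens <- dens / (sum(dens) * cellM^2)
  new("UtilizationDistribution", x = gx, y = gy, density = dens,
      cellM = cellM,
      crsNote = "azimuthal equidistant, metres from colony")
}

#' Isopleth area of a utilization distribution
#'
#' Area of the smallest set of cells whose cumulative density reaches
#' the given fraction, ranking cells by density in descending order
#' (the 50% isopleth is the core area, 95% the overall foraging area).
#'
#' @param ud a \linkS4class{UtilizationDistribution}.
#' @param fraction isopleth fraction in (0, 1).
#' @return area in square kilometres.
#' @export
isoplethArea <- function(ud, fraction) {
  stopifnot(fraction > 0, fraction < 1)
  nCells <- isoplethCellCount(ud, fraction)
  nCells * ud@cellM^2 / 1e6
}

isoplethCellCount <- function(ud, fraction) {
  p <- sort(as.vector(ud@density), decreasing = TRUE) * ud@cellM^2
  which(cumsum(p) >= fraction)[1]
}

#' Mask a UD to its isopleth and renormalize
#'
#' Zeroes every cell outside the smallest cell set reaching
#' \code{fraction} of the mass, then renormalizes to integrate to 1.
#'
#' @param ud a \linkS4class{UtilizationDistribution}.
#' @param fraction isopleth fraction in (0, 1).
#' @return a \linkS4class{UtilizationDistribution}.
#' @export
maskToIsopleth <- function(ud, fraction) {
  n <- isoplethCellCount(ud, fraction)
  thr <- sort(as.vector(ud@density), decreasing = TRUE)[n]
  dens <- ud@density
  dens[dens < thr] <- 0
  dens <- dens / (sum(dens) * ud@cellM^2)
  methods::initialize(ud, density = dens)
}

## resample a UD onto a target grid by nearest-cell lookup (density is
## piecewise constant per cell); cells outside the source get 0
resampleUD <- function(ud, gx, gy, cellM) {
  ix <- round((gx - ud@x[1]) / ud@cellM) + 1
  iy <- round((gy - ud@y[1]) / ud@cellM) + 1
  okx <- ix >= 1 & ix <= length(ud@x)
  oky <- iy >= 1 & iy <= length(ud@y)
  dens <- matrix(0, length(gx), length(gy))
  dens[okx, oky] <- ud@density[ix[okx], iy[oky], drop = FALSE]
  tot <- sum(dens) * cellM^2
  if (tot <= 0) stop("resampled UD has zero mass on the common grid")
  dens / tot
}

#' Bhattacharyya affinity between utilization distributions
#'
#' BA = sum over cells of sqrt(p1 p2) times cell area, ranging from 0
#' (no spatial overlap) to 1 (identical distributions). Following the
#' study's definition on the 95% utilization distributions, both UDs
#' are first masked to their \code{maskFraction} isopleth and
#' renormalized (set \code{maskFraction = NULL} for the unmasked
#' affinity). UDs on different grids are resampled to a common grid
#' (union extent, finer cell size) when \code{resample = TRUE}.
#'
#' @param ud1,ud2 \linkS4class{UtilizationDistribution} objects.
#' @param maskFraction isopleth mask (default 0.95) or NULL.
#' @param resample allow resampling onto a common grid.
#' @return affinity in [0, 1].
#' @export
bhattacharyya <- function(ud1, ud2, maskFraction = 0.95,
                          resample = TRUE) {
  if (!is.null(maskFraction)) {
    ud1 <- maskToIsopleth(ud1, maskFraction)
    ud2 <- maskToIsopleth(ud2, maskFraction)
  }
  sameGrid <- ud1@cellM == ud2@cellM &&
    length(ud1@x) == length(ud2@x) && length(ud1@y) == length(ud2@y) &&
    isTRUE(all.equal(ud1@x, ud2@x)) && isTRUE(all.equal(ud1@y, ud2@y))
  if (sameGrid) {
    p1 <- ud1@density; p2 <- ud2@density; cell <- ud1@cellM
  } else {
    if (!resample)
      stop("UDs on different grids; enable resample to compare them")
    cell <- min(ud1@cellM, ud2@cellM)
    x0 <- min(ud1@x[1], ud2@x[1])
    y0 <- min(ud1@y[1], ud2@y[1])
    x1 <- max(ud1@x[length(ud1@x)], ud2@x[length(ud2@x)])
    y1 <- max(ud1@y[length(ud1@y)], ud2@y[length(ud2@y)])
    gx <- seq(x0, x1, by = cell)
    gy <- seq(y0, y1, by = cell)
    p1 <- resampleUD(ud1, gx, gy, cell)
    p2 <- resampleUD(ud2, gx, gy, cell)
  }
  ba <- sum(sqrt(p1 * p2)) * cell^2
  min(max(ba, 0), 1)
}

#' Uniform UD over a rectangular cell block
#'
#' Convenience constructor used in overlap tests and examples: a
#' normalized uniform density over cells [i0..i1] x [j0..j1] of an
#' nx-by-ny grid.
#'
#' @param nx,ny grid dimensions.
#' @param i0,i1,j0,j1 cell index block carrying the mass.
#' @param cellM cell size (metres).
#' @return a \linkS4class{UtilizationDistribution}.
#' @export
uniformBlockUD <- function(nx, ny, i0, i1, j0, j1, cellM = 800) {
  dens <- matrix(0, nx, ny)
  dens[i0:i1, j0:j1] <- 1
  dens <- dens / (sum(dens) * cellM^2)
  new("UtilizationDistribution",
      x = (seq_len(nx) - 0.5) * cellM, y = (seq_len(ny) - 0.5) * cellM,
      density = dens, cellM = cellM, crsNote = "synthetic grid")
}
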