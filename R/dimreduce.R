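#' @include AllClasses.R
NULL

#' Correlation PCA with Kaiser retention
#'
#' Standardizes the metric table to zero mean and unit variance, runs
#' PCA on the correlation matrix, retains components with eigenvalue
#' above the Kaiser threshold, and varimax-rotates the retained
#' loadings when two or more are kept. Loadings follow a fixed sign
#' convention (each component's largest-magnitude loading is positive)
#' so downstream regressions are reproducible; component scores use the
#' regression method and have mean zero on the fitting sample.
#'
#' @param metrics data.frame or matrix, rows = deployments, columns =
#'   metrics; rows with missing values are dropped with a message.
#' @param kaiser eigenvalue retention threshold (default 1).
#' @param rotate varimax-rotate when two or more components are
#'   retained (default TRUE).
#' @return a \linkS4class{PCAResult}.
#' @export
pcaKaiser <- function(metrics, kaiser = 1.0, rotate = TRUE) {
  X <- as.matrix(metrics)
  keep <- stats::complete.cases(X)
  if (sum(keep) < 2) stop("need at least two complete rows")
  if (any(!keep))
    message("dropping ", sum(!keep), " row(s) with missing values")
  X <- X[keep, , drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant variable(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  ctr <- colMeans(X)
  Z <- scale(X, center = ctr, scale = sds)
  R <- stats::cor(X)
  eg <- eigen(R, symmetric = TRUE)
  ev <- eg$values
  nRet <- sum(ev > kaiser)
  varPct <- 100 * sum(ev[ev > kaiser]) / ncol(X)
  if (nRet == 0) {
    return(new("PCAResult", variables = colnames(X), eigenvalues = ev,
               loadings = matrix(0, ncol(X), 0), rotated = FALSE,
               rotation = matrix(0, 0, 0),
               scores = matrix(0, nrow(X), 0),
               varExplainedPct = 0, center = ctr, scaleV = sds,
               corMatrix = R))
  }
  L <- eg$vectors[, seq_len(nRet), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(nRet)]), nRet)
  rot <- diag(nRet)
  rotated <- FALSE
  if (rotate && nRet >= 2) {
    vr <- varimaxRotate(L)
    L <- vr$loadings
    rot <- vr$rotation
    rotated <- TRUE
  }
  ## sign convention: largest-|loading| entry positive per component
  flip <- vapply(seq_len(ncol(L)), function(j)
    sign(L[which.max(abs(L[, j])), j]), numeric(1))
  L <- sweep(L, 2, flip, "*")
  rot <- sweep(rot, 2, flip, "*")
  rownames(L) <- colnames(X)
  colnames(L) <- paste0("RC", seq_len(nRet))
  res <- new("PCAResult", variables = colnames(X), eigenvalues = ev,
             loadings = L, rotated = rotated, rotation = rot,
             scores = matrix(0, 0, 0), varExplainedPct = varPct,
             center = ctr, scaleV = sds, corMatrix = R)
  sc <- pcaScores(res, X)
  methods::initialize(res, scores = sc)
}

#' Varimax rotation by pairwise planar rotations
#'
#' Maximizes the (Kaiser-normalized) varimax criterion -- the sum over
#' components of the variance of squared loadings -- by sweeps of
#' closed-form two-column rotations, until the criterion improves by
#' less than \code{tol} over a sweep. The rotation is orthogonal, so
#' per-variable communalities are preserved.
#'
#' @param loadings variables x components matrix (2+ columns).
#' @param tol criterion improvement tolerance.
#' @param maxIter maximum sweeps; a warning is issued (and the best
#'   iterate returned) on non-convergence.
#' @param normalize Kaiser-normalize rows (divide by the square root of
#'   the communality) during rotation.
#' @return list with \code{loadings} (rotated), \code{rotation}
#'   (orthonormal), \code{criterionTrace} (one value per sweep,
#'   non-decreasing) and \code{sweeps}.
#' @export
varimaxRotate <- function(loadings, tol = 1e-10, maxIter = 100L,
                          normalize = TRUE) {
  L <- as.matrix(loadings)
  p <- nrow(L); m <- ncol(L)
  if (m < 2) stop("need at least two components to rotate")
  comm <- sqrt(rowSums(L^2))
  scl <- if (normalize) pmax(comm, 1e-12) else rep(1, p)
  A <- L / scl
  R <- diag(m)
  crit <- function(M) sum(apply(M^2, 2, function(c2)
    mean(c2^2) - mean(c2)^2))
  trace <- crit(A)
  converged <- FALSE
  for (sweep in seq_len(maxIter)) {
    for (j in 1:(m - 1)) for (k in (j + 1):m) {
      u <- A[, j]^2 - A[, k]^2
      v <- 2 * A[, j] * A[, k]
      num <- 2 * (p * sum(u * v) - sum(u) * sum(v))
      den <- p * sum(u^2 - v^2) - (sum(u)^2 - sum(v)^2)
      phi <- -atan2(num, den) / 4
      if (abs(phi) < 1e-14) next
      G <- matrix(c(cos(phi), -sin(phi), sin(phi), cos(phi)), 2, 2)
      A[, c(j, k)] <- A[, c(j, k)] %*% G
      R[, c(j, k)] <- R[, c(j, k)] %*% G
    }
    trace <- c(trace, crit(A))
    if (trace[sweep + 1] - trace[sweep] < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("varimax did not converge in ", maxIter,
            " sweeps; returning best iterate")
  list(loadings = (A * scl), rotation = R, criterionTrace = trace,
       sweeps = length(trace) - 1L)
}

#' Component scores for (new) data
#'
#' Regression-method scores: standardized data times
#' \code{solve(corMatrix) \%*\% loadings}. On the fitting sample the
#' scores have mean zero by construction; rows with missing values are
#' dropped with a message.
#'
#' @param result a \linkS4class{PCAResult}.
#' @param metrics data with the fitting variables.
#' @return rows x retained-components score matrix.
#' @export
pcaScores <- function(result, metrics) {
  X <- as.matrix(metrics)[, result@variables, drop = FALSE]
  keep <- stats::complete.cases(X)
  if (any(!keep))
    message("dropping ", sum(!keep), " row(s) with missing values")
  X <- X[keep, , drop = FALSE]
  Z <- scale(X, center = result@center, scale = result@scaleV)
  if (ncol(result@loadings) == 0)
    return(matrix(0, nrow(Z), 0))
  ## pseudo-inverse: a rank-deficient correlation matrix (perfectly
  ## correlated variables) still yields well-defined regression weights
  sv <- svd(result@corMatrix)
  pos <- sv$d > max(sv$d) * 1e-10
  W <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) %*% result@loadings / sv$d[pos])
  sc <- Z %*% W
  colnames(sc) <- colnames(result@loadings)
  sc
}

#' Strongly loaded variables per component
#'
#' @param result a \linkS4class{PCAResult}.
#' @param cutoff absolute-loading threshold (default 0.5).
#' @return named list of character vectors per retained component.
#' @export
strongLoadings <- function(result, cutoff = 0.5) {
  L <- result@loadings
  stats::setNames(lapply(seq_len(ncol(L)), function(j)
    rownames(L)[abs(L[, j]) >= cutoff]), colnames(L))
}
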