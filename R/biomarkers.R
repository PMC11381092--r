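#' @include AllClasses.R
NULL

#' Log-ratio change score
#'
#' Relative change of a biomarker or mass over the foraging deployment:
#' delta = log(post) - log(pre), natural log. Positive values mean the
#' analyte rose while the bird foraged; the score is antisymmetric
#' under swapping pre and post.
#'
#' @param pre,post positive analyte values (vectorized).
#' @return unitless log-ratio change.
#' @export
deltaLog <- function(pre, post) {
  if (any(pre <= 0 | post <= 0, na.rm = TRUE))
    stop("pre and post values must be strictly positive")
  log(post) - log(pre)
}

#' Intra- and inter-assay coefficients of variation
#'
#' Control-sample QC: the intra-assay CV is the mean over plates of the
#' within-plate CV (100 sd/mean of the control replicates); the
#' inter-assay CV is 100 sd/mean of the per-plate control means.
#'
#' @param replicates data.frame with columns \code{plate} and
#'   \code{value} (control replicate measurements).
#' @return named list: intraCvPct, interCvPct (NA with a warning when
#'   replication is insufficient).
#' @export
assayCV <- function(replicates) {
  byPlate <- split(replicates$value, replicates$plate)
  cvs <- vapply(byPlate, function(v) {
    if (length(v) < 2) return(NA_real_)
    100 * stats::sd(v) / mean(v)
  }, numeric(1))
  if (any(is.na(cvs)))
    warning("plate(s) with a single replicate: intra-assay CV incomplete")
  intra <- mean(cvs, na.rm = TRUE)
  if (all(is.na(cvs))) intra <- NA_real_
  means <- vapply(byPlate, mean, numeric(1))
  inter <- if (length(means) >= 2)
    100 * stats::sd(means) / mean(means)
  else {
    warning("single plate: inter-assay CV undefined")
    NA_real_
  }
  list(intraCvPct = intra, interCvPct = inter)
}
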