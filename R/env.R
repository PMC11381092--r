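#' @include AllClasses.R geo.R
NULL

#' Cells within a radius of a point
#'
#' Logical mask of raster cells whose centre lies within great-circle
#' distance \code{radiusKm} of \code{center} (a cell exactly at the
#' radius is included).
#'
#' @param field an \linkS4class{EnvField}.
#' @param center numeric(2) lon, lat (degrees); defaults to the Coats
#'   Island colony.
#' @param radiusKm radius (km), default 130 (the maximum foraging range).
#' @return logical matrix, dim (lon, lat).
#' @export
radiusMask <- function(field, center = c(-82.01, 62.95),
                       radiusKm = 130) {
  stopifnot(radiusKm > 0)
  d <- outer(seq_along(field@lon), seq_along(field@lat),
             function(i, j) haversineKm(field@lon[i], field@lat[j],
                                        center[1], center[2]))
  mask <- d <= radiusKm
  if (!any(mask)) stop("no raster cells within ", radiusKm, " km")
  mask
}

#' Deployment-window mean of an environmental field
#'
#' Unweighted mean over the masked cells of every daily layer whose
#' calendar date intersects the deployment window (any partially
#' covered day counts). Missing cells are excluded; if every value is
#' missing the result is NA. Set \code{areaWeight = TRUE} for
#' cos-latitude cell weighting.
#'
#' @param field an \linkS4class{EnvField}.
#' @param mask logical matrix from \code{\link{radiusMask}}.
#' @param startT,endT POSIXct deployment window (UTC).
#' @param areaWeight weight cells by cos(latitude).
#' @return mean in the field's units, or NA.
#' @export
deploymentMean <- function(field, mask, startT, endT,
                           areaWeight = FALSE) {
  days <- seq(as.Date(startT, tz = "UTC"), as.Date(endT, tz = "UTC"),
              by = "day")
  layers <- which(field@times %in% days)
  if (!length(layers))
    stop("deployment window does not overlap the field's time axis")
  w <- if (areaWeight)
    outer(rep(1, length(field@lon)), cos(field@lat * pi / 180))
  else matrix(1, length(field@lon), length(field@lat))
  num <- 0; den <- 0
  for (k in layers) {
    v <- field@values[, , k]
    ok <- mask & !is.na(v)
    num <- num + sum(v[ok] * w[ok])
    den <- den + sum(w[ok])
  }
  if (den == 0) NA_real_ else num / den
}

#' Per-bird environmental covariates
#'
#' Convenience wrapper assigning each deployment its window-averaged
#' sea ice concentration and SST within the configured radius of the
#' colony.
#'
#' @param iceField,sstField \linkS4class{EnvField} objects (either may
#'   be NULL).
#' @param deployments list of \linkS4class{MurreDeployment}.
#' @param config a \linkS4class{PipelineConfig}.
#' @return data.frame with bird_id, mean_ice_pct, mean_sst_c.
#' @export
envCovariates <- function(iceField, sstField, deployments,
                          config = pipelineConfig()) {
  maskOf <- function(field) radiusMask(field, config@colonyLonLat,
                                       config@envRadiusKm)
  iceMask <- if (!is.null(iceField)) maskOf(iceField)
  sstMask <- if (!is.null(sstField)) maskOf(sstField)
  do.call(rbind, lapply(deployments, function(d) data.frame(
    bird_id = d@birdId,
    mean_ice_pct = if (is.null(iceField)) NA_real_ else
      deploymentMean(iceField, iceMask, d@startT, d@endT),
    mean_sst_c = if (is.null(sstField)) NA_real_ else
      deploymentMean(sstField, sstMask, d@startT, d@endT))))
}
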