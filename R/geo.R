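## Spherical geometry on a sphere of radius 6371 km. At the study scale
## (<= 200 km from the colony) the sphere-vs-ellipsoid error is below
## 0.5%, well under GPS fix spacing.

EARTH_RADIUS_KM <- 6371

#' Great-circle distance (haversine)
#'
#' Vectorized haversine distance on a sphere of radius 6371 km.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees.
#' @return distance in kilometres.
#' @examples
#' haversineKm(0, 0, 1, 0)  # ~111.19 km along the equator
#' @export
haversineKm <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' Initial bearing between two points
#'
#' @inheritParams haversineKm
#' @return bearing in radians, clockwise from north.
#' @keywords internal
bearingRad <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180
  dlon <- (lon2 - lon1) * rad
  y <- sin(dlon) * cos(lat2 * rad)
  x <- cos(lat1 * rad) * sin(lat2 * rad) -
    sin(lat1 * rad) * cos(lat2 * rad) * cos(dlon)
  atan2(y, x)
}

#' Destination point along a great circle
#'
#' @param lon,lat start point (degrees).
#' @param bearing radians clockwise from north.
#' @param distKm distance (km).
#' @return data.frame with columns lon, lat (degrees).
#' @keywords internal
destPoint <- function(lon, lat, bearing, distKm) {
  rad <- pi / 180
  d <- distKm / EARTH_RADIUS_KM
  lat1 <- lat * rad
  lon1 <- lon * rad
  lat2 <- asin(sin(lat1) * cos(d) + cos(lat1) * sin(d) * cos(bearing))
  lon2 <- lon1 +
    atan2(sin(bearing) * sin(d) * cos(lat1),
          cos(d) - sin(lat1) * sin(lat2))
  data.frame(lon = ((lon2 / rad + 180) %% 360) - 180, lat = lat2 / rad)
}

#' Project to a local azimuthal-equidistant plane
#'
#' Projects lon/lat to planar metres in an azimuthal-equidistant
#' projection centred on \code{centerLonLat}: radial distances from the
#' centre are preserved exactly, which suits kernel density estimation of
#' points within a few hundred kilometres of a colony.
#'
#' @param lon,lat coordinates (degrees).
#' @param centerLonLat numeric(2) projection centre (lon, lat).
#' @return data.frame with columns x, y in metres.
#' @export
projectAeqd <- function(lon, lat, centerLonLat) {
  d <- haversineKm(centerLonLat[1], centerLonLat[2], lon, lat) * 1000
  az <- bearingRad(centerLonLat[1], centerLonLat[2], lon, lat)
  out <- data.frame(x = d * sin(az), y = d * cos(az))
  out$x[d == 0] <- 0
  out$y[d == 0] <- 0
  out
}

#' Local solar hour
#'
#' Solar time of day approximated as UTC plus longitude / 15 hours; used
#' for the diel colony-attendance windows.
#'
#' @param t POSIXct (UTC).
#' @param lon longitude in degrees.
#' @return hours in [0, 24).
#' @export
localSolarHour <- function(t, lon) {
  utcH <- (as.numeric(t) %% 86400) / 3600
  (utcH + lon / 15) %% 24
}
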