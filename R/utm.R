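#' Project geographic coordinates to UTM (WGS84)
#'
#' Standard Universal Transverse Mercator forward projection: 6-degree
#' zones, central scale factor 0.9996, WGS84 ellipsoid, computed with the
#' usual series expansion of the transverse Mercator meridian arc
#' (sub-millimeter accuracy within a zone). Field GPS fixes are projected
#' so that all downstream distances are planar meters.
#'
#' All points of one study site must fall in a single UTM zone; a transect
#' spanning a zone boundary needs a local planar projection instead.
#'
#' @param lat latitude in degrees, in \[-90, 90\].
#' @param lon longitude in degrees, in \[-180, 180\].
#' @return a data.frame with columns `easting`, `northing` (meters) and
#'   `zone` (e.g. `"51N"`).
#' @export
to_planar <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon))) {
    stop("non-finite coordinates")
  }
  if (any(lat < -90 | lat > 90)) stop("latitude outside [-90, 90]")
  if (any(lon < -180 | lon > 180)) stop("longitude outside [-180, 180]")

  zone <- floor((lon + 180) / 6) + 1
  zone[lon == 180] <- 60
  if (length(unique(zone)) > 1) {
    stop("points span UTM zones ", paste(sort(unique(zone)), collapse = ", "),
         "; use a local planar projection for cross-zone transects")
  }

  a <- 6378137           # WGS84 semi-major axis, m
  f <- 1 / 298.257223563
  k0 <- 0.9996
  e2 <- f * (2 - f)
  ep2 <- e2 / (1 - e2)

  phi <- lat * pi / 180
  lam <- lon * pi / 180
  lam0 <- (-183 + 6 * zone) * pi / 180

  sphi <- sin(phi); cphi <- cos(phi); tphi <- tan(phi)
  N <- a / sqrt(1 - e2 * sphi^2)
  T <- tphi^2
  C <- ep2 * cphi^2
  A <- cphi * (lam - lam0)

  M <- a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * phi -
            (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * phi) +
            (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * phi) -
            (35 * e2^3 / 3072) * sin(6 * phi))

  easting <- k0 * N * (A + (1 - T + C) * A^3 / 6 +
                       (5 - 18 * T + T^2 + 72 * C - 58 * ep2) * A^5 / 120) +
    500000
  northing <- k0 * (M + N * tphi * (A^2 / 2 +
                    (5 - T + 9 * C + 4 * C^2) * A^4 / 24 +
                    (61 - 58 * T + T^2 + 600 * C - 330 * ep2) * A^6 / 720))
  south <- lat < 0
  northing[south] <- northing[south] + 10000000

  data.frame(easting = easting, northing = northing,
             zone = paste0(zone, ifelse(south, "S", "N")))
}
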