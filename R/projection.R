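# Planar projection: WGS84 UTM (transverse Mercator, Krueger n-series).
# Self-contained so that metric FPT radii and step lengths do not depend on an
# external PROJ installation; forward/inverse agree to well under a millimetre
# within a zone, which is far below GPS error.

.WGS84_A <- 6378137.0
.WGS84_F <- 1 / 298.257223563

.tm_consts <- local({
  f <- .WGS84_F
  n <- f / (2 - f)
  list(
    n = n,
    A = .WGS84_A / (1 + n) * (1 + n^2 / 4 + n^4 / 64),
    alpha = c(
      n / 2 - 2 * n^2 / 3 + 5 * n^3 / 16,
      13 * n^2 / 48 - 3 * n^3 / 5,
      61 * n^3 / 240
    ),
    beta = c(
      n / 2 - 2 * n^2 / 3 + 37 * n^3 / 96,
      n^2 / 48 + n^3 / 15,
      17 * n^3 / 480
    ),
    delta = c(
      2 * n - 2 * n^2 / 3 - 2 * n^3,
      7 * n^2 / 3 - 8 * n^3 / 5,
      56 * n^3 / 15
    )
  )
})

#' UTM zone containing a longitude
#'
#' @param lon Longitude in decimal degrees (WGS84).
#' @return Integer zone number, 1-60.
#' @export
utm_zone <- function(lon) {
  z <- floor((lon + 180) / 6) + 1
  as.integer(pmin(pmax(z, 1), 60))
}

#' Build a projected coordinate reference frame
#'
#' The frame is identified by a standard EPSG string: `"EPSG:326<zz>"` for
#' a northern-hemisphere UTM zone `zz`, `"EPSG:327<zz>"` for southern.
#'
#' @param crs CRS identifier string, e.g. `"EPSG:32614"` (UTM 14N).
#' @return An object of class `utm_frame`.
#' @export
utm_frame <- function(crs) {
  m <- regmatches(crs, regexec("^EPSG:(326|327)([0-5][0-9])$", crs))[[1]]
  if (length(m) != 3)
    stop("unsupported CRS identifier '", crs,
         "'; expected 'EPSG:326zz' or 'EPSG:327zz' (WGS84 UTM)", call. = FALSE)
  zone <- as.integer(m[3])
  if (zone < 1 || zone > 60)
    stop("UTM zone must be 1-60, got ", zone, call. = FALSE)
  south <- identical(m[2], "327")
  structure(
    list(crs = crs, zone = zone, south = south,
         lon0 = -183 + 6 * zone, k0 = 0.9996,
         false_easting = 5e5, false_northing = if (south) 1e7 else 0),
    class = "utm_frame"
  )
}

#' Default UTM frame for a reference point
#'
#' @param lon,lat Reference coordinates in degrees (typically the roost).
#' @return A `utm_frame` for the UTM zone containing the point.
#' @export
frame_for_point <- function(lon, lat) {
  code <- if (lat < 0) 32700L else 32600L
  utm_frame(sprintf("EPSG:%d", code + utm_zone(lon)))
}

#' @export
print.utm_frame <- function(x, ...) {
  cat("<utm_frame> ", x$crs, " (zone ", x$zone,
      if (x$south) "S" else "N", ", lon0 ", x$lon0, ")\n", sep = "")
  invisible(x)
}

#' Project lon/lat to planar metres
#'
#' @param lon,lat Numeric vectors, degrees WGS84.
#' @param frame A [utm_frame()].
#' @return A list with numeric vectors `x` (easting) and `y` (northing), metres.
#' @export
lonlat_to_xy <- function(lon, lat, frame) {
  if (any(abs(lat) > 90, na.rm = TRUE) || any(abs(lon) > 360, na.rm = TRUE))
    stop("lon/lat out of range", call. = FALSE)
  dl <- abs(((lon - frame$lon0 + 180) %% 360) - 180)
  if (any(dl > 12, na.rm = TRUE))
    warning("coordinates more than 12 degrees from the central meridian of ",
            frame$crs, "; projection distortion may exceed nominal accuracy")
  cc <- .tm_consts
  phi <- lat * pi / 180
  lam <- (((lon - frame$lon0 + 180) %% 360) - 180) * pi / 180
  es <- 2 * sqrt(cc$n) / (1 + cc$n)
  t <- sinh(atanh(sin(phi)) - es * atanh(es * sin(phi)))
  xi_p <- atan2(t, cos(lam))
  eta_p <- asinh(sin(lam) / sqrt(t^2 + cos(lam)^2))
  j <- 1:3
  xi <- xi_p
  eta <- eta_p
  for (k in j) {
    xi <- xi + cc$alpha[k] * sin(2 * k * xi_p) * cosh(2 * k * eta_p)
    eta <- eta + cc$alpha[k] * cos(2 * k * xi_p) * sinh(2 * k * eta_p)
  }
  list(x = frame$false_easting + frame$k0 * cc$A * eta,
       y = frame$false_northing + frame$k0 * cc$A * xi)
}

#' Inverse-project planar metres to lon/lat
#'
#' @param x,y Numeric vectors, metres in `frame`.
#' @param frame A [utm_frame()].
#' @return A list with numeric vectors `lon` and `lat`, degrees.
#' @export
xy_to_lonlat <- function(x, y, frame) {
  cc <- .tm_consts
  xi <- (y - frame$false_northing) / (frame$k0 * cc$A)
  eta <- (x - frame$false_easting) / (frame$k0 * cc$A)
  xi_p <- xi
  eta_p <- eta
  for (k in 1:3) {
    xi_p <- xi_p - cc$beta[k] * sin(2 * k * xi) * cosh(2 * k * eta)
    eta_p <- eta_p - cc$beta[k] * cos(2 * k * xi) * sinh(2 * k * eta)
  }
  chi <- asin(pmin(1, pmax(-1, sin(xi_p) / cosh(eta_p))))
  phi <- chi
  for (k in 1:3) phi <- phi + cc$delta[k] * sin(2 * k * chi)
  lam <- atan2(sinh(eta_p), cos(xi_p))
  list(lon = frame$lon0 + lam * 180 / pi, lat = phi * 180 / pi)
}
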