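#' Astronomical daylength
#'
#' Daylength in hours from latitude and day of year, using the CBM model of
#' Forsythe et al. (1995, Ecological Modelling 80:87-95) with the standard
#' sunrise/sunset definition (sun centre 0.8333 degrees below the horizon,
#' accounting for the solar disc and atmospheric refraction). The constant is
#' exposed so alternative twilight definitions can be swapped in.
#'
#' @param latitude latitude in decimal degrees; the temperate range
#'   `|latitude| <= 66.5` is supported (no polar day/night).
#' @param doy day of year (1-366), vectorised.
#' @param horizon solar depression angle in degrees defining day (default
#'   0.8333 = sunrise/sunset; 6 = civil twilight).
#' @return daylength in hours, in (0, 24).
#' @export
daylength <- function(latitude, doy, horizon = 0.8333) {
  check_scalar_number(latitude, "latitude", lower = -66.5, upper = 66.5)
  if (any(doy < 1 | doy > 366)) stop_field("doy", "must lie in [1, 366]")
  # revolution angle and solar declination (CBM model)
  theta <- 0.2163108 + 2 * atan(0.9671396 * tan(0.00860 * (doy - 186)))
  phi <- asin(0.39795 * cos(theta))
  lat <- latitude * pi / 180
  p <- horizon * pi / 180
  cos_h <- (sin(p) + sin(lat) * sin(phi)) / (cos(lat) * cos(phi))
  cos_h <- pmin(1, pmax(-1, cos_h))
  24 - (24 / pi) * acos(cos_h)
}
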