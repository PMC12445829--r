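#' M1 leaf-emergence model parameters
#'
#' The M1 model accumulates photoperiod-weighted thermal forcing from day
#' `t0`: on day i the forcing rate is `(Li/10)^k * max(Ti - Tb, 0)` where `Ti`
#' is the daily mean temperature and `Li` the daylength in hours. Leaf-out is
#' predicted on the first day the accumulated forcing reaches `Fcrit`.
#'
#' @param t0 day of year at which forcing accumulation starts (>= 1, i.e. on
#'   or after 1 January).
#' @param Tb base temperature for accumulation in degrees C (> 0).
#' @param k photoperiod response exponent (dimensionless, >= 0).
#' @param Fcrit critical forcing sum triggering leaf-out (> 0).
#' @return an object of class `m1_params`.
#' @export
m1_parameters <- function(t0, Tb, k, Fcrit) {
  check_scalar_number(t0, "t0", lower = 1)
  check_scalar_number(Tb, "Tb", lower = 0, strict_lower = TRUE)
  check_scalar_number(k, "k", lower = 0)
  check_scalar_number(Fcrit, "Fcrit", lower = 0, strict_lower = TRUE)
  structure(list(t0 = t0, Tb = Tb, k = k, Fcrit = Fcrit), class = "m1_params")
}

#' @export
print.m1_params <- function(x, ...) {
  cat(sprintf("<m1_params> t0 = %.2f, Tb = %.2f degC, k = %.2f, Fcrit = %.1f\n",
              x$t0, x$Tb, x$k, x$Fcrit))
  invisible(x)
}

#' Daily forcing rate of the M1 model
#'
#' @param Ti daily mean temperature, degrees C (vectorised).
#' @param Li daylength in hours (vectorised, recycled against `Ti`).
#' @param Tb base temperature, degrees C.
#' @param k photoperiod exponent.
#' @return forcing units per day: `(Li/10)^k * (Ti - Tb)` when `Ti > Tb`,
#'   else 0. Never negative.
#' @export
forcing_rate <- function(Ti, Li, Tb, k) {
  (Li / 10)^k * pmax(Ti - Tb, 0)
}

#' Predict the leaf-out date for one year
#'
#' Accumulates [forcing_rate()] of daily mean temperature from `params$t0`
#' and returns the first day of year on which the sum reaches `params$Fcrit`.
#'
#' @param climate a [climate_series()].
#' @param year calendar year to predict.
#' @param params an [m1_parameters()] object.
#' @param daylength_fun function `(latitude, doy) -> hours`; defaults to the
#'   astronomical [daylength()]. Swappable for testing and for alternative
#'   twilight definitions.
#' @return integer day of year, or `NA_integer_` if the forcing threshold is
#'   never reached by the end of the year (no predicted emergence).
#' @export
predict_leafout <- function(climate, year, params, daylength_fun = daylength) {
  stopifnot(inherits(params, "m1_params"))
  yr <- climate_year(climate, year)
  t0 <- as.integer(ceiling(params$t0))
  if (nrow(yr) == 0 || min(yr$doy) > t0)
    stop(sprintf("climate does not cover year %d from DOY %d", year, t0), call. = FALSE)
  yr <- yr[yr$doy >= t0, , drop = FALSE]
  expected <- seq(t0, max(yr$doy))
  if (!identical(as.integer(yr$doy), as.integer(expected)))
    stop(sprintf("data gap in year %d accumulation window", year), call. = FALSE)
  if (max(yr$doy) < 200)
    stop(sprintf("climate for year %d must extend through DOY 200", year), call. = FALSE)
  L <- daylength_fun(latitude_of(climate), yr$doy)
  s <- cumsum(forcing_rate(yr$tmean, L, params$Tb, params$k))
  hit <- which(s >= params$Fcrit)
  if (length(hit) == 0) return(NA_integer_)
  as.integer(yr$doy[hit[1]])
}

#' Predict leaf-out for several years
#'
#' @param years integer vector of calendar years.
#' @return data.frame with columns `site_id`, `year`, `leafout_doy`
#'   (`NA` where the model predicts no emergence).
#' @rdname predict_leafout
#' @export
predict_leafout_years <- function(climate, years, params, daylength_fun = daylength) {
  data.frame(
    site_id = site_id_of(climate),
    year = as.integer(years),
    leafout_doy = vapply(years, function(y)
      predict_leafout(climate, y, params, daylength_fun), integer(1)),
    stringsAsFactors = FALSE
  )
}

#' RMSE of M1 predictions against leaf-out observations
#'
#' @param params an [m1_parameters()] object.
#' @param climate_by_site named list of [climate_series()], names matching
#'   `observations$site_id`.
#' @param observations data.frame with `site_id`, `year`, `leafout_doy`.
#' @param na_penalty_doy if `NULL` (default) site-years where the model
#'   predicts no emergence are dropped from the RMSE; otherwise they enter
#'   with this pseudo-date (used during calibration to keep the objective
#'   bounded and steer the optimiser away from non-emerging parameters).
#' @param daylength_fun see [predict_leafout()].
#' @return root mean squared error in days.
#' @export
model_rmse <- function(params, climate_by_site, observations,
                       na_penalty_doy = NULL, daylength_fun = daylength) {
  if (nrow(observations) == 0) stop("empty observation set", call. = FALSE)
  missing_sites <- setdiff(unique(observations$site_id), names(climate_by_site))
  if (length(missing_sites))
    stop_field("climate_by_site", paste("no climate for site(s):",
                                        paste(missing_sites, collapse = ", ")))
  pred <- vapply(seq_len(nrow(observations)), function(i) {
    predict_leafout(climate_by_site[[observations$site_id[i]]],
                    observations$year[i], params, daylength_fun)
  }, integer(1))
  pred <- as.numeric(pred)
  if (!is.null(na_penalty_doy)) pred[is.na(pred)] <- na_penalty_doy
  err <- pred - observations$leafout_doy
  err <- err[!is.na(err)]
  if (length(err) == 0) stop("no site-year has both a prediction and an observation", call. = FALSE)
  sqrt(mean(err^2))
}

#' RMSE of the fixed-mean-date null model
#'
#' The null model predicts, for every test site-year, the mean observed
#' leaf-out day of the training set.
#'
#' @param train,test data.frames with a `leafout_doy` column.
#' @return RMSE in days of the test observations about the training mean.
#' @export
null_model_rmse <- function(train, test) {
  if (NROW(train) == 0) stop("empty training set", call. = FALSE)
  m <- mean(train$leafout_doy)
  sqrt(mean((test$leafout_doy - m)^2))
}
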