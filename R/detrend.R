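# Cubic smoothing spline detrending with a specified frequency response,
# in the Cook & Peters (1981) sense: the smoothing parameter is chosen so the
# fitted curve retains a fraction `f` of the amplitude of a sinusoid with
# wavelength `nyrs` years. Implemented as the discrete penalised
# least-squares smoother with a second-difference penalty, whose transfer
# function is H(w) = 1 / (1 + lambda * (2 - 2*cos w)^2); solving H = f at
# w = 2*pi/nyrs gives lambda analytically.

cps_lambda <- function(nyrs, f) {
  (1 / f - 1) / (2 - 2 * cos(2 * pi / nyrs))^2
}

#' Smoothing-spline growth curve with a 50% frequency cutoff
#'
#' Fits the penalised least-squares cubic smoothing curve whose frequency
#' response at wavelength `nyrs` years equals `f` (default: 50% cutoff at
#' 30 yr, the standard age-trend removal for ring-width series).
#'
#' @param y numeric series at unit (yearly) spacing, no internal `NA`.
#' @param nyrs cutoff wavelength in years.
#' @param f frequency response retained at that wavelength, in (0, 1).
#' @return fitted values, same length as `y`.
#' @export
cps_spline <- function(y, nyrs = 30, f = 0.5) {
  n <- length(y)
  if (anyNA(y)) stop_field("y", "internal NA not allowed")
  if (n < 4) return(rep(mean(y), n))
  lambda <- cps_lambda(nyrs, f)
  D <- diff(diag(n), differences = 2)           # (n-2) x n second differences
  A <- diag(n) + lambda * crossprod(D)
  as.numeric(solve(A, y))
}

#' Detrend a ring-width series to a ring-width index
#'
#' Divides each width by the fitted smoothing-spline growth curve
#' ([cps_spline()]), yielding a dimensionless index that varies around 1. If
#' the spline fit dips to zero or below anywhere, the series falls back to a
#' linear fit, and to the series mean if that is also non-positive; a warning
#' names the fallback.
#'
#' @param widths ring widths in mm (one series, > 0, no internal `NA`).
#' @param years optional matching year vector (returned in the result).
#' @param nyrs,f spline cutoff, see [cps_spline()].
#' @return list: `rwi` (index), `fitted` (growth curve), `years`, `method`
#'   (`"spline"`, `"linear"` or `"mean"`).
#' @export
spline_detrend <- function(widths, years = NULL, nyrs = 30, f = 0.5) {
  if (length(widths) < 10) stop_field("widths", "series length must be >= 10")
  if (any(widths <= 0, na.rm = TRUE)) stop_field("widths", "widths must be > 0")
  if (is.null(years)) years <- seq_along(widths)
  fitted <- cps_spline(widths, nyrs, f)
  method <- "spline"
  if (any(fitted <= 0)) {
    fit <- stats::lm.fit(cbind(1, seq_along(widths)), widths)
    fitted <- as.numeric(cbind(1, seq_along(widths)) %*% fit$coefficients)
    method <- "linear"
    if (any(fitted <= 0)) {
      fitted <- rep(mean(widths), length(widths))
      method <- "mean"
    }
    warning(sprintf("spline growth curve non-positive; fell back to %s detrending",
                    method), call. = FALSE)
  }
  list(rwi = widths / fitted, fitted = fitted, years = years, method = method)
}

#' Detrend every series of a ring-width table
#'
#' Applies [spline_detrend()] column-wise to a wide `rwl` table, preserving
#' each series' span.
#'
#' @param rwl wide data.frame (years as rownames, series as columns).
#' @param nyrs,f spline cutoff, see [cps_spline()].
#' @param exclude character vector of series ids to drop (e.g. cores
#'   discarded after crossdating checks upstream).
#' @return wide data.frame of ring-width indices with the same shape;
#'   attribute `detrend_method` records the per-series fit used.
#' @export
detrend_rwl <- function(rwl, nyrs = 30, f = 0.5, exclude = character()) {
  keep <- setdiff(colnames(rwl), exclude)
  out <- rwl[, keep, drop = FALSE]
  methods <- character(length(keep))
  names(methods) <- keep
  for (id in keep) {
    v <- rwl[[id]]
    ok <- which(!is.na(v))
    span <- ok[1]:ok[length(ok)]
    d <- spline_detrend(v[span], nyrs = nyrs, f = f)
    col <- rep(NA_real_, nrow(rwl))
    col[span] <- d$rwi
    out[[id]] <- col
    methods[id] <- d$method
  }
  attr(out, "detrend_method") <- methods
  class(out) <- c("rwl", "data.frame")
  out
}
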