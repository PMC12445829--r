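#' Mann-Kendall trend test
#'
#' Nonparametric monotone-trend test with the standard tie correction on the
#' variance of the S statistic and a continuity-corrected normal
#' approximation for the two-sided p-value. A constant series returns
#' `S = 0`, `tau = 0`, `p = 1`.
#'
#' @param y numeric series in time order (`NA` dropped).
#' @return list: `S`, `var_S`, `z`, `p` (two-sided), `tau` (Kendall's tau-b),
#'   `n`.
#' @export
mann_kendall <- function(y) {
  y <- y[!is.na(y)]
  n <- length(y)
  if (n < 3) stop_field("y", "needs >= 3 non-missing values")
  s <- 0
  for (i in seq_len(n - 1))
    s <- s + sum(sign(y[(i + 1):n] - y[i]))
  ties <- table(y)
  ties <- ties[ties > 1]
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  # tau-b denominator (time axis has no ties)
  d1 <- n * (n - 1) / 2
  d2 <- d1 - sum(ties * (ties - 1) / 2)
  tau <- if (d2 == 0) 0 else s / sqrt(d1 * d2)
  if (var_s <= 0) {
    z <- 0; p <- 1
  } else {
    z <- (s - sign(s)) / sqrt(var_s)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(S = s, var_S = var_s, z = z, p = min(1, p), tau = tau, n = n)
}

#' Theil-Sen trend with Mann-Kendall significance
#'
#' Robust linear trend of a yearly series: the slope is the median of all
#' pairwise slopes, reported per decade, with the rank-based 95% confidence
#' interval of Sen (1968) and the two-sided [mann_kendall()] p-value.
#'
#' @param values numeric yearly values (`NA` allowed).
#' @param years matching year vector; defaults to `seq_along(values)` treated
#'   as consecutive years.
#' @param conf confidence level for the slope interval (default 0.95).
#' @return object of class `trend_result`: `slope` and `ci95` in days (or
#'   series units) per decade, `mk_p`, `kendall_tau`, `n`.
#' @export
theil_sen_trend <- function(values, years = NULL, conf = 0.95) {
  if (is.null(years)) years <- seq_along(values)
  keep <- !is.na(values) & !is.na(years)
  y <- values[keep]; x <- years[keep]
  n <- length(y)
  if (n < 3) stop_field("values", "needs >= 3 non-missing points")
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  slopes <- (y[ij[2, ]] - y[ij[1, ]]) / dx
  slopes <- sort(slopes[dx != 0])
  slope <- stats::median(slopes)
  mk <- mann_kendall(y[order(x)])
  nn <- length(slopes)
  if (mk$var_S > 0) {
    c_alpha <- stats::qnorm(1 - (1 - conf) / 2) * sqrt(mk$var_S)
    m1 <- max(1L, floor((nn - c_alpha) / 2))
    m2 <- min(nn, ceiling((nn + c_alpha) / 2) + 1)
    ci <- c(slopes[m1], slopes[m2])
  } else {
    ci <- c(slope, slope)
  }
  structure(list(slope = 10 * slope, ci95 = 10 * ci, mk_p = mk$p,
                 kendall_tau = mk$tau, n = n),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("<trend_result> slope %.2f per decade [%.2f, %.2f], MK p = %.3g, tau = %.2f, n = %d\n",
              x$slope, x$ci95[1], x$ci95[2], x$mk_p, x$kendall_tau, x$n))
  invisible(x)
}
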