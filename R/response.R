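#' Daywise climate-growth correlation grid
#'
#' Pearson correlations between a chronology and a daily climate variable
#' aggregated, per year, over every combination of window start day and
#' window length: temperatures are averaged, precipitation is summed.
#' Windows extending past the end of the year are skipped and zero-variance
#' aggregates are dropped.
#'
#' @param chronology data.frame `year, value`.
#' @param climate a [climate_series()].
#' @param variable one of `"tmin"`, `"tmax"`, `"tmean"`, `"precip"`.
#' @param start_doys window start days (default 1..270).
#' @param window_lengths window lengths in days (default 15..90 by 5).
#' @param aggregation `"mean"` or `"sum"`; default `"sum"` for precipitation
#'   and `"mean"` otherwise.
#' @param min_overlap minimum chronology-climate overlap in years (default 20).
#' @param mask_p optional p-value threshold: cells with `p >=` it are removed
#'   from the output (the convention for plotting only significant cells).
#' @return long data.frame `variable, start_doy, window_length, r, p, n`.
#' @export
daywise_correlations <- function(chronology, climate,
                                 variable = c("tmin", "tmax", "tmean", "precip"),
                                 start_doys = 1:270,
                                 window_lengths = seq(15, 90, by = 5),
                                 aggregation = NULL,
                                 min_overlap = 20L,
                                 mask_p = NULL) {
  variable <- match.arg(variable)
  if (is.null(aggregation))
    aggregation <- if (variable == "precip") "sum" else "mean"
  aggregation <- match.arg(aggregation, c("mean", "sum"))
  years <- intersect(chronology$year, unique(climate$year))
  # only years with full DOY coverage up to the largest window end
  doy_need <- min(366L, max(start_doys) + max(window_lengths) - 1L)
  years <- years[vapply(years, function(y) {
    d <- climate$doy[climate$year == y]
    length(d) >= doy_need && all(seq_len(doy_need) %in% d)
  }, logical(1))]
  if (length(years) < min_overlap)
    stop(sprintf("chronology-climate overlap is %d yr (< %d)", length(years),
                 min_overlap), call. = FALSE)
  chron <- chronology$value[match(years, chronology$year)]
  # per-year cumulative sums over DOY for O(1) window aggregation
  cum <- matrix(0, nrow = length(years), ncol = doy_need + 1L)
  for (i in seq_along(years)) {
    yr <- climate[climate$year == years[i] & climate$doy <= doy_need, ]
    cum[i, -1] <- cumsum(yr[[variable]][order(yr$doy)])
  }
  res <- list()
  n <- length(years)
  for (len in window_lengths) {
    for (s in start_doys) {
      e <- s + len - 1L
      if (e > doy_need) next
      agg <- cum[, e + 1L] - cum[, s]
      if (aggregation == "mean") agg <- agg / len
      if (stats::sd(agg) == 0 || stats::sd(chron) == 0) next
      r <- stats::cor(chron, agg)
      tt <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * stats::pt(-abs(tt), df = n - 2)
      res[[length(res) + 1L]] <- c(s, len, r, p)
    }
  }
  if (length(res) == 0)
    return(data.frame(variable = character(), start_doy = integer(),
                      window_length = integer(), r = numeric(), p = numeric(),
                      n = integer()))
  out <- as.data.frame(do.call(rbind, res))
  names(out) <- c("start_doy", "window_length", "r", "p")
  out <- data.frame(variable = variable, out, n = n, stringsAsFactors = FALSE)
  if (!is.null(mask_p)) out <- out[out$p < mask_p, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Superposed epoch analysis of event years
#'
#' Mean scaled chronology anomaly at each lag relative to a set of event
#' years, with a bootstrap null built from equally many pseudo-event years
#' drawn (with replacement) from all years having full lag coverage.
#' Anomalies are departures from the chronology mean scaled by its standard
#' deviation; a lag is significant (two-tailed, 5%) when the observed
#' anomaly falls outside the 2.5-97.5% quantiles of the null means.
#'
#' @param chronology data.frame `year, value`.
#' @param event_years integer years of the aligned events.
#' @param lags integer lags in years relative to each event (default 0..4,
#'   the event year and the four following).
#' @param n_boot bootstrap resamples (>= 199; default 999).
#' @param seed RNG seed for the resampling.
#' @return data.frame of class `sea_result`: `lag, anomaly, lo, hi,
#'   significant`; attributes `n_events`, `n_boot`, `seed`,
#'   `dropped_events`.
#' @export
superposed_epoch <- function(chronology, event_years, lags = 0:4,
                             n_boot = 999L, seed = 1L) {
  if (n_boot < 199) stop_field("n_boot", "must be >= 199")
  years <- chronology$year
  vals <- chronology$value
  s <- stats::sd(vals)
  scaled <- if (is.na(s) || s == 0) rep(0, length(vals)) else (vals - mean(vals)) / s
  # years usable as (pseudo-)events: every lag must land on a non-NA year
  eligible <- years[vapply(years, function(y)
    all((y + lags) %in% years[!is.na(vals)]), logical(1))]
  keep <- event_years %in% eligible
  dropped <- event_years[!keep]
  if (length(dropped))
    warning("event year(s) without full lag coverage dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  ev <- event_years[keep]
  if (length(ev) < 2)
    stop("fewer than 2 event years with full lag coverage", call. = FALSE)
  at <- function(yrs, lag) scaled[match(yrs + lag, years)]
  anomaly <- vapply(lags, function(L) mean(at(ev, L)), numeric(1))
  boot <- with_seed(seed, {
    b <- matrix(NA_real_, nrow = n_boot, ncol = length(lags))
    for (r in seq_len(n_boot)) {
      pseudo <- sample(eligible, length(ev), replace = TRUE)
      b[r, ] <- vapply(lags, function(L) mean(at(pseudo, L)), numeric(1))
    }
    b
  })
  qs <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  out <- data.frame(lag = lags, anomaly = anomaly, lo = qs[1, ], hi = qs[2, ],
                    significant = anomaly < qs[1, ] | anomaly > qs[2, ])
  structure(out, n_events = length(ev), n_boot = n_boot, seed = seed,
            dropped_events = dropped, class = c("sea_result", "data.frame"))
}
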