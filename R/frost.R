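#' Last spring frost of a year
#'
#' Latest day within the search window on which the daily minimum temperature
#' is at or below the frost threshold. Threshold comparisons are inclusive
#' (`tmin <= threshold`) throughout the package.
#'
#' @param climate a [climate_series()].
#' @param year calendar year.
#' @param threshold frost threshold in degrees C (default -1).
#' @param search_window integer `c(first_doy, last_doy)` searched; default
#'   DOY 1-181, i.e. through June.
#' @return integer day of year, or `NA_integer_` when no frost occurs.
#' @export
last_spring_frost <- function(climate, year, threshold = -1,
                              search_window = c(1L, 181L)) {
  yr <- climate_year(climate, year)
  yr <- yr[yr$doy >= search_window[1] & yr$doy <= search_window[2], , drop = FALSE]
  expected <- seq(search_window[1], search_window[2])
  if (!identical(as.integer(yr$doy), as.integer(expected)))
    stop(sprintf("data gap in year %d within DOY %d..%d", year,
                 search_window[1], search_window[2]), call. = FALSE)
  hits <- yr$doy[yr$tmin <= threshold]
  if (length(hits) == 0) NA_integer_ else as.integer(max(hits))
}

#' Frost events within the leaf-out damage window
#'
#' Tests whether any frost at or below `threshold` falls in the window
#' `[leafout + window[1], leafout + window[2]]` (inclusive bounds; default 5
#' days before to 14 days after leaf-out), and lists the qualifying events.
#'
#' @inheritParams last_spring_frost
#' @param leafout_doy predicted leaf-out day of year (`NA` allowed).
#' @param window integer `c(before, after)` day offsets relative to leaf-out.
#' @return list with `window_frost` (logical; `NA` when `leafout_doy` is
#'   `NA`) and `events`, a data.frame `year, doy, tmin, daily_amplitude`.
#' @export
frost_in_window <- function(climate, year, leafout_doy, threshold = -1,
                            window = c(-5L, 14L)) {
  empty <- data.frame(year = integer(), doy = integer(), tmin = numeric(),
                      daily_amplitude = numeric())
  if (is.na(leafout_doy))
    return(list(window_frost = NA, events = empty))
  lo <- leafout_doy + window[1]
  hi <- leafout_doy + window[2]
  yr <- climate_year(climate, year)
  win <- yr[yr$doy >= lo & yr$doy <= hi, , drop = FALSE]
  expected <- seq(max(lo, min(yr$doy)), min(hi, max(yr$doy)))
  if (!identical(as.integer(win$doy), as.integer(expected)))
    stop(sprintf("data gap in year %d within the frost window", year), call. = FALSE)
  ev <- win[win$tmin <= threshold, , drop = FALSE]
  events <- data.frame(year = as.integer(ev$year), doy = as.integer(ev$doy),
                       tmin = ev$tmin, daily_amplitude = ev$tmax - ev$tmin)
  list(window_frost = nrow(events) > 0, events = events)
}

#' Frost safety margin
#'
#' Signed difference between the leaf-out date and the last spring frost:
#' positive values mean the last frost preceded leaf-out (safe), negative
#' values mean frost struck after leaf-out.
#'
#' @param leafout_doy,last_frost_doy day-of-year values (vectorised); `NA` in
#'   either yields `NA`.
#' @return margin in days.
#' @export
safety_margin <- function(leafout_doy, last_frost_doy) {
  as.numeric(leafout_doy) - as.numeric(last_frost_doy)
}

#' Per-year frost-risk records for one site
#'
#' Combines, for every year with a leaf-out value, the last spring frost, the
#' safety margin and the damage-window flag into one record.
#'
#' @inheritParams last_spring_frost
#' @param leafout data.frame `year, leafout_doy` (`NA` leaf-out allowed:
#'   such years get `NA` margin and flag and are excluded from trend sample
#'   sizes downstream).
#' @param window damage window, see [frost_in_window()].
#' @return data.frame `site_id, year, leafout_doy, last_frost_doy,
#'   margin_days, window_frost, n_window_events` with attribute
#'   `window_events` (row-bound event tables).
#' @export
safety_margin_records <- function(climate, leafout, threshold = -1,
                                  window = c(-5L, 14L),
                                  search_window = c(1L, 181L)) {
  stopifnot(all(c("year", "leafout_doy") %in% names(leafout)))
  events <- list()
  rec <- lapply(seq_len(nrow(leafout)), function(i) {
    y <- leafout$year[i]
    lo <- leafout$leafout_doy[i]
    lf <- last_spring_frost(climate, y, threshold, search_window)
    fw <- frost_in_window(climate, y, lo, threshold, window)
    events[[as.character(y)]] <<- fw$events
    data.frame(site_id = site_id_of(climate), year = as.integer(y),
               leafout_doy = as.integer(lo), last_frost_doy = lf,
               margin_days = safety_margin(lo, lf),
               window_frost = fw$window_frost,
               n_window_events = nrow(fw$events),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rec)
  attr(out, "window_events") <- do.call(rbind, events)
  out
}

#' Centered moving average
#'
#' @param x numeric series (NA allowed).
#' @param window window length in points; even windows extend one point
#'   further to the right (a 10-point window uses offsets -4..+5).
#' @param min_obs minimum non-missing points required, else `NA`.
#' @return numeric vector, same length as `x`.
#' @export
moving_average <- function(x, window = 10L, min_obs = 6L) {
  n <- length(x)
  left <- floor((window - 1) / 2)
  right <- window - 1 - left
  vapply(seq_len(n), function(i) {
    w <- x[max(1, i - left):min(n, i + right)]
    if (sum(!is.na(w)) < min_obs) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
}

#' Site-level frost-risk summary
#'
#' @param records output of [safety_margin_records()] (one or more sites
#'   row-bound).
#' @param periods optional list of `c(first_year, last_year)` ranges for
#'   counting negative-margin years per sub-period.
#' @param ma_window,ma_min moving-average window and minimum coverage for the
#'   smoothed margin series (default 10-yr centered, >= 6 non-missing).
#' @return list: `by_site` data.frame (`n_years`, `n_window_frost`,
#'   `pct_window_frost`, `margin_mean`, `margin_se`, `n_negative_margin`),
#'   `negative_by_period` (when `periods` given) and `moving_average`
#'   data.frame (`site_id, year, margin_ma`).
#' @export
risk_summary <- function(records, periods = NULL, ma_window = 10L, ma_min = 6L) {
  if (nrow(records) == 0) stop("no records", call. = FALSE)
  split_site <- split(records, records$site_id)
  by_site <- do.call(rbind, lapply(split_site, function(r) {
    m <- r$margin_days[!is.na(r$margin_days)]
    flagged <- r$window_frost[!is.na(r$window_frost)]
    data.frame(site_id = r$site_id[1],
               n_years = nrow(r),
               n_window_frost = sum(flagged),
               pct_window_frost = 100 * sum(flagged) / length(flagged),
               margin_mean = mean(m),
               margin_se = stats::sd(m) / sqrt(length(m)),
               n_negative_margin = sum(m < 0),
               stringsAsFactors = FALSE)
  }))
  rownames(by_site) <- NULL
  neg <- NULL
  if (!is.null(periods)) {
    neg <- do.call(rbind, lapply(split_site, function(r) {
      do.call(rbind, lapply(periods, function(p) {
        sel <- r$year >= p[1] & r$year <= p[2] & !is.na(r$margin_days)
        data.frame(site_id = r$site_id[1], first = p[1], last = p[2],
                   n_negative = sum(r$margin_days[sel] < 0),
                   stringsAsFactors = FALSE)
      }))
    }))
    rownames(neg) <- NULL
  }
  ma <- do.call(rbind, lapply(split_site, function(r) {
    r <- r[order(r$year), ]
    data.frame(site_id = r$site_id[1], year = r$year,
               margin_ma = moving_average(r$margin_days, ma_window, ma_min),
               stringsAsFactors = FALSE)
  }))
  rownames(ma) <- NULL
  list(by_site = by_site, negative_by_period = neg, moving_average = ma)
}
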