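# Independent oracles and small fixture builders used across the suite.
# Oracles are written as plain day-by-day / element-by-element computations,
# independent of the vectorised implementation paths they check.

# Day-loop leaf-out oracle: accumulate forcing one day at a time.
oracle_leafout <- function(climate, year, params, daylength_fun = daylength) {
  yr <- climate[climate$year == year, ]
  yr <- yr[order(yr$doy), ]
  s <- 0
  for (i in seq_len(nrow(yr))) {
    if (yr$doy[i] < ceiling(params$t0)) next
    L <- daylength_fun(attr(climate, "latitude"), yr$doy[i])
    Ti <- yr$tmean[i]
    r <- if (Ti > params$Tb) (L / 10)^params$k * (Ti - params$Tb) else 0
    s <- s + r
    if (s >= params$Fcrit) return(as.integer(yr$doy[i]))
  }
  NA_integer_
}

# Plain growing-degree-day predictor (no photoperiod term).
oracle_gdd_leafout <- function(climate, year, Tb, Fcrit, t0 = 1) {
  yr <- climate[climate$year == year, ]
  yr <- yr[order(yr$doy), ]
  s <- 0
  for (i in seq_len(nrow(yr))) {
    if (yr$doy[i] < t0) next
    s <- s + max(yr$tmean[i] - Tb, 0)
    if (s >= Fcrit) return(as.integer(yr$doy[i]))
  }
  NA_integer_
}

# Iterative Tukey biweight oracle (explicit while loop).
oracle_biweight <- function(x, const = 9) {
  x <- x[!is.na(x)]
  m <- median(x)
  s <- 1.4826 * median(abs(x - median(x)))
  if (s == 0) return(m)
  repeat {
    u <- (x - m) / (const * s)
    w <- rep(0, length(x))
    inside <- abs(u) < 1
    w[inside] <- (1 - u[inside]^2)^2
    m_new <- sum(w * x) / sum(w)
    if (abs(m_new - m) < 1e-12) return(m_new)
    m <- m_new
  }
}

# Exhaustive pairwise-slope median.
oracle_median_pairwise_slope <- function(x, y) {
  slopes <- c()
  n <- length(x)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (x[j] != x[i]) slopes <- c(slopes, (y[j] - y[i]) / (x[j] - x[i]))
    }
  }
  median(slopes)
}

# Hand-made constant-temperature climate covering given years.
constant_climate <- function(years, tmean, diurnal_range = 8, latitude = 47.4,
                             site_id = "const") {
  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  climate_series(data.frame(date = dates, tmin = tmean - diurnal_range / 2,
                            tmean = tmean, tmax = tmean + diurnal_range / 2),
                 site_id = site_id, latitude = latitude)
}

# Small, fast synthetic site for unit tests (overridable defaults).
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_years = 40, start_year = 1961, n_trees_per_species = 8),
    list(...))
  do.call(synthetic_config, args)
}

# Detrended per-tree indices for one generated species table.
trees_from_rwl <- function(rwl, nyrs = 30) {
  average_cores(detrend_rwl(rwl, nyrs = nyrs))
}
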