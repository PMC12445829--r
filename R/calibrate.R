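# M1 calibration: bounded simulated annealing with an optional analytic
# profile of Fcrit, plus a coordinate-descent polish. The public contract is
# "seeded derivative-free global minimiser of model_rmse within bounds"; the
# annealing budget and starting temperature are tunable and match the
# published calibration setup by default.

#' Default M1 calibration bounds
#'
#' Forcing may start on or after 1 January (`t0 >= 1`) and the base
#' temperature must be positive; the box encloses all published values.
#'
#' @return list with elements `t0`, `Tb`, `k`, `Fcrit`, each `c(lower, upper)`.
#' @export
default_m1_bounds <- function() {
  list(t0 = c(1, 90), Tb = c(0.01, 10), k = c(0, 10), Fcrit = c(1, 5000))
}

validate_bounds <- function(bounds) {
  for (nm in c("t0", "Tb", "k", "Fcrit")) {
    b <- bounds[[nm]]
    if (is.null(b) || length(b) != 2 || b[1] > b[2])
      stop_field("bounds", sprintf("%s must be c(lower, upper)", nm))
  }
  if (bounds$t0[1] < 1)
    stop_field("bounds", "forcing may only start on/after 1 January (t0 >= 1)")
  if (bounds$Tb[1] <= 0)
    stop_field("bounds", "base temperature must be > 0 degC")
  invisible(bounds)
}

# Precompute, per site, a (years x doy) mean-temperature matrix and the
# daylength weights, and index every observation into it. doy_max caps the
# accumulation window; non-emerging predictions are penalised at doy_max.
forcing_context <- function(climate_by_site, observations, doy_max = 250L,
                            daylength_fun = daylength) {
  if (nrow(observations) == 0) stop("empty observation set", call. = FALSE)
  obs <- observations[order(observations$site_id, observations$year), , drop = FALSE]
  sites <- unique(obs$site_id)
  missing_sites <- setdiff(sites, names(climate_by_site))
  if (length(missing_sites))
    stop_field("climate_by_site", paste("no climate for site(s):",
                                        paste(missing_sites, collapse = ", ")))
  ctx_sites <- lapply(sites, function(s) {
    cl <- climate_by_site[[s]]
    years <- sort(unique(obs$year[obs$site_id == s]))
    Tm <- matrix(NA_real_, nrow = length(years), ncol = doy_max,
                 dimnames = list(years, NULL))
    for (i in seq_along(years)) {
      yr <- climate_year(cl, years[i])
      yr <- yr[yr$doy <= doy_max, , drop = FALSE]
      if (nrow(yr) < doy_max || !identical(as.integer(yr$doy), seq_len(doy_max)))
        stop(sprintf("site %s year %d: climate must cover DOY 1..%d without gaps",
                     s, years[i], doy_max), call. = FALSE)
      Tm[i, ] <- yr$tmean
    }
    list(T = Tm, L = daylength_fun(latitude_of(cl), seq_len(doy_max)),
         years = years)
  })
  names(ctx_sites) <- sites
  obs$row_in_site <- vapply(seq_len(nrow(obs)), function(i)
    match(obs$year[i], ctx_sites[[obs$site_id[i]]]$years), integer(1))
  list(sites = ctx_sites, obs = obs, doy_max = doy_max)
}

# Per-site cumulative forcing matrices (rows = site-years). Row-wise cumsum
# is done on one row-major vector with per-row offsets subtracted, which is
# much faster than apply().
context_forcing <- function(ctx, t0, Tb, k) {
  t0c <- as.integer(ceiling(t0))
  lapply(ctx$sites, function(sc) {
    w <- (sc$L / 10)^k
    R <- pmax(sc$T - Tb, 0) * matrix(w, nrow(sc$T), ctx$doy_max, byrow = TRUE)
    if (t0c > 1) R[, seq_len(t0c - 1)] <- 0
    n <- nrow(R); m <- ncol(R)
    v <- cumsum(as.vector(t(R)))
    S <- matrix(v, n, m, byrow = TRUE)
    off <- c(0, v[seq_len(n - 1) * m])
    S - off   # off recycles down each column, i.e. per row
  })
}

# RMSE of the fast matrix path; Fcrit = NULL profiles it as the median
# accumulated forcing at the observed dates (clamped to fcrit_bounds).
context_rmse <- function(ctx, t0, Tb, k, Fcrit = NULL,
                         fcrit_bounds = c(1, 5000), details = FALSE) {
  S <- context_forcing(ctx, t0, Tb, k)
  obs <- ctx$obs
  if (is.null(Fcrit)) {
    s_at_obs <- vapply(seq_len(nrow(obs)), function(i) {
      S[[obs$site_id[i]]][obs$row_in_site[i], min(obs$leafout_doy[i], ctx$doy_max)]
    }, numeric(1))
    Fcrit <- stats::median(s_at_obs)
    Fcrit <- min(fcrit_bounds[2], max(fcrit_bounds[1], Fcrit))
  }
  pred <- vapply(seq_len(nrow(obs)), function(i) {
    row <- S[[obs$site_id[i]]][obs$row_in_site[i], ]
    n_below <- sum(row < Fcrit)
    if (n_below >= ctx$doy_max) ctx$doy_max else n_below + 1L
  }, numeric(1))
  rmse <- sqrt(mean((pred - obs$leafout_doy)^2))
  if (details) list(rmse = rmse, Fcrit = Fcrit, pred = pred) else rmse
}

reflect_into <- function(x, lower, upper) {
  span <- upper - lower
  for (j in seq_along(x)) {
    if (span[j] == 0) { x[j] <- lower[j]; next }
    while (x[j] < lower[j] || x[j] > upper[j]) {
      if (x[j] < lower[j]) x[j] <- 2 * lower[j] - x[j]
      if (x[j] > upper[j]) x[j] <- 2 * upper[j] - x[j]
    }
  }
  x
}

# Bounded simulated annealing (geometric cooling, reflecting proposals).
# Caller is responsible for seeding the RNG.
sa_minimize <- function(energy, lower, upper, n_calls,
                        initial_temperature = 1e4, final_temperature = 1e-6,
                        step0 = 0.5) {
  d <- length(lower)
  range <- upper - lower
  x <- lower + stats::runif(d) * range
  e <- energy(x)
  best_x <- x; best_e <- e
  if (n_calls > 1) {
    alpha <- (final_temperature / initial_temperature)^(1 / (n_calls - 1))
    temp <- initial_temperature
    for (i in seq_len(n_calls - 1)) {
      step <- step0 * (1 - 0.96 * i / n_calls)
      prop <- reflect_into(x + (stats::runif(d) * 2 - 1) * step * range,
                           lower, upper)
      ep <- energy(prop)
      if (ep <= e || stats::runif(1) < exp(-(ep - e) / temp)) {
        x <- prop; e <- ep
      }
      if (ep < best_e) { best_x <- prop; best_e <- ep }
      temp <- temp * alpha
    }
  }
  list(par = best_x, value = best_e, calls = n_calls)
}

# Derivative-free coordinate descent with shrinking steps; robust on the
# plateaued (integer-valued-prediction) RMSE surface.
coord_polish <- function(energy, x, e, lower, upper, budget,
                         step_frac = 0.08, shrink = 0.5, min_frac = 5e-5) {
  range <- pmax(upper - lower, .Machine$double.eps)
  step <- step_frac * range
  calls <- 0L
  while (calls < budget && max(step / range) > min_frac) {
    improved <- FALSE
    for (j in seq_along(x)) {
      for (s in c(step[j], -step[j])) {
        if (calls >= budget) break
        xp <- x
        xp[j] <- min(upper[j], max(lower[j], x[j] + s))
        ep <- energy(xp); calls <- calls + 1L
        if (ep < e - 1e-12) { x <- xp; e <- ep; improved <- TRUE; break }
      }
    }
    if (!improved) step <- step * shrink
  }
  list(par = x, value = e, calls = calls)
}

#' Calibrate the M1 model on leaf-out observations
#'
#' Minimises the root mean squared error between predicted and observed
#' leaf-out dates over the parameter box, using seeded simulated annealing
#' followed by a coordinate-descent polish. By default `Fcrit` is profiled
#' analytically at each candidate `(t0, Tb, k)` (the median accumulated
#' forcing at the observed dates), which removes the strongest parameter
#' ridge from the search. Site-years where a candidate model predicts no
#' emergence are penalised with pseudo-day `doy_max` (250) so the objective
#' stays bounded.
#'
#' @param climate_by_site named list of [climate_series()].
#' @param observations data.frame `site_id, year, leafout_doy`.
#' @param bounds parameter box, see [default_m1_bounds()]; lower bounds must
#'   respect `t0 >= 1` and `Tb > 0`.
#' @param control list: `max_calls` total objective budget (default 40000),
#'   `initial_temperature` (default 1e4), `seed`, `profile_fcrit` (default
#'   TRUE), `sa_fraction` share of the budget spent annealing (default 0.6),
#'   `doy_max` accumulation cap / non-emergence penalty day (default 250).
#' @return object of class `m1_calibration`: `params` ([m1_parameters()]),
#'   `train_rmse`, `null_rmse` (fixed-mean null on the same data),
#'   `n_site_years`, `optimizer_calls`, `seed`, `bounds`, `degenerate`
#'   (TRUE when there are fewer observations than free parameters).
#' @export
calibrate <- function(climate_by_site, observations,
                      bounds = default_m1_bounds(), control = list()) {
  validate_bounds(bounds)
  ctrl <- utils::modifyList(list(max_calls = 40000L, initial_temperature = 1e4,
                                 seed = 1L, profile_fcrit = TRUE,
                                 sa_fraction = 0.6, doy_max = 250L), control)
  ctx <- forcing_context(climate_by_site, observations, doy_max = ctrl$doy_max)
  n_obs <- nrow(ctx$obs)
  n_sa <- max(2L, as.integer(round(ctrl$sa_fraction * ctrl$max_calls)))
  calls <- 0L
  if (isTRUE(ctrl$profile_fcrit)) {
    n_polish <- max(0L, as.integer(round(0.3 * ctrl$max_calls)))
    n_final <- max(0L, ctrl$max_calls - n_sa - n_polish)
    lower <- c(bounds$t0[1], bounds$Tb[1], bounds$k[1])
    upper <- c(bounds$t0[2], bounds$Tb[2], bounds$k[2])
    energy <- function(v) {
      calls <<- calls + 1L
      context_rmse(ctx, v[1], v[2], v[3], Fcrit = NULL,
                   fcrit_bounds = bounds$Fcrit)
    }
    lower4 <- c(lower, bounds$Fcrit[1])
    upper4 <- c(upper, bounds$Fcrit[2])
    energy4 <- function(v) {
      calls <<- calls + 1L
      context_rmse(ctx, v[1], v[2], v[3], Fcrit = v[4])
    }
    fit <- with_seed(ctrl$seed, {
      sa <- sa_minimize(energy, lower, upper, n_sa,
                        initial_temperature = ctrl$initial_temperature)
      p3 <- coord_polish(energy, sa$par, sa$value, lower, upper, n_polish)
      det <- context_rmse(ctx, p3$par[1], p3$par[2], p3$par[3], Fcrit = NULL,
                          fcrit_bounds = bounds$Fcrit, details = TRUE)
      # free Fcrit for a short final polish around the profiled value
      coord_polish(energy4, c(p3$par, det$Fcrit), det$rmse, lower4, upper4,
                   n_final, step_frac = 0.01)
    })
    params <- m1_parameters(fit$par[1], fit$par[2], fit$par[3], fit$par[4])
    train_rmse <- fit$value
  } else {
    n_polish <- max(0L, ctrl$max_calls - n_sa)
    lower <- c(bounds$t0[1], bounds$Tb[1], bounds$k[1], bounds$Fcrit[1])
    upper <- c(bounds$t0[2], bounds$Tb[2], bounds$k[2], bounds$Fcrit[2])
    energy <- function(v) {
      calls <<- calls + 1L
      context_rmse(ctx, v[1], v[2], v[3], Fcrit = v[4])
    }
    fit <- with_seed(ctrl$seed, {
      sa <- sa_minimize(energy, lower, upper, n_sa,
                        initial_temperature = ctrl$initial_temperature)
      coord_polish(energy, sa$par, sa$value, lower, upper, n_polish)
    })
    params <- m1_parameters(fit$par[1], fit$par[2], fit$par[3], fit$par[4])
    train_rmse <- fit$value
  }
  structure(list(
    params = params,
    train_rmse = train_rmse,
    null_rmse = null_model_rmse(ctx$obs, ctx$obs),
    n_site_years = n_obs,
    optimizer_calls = calls,
    seed = ctrl$seed,
    bounds = bounds,
    degenerate = n_obs < 4L
  ), class = "m1_calibration")
}

#' @export
print.m1_calibration <- function(x, ...) {
  cat(sprintf("<m1_calibration> %d site-years, %d objective calls%s\n",
              x$n_site_years, x$optimizer_calls,
              if (x$degenerate) " [DEGENERATE FIT]" else ""))
  print(x$params)
  cat(sprintf("  train RMSE %.2f d (null %.2f d)\n", x$train_rmse, x$null_rmse))
  invisible(x)
}

#' k-fold cross-validation of the M1 model
#'
#' Site-years are partitioned into `n_folds` random folds (reproducible from
#' `seed`, invariant to the input row order); each fold is predicted by a
#' model calibrated on the remaining folds. Non-emerging predictions on the
#' held-out fold are penalised at the calibration pseudo-day.
#'
#' @inheritParams calibrate
#' @param n_folds number of folds (>= 2, <= number of site-years).
#' @param seed seed for the fold assignment and per-fold calibrations.
#' @return list: `mean_rmse` (mean held-out RMSE over folds, days),
#'   `fold_rmse`, `null_mean_rmse` (held-out RMSE of the fixed-mean null),
#'   `folds` (assignment aligned to observations sorted by site then year),
#'   `fits` (per-fold `m1_calibration` objects).
#' @export
cross_validate <- function(climate_by_site, observations, n_folds = 10L,
                           seed = 1L, bounds = default_m1_bounds(),
                           control = list()) {
  obs <- observations[order(observations$site_id, observations$year), , drop = FALSE]
  n <- nrow(obs)
  if (n_folds < 2) stop_field("n_folds", "must be >= 2")
  if (n_folds > n) stop_field("n_folds", "exceeds the number of site-years")
  folds <- with_seed(seed, sample(rep(seq_len(n_folds), length.out = n)))
  ctrl <- utils::modifyList(list(doy_max = 250L), control)
  fold_rmse <- numeric(n_folds)
  null_rmse <- numeric(n_folds)
  fits <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    train <- obs[folds != f, , drop = FALSE]
    test <- obs[folds == f, , drop = FALSE]
    ctrl_f <- ctrl
    ctrl_f$seed <- seed + f
    fit <- calibrate(climate_by_site, train, bounds = bounds, control = ctrl_f)
    ctx_test <- forcing_context(climate_by_site, test, doy_max = ctrl$doy_max)
    fold_rmse[f] <- context_rmse(ctx_test, fit$params$t0, fit$params$Tb,
                                 fit$params$k, Fcrit = fit$params$Fcrit)
    null_rmse[f] <- null_model_rmse(train, test)
    fits[[f]] <- fit
  }
  list(mean_rmse = mean(fold_rmse), fold_rmse = fold_rmse,
       null_mean_rmse = mean(null_rmse), null_fold_rmse = null_rmse,
       folds = folds, fits = fits, seed = seed)
}
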