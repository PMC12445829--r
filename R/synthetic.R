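#' Configuration for the synthetic two-species study-site generator
#'
#' Defines one site of a synthetic analogue of a mid-elevation Jura beech /
#' spruce study design: ~nine decades of daily climate with autocorrelated
#' noise and injected spring cold snaps, leaf-out observations generated from
#' known M1 parameters plus observation noise, and two-core-per-tree
#' ring-width series combining an age trend, a shared summer climate signal
#' and a species-specific frost-year growth reduction.
#'
#' Defaults emulate the high-elevation site of the study system: mean annual
#' temperature 4.7 degC (use 6.3 for a low site), seasonal half-amplitude
#' 8.5 degC so January averages about -4 degC and July about 13 degC, and a
#' 91-year record starting in 1931.
#'
#' @param n_years number of calendar years generated (>= 1).
#' @param start_year first calendar year.
#' @param site_id site identifier.
#' @param site_latitude latitude in decimal degrees.
#' @param elevation site elevation (metadata only).
#' @param mean_annual_temp mean of the seasonal temperature cycle, degC.
#' @param seasonal_amplitude half-amplitude of the seasonal cycle, degC; the
#'   coldest day falls mid-January (DOY 15).
#' @param diurnal_range tmax - tmin, degC.
#' @param ar1_coefficient lag-1 autocorrelation of the daily temperature
#'   noise, in [0, 1).
#' @param noise_sd marginal standard deviation of the daily noise, degC.
#' @param frost_events list of `list(year=, doy=, depth=)`: on that day tmin
#'   is forced down by `depth` degC (tmean/tmax untouched, emulating
#'   radiative-cooling nights with high daily amplitude).
#' @param true_m1_params [m1_parameters()] generating the leaf-out dates.
#' @param pheno_noise_sd SD in days of the leaf-out observation noise.
#' @param n_trees_per_species trees per species (two cores each).
#' @param ring_age_trend numeric `c(initial, decay)`: expected ring width is
#'   `initial * exp(-decay * age)` mm.
#' @param climate_signal_beta strength of the shared summer climate signal on
#'   log ring width.
#' @param frost_multiplier multiplicative growth reduction applied to the
#'   frost-sensitive species in frost years, in (0, 1].
#' @param drought_years integer years in which BOTH species are reduced.
#' @param drought_multiplier multiplicative reduction in drought years, (0, 1].
#' @param ring_noise_sd SD of tree-level lognormal noise (log scale).
#' @param core_noise_sd SD of the additional core-level lognormal noise.
#' @param seed integer RNG seed; every generator draw derives from it.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_years = 91,
                             start_year = 1931,
                             site_id = "high",
                             site_latitude = 47.4,
                             elevation = 1365,
                             mean_annual_temp = 4.7,
                             seasonal_amplitude = 8.5,
                             diurnal_range = 8,
                             ar1_coefficient = 0.7,
                             noise_sd = 3,
                             frost_events = list(),
                             true_m1_params = m1_parameters(3, 0.29, 4.76, 1248),
                             pheno_noise_sd = 7.5,
                             n_trees_per_species = 12,
                             ring_age_trend = c(initial = 3, decay = 0.02),
                             climate_signal_beta = 0.3,
                             frost_multiplier = 0.4,
                             drought_years = integer(),
                             drought_multiplier = 1,
                             ring_noise_sd = 0.2,
                             core_noise_sd = 0.1,
                             seed = 1L) {
  check_scalar_number(n_years, "n_years", lower = 1)
  check_scalar_number(start_year, "start_year")
  check_scalar_number(site_latitude, "site_latitude", lower = -66.5, upper = 66.5)
  check_scalar_number(seasonal_amplitude, "seasonal_amplitude", lower = 0)
  check_scalar_number(diurnal_range, "diurnal_range", lower = 0)
  check_scalar_number(ar1_coefficient, "ar1_coefficient", lower = 0, upper = 1,
                      strict_upper = TRUE)
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  check_scalar_number(pheno_noise_sd, "pheno_noise_sd", lower = 0)
  check_scalar_number(n_trees_per_species, "n_trees_per_species", lower = 1)
  check_scalar_number(climate_signal_beta, "climate_signal_beta")
  check_scalar_number(frost_multiplier, "frost_multiplier", lower = 0, upper = 1,
                      strict_lower = TRUE)
  check_scalar_number(drought_multiplier, "drought_multiplier", lower = 0, upper = 1,
                      strict_lower = TRUE)
  check_scalar_number(ring_noise_sd, "ring_noise_sd", lower = 0)
  check_scalar_number(core_noise_sd, "core_noise_sd", lower = 0)
  check_scalar_number(seed, "seed")
  stopifnot(inherits(true_m1_params, "m1_params"))
  if (length(ring_age_trend) != 2 || any(!is.finite(ring_age_trend)) ||
      ring_age_trend[1] <= 0)
    stop_field("ring_age_trend", "must be c(initial > 0, decay)")
  years <- seq(start_year, length.out = n_years)
  for (ev in frost_events) {
    if (!all(c("year", "doy", "depth") %in% names(ev)))
      stop_field("frost_events", "each event needs year, doy, depth")
    if (!(ev$year %in% years))
      stop_field("frost_events", sprintf("year %d outside [%d, %d]",
                                         ev$year, min(years), max(years)))
    if (ev$doy < 1 || ev$doy > 366) stop_field("frost_events", "doy must be in [1, 366]")
    if (ev$depth < 0) stop_field("frost_events", "depth must be >= 0")
  }
  if (length(drought_years) && !all(drought_years %in% years))
    stop_field("drought_years", "must lie within the generated years")
  structure(list(
    n_years = as.integer(n_years), start_year = as.integer(start_year),
    site_id = site_id, site_latitude = site_latitude, elevation = elevation,
    mean_annual_temp = mean_annual_temp, seasonal_amplitude = seasonal_amplitude,
    diurnal_range = diurnal_range, ar1_coefficient = ar1_coefficient,
    noise_sd = noise_sd, frost_events = frost_events,
    true_m1_params = true_m1_params, pheno_noise_sd = pheno_noise_sd,
    n_trees_per_species = as.integer(n_trees_per_species),
    ring_age_trend = ring_age_trend, climate_signal_beta = climate_signal_beta,
    frost_multiplier = frost_multiplier, drought_years = as.integer(drought_years),
    drought_multiplier = drought_multiplier, ring_noise_sd = ring_noise_sd,
    core_noise_sd = core_noise_sd, seed = as.integer(seed)
  ), class = "synthetic_config")
}

config_years <- function(config) {
  seq(config$start_year, length.out = config$n_years)
}

#' Generate a synthetic daily climate series
#'
#' Daily mean temperature is a seasonal sinusoid (coldest mid-January) plus
#' AR(1) noise; `tmin`/`tmax` sit half a diurnal range below/above it. Each
#' configured frost event lowers `tmin` on its day by the stated depth,
#' leaving `tmean` and `tmax` untouched. Fully reproducible from
#' `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return a [climate_series()] covering every calendar day of the configured
#'   span (leap days included).
#' @export
generate_climate <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  years <- config_years(config)
  dates <- seq(as.Date(sprintf("%d-01-01", config$start_year)),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  doy <- doy_of(dates)
  seasonal <- config$mean_annual_temp -
    config$seasonal_amplitude * cos(2 * pi * (doy - 15) / 365.25)
  n <- length(dates)
  eps <- with_seed(config$seed, {
    innov_sd <- config$noise_sd * sqrt(1 - config$ar1_coefficient^2)
    e <- numeric(n)
    if (config$noise_sd > 0) {
      z <- stats::rnorm(n, sd = innov_sd)
      e[1] <- stats::rnorm(1, sd = config$noise_sd)
      for (i in seq_len(n - 1)) e[i + 1] <- config$ar1_coefficient * e[i] + z[i + 1]
    }
    e
  })
  tmean <- seasonal + eps
  tmin <- tmean - config$diurnal_range / 2
  tmax <- tmean + config$diurnal_range / 2
  yr <- as.integer(format(dates, "%Y"))
  for (ev in config$frost_events) {
    i <- which(yr == ev$year & doy == ev$doy)
    tmin[i] <- tmin[i] - ev$depth
  }
  climate_series(
    data.frame(date = dates, tmin = tmin, tmean = tmean, tmax = tmax, precip = 0),
    site_id = config$site_id, latitude = config$site_latitude,
    elevation = config$elevation
  )
}

#' Generate noisy leaf-out observations from known M1 parameters
#'
#' For each year covered by `climate`, the true leaf-out date is the M1
#' prediction under `true_params`; the observation adds Gaussian noise
#' (rounded to a whole day, clamped to [1, 366]). Years where the model never
#' reaches the forcing threshold yield no observation and are reported in the
#' `non_emerging` attribute.
#'
#' @param climate a [climate_series()].
#' @param true_params [m1_parameters()] used as ground truth.
#' @param pheno_noise_sd observation noise SD in days.
#' @param seed integer RNG seed.
#' @return data.frame `site_id, year, leafout_doy` with attribute
#'   `non_emerging` (integer years dropped).
#' @export
generate_phenology <- function(climate, true_params, pheno_noise_sd, seed = 1L) {
  years <- sort(unique(climate$year))
  # only full years (prediction needs coverage from DOY 1 through 200)
  years <- years[vapply(years, function(y) {
    yr <- climate_year(climate, y); min(yr$doy) == 1 && max(yr$doy) >= 200
  }, logical(1))]
  pred <- predict_leafout_years(climate, years, true_params)
  non_emerging <- pred$year[is.na(pred$leafout_doy)]
  obs <- pred[!is.na(pred$leafout_doy), , drop = FALSE]
  if (nrow(obs) && pheno_noise_sd > 0) {
    noise <- with_seed(seed, stats::rnorm(nrow(obs), sd = pheno_noise_sd))
    obs$leafout_doy <- as.integer(pmin(366, pmax(1, round(obs$leafout_doy + noise))))
  }
  rownames(obs) <- NULL
  structure(obs, non_emerging = as.integer(non_emerging))
}

#' Standardised summer climate index
#'
#' Per-year mean of a daily variable over a day-of-year window, standardised
#' to zero mean and unit SD across years. This is the shared "common climate
#' signal" that drives ring growth of both synthetic species.
#'
#' @param climate a [climate_series()].
#' @param doy_range integer `c(first, last)` day-of-year window (default
#'   160-220, high summer).
#' @param variable climate column to aggregate (default `tmax`).
#' @return data.frame `year, index` with mean 0 and SD 1 over years.
#' @export
summer_climate_index <- function(climate, doy_range = c(160, 220), variable = "tmax") {
  sel <- climate$doy >= doy_range[1] & climate$doy <= doy_range[2]
  agg <- tapply(climate[[variable]][sel], climate$year[sel], mean)
  idx <- as.numeric(agg)
  s <- stats::sd(idx)
  z <- if (is.na(s) || s == 0) rep(0, length(idx)) else (idx - mean(idx)) / s
  data.frame(year = as.integer(names(agg)), index = z)
}

#' Generate synthetic ring-width series for one species
#'
#' Tree-level expected width in year y is
#' `initial * exp(-decay * age) * exp(beta * z_y + eta_ty) * m_y`
#' where `z_y` is the standardised summer climate index shared by both
#' species, `eta_ty` is tree-level lognormal noise, and `m_y` is the
#' frost multiplier in `frost_years` (frost-sensitive species only) times the
#' drought multiplier in drought years (both species). Two cores per tree add
#' independent lognormal core noise. All widths are strictly positive.
#'
#' @param climate a [climate_series()].
#' @param frost_years integer years of injected frost damage.
#' @param config a [synthetic_config()].
#' @param species `"frost_sensitive"` or `"reference"`.
#' @param seed RNG seed; defaults to a species-specific stream derived from
#'   `config$seed` so the two species share the climate signal but have
#'   independent tree noise.
#' @return a ring-width table in wide form (class `rwl`): rownames are years,
#'   one column per core, series ids `FS01A`/`RF01A` style (species code,
#'   tree number, core letter). Attributes: `site_id`, `species`, `truth`
#'   (list with `frost_years`, `drought_years`, `climate_index`, `age_curve`).
#' @export
generate_ring_series <- function(climate, frost_years, config,
                                 species = c("frost_sensitive", "reference"),
                                 seed = NULL) {
  species <- match.arg(species)
  stopifnot(inherits(config, "synthetic_config"))
  years <- sort(unique(climate$year))
  frost_years <- as.integer(frost_years)
  if (length(frost_years) && !all(frost_years %in% years))
    stop_field("frost_years", "outside climate coverage")
  if (is.null(seed))
    seed <- config$seed * 101L + if (species == "reference") 1L else 0L
  n_years <- length(years)
  n_trees <- config$n_trees_per_species
  ci <- summer_climate_index(climate)
  z <- ci$index[match(years, ci$year)]
  age <- seq_len(n_years)
  age_curve <- config$ring_age_trend[1] * exp(-config$ring_age_trend[2] * age)
  m <- rep(1, n_years)
  if (species == "frost_sensitive")
    m[years %in% frost_years] <- m[years %in% frost_years] * config$frost_multiplier
  m[years %in% config$drought_years] <-
    m[years %in% config$drought_years] * config$drought_multiplier
  code <- if (species == "frost_sensitive") "FS" else "RF"
  out <- with_seed(seed, {
    cols <- list()
    for (tr in seq_len(n_trees)) {
      eta <- if (config$ring_noise_sd > 0)
        stats::rnorm(n_years, sd = config$ring_noise_sd) else numeric(n_years)
      tree_width <- age_curve * exp(config$climate_signal_beta * z + eta) * m
      for (core in c("A", "B")) {
        ce <- if (config$core_noise_sd > 0)
          stats::rnorm(n_years, sd = config$core_noise_sd) else numeric(n_years)
        cols[[sprintf("%s%02d%s", code, tr, core)]] <- tree_width * exp(ce)
      }
    }
    cols
  })
  rwl <- as.data.frame(out, row.names = as.character(years))
  structure(rwl,
            site_id = site_id_of(climate), species = species,
            truth = list(frost_years = frost_years,
                         drought_years = config$drought_years,
                         climate_index = ci, age_curve = age_curve),
            class = c("rwl", "data.frame"))
}
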