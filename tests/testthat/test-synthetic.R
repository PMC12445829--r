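test_that("zero-noise climate is an exact seasonal sinusoid", {
  cfg <- small_config(noise_sd = 0, ar1_coefficient = 0, n_years = 2)
  cl <- generate_climate(cfg)
  expected <- cfg$mean_annual_temp -
    cfg$seasonal_amplitude * cos(2 * pi * (cl$doy - 15) / 365.25)
  expect_equal(cl$tmean, expected)
  expect_equal(cl$tmin, expected - cfg$diurnal_range / 2)
  expect_equal(cl$tmax, expected + cfg$diurnal_range / 2)
  # coldest day of a 365-day year is mid-January
  y1 <- cl[cl$year == 1961, ]
  expect_equal(y1$doy[which.min(y1$tmean)], 15)
})

test_that("generators are deterministic given the seed", {
  cfg <- small_config(seed = 42, n_years = 5)
  expect_identical(generate_climate(cfg), generate_climate(cfg))
  cl <- generate_climate(cfg)
  p <- cfg$true_m1_params
  expect_identical(generate_phenology(cl, p, 5, seed = 9),
                   generate_phenology(cl, p, 5, seed = 9))
  expect_identical(generate_ring_series(cl, 1963, cfg),
                   generate_ring_series(cl, 1963, cfg))
})

test_that("a frost event lowers that day's tmin by exactly its depth", {
  base <- small_config(seed = 7, n_years = 3)
  with_ev <- small_config(seed = 7, n_years = 3,
                          frost_events = list(list(year = 1962, doy = 133, depth = 8)))
  cl0 <- generate_climate(base)
  cl1 <- generate_climate(with_ev)
  i <- which(cl0$year == 1962 & cl0$doy == 133)
  expect_equal(cl1$tmin[i] - cl0$tmin[i], -8)
  expect_equal(cl1$tmin[-i], cl0$tmin[-i])
  expect_equal(cl1$tmean, cl0$tmean)
})

test_that("daily noise has the configured lag-1 autocorrelation", {
  cfg <- small_config(seed = 5, ar1_coefficient = 0.7, noise_sd = 3)
  cl <- generate_climate(cfg)
  resid <- cl$tmean - (cfg$mean_annual_temp -
    cfg$seasonal_amplitude * cos(2 * pi * (cl$doy - 15) / 365.25))
  r1 <- cor(resid[-1], resid[-length(resid)])
  expect_lt(abs(r1 - 0.7), 0.1)
})

test_that("noise-free phenology equals the model predictions; cold climates emerge nowhere", {
  cfg <- small_config(seed = 3, n_years = 8)
  cl <- generate_climate(cfg)
  obs <- generate_phenology(cl, cfg$true_m1_params, 0)
  pred <- predict_leafout_years(cl, obs$year, cfg$true_m1_params)
  expect_equal(obs$leafout_doy, pred$leafout_doy)
  expect_true(all(obs$leafout_doy >= 1 & obs$leafout_doy <= 366))
  # constant tmean equal to Tb accumulates nothing
  flat <- constant_climate(2000:2002, tmean = 0.29)
  none <- generate_phenology(flat, cfg$true_m1_params, 0)
  expect_identical(nrow(none), 0L)
  expect_identical(attr(none, "non_emerging"), 2000:2002)
})

test_that("observation noise of 5 d yields a sample SD near 5 over 60 years", {
  cfg <- synthetic_config(n_years = 60, start_year = 1951, pheno_noise_sd = 5, seed = 21)
  cl <- generate_climate(cfg)
  obs <- generate_phenology(cl, cfg$true_m1_params, 5, seed = 77)
  pred <- predict_leafout_years(cl, obs$year, cfg$true_m1_params)
  s <- sd(obs$leafout_doy - pred$leafout_doy)
  expect_gte(s, 3.5)
  expect_lte(s, 6.5)
})

test_that("ring generator skeleton: no noise and no signal leaves age trend times multiplier", {
  cfg <- small_config(ring_noise_sd = 0, core_noise_sd = 0, climate_signal_beta = 0,
                      frost_multiplier = 0.4, n_trees_per_species = 2)
  cl <- generate_climate(cfg)
  fy <- 1975L
  rwl <- generate_ring_series(cl, fy, cfg, species = "frost_sensitive")
  age <- seq_len(cfg$n_years)
  expected <- cfg$ring_age_trend[1] * exp(-cfg$ring_age_trend[2] * age)
  expected[seq(cfg$start_year, length.out = cfg$n_years) == fy] <- 0.4 *
    expected[seq(cfg$start_year, length.out = cfg$n_years) == fy]
  for (col in colnames(rwl)) expect_equal(rwl[[col]], expected, ignore_attr = TRUE)
  # reference species unaffected by frost years: pure age trend
  ref <- generate_ring_series(cl, fy, cfg, species = "reference")
  expect_equal(ref[["RF01A"]],
               cfg$ring_age_trend[1] * exp(-cfg$ring_age_trend[2] * age),
               ignore_attr = TRUE)
  expect_true(all(as.matrix(rwl) > 0))
})

test_that("frost multiplier shifts sensitive log-widths by about log(0.4)", {
  cfg <- synthetic_config(n_years = 50, start_year = 1961, seed = 13,
                          n_trees_per_species = 12, frost_multiplier = 0.4)
  cl <- generate_climate(cfg)
  fy <- 1990L
  sens <- generate_ring_series(cl, fy, cfg, species = "frost_sensitive")
  ref <- generate_ring_series(cl, fy, cfg, species = "reference")
  i <- which(rownames(sens) == "1990")
  d <- mean(log(as.numeric(sens[i, ]))) - mean(log(as.numeric(ref[i, ])))
  expect_equal(d, log(0.4), tolerance = 0.3 / abs(log(0.4)))
})

test_that("multiplier 1 leaves the two species indistinguishable in frost years", {
  cfg <- synthetic_config(n_years = 50, start_year = 1961, seed = 17,
                          n_trees_per_species = 12, frost_multiplier = 1)
  cl <- generate_climate(cfg)
  fy <- c(1980L, 1990L)
  sens <- generate_ring_series(cl, fy, cfg, species = "frost_sensitive")
  ref <- generate_ring_series(cl, fy, cfg, species = "reference")
  rows <- rownames(sens) %in% c("1980", "1990")
  pv <- t.test(log(as.numeric(as.matrix(sens[rows, ]))),
               log(as.numeric(as.matrix(ref[rows, ]))))$p.value
  expect_gt(pv, 0.01)
})

test_that("invalid configurations name the offending field", {
  expect_error(synthetic_config(ar1_coefficient = 1), "ar1_coefficient")
  expect_error(synthetic_config(frost_multiplier = 0), "frost_multiplier")
  expect_error(synthetic_config(noise_sd = -1), "noise_sd")
  expect_error(synthetic_config(frost_events = list(list(year = 1800, doy = 100, depth = 2))),
               "frost_events")
  cfg <- small_config()
  cl <- generate_climate(cfg)
  expect_error(generate_ring_series(cl, 1900L, cfg), "frost_years")
})
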