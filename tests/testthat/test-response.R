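test_that("a chronology built from a climate window self-correlates at r = 1", {
  cfg <- small_config(seed = 12, n_years = 30)
  cl <- generate_climate(cfg)
  years <- sort(unique(cl$year))
  agg <- vapply(years, function(y) {
    d <- cl[cl$year == y & cl$doy >= 160 & cl$doy <= 189, ]
    mean(d$tmin)
  }, numeric(1))
  chron <- data.frame(year = years, value = agg)
  g <- daywise_correlations(chron, cl, "tmin", start_doys = c(100, 160),
                            window_lengths = c(30, 60), min_overlap = 20)
  cell <- g[g$start_doy == 160 & g$window_length == 30, ]
  expect_equal(cell$r, 1)
  expect_lt(cell$p, 1e-12)
  expect_equal(cell$n, 30)
})

test_that("the grid equals a brute-force per-cell loop oracle", {
  cfg <- small_config(seed = 18, n_years = 25)
  cl <- generate_climate(cfg)
  years <- sort(unique(cl$year))
  set.seed(6)
  chron <- data.frame(year = years, value = rnorm(length(years), 1, 0.1))
  starts <- c(50, 80, 110, 140, 170)
  lens <- c(15, 20, 25, 30, 35)
  g <- daywise_correlations(chron, cl, "tmax", start_doys = starts,
                            window_lengths = lens)
  for (s in starts) {
    for (len in lens) {
      agg <- vapply(years, function(y) {
        d <- cl[cl$year == y & cl$doy >= s & cl$doy <= s + len - 1, ]
        mean(d$tmax)
      }, numeric(1))
      ct <- cor.test(chron$value, agg)
      cell <- g[g$start_doy == s & g$window_length == len, ]
      expect_equal(cell$r, unname(ct$estimate), tolerance = 1e-12)
      expect_equal(cell$p, ct$p.value, tolerance = 1e-12)
    }
  }
})

test_that("white-noise chronologies trigger about the nominal type-I rate", {
  cfg <- synthetic_config(n_years = 90, start_year = 1931, seed = 25)
  cl <- generate_climate(cfg)
  years <- sort(unique(cl$year))
  set.seed(30)
  chron <- data.frame(year = years, value = rnorm(length(years), 1, 0.1))
  g <- daywise_correlations(chron, cl, "tmin",
                            start_doys = seq(1, 250, by = 10),
                            window_lengths = seq(15, 75, by = 15))
  frac <- mean(g$p < 0.05)
  expect_gte(frac, 0)
  expect_lte(frac, 0.15)
})

test_that("degenerate climate variables yield no cells; p-masking filters output", {
  cfg <- small_config(seed = 12, n_years = 30)
  cl <- generate_climate(cfg)   # precip is identically 0
  years <- sort(unique(cl$year))
  set.seed(6)
  chron <- data.frame(year = years, value = rnorm(length(years)))
  g <- daywise_correlations(chron, cl, "precip", start_doys = c(50, 100),
                            window_lengths = 30)
  expect_identical(nrow(g), 0L)
  gm <- daywise_correlations(chron, cl, "tmin", start_doys = seq(10, 200, 10),
                             window_lengths = c(20, 40), mask_p = 0.05)
  expect_true(all(gm$p < 0.05))
})

test_that("SEA flags a constructed lag-0 depression and nothing else", {
  years <- 1931:2030
  vals <- rep(1, 100)
  events <- c(1950, 1965, 1980, 1995, 2010)
  vals[match(events, years)] <- 0.5
  chron <- data.frame(year = years, value = vals)
  sea <- superposed_epoch(chron, events, lags = 0:4, n_boot = 999, seed = 5)
  expect_true(sea$significant[sea$lag == 0])
  expect_lt(sea$anomaly[sea$lag == 0], 0)
  expect_false(any(sea$significant[sea$lag > 0]))
  # determinism
  sea2 <- superposed_epoch(chron, events, lags = 0:4, n_boot = 999, seed = 5)
  expect_identical(sea$lo, sea2$lo)
  expect_identical(sea$hi, sea2$hi)
})

test_that("SEA handles constant chronologies and incomplete lag coverage", {
  years <- 1931:2030
  flat <- data.frame(year = years, value = rep(1, 100))
  sea <- superposed_epoch(flat, c(1950, 1980), lags = 0:4, n_boot = 199, seed = 1)
  expect_equal(sea$anomaly, rep(0, 5))
  expect_false(any(sea$significant))
  # events too close to the end of the record are dropped with a warning
  vals <- c(rep(1, 99), 0.5)
  chron <- data.frame(year = years, value = vals)
  expect_warning(
    sea2 <- superposed_epoch(chron, c(1950, 1970, 2029), lags = 0:4,
                             n_boot = 199, seed = 2),
    "dropped")
  expect_equal(attr(sea2, "n_events"), 2L)
  expect_error(suppressWarnings(superposed_epoch(chron, c(2028, 2029), lags = 0:4,
                                                 n_boot = 199, seed = 1)),
               "fewer than 2")
  expect_error(superposed_epoch(chron, c(1950, 1970), lags = 0:4,
                                n_boot = 50, seed = 1), "n_boot")
})
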