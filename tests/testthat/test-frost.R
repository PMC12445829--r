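# A fixture emulating the high-site 2020 spring: one hard frost (tmin -2.0)
# on DOY 133 inside the damage window of a DOY-124 leaf-out, and an earlier
# frost on DOY 121 that sits outside the window of a DOY-140 leaf-out.
frost_fixture <- function(events = list(c(133, -2.0)), year = 2020) {
  cl <- constant_climate(year, tmean = 8, diurnal_range = 9.6)
  for (ev in events) {
    i <- which(cl$year == year & cl$doy == ev[1])
    cl$tmin[i] <- ev[2]
  }
  cl
}

test_that("last spring frost is the latest day at or below the threshold", {
  cl <- frost_fixture(list(c(90, -2.0), c(100, -1.0)))
  expect_identical(last_spring_frost(cl, 2020), 100L)   # inclusive threshold
  expect_identical(last_spring_frost(frost_fixture(list()), 2020), NA_integer_)
  # 2020 high-site configuration: frost of -2.0 degC on DOY 133
  expect_identical(last_spring_frost(frost_fixture(), 2020), 133L)
  # search window is respected
  expect_identical(last_spring_frost(cl, 2020, search_window = c(1L, 95L)), 90L)
})

test_that("damage-window flag uses inclusive bounds around leaf-out", {
  cl <- frost_fixture()                       # tmin -2.0 on DOY 133
  hit <- frost_in_window(cl, 2020, 124)       # offset +9
  expect_true(hit$window_frost)
  expect_equal(hit$events$doy, 133)
  expect_equal(hit$events$tmin, -2)
  expect_equal(hit$events$daily_amplitude, 8 + 9.6 / 2 - (-2))
  # frost at DOY 121 is outside the window of a DOY-140 leaf-out (offset -19)
  early <- frost_fixture(list(c(121, -3.6)))
  expect_false(frost_in_window(early, 2020, 140)$window_frost)
  # exact window edges are included
  expect_true(frost_in_window(cl, 2020, 138)$window_frost)   # offset -5
  expect_true(frost_in_window(cl, 2020, 119)$window_frost)   # offset +14
  expect_false(frost_in_window(cl, 2020, 118)$window_frost)  # offset +15
  # no qualifying day anywhere
  none <- frost_in_window(frost_fixture(list()), 2020, 124)
  expect_false(none$window_frost)
  expect_identical(nrow(none$events), 0L)
  # absent leaf-out is an absent result, not an error
  expect_true(is.na(frost_in_window(cl, 2020, NA)$window_frost))
})

test_that("window flag depends on tmin only", {
  cl <- frost_fixture()
  warm <- cl
  warm$tmean <- warm$tmean + 3
  warm$tmax <- warm$tmax + 6
  expect_identical(frost_in_window(warm, 2020, 124)$window_frost,
                   frost_in_window(cl, 2020, 124)$window_frost)
})

test_that("safety margin is the signed leaf-out minus last-frost difference", {
  expect_equal(safety_margin(130, 130), 0)
  expect_equal(safety_margin(124, 133), -9)
  expect_equal(safety_margin(138, 120), 18)
  expect_true(is.na(safety_margin(NA, 120)))
  # anti-symmetry under swapping the two roles
  expect_equal(safety_margin(124, 133), -safety_margin(133, 124))
})

test_that("per-year records combine leaf-out, last frost, margin and flag", {
  cl <- frost_fixture()
  rec <- safety_margin_records(cl, data.frame(year = 2020, leafout_doy = 124))
  expect_equal(rec$last_frost_doy, 133L)
  expect_equal(rec$margin_days, -9)
  expect_true(rec$window_frost)
  expect_equal(rec$n_window_events, 1L)
  # NA leaf-out propagates without error
  rec2 <- safety_margin_records(cl, data.frame(year = 2020, leafout_doy = NA))
  expect_true(is.na(rec2$margin_days) && is.na(rec2$window_frost))
})

test_that("risk summary reproduces percentage, SE and moving-average contracts", {
  rec <- data.frame(site_id = "s", year = 1931:2021,
                    leafout_doy = 130L, last_frost_doy = 120L,
                    margin_days = 10, window_frost = FALSE,
                    n_window_events = 0L)
  rec$window_frost[1:17] <- TRUE
  rs <- risk_summary(rec)
  expect_equal(round(rs$by_site$pct_window_frost, 1), 18.7)   # 17 of 91
  expect_equal(rs$by_site$margin_se, 0)                       # all margins equal
  rec2 <- rec[1:2, ]
  rec2$margin_days <- c(10, 14)
  rs2 <- risk_summary(rec2, ma_window = 2, ma_min = 1)
  expect_equal(rs2$by_site$margin_mean, 12)
  expect_equal(rs2$by_site$margin_se, sd(c(10, 14)) / sqrt(2))  # = 2
  # period counting of negative margins
  rec$margin_days[rec$year >= 2003] <- -2
  rs3 <- risk_summary(rec, periods = list(c(1931, 2002), c(2003, 2021)))
  expect_equal(rs3$negative_by_period$n_negative, c(0, 19))
})

test_that("centered moving average honours the minimum-coverage rule", {
  x <- c(rep(1, 20), rep(NA, 8), rep(3, 20))
  ma <- moving_average(x, window = 10, min_obs = 6)
  expect_equal(ma[10], 1)
  expect_true(is.na(ma[26]))   # mostly NA neighbourhood
  expect_equal(ma[40], 3)
  expect_length(ma, length(x))
})
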