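chron_df <- function(years, values) data.frame(year = years, value = values)

test_that("residual z-scores: degenerate and location-invariance contracts", {
  years <- 1981:2020
  base <- 1 + 0.1 * sin(1:40)
  tree <- as.data.frame(list(T1 = base), row.names = as.character(years))
  ref <- chron_df(years, base)
  expect_warning(z0 <- residual_series(tree, ref), "SD is 0")
  expect_equal(z0$T1, rep(0, 40))
  set.seed(2)
  tree$T1 <- base + rnorm(40, sd = 0.1)
  z1 <- residual_series(tree, ref)
  expect_equal(mean(z1$T1), 0, tolerance = 1e-9)
  expect_equal(sd(z1$T1), 1, tolerance = 1e-9)
  shifted <- tree
  shifted$T1 <- tree$T1 + 0.37
  expect_equal(residual_series(shifted, ref)$T1, z1$T1)
  # too little overlap errors
  short <- as.data.frame(list(T1 = c(base[1:10], rep(NA, 30))),
                         row.names = as.character(years))
  expect_error(residual_series(short, ref), "overlap")
})

test_that("an injected frost year attains the minimum z of each sensitive tree", {
  cfg <- synthetic_config(n_years = 70, start_year = 1951, seed = 31,
                          n_trees_per_species = 8, frost_multiplier = 0.4,
                          ring_noise_sd = 0.1, core_noise_sd = 0.05)
  cl <- generate_climate(cfg)
  fy <- 1990L
  sens <- trees_from_rwl(generate_ring_series(cl, fy, cfg, "frost_sensitive"))
  ref_chron <- biweight_chronology(trees_from_rwl(
    generate_ring_series(cl, fy, cfg, "reference")))
  z <- residual_series(sens, ref_chron)
  for (id in colnames(z))
    expect_identical(rownames(z)[which.min(z[[id]])], "1990")
  # and the residual site chronology bottoms out there too
  rc <- build_site_residual_chronology(z)
  expect_identical(rc$year[which.min(rc$value)], 1990L)
})

test_that("the residual site chronology is a plain mean of z series", {
  z <- as.data.frame(list(A = c(1, 0.5), B = c(-1, 0.5)),
                     row.names = c("2000", "2001"))
  rc <- build_site_residual_chronology(z)
  expect_equal(rc$value, c(0, 0.5))
  expect_equal(rc$sample_depth, c(2L, 2L))
  one <- as.data.frame(list(A = c(0.3, -0.2)), row.names = c("2000", "2001"))
  expect_equal(build_site_residual_chronology(one)$value, c(0.3, -0.2))
})

test_that("frost-year calls apply the supermajority rule", {
  years <- as.character(2001:2003)
  z <- as.data.frame(matrix(0, 3, 12, dimnames = list(years, paste0("T", 1:12))))
  z[1, 1:8] <- -1.2    # 8 of 12 = 0.667 >= 0.60 -> flagged moderate
  z[2, 1:7] <- -1.2    # 7 of 12 = 0.583 -> not flagged
  calls <- flag_frost_years(z)
  expect_identical(calls$flagged, c(TRUE, FALSE, FALSE))
  expect_identical(calls$severity[1], "moderate")
  expect_equal(calls$frac_moderate[1], 8 / 12)
  # severe when the same fraction passes the severe threshold
  z[3, 1:8] <- -1.7
  expect_identical(flag_frost_years(z)$severity[3], "severe")
  # all z above the moderate threshold yields no call
  znone <- as.data.frame(matrix(0.2, 3, 12, dimnames = dimnames(z)))
  expect_false(any(flag_frost_years(znone)$flagged))
  # invariance to tree relabeling / column order
  perm <- z[, sample(ncol(z))]
  expect_equal(flag_frost_years(perm)[, -1], calls_perm <- flag_frost_years(z)[, -1])
  # years with too few trees are not evaluated
  zthin <- z
  zthin[1, 3:12] <- NA
  expect_false(2001 %in% flag_frost_years(zthin, min_trees = 3)$year)
})

test_that("the window rule on the bundled site records reproduces the reported concordance", {
  rows <- read.csv(system.file("extdata", "site_frost_year_records.csv",
                               package = "frostring"))
  high <- concordance_from_rows(rows[rows$site == "high", ])
  expect_equal(nrow(high$table), 10L)
  expect_equal(high$n_concordant, 7L)
  expect_equal(high$pct_concordant, 70)
  low <- concordance_from_rows(rows[rows$site == "low", ])
  expect_equal(nrow(low$table), 6L)
  expect_equal(low$n_concordant, 2L)
})

test_that("period counts over the reported frost-year lists match the published tallies", {
  rows <- read.csv(system.file("extdata", "site_frost_year_records.csv",
                               package = "frostring"))
  high_years <- rows$year[rows$site == "high"]
  low_years <- rows$year[rows$site == "low"]
  pc <- period_counts(high_years, list(c(1991, 2021), c(1930, 1990),
                                       c(1977, 2021), c(1931, 1976)))
  expect_equal(pc$count, c(6L, 4L, 7L, 3L))
  expect_equal(period_counts(low_years, list(c(1977, 2021)))$count, 5L)
  # return interval and edge cases
  expect_equal(pc$return_interval_yr[1], 31 / 6)
  expect_equal(period_counts(integer(), list(c(1931, 2021)))$count, 0L)
  expect_identical(period_counts(integer(), list(c(1931, 2021)))$return_interval_yr, Inf)
  expect_error(period_counts(high_years, list(c(2000, 1999))), "period")
})

test_that("concordance table cross-references calls with the climate-phenology flags", {
  cl <- constant_climate(2000:2002, tmean = 8)
  cl$tmin[cl$year == 2000 & cl$doy == 130] <- -2    # inside window of leafout 124
  margins <- safety_margin_records(
    cl, data.frame(year = 2000:2002, leafout_doy = c(124L, 124L, 124L)))
  calls <- data.frame(year = c(2000L, 2001L), n_trees = 12L,
                      frac_moderate = 0.8, frac_severe = 0.2,
                      flagged = TRUE, severity = "moderate")
  cc <- concordance_table(calls, margins, climate = cl)
  expect_equal(cc$table$climate_pheno_flagged, c(TRUE, FALSE))
  expect_equal(cc$fraction_concordant, 0.5)
  expect_equal(cc$table$window_tmin[1], -2)
  # empty calls yield an empty table, not an error
  none <- concordance_table(calls[0, ], margins)
  expect_identical(nrow(none$table), 0L)
  expect_true(is.na(none$fraction_concordant))
})

test_that("a shared drought year is never flagged on the noise-free fixture", {
  cfg <- synthetic_config(n_years = 60, start_year = 1951, seed = 41,
                          n_trees_per_species = 8, ring_noise_sd = 0,
                          core_noise_sd = 0, frost_multiplier = 0.4,
                          drought_years = 1980L, drought_multiplier = 0.4)
  cl <- generate_climate(cfg)
  fy <- c(1970L, 1995L)
  sens <- trees_from_rwl(generate_ring_series(cl, fy, cfg, "frost_sensitive"))
  ref <- biweight_chronology(trees_from_rwl(generate_ring_series(cl, fy, cfg, "reference")))
  z <- residual_series(sens, ref)
  calls <- flag_frost_years(z)
  flagged <- calls$year[calls$flagged]
  expect_true(all(flagged %in% fy))          # only true frost years
  expect_false(1980 %in% flagged)            # the drought year cancels out
  expect_setequal(flagged, fy)               # and both frost years are found
})
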