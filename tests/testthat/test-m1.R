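test_that("forcing rate obeys the base-temperature switch and photoperiod factor", {
  expect_identical(forcing_rate(0.2, 12, 0.29, 4.76), 0)       # Ti <= Tb
  expect_identical(forcing_rate(0.29, 12, 0.29, 4.76), 0)      # boundary
  expect_equal(forcing_rate(5.29, 10, 0.29, 4.76), 5)          # (L/10)^k = 1
  expect_equal(forcing_rate(10.29, 12, 0.29, 4.76), 10 * 1.2^4.76,
               tolerance = 1e-9)
  expect_equal(forcing_rate(10.29, 12, 0.29, 4.76), 23.82, tolerance = 0.01 / 23.82)
  # never negative over a random sweep
  set.seed(1)
  expect_true(all(forcing_rate(runif(100, -10, 20), runif(100, 8, 16), 2, 3) >= 0))
})

test_that("leaf-out is the first day accumulated forcing reaches Fcrit", {
  cl <- constant_climate(2000, tmean = 1.29)
  fixed10 <- function(lat, doy) rep(10, length(doy))
  p <- m1_parameters(1, 0.29, 4.76, 30)     # 1 unit/day at L = 10
  expect_identical(predict_leafout(cl, 2000, p, daylength_fun = fixed10), 30L)
  # threshold never reached when Ti stays below Tb
  cold <- constant_climate(2000, tmean = 0.29 - 5)
  expect_identical(predict_leafout(cold, 2000, m1_parameters(1, 0.29, 4.76, 10)),
                   NA_integer_)
})

test_that("prediction equals the day-loop oracle exactly on synthetic climates", {
  p_pub <- m1_parameters(3, 0.29, 4.76, 1248)
  for (seed in 1:3) {
    cfg <- small_config(seed = seed, n_years = 6)
    cl <- generate_climate(cfg)
    for (y in config_years <- seq(cfg$start_year, length.out = cfg$n_years)) {
      expect_identical(predict_leafout(cl, y, p_pub), oracle_leafout(cl, y, p_pub))
    }
  }
})

test_that("warming never delays and a higher threshold never advances leaf-out", {
  p <- m1_parameters(3, 0.29, 4.76, 1248)
  for (seed in 1:5) {
    cl <- generate_climate(small_config(seed = seed, n_years = 2))
    y <- 1961
    base <- predict_leafout(cl, y, p)
    warm <- cl
    warm$tmean <- warm$tmean + 1
    warm$tmax <- warm$tmax + 1
    expect_lte(predict_leafout(warm, y, p), base)
    harder <- m1_parameters(p$t0, p$Tb, p$k, p$Fcrit * 1.3)
    later <- predict_leafout(cl, y, harder)
    if (!is.na(later)) expect_gte(later, base)
  }
})

test_that("k = 0 reduces the model to a plain growing-degree-day model", {
  cl <- generate_climate(small_config(seed = 8, n_years = 3))
  p <- m1_parameters(5, 2, 0, 150)
  for (y in 1961:1963)
    expect_identical(predict_leafout(cl, y, p),
                     oracle_gdd_leafout(cl, y, Tb = 2, Fcrit = 150, t0 = 5))
})

test_that("model RMSE matches hand computations and contracts", {
  cl <- constant_climate(2000:2001, tmean = 1.29)
  fixed10 <- function(lat, doy) rep(10, length(doy))
  p <- m1_parameters(1, 0.29, 4.76, 30)   # predicts DOY 30 both years
  obs_exact <- data.frame(site_id = "const", year = 2000:2001, leafout_doy = c(30, 30))
  cbs <- list(const = cl)
  expect_equal(model_rmse(p, cbs, obs_exact, daylength_fun = fixed10), 0)
  # errors +3 and -4 days
  obs <- data.frame(site_id = "const", year = 2000:2001, leafout_doy = c(27, 34))
  expect_equal(model_rmse(p, cbs, obs, daylength_fun = fixed10),
               sqrt((9 + 16) / 2), tolerance = 1e-6)
  expect_error(model_rmse(p, cbs, obs[0, ]), "empty")
  # non-emergence penalty path
  cold <- constant_climate(2000, tmean = -5)
  obs1 <- data.frame(site_id = "const", year = 2000, leafout_doy = 130)
  expect_equal(model_rmse(p, list(const = cold), obs1, na_penalty_doy = 250),
               120)
  expect_error(model_rmse(p, list(const = cold), obs1), "prediction")
})

test_that("null model RMSE is the spread about the training mean", {
  tr <- data.frame(leafout_doy = c(128, 132))
  expect_equal(null_model_rmse(tr, data.frame(leafout_doy = 135)), 5)
  expect_equal(null_model_rmse(tr, data.frame(leafout_doy = c(130, 130))), 0)
  set.seed(2)
  x <- data.frame(leafout_doy = rpois(40, 130))
  expect_equal(null_model_rmse(x, x),
               sqrt(mean((x$leafout_doy - mean(x$leafout_doy))^2)))
  expect_error(null_model_rmse(tr[0, , drop = FALSE], tr), "empty")
})
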