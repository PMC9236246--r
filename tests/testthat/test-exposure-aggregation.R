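test_that("daily 24-h means average available hours and enforce completeness", {
  # constant day
  rec <- hourly_day(rep(0.3, 24))
  out <- daily_mean_24h(rec)
  expect_equal(out$value, 0.3)

  # two-level day: plain arithmetic mean
  rec <- hourly_day(c(rep(10, 12), rep(20, 12)))
  expect_equal(daily_mean_24h(rec, 0.75)$value, 15)

  # exhaustive hour-count table: a day with k hours present is reported
  # iff k/24 >= completeness_min, and its value is the mean of the k hours
  for (k in 1:24) {
    rec <- hourly_day(seq_len(k), hours = 0:(k - 1))
    for (cm in c(0.5, 0.7, 0.75, 0.8)) {
      out <- daily_mean_24h(rec, completeness_min = cm)
      if (k / 24 >= cm) {
        expect_equal(out$value, mean(seq_len(k)))
      } else {
        expect_true(is.na(out$value))
      }
    }
  }
  # 17 of 24 hours fails the default 18-hour rule but passes at 70%
  rec17 <- hourly_day(rep(5, 17), hours = 0:16)
  expect_true(is.na(daily_mean_24h(rec17, 0.75)$value))
  expect_equal(daily_mean_24h(rec17, 0.70)$value, 5)
})

test_that("duplicate hourly timestamps are rejected with their keys", {
  rec <- dplyr::bind_rows(hourly_day(1:24), hourly_day(1:2, hours = 0:1))
  expect_error(daily_mean_24h(rec), "duplicated")
})

test_that("daily max 8-h mean matches a brute-force window oracle", {
  # constant series
  expect_equal(daily_max_8h(hourly_day(rep(40, 24)))$value, 40)

  # hourly ramp: oracle enumerates all 17 within-day windows
  ramp <- 0:23
  oracle <- max(vapply(0:16, function(s) mean(ramp[s + 1:8]), numeric(1)))
  expect_equal(oracle, 19.5) # window over hours 16-23
  expect_equal(daily_max_8h(hourly_day(ramp))$value, 19.5)

  # isolated 8-hour block is recovered exactly by its aligned window
  v <- rep(0, 24); v[9:16] <- 100
  expect_equal(daily_max_8h(hourly_day(v))$value, 100)

  # random series against the oracle, both policies
  set.seed(42)
  for (r in 1:10) {
    v2 <- round(runif(48, 0, 80), 1)
    h <- tibble::tibble(date = rep(as.Date("2020-01-01") + 0:1, each = 24),
                        hour = rep(0:23, 2), value = v2)
    ora <- function(starts) {
      max(vapply(starts, function(s) mean(v2[s + 1:8]), numeric(1)))
    }
    expect_equal(daily_max_8h(h, "within_day")$value[1], ora(0:16))
    expect_equal(daily_max_8h(h, "spillover")$value[1], ora(0:23))
  }
})

test_that("8-h windows never straddle a calendar gap under spillover", {
  h <- tibble::tibble(
    date = rep(as.Date("2020-01-01") + c(0, 5), each = 24),
    hour = rep(0:23, 2),
    value = c(rep(0, 20), rep(80, 4), rep(80, 24))
  )
  out <- daily_max_8h(h, "spillover")
  # the trailing day-1 windows reach into missing padding, not into day 6
  expect_equal(out$value[out$date == as.Date("2020-01-01")], 40) # hours 16-23
  expect_equal(out$value[out$date == as.Date("2020-01-06")], 80)
})

test_that("max 8-h mean dominates the 24-h mean on complete data", {
  set.seed(11)
  for (r in 1:20) {
    v <- runif(24, 0, 60)
    expect_gte(daily_max_8h(hourly_day(v))$value, mean(v))
  }
})

test_that("station averaging is an unweighted mean with a minimum count", {
  day <- as.Date("2020-06-01")
  tab <- tibble::tibble(station_id = paste0("S", 1:3), date = day,
                        pollutant = "NO2", value = c(10, 20, 30))
  expect_equal(average_stations(tab)$value, 20)

  tab7 <- tibble::tibble(station_id = paste0("S", 1:7), date = day,
                         pollutant = "NO2", value = 1:7)
  expect_equal(average_stations(tab7)$value, 4)

  tab$value[2] <- NA
  expect_equal(average_stations(tab, min_stations = 2)$value, 20)
  expect_true(is.na(average_stations(tab, min_stations = 3)$value))

  # permutation invariance in stations
  perm <- tab7[sample(7), ]
  expect_equal(average_stations(perm)$value, average_stations(tab7)$value)
})

test_that("the AQHI formula reproduces hand-evaluated values", {
  expect_equal(compute_aqhi(0, 0, 0), 0)
  # single-pollutant value, arbitrary-precision evaluation of the formula
  expect_equal(compute_aqhi(100, 0, 0), 1000 / 10.4 * (exp(0.0537) - 1),
               tolerance = 1e-12)
  expect_equal(round(compute_aqhi(100, 0, 0), 4), 5.3046)
  # missing input propagates
  expect_true(is.na(compute_aqhi(NA, 10, 10)))
})

test_that("AQHI is strictly increasing in each pollutant", {
  base <- expand.grid(o3 = c(0, 20, 60), no2 = c(0, 15, 50),
                      pm25 = c(0, 9, 40))
  eps <- 0.5
  for (i in seq_len(nrow(base))) {
    a0 <- compute_aqhi(base$o3[i], base$no2[i], base$pm25[i])
    expect_gt(compute_aqhi(base$o3[i] + eps, base$no2[i], base$pm25[i]), a0)
    expect_gt(compute_aqhi(base$o3[i], base$no2[i] + eps, base$pm25[i]), a0)
    expect_gt(compute_aqhi(base$o3[i], base$no2[i], base$pm25[i] + eps), a0)
  }
})

test_that("AQHI is near-linear over typical day-to-day variation", {
  # first-order Taylor expansion about the long-run means, evaluated over
  # mean +/- one IQR for each input
  cf <- aqhi_coefficients()
  m <- c(o3 = 23.5, no2 = 16.1, pm25 = 8.9)
  iqr <- c(o3 = 12.8, no2 = 8.8, pm25 = 6.5)
  grad <- cf$scale * c(cf$c_o3 * exp(cf$c_o3 * m["o3"]),
                       cf$c_no2 * exp(cf$c_no2 * m["no2"]),
                       cf$c_pm25 * exp(cf$c_pm25 * m["pm25"]))
  a_m <- compute_aqhi(m["o3"], m["no2"], m["pm25"])
  pts <- expand.grid(d1 = c(-1, 0, 1), d2 = c(-1, 0, 1), d3 = c(-1, 0, 1))
  for (i in seq_len(nrow(pts))) {
    d <- c(pts$d1[i] * iqr[1], pts$d2[i] * iqr[2], pts$d3[i] * iqr[3])
    x <- pmax(m + d, 0)
    exact <- compute_aqhi(x[1], x[2], x[3])
    taylor <- a_m + sum(grad * (x - m))
    expect_lt(abs(exact - taylor), 0.05)
  }
})

test_that("the public scale rounds and saturates, but models keep the continuous index", {
  expect_equal(aqhi_public_scale(c(0.2, 3.44, 3.56, 10.4, 12)),
               c(1L, 3L, 4L, 10L, 11L))
})

test_that("IQR follows the pinned linear-interpolation percentile convention", {
  # brute-force oracle: sort and interpolate at positions 1 + (n-1) p
  oracle_iqr <- function(x) {
    x <- sort(x)
    n <- length(x)
    at <- function(p) {
      h <- 1 + (n - 1) * p
      lo <- floor(h)
      x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
    }
    at(0.75) - at(0.25)
  }
  expect_equal(compute_iqr(1:100), 49.5)
  expect_equal(compute_iqr(1:100), oracle_iqr(1:100))
  expect_equal(compute_iqr(rep(7, 10)), 0)
  # regression pin for a short asymmetric series under the convention
  expect_equal(compute_iqr(c(0, 0, 10, 10)), 10)
  expect_equal(compute_iqr(c(0, 0, 10, 10)), oracle_iqr(c(0, 0, 10, 10)))
  set.seed(5)
  for (r in 1:10) {
    v <- rnorm(1 + rpois(1, 30))
    if (length(v) >= 4) expect_equal(compute_iqr(v), oracle_iqr(v))
  }
  expect_error(compute_iqr(c(NA, NA, 1, 2)), "at least 4")
})

test_that("hourly records aggregate end-to-end into a daily exposure table", {
  days <- as.Date("2020-06-01") + 0:1
  make <- function(stn, pol, lev) {
    tibble::tibble(station_id = stn,
                   date = rep(days, each = 24), hour = rep(0:23, 2),
                   pollutant = pol, value = lev)
  }
  hourly <- dplyr::bind_rows(
    make("S1", "O3", 20), make("S2", "O3", 30),
    make("S1", "NO2", 16), make("S1", "PM2.5", 9),
    make("S1", "CO", 0.3), make("S1", "SO2", 1)
  )
  # knock out NO2 entirely on day 2 so the index inputs are incomplete
  hourly$value[hourly$pollutant == "NO2" &
                 hourly$date == days[2]] <- NA
  wx <- tibble::tibble(date = days, temperature = c(18, 20),
                       humidity = c(70, 65))
  daily <- build_daily_exposures(hourly, weather = wx)
  expect_equal(daily$O3, c(25, 25)) # mean of the two stations
  expect_equal(daily$O3H8, c(25, 25)) # constant hours
  expect_equal(daily$NO2[1], 16)
  expect_true(is.na(daily$NO2[2]))
  # AQHI present only where all three inputs are present
  expect_false(is.na(daily$AQHI[1]))
  expect_true(is.na(daily$AQHI[2]))
  expect_equal(daily$temperature, c(18, 20))
})

test_that("seasonal exposure summaries respect ordering invariants", {
  p <- sim_params(n_days = 400, seed = 21)
  ex <- simulate_exposures(p)
  s <- exposure_summary(ex)
  ok <- !is.na(s$mean)
  expect_true(all(s$iqr[ok] >= 0))
  expect_true(all(s$min[ok] <= s$mean[ok] & s$mean[ok] <= s$max[ok]))
  expect_setequal(unique(s$season), c("all", "cold", "warm"))
})
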