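# shared fixtures and simulation helpers, built in code at test time

# one station-day of hourly values for a single pollutant
hourly_day <- function(values, date = as.Date("2020-06-01"),
                       station = "S1", pollutant = "CO",
                       hours = seq_along(values) - 1L) {
  tibble::tibble(station_id = station, date = date, hour = as.integer(hours),
                 pollutant = pollutant, value = values)
}

# simulate one replicate and fit the single-exposure model at the given lag
sim_and_fit <- function(seed, slope = 0, kappa = 1.5, n_days = 1000,
                        lag = 1L, exposure = "CO") {
  eff <- if (slope != 0) {
    tibble::tibble(exposure = exposure, lag = lag, slope = slope)
  } else NULL
  p <- sim_params(n_days = n_days, seed = seed, overdispersion = kappa,
                  true_effects = eff)
  dates <- seq(p$start_date - lag, by = "day", length.out = p$n_days + lag)
  ex <- simulate_exposures(p, dates = dates)
  cnt <- simulate_counts(p, ex)
  md <- attach_lags(cnt[, c("date", "count")], ex, exposure, lag)
  fit_model(md)
}

# independent fixed-effects Poisson oracle: exposure coefficient from glm
# with one indicator per cluster (clusters with zero totals removed)
glm_fixed_effects_beta <- function(y, x, cluster) {
  keep <- stats::ave(y, cluster, FUN = sum) > 0
  dat <- data.frame(y = y[keep], x = x[keep],
                    cl = factor(cluster[keep]))
  fml <- if (nlevels(droplevels(dat$cl)) > 1) y ~ x + cl else y ~ x
  g <- suppressWarnings(stats::glm(fml, data = dat, family = stats::poisson,
                                   control = stats::glm.control(
                                     epsilon = 1e-13, maxit = 100)))
  stats::coef(g)[["x"]]
}
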