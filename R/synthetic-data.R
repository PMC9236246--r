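#' Default per-pollutant generator settings
#'
#' Mean, seasonal amplitude, lag-1 autocorrelation and innovation standard
#' deviation of each simulated pollutant series, in native units, plus the
#' clipping floor. Means match typical long-run urban levels in a large
#' Canadian city (CO 0.3 ppm, NO2 16.1 ppb, O3 23.5 ppb, SO2 1.4 ppb,
#' PM2.5 8.9 ug/m3); amplitudes and noise scales are chosen so that the
#' interquartile ranges of the simulated series land near the observed
#' ones (e.g. about 0.1 ppm for CO).
#'
#' @return Tibble with columns `pollutant`, `mean`, `amplitude`, `ar1`,
#'   `sd`, `floor`.
#' @export
default_pollutant_params <- function() {
  tibble::tibble(
    pollutant = c("CO", "NO2", "SO2", "O3", "PM2.5"),
    mean = c(0.3, 16.1, 1.4, 23.5, 8.9),
    amplitude = c(0.05, 3.0, 0.5, 3.0, 1.0),
    ar1 = c(0.6, 0.6, 0.5, 0.5, 0.6),
    sd = c(0.05, 4.5, 0.7, 7.0, 3.8),
    floor = c(0, 0, 0, 0, 0)
  )
}

#' Simulation parameters
#'
#' Bundles everything the generator needs: study length, per-pollutant
#' series settings, true lagged exposure effects on the log visit rate,
#' baseline visit rate, overdispersion, cluster heterogeneity, smooth
#' weather effects and demographic category weights.
#'
#' @param n_days Number of study days (>= 1).
#' @param start_date First study day.
#' @param seed Integer seed; every stochastic stage derives its stream
#'   from it, so identical parameters give identical datasets.
#' @param pollutants Per-pollutant settings, see
#'   [default_pollutant_params()].
#' @param true_effects Tibble with columns `exposure`, `lag`, `slope`:
#'   log-rate slope per native exposure unit at the given lag. Empty by
#'   default (the null model).
#' @param baseline_rate Expected visits per day for the whole population
#'   at reference conditions, > 0.
#' @param overdispersion Variance inflation kappa >= 1 of daily counts
#'   (variance = kappa * mean); 1 gives exact Poisson, the default 1.5 is
#'   a moderate, realistic inflation for ED visit counts.
#' @param cluster_sd Standard deviation of i.i.d. normal log-rate
#'   intercepts per year-month-weekday cluster. The case-crossover
#'   estimator must be insensitive to these.
#' @param weather_effect Named coefficients `temp1`, `temp2`, `hum1`,
#'   `hum2` of a quadratic in standardised temperature and humidity added
#'   to the log rate (smooth, so a 3-df natural spline can absorb it).
#' @param sex_weights,age_weights,block_weights,tag_weights Category
#'   weights used to disaggregate daily counts into visit records;
#'   defaults follow the demographic and diagnostic mix of nervous-system
#'   ED visits (59.5% female; episodic and paroxysmal disorders about 64%
#'   of visits, migraine about 39% of those).
#' @param o3h8_scale,o3h8_sd The simulated daily max 8-h ozone is
#'   `o3h8_scale * O3` plus noise; the default scale 1.86 reproduces the
#'   observed ratio of the two ozone metrics' long-run means.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(n_days = 1000L,
                       start_date = as.Date("2010-01-01"),
                       seed = 1L,
                       pollutants = default_pollutant_params(),
                       true_effects = NULL,
                       baseline_rate = 32.7,
                       overdispersion = 1.5,
                       cluster_sd = 0.1,
                       weather_effect = c(temp1 = -0.05, temp2 = 0.04,
                                          hum1 = 0.02, hum2 = 0),
                       sex_weights = c(M = 0.405, F = 0.595),
                       age_weights = c(`0-10` = 0.03054,
                                       `11-60` = 0.66638,
                                       `>60` = 0.30308),
                       block_weights = NULL,
                       tag_weights = NULL,
                       o3h8_scale = 1.86,
                       o3h8_sd = 2) {
  if (is.null(true_effects)) {
    true_effects <- tibble::tibble(exposure = character(0),
                                   lag = integer(0), slope = numeric(0))
  }
  if (is.null(block_weights)) {
    block_weights <- c(`G00-G09` = 1913, `G10-G14` = 472, `G20-G26` = 4075,
                       `G30-G32` = 1704, `G35-G37` = 1816,
                       `G40-G47` = 89708, `G50-G59` = 30607,
                       `G60-G64` = 3436, `G70-G73` = 889,
                       `G80-G83` = 1244, `G90-G99` = 4650)
  }
  if (is.null(tag_weights)) {
    tag_weights <- c(G40 = 18670, G43 = 34864, G44 = 8159, G45 = 21914,
                     G47 = 6101)
  }
  p <- list(n_days = as.integer(n_days), start_date = as.Date(start_date),
            seed = as.integer(seed), pollutants = pollutants,
            true_effects = true_effects, baseline_rate = baseline_rate,
            overdispersion = overdispersion, cluster_sd = cluster_sd,
            weather_effect = weather_effect, sex_weights = sex_weights,
            age_weights = age_weights, block_weights = block_weights,
            tag_weights = tag_weights, o3h8_scale = o3h8_scale,
            o3h8_sd = o3h8_sd)
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  vals <- unlist(p$pollutants[c("mean", "amplitude", "ar1", "sd")])
  if (any(!is.finite(vals))) {
    stop("sim_params: non-finite pollutant parameter")
  }
  # the floor may be -Inf (no clipping) but never NA/NaN/+Inf
  if (any(is.na(p$pollutants$floor) | p$pollutants$floor == Inf)) {
    stop("sim_params: non-finite pollutant parameter (floor)")
  }
  if (any(p$pollutants$ar1 <= -1 | p$pollutants$ar1 >= 1)) {
    stop("sim_params: AR1 coefficient must lie in (-1, 1)")
  }
  if (any(p$pollutants$sd < 0) || any(p$pollutants$amplitude < 0)) {
    stop("sim_params: negative amplitude or noise sd")
  }
  if (p$n_days < 1) stop("sim_params: n_days must be >= 1")
  if (!is.finite(p$baseline_rate) || p$baseline_rate < 0) {
    stop("sim_params: baseline_rate must be finite and >= 0")
  }
  if (p$overdispersion < 1) stop("sim_params: overdispersion must be >= 1")
  if (nrow(p$true_effects) > 0) {
    bad <- setdiff(p$true_effects$exposure, exposure_names())
    if (length(bad) > 0) {
      stop("sim_params: true_effects name unknown exposure(s): ",
           paste(bad, collapse = ", "))
    }
    if (any(p$true_effects$lag < 0 | p$true_effects$lag > 14)) {
      stop("sim_params: true_effects lags must lie in 0-14")
    }
  }
  invisible(p)
}

# stationary AR(1): x_t = rho x_{t-1} + e_t, e ~ N(0, sd^2),
# x_1 drawn from the stationary distribution
ar1_series <- function(n, rho, sd) {
  if (sd == 0) return(rep(0, n))
  e <- stats::rnorm(n, 0, sd)
  e[1] <- stats::rnorm(1, 0, sd / sqrt(1 - rho^2))
  if (rho == 0) return(e)
  as.numeric(stats::filter(e, rho, method = "recursive"))
}

seasonal_ar1 <- function(dates, mean, amplitude, rho, sd, phase = 0) {
  t <- as.numeric(dates - as.Date("2000-01-01"))
  mean + amplitude * sin(2 * pi * (t + phase) / 365.25) +
    ar1_series(length(dates), rho, sd)
}

#' Simulate a daily exposure and weather series
#'
#' Each pollutant is a seasonal sinusoid (period 365.25 days) around its
#' long-run mean plus stationary AR(1) noise, clipped at the configured
#' floor. Temperature peaks in midsummer with an annual amplitude typical
#' of a continental mid-latitude city; relative humidity is nearly
#' aseasonal. The 8-hour ozone metric is a scaled version of the 24-hour
#' ozone mean with additional noise, and the two composite indices are
#' computed from the simulated components with [compute_aqhi()].
#'
#' @param params A [sim_params()] object.
#' @param dates Optional explicit date vector overriding
#'   `params$start_date` / `params$n_days` (used internally to extend the
#'   series backwards for lag coverage).
#' @return Daily tibble: `date`, `CO`, `NO2`, `SO2`, `O3`, `PM2.5`,
#'   `O3H8`, `AQHI`, `AQHIX`, `temperature`, `humidity`.
#' @export
simulate_exposures <- function(params, dates = NULL) {
  validate_sim_params(params)
  if (is.null(dates)) {
    dates <- seq(params$start_date, by = "day", length.out = params$n_days)
  }
  set.seed(params$seed)
  out <- tibble::tibble(date = dates)
  for (i in seq_len(nrow(params$pollutants))) {
    row <- params$pollutants[i, ]
    # phase -91.31 puts the sinusoid peak near early July
    x <- seasonal_ar1(dates, row$mean, row$amplitude, row$ar1, row$sd,
                      phase = -91.31)
    out[[row$pollutant]] <- pmax(x, row$floor)
  }
  if ("O3" %in% names(out)) {
    out$O3H8 <- pmax(params$o3h8_scale * out$O3 +
                       stats::rnorm(length(dates), 0, params$o3h8_sd), 0)
  }
  if (all(c("O3", "NO2", "PM2.5") %in% names(out))) {
    out$AQHI <- compute_aqhi(out$O3, out$NO2, out$`PM2.5`)
    out$AQHIX <- compute_aqhi(out$O3H8, out$NO2, out$`PM2.5`)
  }
  out$temperature <- seasonal_ar1(dates, 9.5, 12, 0.7, 3, phase = -91.31)
  out$humidity <- pmin(pmax(
    seasonal_ar1(dates, 70.7, 2, 0.5, 7, phase = 91.31), 0), 100)
  out
}

#' Simulate daily whole-population visit counts
#'
#' The log daily rate is the log baseline plus an i.i.d. normal intercept
#' for the day's year-month-weekday cluster, plus the configured lagged
#' exposure effects, plus a quadratic in standardised temperature and
#' humidity. Counts are negative binomial with mean mu and variance
#' kappa * mu (exactly Poisson when the overdispersion kappa is 1).
#'
#' @param params A [sim_params()] object.
#' @param exposures Daily exposure tibble covering every study day back to
#'   the maximum configured lag (see [simulate_exposures()]).
#' @return Tibble: `date`, `count`, `mu` (true mean), `cluster`.
#' @export
simulate_counts <- function(params, exposures) {
  validate_sim_params(params)
  dates <- seq(params$start_date, by = "day", length.out = params$n_days)
  max_lag <- if (nrow(params$true_effects) > 0) max(params$true_effects$lag)
             else 0L
  need <- seq(params$start_date - max_lag, by = "day",
              length.out = params$n_days + max_lag)
  if (!all(need %in% exposures$date)) {
    stop("simulate_counts: exposures must cover the study days plus ",
         max_lag, " lag day(s) before the start")
  }
  set.seed(params$seed + 1L)
  des <- build_clusters(min(dates), max(dates))
  cluster <- des$days$cluster[match(dates, des$days$date)]
  cl_levels <- unique(cluster)
  cl_eff <- stats::rnorm(length(cl_levels), 0, params$cluster_sd)
  names(cl_eff) <- cl_levels
  eta <- rep(log(max(params$baseline_rate, 1e-300)), length(dates)) +
    unname(cl_eff[cluster])
  if (nrow(params$true_effects) > 0) {
    for (i in seq_len(nrow(params$true_effects))) {
      eff <- params$true_effects[i, ]
      lagged <- exposures[[eff$exposure]][match(dates - eff$lag,
                                                exposures$date)]
      eta <- eta + eff$slope * lagged
    }
  }
  we <- params$weather_effect
  expo_now <- exposures[match(dates, exposures$date), ]
  zt <- as.numeric(scale(expo_now$temperature))
  zh <- as.numeric(scale(expo_now$humidity))
  eta <- eta + we[["temp1"]] * zt + we[["temp2"]] * zt^2 +
    we[["hum1"]] * zh + we[["hum2"]] * zh^2
  mu <- exp(eta)
  if (params$baseline_rate == 0) {
    count <- integer(length(mu))
  } else if (params$overdispersion == 1) {
    count <- stats::rpois(length(mu), mu)
  } else {
    size <- mu / (params$overdispersion - 1) # var = mu + mu^2/size = kappa mu
    count <- stats::rnbinom(length(mu), size = size, mu = mu)
  }
  tibble::tibble(date = dates, count = as.integer(count), mu = mu,
                 cluster = unname(cluster))
}

# representative ICD-10 code sampled for each diagnostic block
block_codes <- function() {
  c(`G00-G09` = "G03", `G10-G14` = "G12", `G20-G26` = "G20",
    `G30-G32` = "G31", `G35-G37` = "G35", `G50-G59` = "G51",
    `G60-G64` = "G62", `G70-G73` = "G70", `G80-G83` = "G81",
    `G90-G99` = "G93")
}

#' Simulate individual emergency department visit records
#'
#' Draws daily whole-population counts with [simulate_counts()] and
#' disaggregates each day's count into individual records, sampling sex,
#' age group (then a uniform age within the group) and diagnostic code
#' independently from the configured category weights. Within the
#' episodic and paroxysmal block the code is drawn from the sub-code
#' weights (epilepsy, migraine, other headaches, ischaemic attacks, sleep
#' disorders); other blocks use a fixed representative code.
#'
#' @param params A [sim_params()] object.
#' @param exposures Daily exposure tibble, see [simulate_counts()].
#' @return Tibble of visit records: `date`, `icd10`, `sex`, `age`.
#' @export
simulate_visits <- function(params, exposures) {
  daily <- simulate_counts(params, exposures)
  n <- sum(daily$count)
  set.seed(params$seed + 2L)
  if (n == 0) {
    return(tibble::tibble(date = as.Date(character(0)),
                          icd10 = character(0), sex = character(0),
                          age = numeric(0)))
  }
  date <- rep(daily$date, daily$count)
  sex <- sample(names(params$sex_weights), n, replace = TRUE,
                prob = params$sex_weights)
  grp <- sample(names(params$age_weights), n, replace = TRUE,
                prob = params$age_weights)
  age <- numeric(n)
  age[grp == "0-10"] <- stats::runif(sum(grp == "0-10"), 0, 11)
  age[grp == "11-60"] <- stats::runif(sum(grp == "11-60"), 11, 61)
  age[grp == ">60"] <- stats::runif(sum(grp == ">60"), 61, 95)
  block <- sample(names(params$block_weights), n, replace = TRUE,
                  prob = params$block_weights)
  icd10 <- unname(block_codes()[block])
  in47 <- block == "G40-G47"
  icd10[in47] <- sample(names(params$tag_weights), sum(in47),
                        replace = TRUE, prob = params$tag_weights)
  tibble::tibble(date = date, icd10 = icd10, sex = sex,
                 age = floor(age))
}

#' Simulate a complete synthetic study dataset
#'
#' Generates an exposure/weather series long enough to cover every
#' configured lag, then visit records over the study period. This is the
#' one-call entry point mirroring the real pipeline's inputs.
#'
#' @param params A [sim_params()] object.
#' @return List of class `synthetic_dataset` with elements `exposures`
#'   (covering `max_lag` days before the study start), `visits`, and
#'   `params`.
#' @export
simulate_dataset <- function(params) {
  validate_sim_params(params)
  max_lag <- if (nrow(params$true_effects) > 0) max(params$true_effects$lag)
             else 0L
  dates <- seq(params$start_date - max_lag, by = "day",
               length.out = params$n_days + max_lag)
  exposures <- simulate_exposures(params, dates = dates)
  visits <- simulate_visits(params, exposures)
  structure(list(exposures = exposures, visits = visits, params = params),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic case-crossover dataset:", x$params$n_days, "study days,",
      nrow(x$visits), "visits,",
      nrow(x$exposures), "exposure days\n")
  invisible(x)
}
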