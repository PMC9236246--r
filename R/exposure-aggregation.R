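#' Pollutants recognised by the pipeline
#'
#' The five measured pollutants plus the derived 8-hour ozone metric and the
#' two composite air-quality indices. Units are the native monitoring units:
#' ppm for CO; ppb for NO2, SO2, O3 and O3H8; micrograms per cubic metre for
#' PM2.5; index units for AQHI and AQHIX.
#'
#' @return Character vector of the eight exposure names.
#' @export
exposure_names <- function() {
  c("CO", "NO2", "SO2", "PM2.5", "O3", "O3H8", "AQHI", "AQHIX")
}

measured_pollutants <- function() c("CO", "NO2", "SO2", "O3", "PM2.5")

#' AQHI coefficients
#'
#' Frozen constants of the Canadian Air Quality Health Index: a scale of
#' 1000/10.4, exponential slopes of 0.000537 per ppb O3, 0.000871 per ppb
#' NO2 and 0.000487 per ug/m3 PM2.5, and an offset of 3. The slopes were
#' originally derived from mortality risk coefficients in large Canadian
#' cities; they are treated here as fixed constants of the index, not as
#' quantities to re-estimate.
#'
#' @param scale,c_o3,c_no2,c_pm25,offset Override individual constants.
#'   Defaults are the published values.
#' @return Named list of coefficients.
#' @export
aqhi_coefficients <- function(scale = 1000 / 10.4,
                              c_o3 = 0.000537,
                              c_no2 = 0.000871,
                              c_pm25 = 0.000487,
                              offset = 3) {
  stopifnot(is.numeric(scale), is.numeric(c_o3), is.numeric(c_no2),
            is.numeric(c_pm25), is.numeric(offset))
  list(scale = scale, c_o3 = c_o3, c_no2 = c_no2, c_pm25 = c_pm25,
       offset = offset)
}

#' Compute the Air Quality Health Index
#'
#' AQHI = scale * (exp(c_o3 * O3) + exp(c_no2 * NO2) + exp(c_pm25 * PM2.5)
#' - offset). The continuous value is returned; it is what enters the
#' regression models. Feeding the daily maximum 8-hour ozone average instead
#' of the 24-hour mean gives the AQHI-x variant. Missing inputs propagate
#' to a missing index value.
#'
#' @param o3 Ozone in ppb (24-h mean for AQHI, daily max 8-h mean for AQHI-x).
#' @param no2 Nitrogen dioxide in ppb (24-h mean).
#' @param pm25 Fine particulate matter in ug/m3 (24-h mean).
#' @param coef Coefficient set, see [aqhi_coefficients()].
#' @return Numeric vector of continuous index values.
#' @seealso [aqhi_public_scale()] for the rounded public 1-10+ presentation.
#' @export
compute_aqhi <- function(o3, no2, pm25, coef = aqhi_coefficients()) {
  n <- max(length(o3), length(no2), length(pm25))
  o3 <- rep_len(as.numeric(o3), n)
  no2 <- rep_len(as.numeric(no2), n)
  pm25 <- rep_len(as.numeric(pm25), n)
  if (any(is.infinite(c(o3, no2, pm25)))) {
    stop("compute_aqhi: inputs must be finite or NA")
  }
  coef$scale * (exp(coef$c_o3 * o3) + exp(coef$c_no2 * no2) +
                  exp(coef$c_pm25 * pm25) - coef$offset)
}

#' Round a continuous AQHI value to the public communication scale
#'
#' The public scale shows integers 1 to 10 and "10+" (coded 11). Values are
#' rounded to the nearest integer and floored at 1. This presentation scale
#' is never used in the regression models, which consume the continuous
#' index.
#'
#' @param aqhi Continuous index values.
#' @return Integer vector on the 1-11 scale (11 encodes "10+").
#' @export
aqhi_public_scale <- function(aqhi) {
  out <- pmax(1L, as.integer(round(aqhi)))
  out[out > 10L] <- 11L
  out[is.na(aqhi)] <- NA_integer_
  out
}

#' Daily 24-hour means per station and pollutant
#'
#' Averages hourly records into one value per station, pollutant and day.
#' A day is reported missing when the fraction of available hours falls
#' below `completeness_min`; the default 0.75 (18 of 24 hours) follows
#' common air-monitoring validity rules.
#'
#' @param records Tibble of hourly records with columns `station_id`,
#'   `date` (Date), `hour` (0-23), `pollutant`, `value`.
#' @param completeness_min Minimum fraction of the 24 hours that must be
#'   non-missing, in (0, 1].
#' @return Tibble with columns `station_id`, `date`, `pollutant`, `value`,
#'   `n_hours`; `value` is NA where completeness fails.
#' @export
daily_mean_24h <- function(records, completeness_min = 0.75) {
  stopifnot(is.numeric(completeness_min),
            completeness_min > 0, completeness_min <= 1)
  req <- c("station_id", "date", "hour", "pollutant", "value")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0) {
    stop("daily_mean_24h: missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(records$hour < 0 | records$hour > 23, na.rm = TRUE)) {
    stop("daily_mean_24h: hour must lie in 0-23")
  }
  bad <- setdiff(unique(records$pollutant), measured_pollutants())
  if (length(bad) > 0) {
    stop("daily_mean_24h: unknown pollutant(s): ", paste(bad, collapse = ", "))
  }
  dup <- records |>
    dplyr::count(.data$station_id, .data$date, .data$hour, .data$pollutant) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("daily_mean_24h: duplicated (station, pollutant, timestamp) rows, e.g. ",
         paste(utils::head(paste(dup$station_id, dup$date, dup$hour,
                                 dup$pollutant, sep = "/"), 5),
               collapse = "; "))
  }
  records |>
    dplyr::group_by(.data$station_id, .data$date, .data$pollutant) |>
    dplyr::summarise(
      n_hours = sum(!is.na(.data$value)),
      value = mean(.data$value, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(value = ifelse(.data$n_hours / 24 < completeness_min,
                                 NA_real_, .data$value)) |>
    dplyr::select("station_id", "date", "pollutant", "value", "n_hours")
}

#' Daily maximum 8-hour running mean
#'
#' Computes, for each day, the maximum over forward-looking 8-hour running
#' means whose start hour lies in that day. Under the default
#' `window_policy = "within_day"` only windows wholly contained in the day
#' (start hours 0-16) are considered; under `"spillover"` start hours 0-23
#' are allowed and the trailing windows borrow the first 7 hours of the
#' following day. Windows containing any missing hour are discarded; a day
#' with no complete window is missing.
#'
#' @param hourly Tibble with columns `date`, `hour` (0-23) and `value`
#'   (typically O3 in ppb), one row per hour, for a single station or an
#'   already station-averaged series.
#' @param window_policy `"within_day"` or `"spillover"`.
#' @return Tibble with columns `date` and `value` (the daily max 8-h mean).
#' @export
daily_max_8h <- function(hourly, window_policy = c("within_day", "spillover")) {
  window_policy <- match.arg(window_policy)
  stopifnot(all(c("date", "hour", "value") %in% names(hourly)))
  if (anyDuplicated(hourly[c("date", "hour")]) > 0) {
    stop("daily_max_8h: duplicated (date, hour)")
  }
  days <- sort(unique(hourly$date))
  # pad calendar gaps with all-missing days so 8-h windows never straddle
  # non-adjacent dates under the spillover policy
  all_days <- seq(min(days), max(days), by = "day")
  full <- tidyr::expand_grid(date = all_days, hour = 0:23) |>
    dplyr::left_join(hourly, by = c("date", "hour")) |>
    dplyr::arrange(.data$date, .data$hour)
  v <- full$value
  n <- length(v)
  # running 8-h forward mean at every hour of the concatenated series
  run <- rep(NA_real_, n)
  if (n >= 8) {
    cs <- cumsum(ifelse(is.na(v), 0, v))
    nna <- cumsum(is.na(v))
    idx <- seq_len(n - 7)
    complete <- (nna[idx + 7] - c(0, nna)[idx]) == 0
    run[idx][complete] <- (cs[idx + 7] - c(0, cs)[idx])[complete] / 8
  }
  full$run8 <- run
  max_start <- if (window_policy == "within_day") 16L else 23L
  full |>
    dplyr::filter(.data$hour <= max_start, .data$date %in% days) |>
    dplyr::group_by(.data$date) |>
    dplyr::summarise(
      value = if (all(is.na(.data$run8))) NA_real_ else
        max(.data$run8, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Average station-level daily values into a city-wide series
#'
#' Unweighted mean over the stations reporting on each day, per pollutant.
#' A day is missing when fewer than `min_stations` stations report; this is
#' treated as data, not as an error.
#'
#' @param per_station_daily Tibble with columns `station_id`, `date`,
#'   `pollutant`, `value` (as produced by [daily_mean_24h()]).
#' @param min_stations Minimum number of reporting stations, >= 1.
#' @return Tibble with columns `date`, `pollutant`, `value`, `n_stations`.
#' @export
average_stations <- function(per_station_daily, min_stations = 1L) {
  stopifnot(min_stations >= 1)
  per_station_daily |>
    dplyr::group_by(.data$date, .data$pollutant) |>
    dplyr::summarise(
      n_stations = sum(!is.na(.data$value)),
      value = mean(.data$value, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(value = ifelse(.data$n_stations < min_stations,
                                 NA_real_, .data$value)) |>
    dplyr::select("date", "pollutant", "value", "n_stations")
}

#' Interquartile range of a daily series
#'
#' 75th minus 25th percentile under the linear-interpolation convention
#' (R quantile type 7). The convention is pinned because relative risks are
#' reported per IQR increment, so the IQR definition feeds directly into
#' the effect scale.
#'
#' @param x Numeric vector; missing values are dropped.
#' @return Scalar IQR (>= 0).
#' @export
compute_iqr <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 4) {
    stop("compute_iqr: need at least 4 non-missing values")
  }
  q <- stats::quantile(x, probs = c(0.25, 0.75), type = 7, names = FALSE)
  q[2] - q[1]
}

#' Seasonal summary of an exposure series
#'
#' Mean, min, max and IQR per exposure, for all days and separately for the
#' cold (October-March) and warm (April-September) seasons.
#'
#' @param exposures Daily exposure tibble with a `date` column and one
#'   column per exposure (see [simulate_exposures()] or
#'   [build_daily_exposures()]).
#' @return Tibble with columns `exposure`, `season` (all/cold/warm),
#'   `mean`, `min`, `max`, `iqr`, `n`.
#' @export
exposure_summary <- function(exposures) {
  stopifnot("date" %in% names(exposures))
  vars <- intersect(exposure_names(), names(exposures))
  vars <- c(vars, intersect(c("temperature", "humidity"), names(exposures)))
  long <- exposures |>
    dplyr::mutate(season = classify_season(.data$date)) |>
    tidyr::pivot_longer(dplyr::all_of(vars), names_to = "exposure",
                        values_to = "value")
  one <- function(d, label) {
    d |>
      dplyr::group_by(.data$exposure) |>
      dplyr::summarise(
        season = label,
        mean = mean(.data$value, na.rm = TRUE),
        min = suppressWarnings(min(.data$value, na.rm = TRUE)),
        max = suppressWarnings(max(.data$value, na.rm = TRUE)),
        iqr = if (sum(!is.na(.data$value)) >= 4) compute_iqr(.data$value)
              else NA_real_,
        n = sum(!is.na(.data$value)),
        .groups = "drop"
      )
  }
  dplyr::bind_rows(
    one(long, "all"),
    one(dplyr::filter(long, .data$season == "cold"), "cold"),
    one(dplyr::filter(long, .data$season == "warm"), "warm")
  ) |>
    dplyr::arrange(match(.data$exposure, c(vars)), .data$season)
}

#' Assemble a daily city-wide exposure table from station-level hourly data
#'
#' Convenience wrapper chaining [daily_mean_24h()], [daily_max_8h()] (for
#' O3H8, on the station-averaged hourly ozone), [average_stations()] and
#' [compute_aqhi()] into the wide daily table consumed by the design stage.
#'
#' @param hourly Hourly records as for [daily_mean_24h()].
#' @param weather Optional tibble with columns `date`, `temperature`,
#'   `humidity` to join onto the result.
#' @param completeness_min Hourly completeness threshold, see
#'   [daily_mean_24h()].
#' @param min_stations Minimum reporting stations, see [average_stations()].
#' @param window_policy 8-hour window policy, see [daily_max_8h()].
#' @return Wide tibble with one row per day: `date`, the five pollutants,
#'   `O3H8`, `AQHI`, `AQHIX`, and weather columns when supplied.
#' @export
build_daily_exposures <- function(hourly, weather = NULL,
                                  completeness_min = 0.75,
                                  min_stations = 1L,
                                  window_policy = "within_day") {
  per_station <- daily_mean_24h(hourly, completeness_min)
  city <- average_stations(per_station, min_stations)
  wide <- city |>
    dplyr::select("date", "pollutant", "value") |>
    tidyr::pivot_wider(names_from = "pollutant", values_from = "value")
  for (p in setdiff(measured_pollutants(), names(wide))) wide[[p]] <- NA_real_
  # O3H8 from the station-mean hourly ozone series
  o3_hourly <- hourly |>
    dplyr::filter(.data$pollutant == "O3") |>
    dplyr::group_by(.data$date, .data$hour) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop")
  if (nrow(o3_hourly) > 0) {
    o3h8 <- daily_max_8h(o3_hourly, window_policy) |>
      dplyr::rename(O3H8 = "value")
    wide <- dplyr::left_join(wide, o3h8, by = "date")
  } else {
    wide$O3H8 <- NA_real_
  }
  wide$AQHI <- compute_aqhi(wide$O3, wide$NO2, wide$`PM2.5`)
  wide$AQHIX <- compute_aqhi(wide$O3H8, wide$NO2, wide$`PM2.5`)
  if (!is.null(weather)) {
    wide <- dplyr::left_join(wide, weather, by = "date")
  }
  dplyr::arrange(wide, .data$date)
}
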