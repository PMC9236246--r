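#' Read emergency department visit records
#'
#' Reads a delimited table (CSV, header row, ISO-8601 dates, empty cell =
#' missing) with columns `date`, `icd10`, `sex`, `age`. Rows failing
#' validation — unparseable date, sex outside {M, F}, negative or missing
#' age, malformed ICD-10 code — are dropped with a warning reporting how
#' many and which lines; valid rows are kept.
#'
#' @param path Path to the CSV file.
#' @return Tibble of validated visit records: `date` (Date), `icd10`,
#'   `sex`, `age`.
#' @export
read_visits <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  req <- c("date", "icd10", "sex", "age")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols) > 0) {
    stop("read_visits: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  date <- suppressWarnings(as.Date(raw$date, format = "%Y-%m-%d"))
  age <- suppressWarnings(as.numeric(raw$age))
  icd_ok <- grepl("^[A-Za-z][0-9]{2}(\\.?[0-9]*)?$", trimws(raw$icd10))
  valid <- !is.na(date) & raw$sex %in% c("M", "F") &
    !is.na(age) & age >= 0 & icd_ok
  if (any(!valid)) {
    bad_lines <- which(!valid) + 1L # header is line 1
    warning("read_visits: dropped ", sum(!valid), " invalid row(s) at line(s) ",
            paste(utils::head(bad_lines, 10), collapse = ", "),
            if (sum(!valid) > 10) ", ..." else "")
  }
  tibble::tibble(
    date = date[valid],
    icd10 = toupper(trimws(raw$icd10[valid])),
    sex = raw$sex[valid],
    age = age[valid]
  )
}

#' Write visit records
#'
#' Inverse of [read_visits()]: CSV with ISO dates, suitable for
#' round-tripping simulated datasets through the reader.
#'
#' @param visits Visit tibble (`date`, `icd10`, `sex`, `age`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_visits <- function(visits, path) {
  readr::write_csv(visits[c("date", "icd10", "sex", "age")], path, na = "")
  invisible(path)
}

#' Read exposure tables
#'
#' Two kinds are supported. `kind = "hourly"` expects station-level hourly
#' records with columns `station_id`, `date`, `hour`, `pollutant`,
#' `value`; duplicated (station, pollutant, date, hour) keys are an error.
#' `kind = "daily"` expects one row per day: `date` plus any of the
#' exposure columns (see [exposure_names()]) and `temperature`,
#' `humidity`. Empty cells are preserved as missing values, never coerced
#' to zero.
#'
#' @param path Path to the CSV file.
#' @param kind `"hourly"` or `"daily"`.
#' @return Tibble of the requested kind.
#' @export
read_exposures <- function(path, kind = c("daily", "hourly")) {
  kind <- match.arg(kind)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (kind == "hourly") {
    req <- c("station_id", "date", "hour", "pollutant", "value")
    missing_cols <- setdiff(req, names(raw))
    if (length(missing_cols) > 0) {
      stop("read_exposures: missing required column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    date <- suppressWarnings(as.Date(raw$date, format = "%Y-%m-%d"))
    hour <- suppressWarnings(as.integer(raw$hour))
    if (any(is.na(date)) || any(is.na(hour) & !is.na(raw$hour))) {
      stop("read_exposures: unparseable date/hour at line(s) ",
           paste(utils::head(which(is.na(date) | is.na(hour)) + 1L, 10),
                 collapse = ", "))
    }
    if (any(hour < 0 | hour > 23, na.rm = TRUE)) {
      stop("read_exposures: hour outside 0-23")
    }
    out <- tibble::tibble(
      station_id = raw$station_id, date = date, hour = hour,
      pollutant = raw$pollutant,
      value = suppressWarnings(as.numeric(raw$value))
    )
    if (anyDuplicated(out[c("station_id", "date", "hour", "pollutant")]) > 0) {
      stop("read_exposures: duplicated (station, pollutant, timestamp) rows")
    }
    return(out)
  }
  if (!"date" %in% names(raw)) {
    stop("read_exposures: missing required column(s): date")
  }
  date <- suppressWarnings(as.Date(raw$date, format = "%Y-%m-%d"))
  if (any(is.na(date))) {
    stop("read_exposures: unparseable date at line(s) ",
         paste(utils::head(which(is.na(date)) + 1L, 10), collapse = ", "))
  }
  if (anyDuplicated(date) > 0) {
    stop("read_exposures: duplicated dates in daily table")
  }
  out <- tibble::tibble(date = date)
  for (nm in setdiff(names(raw), "date")) {
    out[[nm]] <- suppressWarnings(as.numeric(raw[[nm]]))
  }
  out
}

#' Write a daily exposure table
#'
#' @param exposures Daily exposure tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exposures <- function(exposures, path) {
  readr::write_csv(exposures, path, na = "")
  invisible(path)
}

#' Default pipeline configuration
#'
#' The configuration block mirrors the tunable conventions of the
#' pipeline: the study period, hourly completeness threshold, minimum
#' reporting stations, 8-hour ozone window policy, weather-spline degrees
#' of freedom, IQR scope for RR scaling, and a `simulate` block holding
#' generator settings.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    study_period = list(start = "2004-04-01", end = "2015-12-31"),
    completeness_min = 0.75,
    min_stations = 1L,
    window_policy = "within_day",
    spline_df = 3L,
    iqr_scope = "all_days",
    blocks = c("G00-G99", "G40-G47"),
    simulate = list(n_days = 1000L, start_date = "2010-01-01", seed = 1L,
                    baseline_rate = 32.7, overdispersion = 1.5,
                    cluster_sd = 0.1)
  )
}

#' Read a pipeline configuration file
#'
#' YAML with the keys of [default_config()]; unknown top-level keys are
#' rejected so typos fail loudly, and omitted keys take their defaults.
#'
#' @param path Path to a YAML file.
#' @return Nested named list merged over the defaults.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0) {
    stop("read_config: unknown configuration key(s): ",
         paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(base, user)
  stopifnot(cfg$completeness_min > 0, cfg$completeness_min <= 1,
            cfg$min_stations >= 1,
            cfg$window_policy %in% c("within_day", "spillover"),
            cfg$iqr_scope %in% c("all_days", "per_stratum"))
  cfg
}

#' Write a pipeline configuration file
#'
#' @param config Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
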