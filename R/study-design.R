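#' Classify dates into the cold and warm season
#'
#' Seasons are a month-based dichotomy: cold from October to March, warm
#' from April to September, following the mean monthly temperatures of a
#' mid-latitude Canadian city.
#'
#' @param date Date vector.
#' @return Character vector, `"cold"` or `"warm"`.
#' @export
classify_season <- function(date) {
  date <- as.Date(date)
  m <- as.integer(format(date, "%m"))
  ifelse(m >= 4 & m <= 9, "warm", "cold")
}

# ICD-10 chapter VI blocks: closed prefix ranges over the two-digit part.
# Gaps (G15-G19, G27-G29, ...) map to no block.
icd_block_table <- function() {
  tibble::tibble(
    block = c("G00-G09", "G10-G14", "G20-G26", "G30-G32", "G35-G37",
              "G40-G47", "G50-G59", "G60-G64", "G70-G73", "G80-G83",
              "G90-G99"),
    lo = c(0L, 10L, 20L, 30L, 35L, 40L, 50L, 60L, 70L, 80L, 90L),
    hi = c(9L, 14L, 26L, 32L, 37L, 47L, 59L, 64L, 73L, 83L, 99L)
  )
}

# Sub-code tags within G40-G47 reported separately in descriptive tables.
icd_tag_table <- function() {
  tibble::tibble(
    prefix = c("G40", "G41", "G43", "G44", "G45", "G47"),
    tag = c("epilepsy", "epilepsy", "migraine", "other_headache",
            "tia", "sleep_disorders")
  )
}

#' Map ICD-10 codes to nervous-system diagnostic blocks
#'
#' Assigns each code of ICD-10 chapter VI (G00-G99) to one of the eleven
#' diagnostic blocks (G00-G09 inflammatory, ..., G90-G99 other) by the
#' numeric part of its three-character prefix. Codes in undefined gaps
#' (e.g. G15-G19) and codes from other chapters map to `NA`. Sub-codes of
#' the episodic and paroxysmal block carry an additional tag: epilepsy
#' (G40/G41), migraine (G43), other headache syndromes (G44), cerebral
#' ischaemic attacks (G45) and sleep disorders (G47).
#'
#' @param icd10 Character vector of codes such as `"G43"` or `"G43.1"`.
#' @return Tibble with columns `icd10`, `block`, `tag` (`NA` where
#'   unassigned). Malformed codes (not letter + two digits) raise an error.
#' @export
icd_block <- function(icd10) {
  icd10 <- toupper(trimws(as.character(icd10)))
  ok <- grepl("^[A-Z][0-9]{2}(\\.?[0-9]*)?$", icd10)
  if (any(!ok)) {
    stop("icd_block: malformed ICD-10 code(s): ",
         paste(utils::head(icd10[!ok], 5), collapse = ", "))
  }
  num <- suppressWarnings(as.integer(substr(icd10, 2, 3)))
  is_g <- substr(icd10, 1, 1) == "G"
  tab <- icd_block_table()
  idx <- findInterval(num, tab$lo)
  block <- ifelse(is_g & idx >= 1 & num <= tab$hi[pmax(idx, 1)],
                  tab$block[pmax(idx, 1)], NA_character_)
  tags <- icd_tag_table()
  tag <- tags$tag[match(substr(icd10, 1, 3), tags$prefix)]
  tag[is.na(block)] <- NA_character_
  tibble::tibble(icd10 = icd10, block = block, tag = tag)
}

#' Enumerate the 18 analysis strata
#'
#' The strata cross sex (all, male, female) with either an age group
#' (0-10, 11-60, >60 years) or a season (cold, warm), never both: 3 sex
#' overall + 3 sex x 3 age + 3 sex x 2 season = 18 strata.
#'
#' @return Tibble with columns `stratum_id`, `sex` (all/M/F), `age_group`
#'   (all/0-10/11-60/>60) and `season` (all/cold/warm); exactly 18 rows.
#' @export
enumerate_strata <- function() {
  sexes <- c("all", "M", "F")
  specs <- dplyr::bind_rows(
    tidyr::expand_grid(sex = sexes, age_group = "all", season = "all"),
    tidyr::expand_grid(sex = sexes, age_group = c("0-10", "11-60", ">60"),
                       season = "all"),
    tidyr::expand_grid(sex = sexes, age_group = "all",
                       season = c("cold", "warm"))
  )
  specs$stratum_id <- paste(specs$sex, specs$age_group, specs$season,
                            sep = "|")
  dplyr::select(specs, "stratum_id", "sex", "age_group", "season")
}

#' Age group of the design
#'
#' Groups are 0-10, 11-60 and >60 years; the top group takes age >= 61.
#' Switching the top group to >= 60 amounts to changing the single `60`
#' below.
#'
#' @param age_years Non-negative numeric ages.
#' @return Character vector in `{"0-10", "11-60", ">60"}`.
#' @export
age_group_of <- function(age_years) {
  ifelse(age_years <= 10, "0-10", ifelse(age_years <= 60, "11-60", ">60"))
}

#' Build the time-stratified referent design
#'
#' Assigns every calendar day of the study period to a cluster keyed by
#' (year, month, day of week). Within a month each weekday occurs four or
#' five times, so clusters of referent days have size 4 or 5 and never
#' cross month boundaries. Weekdays follow the ISO convention (Monday = 1);
#' any fixed convention induces the same partition.
#'
#' @param start_date,end_date Study period bounds (inclusive).
#' @return List of class `ts_design` with elements `days` (tibble: `date`,
#'   `cluster`, `year`, `month`, `weekday`), `cluster_sizes` (tibble:
#'   `cluster`, `size`), and `n_days`.
#' @export
build_clusters <- function(start_date, end_date) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (is.na(start_date) || is.na(end_date)) {
    stop("build_clusters: unparseable date bounds")
  }
  if (start_date > end_date) {
    stop("build_clusters: start_date must not exceed end_date")
  }
  date <- seq(start_date, end_date, by = "day")
  year <- as.integer(format(date, "%Y"))
  month <- as.integer(format(date, "%m"))
  weekday <- as.integer(format(date, "%u")) # ISO: Mon=1 .. Sun=7
  cluster <- sprintf("%04d-%02d-%d", year, month, weekday)
  days <- tibble::tibble(date = date, cluster = cluster, year = year,
                         month = month, weekday = weekday)
  sizes <- dplyr::count(days, .data$cluster, name = "size")
  structure(
    list(days = days, cluster_sizes = sizes, n_days = length(date)),
    class = "ts_design"
  )
}

#' @export
print.ts_design <- function(x, ...) {
  cat("Time-stratified design:", x$n_days, "days,",
      nrow(x$cluster_sizes), "year-month-weekday clusters (sizes ",
      paste(range(x$cluster_sizes$size), collapse = "-"), ")\n", sep = " ")
  invisible(x)
}

#' Daily visit counts per stratum and diagnostic block
#'
#' Aggregates individual visit records into a complete, zero-filled daily
#' count series for each analysis stratum and outcome block. Sex and age
#' filters select records; season strata restrict the calendar days
#' retained (clusters are month-bound, and months are wholly cold or warm,
#' so the restriction is self-consistent). The block `"G00-G99"` counts
#' every in-chapter visit; named blocks use [icd_block()].
#'
#' @param visits Tibble of visit records: `date`, `icd10`, `sex` (M/F),
#'   `age` (years).
#' @param period Date vector of length 2, the study period (inclusive);
#'   defaults to the range of visit dates.
#' @param strata Stratum tibble as from [enumerate_strata()] (the default).
#' @param blocks Character vector of outcome blocks; default the whole
#'   chapter and the episodic and paroxysmal block.
#' @return Tibble: `date`, `stratum_id`, `block`, `count`. For season
#'   strata only in-season days appear.
#' @export
build_counts <- function(visits,
                         period = NULL,
                         strata = enumerate_strata(),
                         blocks = c("G00-G99", "G40-G47")) {
  stopifnot(all(c("date", "icd10", "sex", "age") %in% names(visits)))
  if (is.null(period)) {
    period <- if (nrow(visits) > 0) range(as.Date(visits$date))
              else stop("build_counts: empty visits need an explicit period")
  }
  all_days <- seq(as.Date(period[1]), as.Date(period[2]), by = "day")
  known <- c("G00-G99", icd_block_table()$block)
  if (!all(blocks %in% known)) {
    stop("build_counts: unknown block(s): ",
         paste(setdiff(blocks, known), collapse = ", "))
  }
  if (nrow(visits) > 0) {
    coded <- icd_block(visits$icd10)
    visits <- visits |>
      dplyr::mutate(
        date = as.Date(.data$date),
        block = coded$block,
        age_group = age_group_of(.data$age)
      ) |>
      dplyr::filter(!is.na(.data$block),
                    .data$date >= period[1], .data$date <= period[2])
  } else {
    visits$block <- character(0)
    visits$age_group <- character(0)
    visits$date <- as.Date(character(0))
  }
  out <- vector("list", nrow(strata) * length(blocks))
  k <- 0
  for (i in seq_len(nrow(strata))) {
    st <- strata[i, ]
    sel <- visits
    if (st$sex != "all") sel <- sel[sel$sex == st$sex, ]
    if (st$age_group != "all") sel <- sel[sel$age_group == st$age_group, ]
    days_i <- all_days
    if (st$season != "all") {
      days_i <- days_i[classify_season(days_i) == st$season]
    }
    for (b in blocks) {
      sel_b <- if (b == "G00-G99") sel else sel[sel$block == b, ]
      cnt <- table(factor(as.character(sel_b$date),
                          levels = as.character(days_i)))
      k <- k + 1
      out[[k]] <- tibble::tibble(
        date = days_i,
        stratum_id = st$stratum_id,
        block = b,
        count = as.integer(cnt)
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Attach lagged exposure and weather to a daily count series
#'
#' Joins onto each outcome day the exposure and weather values of `lag`
#' days earlier. Rows whose lagged exposure or weather is missing (or
#' falls before the start of the exposure series) are dropped and the
#' number dropped is reported as an attribute `n_dropped`.
#'
#' @param counts Daily count tibble (`date`, `count`, and any stratum or
#'   block columns), typically one stratum-block slice of [build_counts()].
#' @param exposures Daily exposure tibble with `date`, the exposure column,
#'   `temperature` and `humidity`.
#' @param exposure Name of the exposure column to attach.
#' @param lag Integer lag in days, 0 to 14.
#' @return Tibble `counts` plus columns `exposure`, `temperature`,
#'   `humidity` taken from day `date - lag`, with incomplete rows removed.
#' @export
attach_lags <- function(counts, exposures, exposure, lag) {
  if (!(is.numeric(lag) && length(lag) == 1 && lag == as.integer(lag) &&
        lag >= 0 && lag <= 14)) {
    stop("attach_lags: lag must be an integer in 0-14")
  }
  if (!exposure %in% names(exposures)) {
    stop("attach_lags: exposure column not found: ", exposure)
  }
  stopifnot(all(c("temperature", "humidity") %in% names(exposures)))
  lagged <- exposures |>
    dplyr::transmute(
      date = .data$date + lag,
      exposure = .data[[exposure]],
      temperature = .data$temperature,
      humidity = .data$humidity
    )
  joined <- dplyr::left_join(counts, lagged, by = "date")
  keep <- !(is.na(joined$exposure) | is.na(joined$temperature) |
              is.na(joined$humidity))
  out <- joined[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Percentage share of a count in a total
#'
#' Descriptive helper used when tabulating visit frequencies: the share of
#' `part` in `whole` as a percentage rounded to one decimal.
#'
#' @param part,whole Non-negative counts, `whole > 0`.
#' @return Numeric percentage.
#' @export
pct_share <- function(part, whole) {
  stopifnot(all(whole > 0), all(part >= 0))
  round(100 * part / whole, 1)
}

#' Descriptive frequency table of visits
#'
#' Tabulates visit records by sex, season and diagnostic block (with the
#' episodic and paroxysmal sub-tags), reporting counts and percentage
#' shares.
#'
#' @param visits Visit tibble as for [build_counts()].
#' @return Tibble with columns `dimension`, `level`, `n`, `pct` (share of
#'   the dimension's total, one decimal).
#' @export
visit_frequency_table <- function(visits) {
  coded <- icd_block(visits$icd10)
  v <- dplyr::mutate(visits,
                     block = coded$block, tag = coded$tag,
                     season = classify_season(.data$date))
  v <- dplyr::filter(v, !is.na(.data$block))
  n_all <- nrow(v)
  one <- function(dim, tab) {
    tibble::tibble(dimension = dim, level = names(tab),
                   n = as.integer(tab),
                   pct = pct_share(as.integer(tab), sum(tab)))
  }
  g47 <- dplyr::filter(v, .data$block == "G40-G47", !is.na(.data$tag))
  dplyr::bind_rows(
    tibble::tibble(dimension = "all", level = "all", n = n_all, pct = 100),
    one("sex", table(v$sex)),
    one("season", table(v$season)),
    one("block", table(v$block)),
    if (nrow(g47) > 0) {
      tibble::tibble(dimension = "G40-G47 tag",
                     level = names(table(g47$tag)),
                     n = as.integer(table(g47$tag)),
                     pct = pct_share(as.integer(table(g47$tag)),
                                     nrow(dplyr::filter(v, .data$block == "G40-G47"))))
    }
  )
}
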