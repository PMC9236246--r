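test_that("seasons are the month dichotomy October-March vs April-September", {
  expect_equal(classify_season(as.Date("2010-10-15")), "cold")
  expect_equal(classify_season(as.Date("2010-04-01")), "warm")
  expect_equal(classify_season(as.Date("2010-03-31")), "cold")
  expect_equal(classify_season(as.Date("2010-09-30")), "warm")
  # every date in a month gets the month's season
  d <- seq(as.Date("2012-01-01"), as.Date("2012-12-31"), by = "day")
  s <- classify_season(d)
  m <- as.integer(format(d, "%m"))
  expect_true(all((s == "warm") == (m >= 4 & m <= 9)))
})

test_that("ICD-10 codes map to chapter VI blocks with sub-code tags", {
  out <- icd_block(c("G43.1", "G47.9", "G40", "G45.0"))
  expect_equal(out$block, rep("G40-G47", 4))
  expect_equal(out$tag, c("migraine", "sleep_disorders", "epilepsy", "tia"))

  expect_true(is.na(icd_block("H10")$block)) # wrong chapter
  expect_true(is.na(icd_block("G15")$block)) # undefined gap
  expect_error(icd_block("G4"), "malformed")
  expect_error(icd_block(""), "malformed")
})

test_that("block assignment is total and single-valued over G00-G99", {
  # independent range table written out in full
  ranges <- list(`G00-G09` = 0:9, `G10-G14` = 10:14, `G20-G26` = 20:26,
                 `G30-G32` = 30:32, `G35-G37` = 35:37, `G40-G47` = 40:47,
                 `G50-G59` = 50:59, `G60-G64` = 60:64, `G70-G73` = 70:73,
                 `G80-G83` = 80:83, `G90-G99` = 90:99)
  codes <- sprintf("G%02d", 0:99)
  got <- icd_block(codes)$block
  want <- rep(NA_character_, 100)
  for (b in names(ranges)) want[ranges[[b]] + 1] <- b
  expect_equal(got, want)
})

test_that("the stratum enumeration has exactly the 18 design cells", {
  st <- enumerate_strata()
  expect_equal(nrow(st), 18)
  expect_equal(anyDuplicated(st$stratum_id), 0)
  # membership
  expect_true(any(st$sex == "F" & st$age_group == "all" & st$season == "all"))
  # age and season are never crossed
  expect_false(any(st$age_group != "all" & st$season != "all"))
  # composition: 3 overall + 9 sex x age + 6 sex x season
  expect_equal(sum(st$age_group == "all" & st$season == "all"), 3)
  expect_equal(sum(st$age_group != "all"), 9)
  expect_equal(sum(st$season != "all"), 6)
})

test_that("time-stratified clusters partition the study days", {
  des <- build_clusters("2004-04-01", "2015-12-31")
  expect_equal(des$n_days, 4292)
  expect_true(all(des$cluster_sizes$size %in% c(4, 5)))
  expect_equal(sum(des$cluster_sizes$size), des$n_days)
  # every day belongs to exactly one cluster
  expect_equal(anyDuplicated(des$days$date), 0)

  # single-day degenerate design
  one <- build_clusters("2010-05-03", "2010-05-03")
  expect_equal(one$n_days, 1)
  expect_equal(one$cluster_sizes$size, 1)

  # calendar enumeration oracle for one month
  jan <- build_clusters("2015-01-01", "2015-01-31")
  expect_equal(nrow(jan$cluster_sizes), 7)
  expect_equal(sum(jan$cluster_sizes$size), 31)
  expect_true(all(jan$cluster_sizes$size %in% c(4, 5)))

  expect_error(build_clusters("2010-02-01", "2010-01-01"), "must not exceed")
})

test_that("clusters never cross month boundaries", {
  des <- build_clusters("2009-11-15", "2010-02-10")
  by_cluster <- split(des$days$month, des$days$cluster)
  expect_true(all(vapply(by_cluster, function(m) length(unique(m)) == 1,
                         logical(1))))
})

test_that("daily counts zero-fill and respect the stratum filters", {
  period <- as.Date(c("2012-01-01", "2012-01-10"))
  empty <- tibble::tibble(date = as.Date(character(0)),
                          icd10 = character(0), sex = character(0),
                          age = numeric(0))
  z <- build_counts(empty, period = period)
  expect_true(all(z$count == 0))
  # all-season strata cover all 10 days for each of the 2 default blocks
  expect_equal(sum(z$stratum_id == "all|all|all"), 20)

  visits <- tibble::tibble(
    date = as.Date("2012-01-05"),
    icd10 = c("G43", "G43.1", "G43"),
    sex = "F", age = c(30, 45, 25)
  )
  cnt <- build_counts(visits, period = period)
  pick <- function(sid, blk) {
    cnt$count[cnt$stratum_id == sid & cnt$block == blk &
                cnt$date == as.Date("2012-01-05")]
  }
  expect_equal(pick("F|all|all", "G40-G47"), 3)
  expect_equal(pick("F|11-60|all", "G40-G47"), 3)
  expect_equal(pick("F|0-10|all", "G40-G47"), 0)
  expect_equal(pick("M|all|all", "G40-G47"), 0)
  expect_equal(pick("all|all|all", "G00-G99"), 3)
  # January is cold season: the warm stratum has no January days at all
  expect_false(any(cnt$stratum_id == "F|all|warm"))
})

test_that("sex and season strata sum to the overall counts cell by cell", {
  p <- sim_params(n_days = 120, seed = 9, baseline_rate = 15,
                  start_date = as.Date("2011-03-01"))
  ds <- simulate_dataset(p)
  cnt <- build_counts(ds$visits,
                      period = range(ds$visits$date))
  wide <- tidyr::pivot_wider(cnt, names_from = "stratum_id",
                             values_from = "count")
  expect_equal(wide$`M|all|all` + wide$`F|all|all`, wide$`all|all|all`)
  expect_equal(wide$`M|0-10|all` + wide$`M|11-60|all` + wide$`M|>60|all`,
               wide$`M|all|all`)
  # season strata: totals over in-season days add to the all-season total
  tot <- function(sid) sum(cnt$count[cnt$stratum_id == sid &
                                       cnt$block == "G00-G99"])
  expect_equal(tot("all|all|cold") + tot("all|all|warm"), tot("all|all|all"))
})

test_that("lag attachment shifts the exposure series by exactly lag days", {
  days <- as.Date("2020-03-01") + 0:9
  ex <- tibble::tibble(date = days, CO = rnorm(10, 0.3, 0.05),
                       temperature = rnorm(10, 10), humidity = rnorm(10, 70))
  cnt <- tibble::tibble(date = days, count = rpois(10, 5))

  lag0 <- attach_lags(cnt, ex, "CO", 0)
  expect_equal(lag0$exposure, ex$CO)
  expect_equal(attr(lag0, "n_dropped"), 0)

  lag7 <- attach_lags(cnt, ex, "CO", 7)
  expect_equal(nrow(lag7), 3)
  expect_equal(attr(lag7, "n_dropped"), 7)

  # index-arithmetic oracle at lag 1
  lag1 <- attach_lags(cnt, ex, "CO", 1)
  expect_equal(lag1$exposure, ex$CO[match(lag1$date - 1, ex$date)])
  expect_equal(lag1$temperature, ex$temperature[match(lag1$date - 1, ex$date)])

  expect_error(attach_lags(cnt, ex, "CO", 15), "0-14")
  expect_error(attach_lags(cnt, ex, "CO", -1), "0-14")
})

test_that("descriptive frequency tables reproduce hand counts", {
  visits <- tibble::tibble(
    date = as.Date("2012-07-01") + c(0, 0, 1, 200),
    icd10 = c("G43", "G40", "G51", "G93"),
    sex = c("F", "F", "M", "F"),
    age = c(30, 8, 70, 40)
  )
  tab <- visit_frequency_table(visits)
  expect_equal(tab$n[tab$dimension == "all"], 4)
  expect_equal(tab$pct[tab$dimension == "sex" & tab$level == "F"], 75)
  expect_equal(tab$n[tab$dimension == "block" & tab$level == "G40-G47"], 2)
  expect_equal(tab$pct[tab$dimension == "G40-G47 tag" &
                         tab$level == "migraine"], 50)
})
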