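hours6 <- as.POSIXct("2014-03-01 00:00:00", tz = "UTC") + 3600 * (0:5)

test_that("hourly presence is binary regardless of pulse counts", {
  ev <- tibble::tibble(
    utc_time = hours6[2] + runif(500, 0, 3599), accepted = TRUE)
  out <- hourly_presence(ev, hours6)
  expect_identical(out$presence, c(0L, 1L, 0L, 0L, 0L, 0L))
  expect_identical(out$n_events[2], 500L)

  none <- hourly_presence(tibble::tibble(utc_time = hours6[0],
                                         accepted = logical(0)), hours6)
  expect_identical(sum(none$presence), 0L)
})

test_that("events on an hour boundary belong to the later hour and
           out-of-grid events warn", {
  ev <- tibble::tibble(utc_time = hours6[3], accepted = TRUE)
  out <- hourly_presence(ev, hours6)
  expect_identical(out$presence[3], 1L)
  expect_identical(out$presence[2], 0L)

  late <- tibble::tibble(utc_time = hours6[6] + 7200, accepted = TRUE)
  expect_warning(out2 <- hourly_presence(late, hours6), "outside")
  expect_identical(sum(out2$presence), 0L)
})

test_that("detection-day conditioning keeps exactly the days with presence", {
  tab <- make_presence_table(n_days = 15, seed = 31)
  dd <- detection_days(tab)
  by_day <- tapply(tab$presence, tab$date, sum)
  expect_identical(attr(dd, "n_days"), sum(by_day > 0))
  expect_identical(attr(dd, "n_hours"), sum(tab$presence))
  expect_true(all(tapply(dd$presence, droplevels(factor(dd$date)), sum) > 0))

  # single presence hour in a day is enough to retain the day
  one <- tab
  one$presence <- 0L
  one$presence[25] <- 1L                     # second day, first hour
  dd1 <- detection_days(one)
  expect_identical(attr(dd1, "n_days"), 1L)
  expect_identical(nrow(dd1), 24L)

  # all-absent data: empty table, zero totals
  zero <- tab
  zero$presence <- 0L
  dd0 <- detection_days(zero)
  expect_identical(nrow(dd0), 0L)
  expect_identical(attr(dd0, "n_days"), 0L)
})

test_that("the presence matrix sums presence across years conservatively", {
  one <- tibble::tibble(
    utc_hour = as.POSIXct("2014-02-10 07:00:00", tz = "UTC"), presence = 1L)
  m1 <- presence_matrix(one)
  expect_identical(sum(m1), 1L)
  expect_identical(m1[as.integer(format(one$utc_hour, "%j")), "7"], 1L)

  two <- dplyr::bind_rows(one, dplyr::mutate(
    one, utc_hour = as.POSIXct("2015-02-10 07:00:00", tz = "UTC")))
  m2 <- presence_matrix(two)
  expect_identical(max(m2), 2L)

  tab <- make_presence_table(n_days = 20, seed = 33)
  m <- presence_matrix(tab)
  expect_identical(sum(m), sum(tab$presence))
  by_doy <- tapply(tab$presence, tab$day_of_year, sum)
  expect_identical(unname(rowSums(m)[names(by_doy)]),
                   unname(as.numeric(by_doy)))
})

test_that("regime proportions follow their arithmetic definition", {
  full <- make_presence_table(n_days = 3, seed = 35)
  full$presence <- 1L
  rp <- regime_proportions(detection_days(full))
  expect_true(all(rp$mean_proportion == 1))

  # a day with 12 day-regime hours of which 3 present
  tab <- tibble::tibble(
    site = "s", date = as.Date("2014-03-01") + rep(0:1, each = 24),
    utc_hour = as.POSIXct("2014-03-01 00:00:00", tz = "UTC") + 3600 * (0:47),
    regime = rep(rep(c("night", "dawn", "day", "dusk"), c(8, 2, 12, 2)), 2),
    presence = 0L)
  tab$presence[tab$regime == "day"] <- rep(c(1L, 1L, 1L, rep(0L, 9)), 2)
  rp2 <- regime_proportions(suppressWarnings(detection_days(tab)))
  expect_equal(rp2$mean_proportion[rp2$regime == "day"], 0.25)
  expect_identical(rp2$n_days[rp2$regime == "day"], 2L)

  # row order never matters
  dd <- detection_days(make_presence_table(n_days = 25, seed = 36))
  rp3 <- regime_proportions(dd)
  rp4 <- regime_proportions(dd[sample.int(nrow(dd)), ])
  expect_equal(rp3, rp4, ignore_attr = TRUE)
})

test_that("generated night-heavy series show night > day mean proportions", {
  tab <- make_presence_table(
    n_days = 200, effects = c(dawn = 0.5, day = 0, dusk = 0, night = 1.2),
    intercept = -0.8, rho = 0.6, seed = 37)
  rp <- regime_proportions(detection_days(tab))
  expect_gt(rp$mean_proportion[rp$regime == "night"],
            rp$mean_proportion[rp$regime == "day"])
})

test_that("both Fig-4 denominator conventions are available and differ", {
  dd <- detection_days(make_presence_table(n_days = 40, seed = 38))
  a <- regime_proportions(dd, denominator = "regime_hours")
  b <- regime_proportions(dd, denominator = "presence_hours")
  expect_false(isTRUE(all.equal(a$mean_proportion, b$mean_proportion)))
  # the presence-hours shares sum to 1 within each day
  daily <- attr(b, "daily")
  sums <- tapply(daily$proportion, paste(daily$site, daily$date), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})
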