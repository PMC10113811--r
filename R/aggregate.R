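#' Hourly acoustic presence from detection events
#'
#' Presence is binary per hour — at least one accepted detection in the
#' half-open hour `[h, h + 1h)` — rather than a pulse count. Events outside
#' the hour grid are dropped with a warning.
#'
#' @param events Detection tibble with a `utc_time` column (and `accepted`,
#'   used if present; otherwise all events count).
#' @param hours `POSIXct` vector of UTC hour starts defining the grid.
#' @return Tibble: `utc_hour`, `presence` (0/1), `n_events`.
#' @export
hourly_presence <- function(events, hours) {
  hours <- as.POSIXct(hours, tz = "UTC")
  ev_t <- if (nrow(events)) {
    tm <- as.POSIXct(events$utc_time, tz = "UTC")
    if ("accepted" %in% names(events)) tm <- tm[events$accepted]
    tm
  } else as.POSIXct(character(), tz = "UTC")
  lo <- min(hours)
  hi <- max(hours) + 3600
  outside <- ev_t < lo | ev_t >= hi
  if (any(outside)) {
    warn(sprintf("%d event(s) outside the hour grid ignored", sum(outside)))
    ev_t <- ev_t[!outside]
  }
  ev_hour <- as.numeric(lo) + 3600 * floor((as.numeric(ev_t) - as.numeric(lo)) / 3600)
  counts <- table(ev_hour)
  n_events <- integer(length(hours))
  idx <- match(as.character(as.numeric(hours)), names(counts))
  n_events[!is.na(idx)] <- as.integer(counts[idx[!is.na(idx)]])
  tibble(utc_hour = hours, presence = as.integer(n_events > 0),
         n_events = n_events)
}

#' Condition hourly records on detection days
#'
#' Retains only site-dates with fin whale acoustic presence in at least one
#' hour (detection days): the unit on which the diel analysis is
#' conditioned.
#'
#' @param hourly Tibble of hourly records with `site`, `utc_hour` (or
#'   `date`) and `presence`.
#' @return The retained rows, with a `date` column, as a
#'   `detection_day_table` tibble. Attributes `n_days` and `n_hours` report
#'   the retained totals.
#' @export
detection_days <- function(hourly) {
  stopifnot("presence" %in% names(hourly))
  if (!"site" %in% names(hourly)) hourly$site <- "site"
  if (!"date" %in% names(hourly)) {
    hourly <- mutate(hourly, date = as.Date(.data$utc_hour, tz = "UTC"))
  }
  out <- hourly %>%
    group_by(.data$site, .data$date) %>%
    filter(any(.data$presence == 1)) %>%
    ungroup()
  attr(out, "n_days") <- nrow(distinct(out, .data$site, .data$date))
  attr(out, "n_hours") <- sum(out$presence)
  class(out) <- c("detection_day_table", class(out))
  out
}

#' Day-of-year by hour-of-day presence matrix
#'
#' Sums hourly presence across recording years into a 366 x 24 grid of
#' presence counts (presence overlapping across years), the data product
#' behind seasonal/diel presence maps.
#'
#' @param hourly Tibble with `utc_hour` and `presence` (optionally
#'   pre-computed `day_of_year` / `hour_of_day`).
#' @return A 366 x 24 integer matrix; `dimnames` are day-of-year 1-366 and
#'   hour-of-day 0-23. The long form is attached as attribute `long`.
#' @export
presence_matrix <- function(hourly) {
  stopifnot("presence" %in% names(hourly))
  if (!"day_of_year" %in% names(hourly)) {
    hourly <- mutate(hourly,
                     day_of_year = as.integer(format(.data$utc_hour, "%j",
                                                     tz = "UTC")),
                     hour_of_day = as.integer(format(.data$utc_hour, "%H",
                                                     tz = "UTC")))
  }
  m <- matrix(0L, nrow = 366, ncol = 24,
              dimnames = list(doy = 1:366, hour = 0:23))
  agg <- hourly %>%
    group_by(.data$day_of_year, .data$hour_of_day) %>%
    summarise(n = sum(.data$presence), .groups = "drop")
  m[cbind(agg$day_of_year, agg$hour_of_day + 1L)] <- as.integer(agg$n)
  attr(m, "long") <- agg
  m
}

#' Mean proportion of presence hours per detection day, by light regime
#'
#' For every detection day and regime occurring on it, the proportion of
#' that regime's hours with acoustic presence is computed; the summary is
#' the mean and standard error of these daily proportions across detection
#' days. With `denominator = "presence_hours"` the alternative definition —
#' the share of the day's presence hours falling in each regime — is used
#' instead.
#'
#' @param table A [detection_days()] table with `regime` and `presence`.
#' @param denominator `"regime_hours"` (default: presence hours of the
#'   regime over hours of the regime that day) or `"presence_hours"`
#'   (regime's presence hours over the day's total presence hours).
#' @return Tibble per regime: `mean_proportion`, `se`, `n_days` (days
#'   contributing a value). The per-day proportions are attached as
#'   attribute `daily`.
#' @export
regime_proportions <- function(table,
                               denominator = c("regime_hours",
                                               "presence_hours")) {
  denominator <- arg_match(denominator)
  stopifnot(all(c("regime", "presence") %in% names(table)))
  if (!nrow(table)) abort("regime_proportions needs at least one detection day")
  if (!"site" %in% names(table)) table$site <- "site"
  if (!"date" %in% names(table)) {
    table <- mutate(table, date = as.Date(.data$utc_hour, tz = "UTC"))
  }
  daily <- table %>%
    group_by(.data$site, .data$date) %>%
    mutate(day_presence_hours = sum(.data$presence)) %>%
    group_by(.data$site, .data$date, regime = as.character(.data$regime)) %>%
    summarise(n_hours = dplyr::n(),
              n_present = sum(.data$presence),
              day_presence_hours = .data$day_presence_hours[1],
              .groups = "drop") %>%
    mutate(proportion = if (denominator == "regime_hours") {
      .data$n_present / .data$n_hours
    } else {
      .data$n_present / .data$day_presence_hours
    })
  all_lv <- c("dawn", "day", "dusk", "night")
  missing_lv <- setdiff(all_lv, unique(daily$regime))
  if (length(missing_lv)) {
    warn(paste0("regime(s) never occurring in the table: ",
                paste(missing_lv, collapse = ", ")))
  }
  out <- daily %>%
    group_by(.data$regime) %>%
    summarise(mean_proportion = mean(.data$proportion),
              se = sd(.data$proportion) / sqrt(dplyr::n()),
              n_days = dplyr::n(), .groups = "drop") %>%
    arrange(match(.data$regime, all_lv))
  attr(out, "daily") <- daily
  out
}

#' Assemble the hourly record table for a site
#'
#' Joins hourly presence, light regimes and hourly noise percentiles into
#' the per-site-hour analysis table.
#'
#' @param presence Tibble from [hourly_presence()].
#' @param regimes Tibble from [classify_series()].
#' @param noise Optional tibble with `utc_hour` and `p_db` (from
#'   [hourly_percentile()]).
#' @param site Site identifier.
#' @return Tibble of hourly records: `site`, `utc_hour`, `date`,
#'   `day_of_year`, `hour_of_day`, `presence`, `regime`, `noise_p20_db`.
#' @export
hourly_records <- function(presence, regimes, noise = NULL, site = "site") {
  out <- presence %>%
    left_join(select(regimes, "utc_hour", "regime"), by = "utc_hour") %>%
    mutate(site = site,
           date = as.Date(.data$utc_hour, tz = "UTC"),
           day_of_year = as.integer(format(.data$utc_hour, "%j", tz = "UTC")),
           hour_of_day = as.integer(format(.data$utc_hour, "%H", tz = "UTC")),
           .before = 1) %>%
    relocate("site", "utc_hour")
  if (!is.null(noise)) {
    out <- left_join(out,
                     select(noise, "utc_hour", noise_p20_db = "p_db"),
                     by = "utc_hour")
  } else {
    out$noise_p20_db <- NA_real_
  }
  out
}
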