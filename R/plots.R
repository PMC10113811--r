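#' Plot a spectrogram
#'
#' @param object A [compute_spectrogram()] result.
#' @param db_floor Clip the colour scale this many dB below the maximum.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectrogram <- function(object, db_floor = 60, ...) {
  d <- expand.grid(time_s = object$times, freq_hz = object$freqs)
  d$db <- as.vector(t(10 * log10(pmax(object$psd, 1e-30))))
  top <- max(d$db)
  d$db <- pmax(d$db, top - db_floor)
  ggplot(d, aes(.data$time_s, .data$freq_hz, fill = .data$db)) +
    geom_raster() +
    scale_fill_viridis_c(name = "PSD (dB)") +
    labs(x = "time (s)", y = "frequency (Hz)") +
    theme_minimal()
}

#' Day-of-year by hour-of-day presence map
#'
#' Tile map of summed presence counts, the seasonal/diel presence figure.
#' When site coordinates are supplied, dawn and dusk hour bands for a
#' reference year are overlaid to show the shifting light regimes.
#'
#' @param m A [presence_matrix()] result.
#' @param lat,lon Optional site coordinates for the twilight overlay.
#' @param year Reference year for the overlay ephemeris.
#' @return A ggplot.
#' @export
plot_presence_matrix <- function(m, lat = NULL, lon = NULL, year = 2018) {
  long <- attr(m, "long")
  if (is.null(long)) {
    long <- as_tibble(as.data.frame(as.table(m), stringsAsFactors = FALSE))
    names(long) <- c("day_of_year", "hour_of_day", "n")
    long <- mutate(long, across(c("day_of_year", "hour_of_day"), as.integer))
  }
  p <- ggplot(filter(long, .data$n > 0),
              aes(.data$day_of_year, .data$hour_of_day, fill = .data$n)) +
    geom_tile() +
    scale_fill_viridis_c(name = "presence\n(years)") +
    coord_cartesian(xlim = c(1, 366), ylim = c(0, 23)) +
    labs(x = "day of year", y = "hour of day (UTC)") +
    theme_minimal()
  if (!is.null(lat) && !is.null(lon)) {
    days <- seq.Date(as.Date(sprintf("%d-01-01", year)),
                     as.Date(sprintf("%d-12-31", year)), by = "7 days")
    hours <- as.POSIXct(rep(days, each = 24), tz = "UTC") +
      3600 * rep(0:23, length(days))
    reg <- classify_series(hours, lat, lon)
    reg <- mutate(reg,
                  day_of_year = as.integer(format(.data$utc_hour, "%j",
                                                  tz = "UTC")),
                  hour_of_day = as.integer(format(.data$utc_hour, "%H",
                                                  tz = "UTC")))
    twil <- filter(reg, .data$regime %in% c("dawn", "dusk"))
    p <- p + geom_point(data = twil,
                        aes(.data$day_of_year, .data$hour_of_day,
                            shape = .data$regime),
                        inherit.aes = FALSE, size = 0.5, colour = "grey40")
  }
  p
}

#' Regime proportion bar plot with letters
#'
#' Mean (+/- s.e.) proportion of presence hours per detection day in each
#' light regime; regimes sharing a letter are statistically similar.
#'
#' @param summary A [regime_proportions()] result.
#' @param letters Optional [letter_display()] result.
#' @return A ggplot.
#' @export
plot_regime_proportions <- function(summary, letters = NULL) {
  d <- mutate(summary,
              regime = factor(.data$regime,
                              levels = c("dawn", "day", "dusk", "night")))
  p <- ggplot(d, aes(.data$regime, .data$mean_proportion)) +
    geom_col(fill = "grey65") +
    geom_errorbar(aes(ymin = .data$mean_proportion - .data$se,
                      ymax = .data$mean_proportion + .data$se),
                  width = 0.2) +
    labs(x = NULL, y = "mean proportion of presence hours per detection day") +
    theme_minimal()
  if (!is.null(letters)) {
    d2 <- left_join(d, letters, by = "regime")
    p <- p + geom_text(data = d2,
                       aes(y = .data$mean_proportion + .data$se + 0.03,
                           label = .data$letters))
  }
  p
}

#' Hourly noise levels by light regime
#'
#' Pirate-plot-style display: smoothed density (violin), raw hourly points
#' and the regime mean bar.
#'
#' @param hourly Hourly records with `regime` and `noise_p20_db`.
#' @return A ggplot.
#' @export
plot_regime_noise <- function(hourly) {
  d <- filter(hourly, !is.na(.data$noise_p20_db)) %>%
    mutate(regime = factor(as.character(.data$regime),
                           levels = c("dawn", "day", "dusk", "night")))
  ggplot(d, aes(.data$regime, .data$noise_p20_db)) +
    geom_violin(fill = "grey85", colour = NA) +
    geom_jitter(width = 0.15, alpha = 0.25, size = 0.4) +
    stat_summary(fun = mean, geom = "crossbar", width = 0.5,
                 linewidth = 0.3, colour = "firebrick") +
    labs(x = NULL, y = "20th-percentile band level (dB)") +
    theme_minimal()
}

#' Residual autocorrelation plot
#'
#' @param acf Tibble from [acf_values()] (or `gee_diagnostics()$acf`).
#' @param n Series length for the approximate white-noise band
#'   (`+/- 1.96 / sqrt(n)`); omitted if `NULL`.
#' @return A ggplot.
#' @export
plot_acf <- function(acf, n = NULL) {
  p <- ggplot(acf, aes(.data$lag, .data$acf)) +
    geom_segment(aes(xend = .data$lag, yend = 0)) +
    geom_hline(yintercept = 0) +
    labs(x = "lag (hours)", y = "autocorrelation") +
    theme_minimal()
  if (!is.null(n)) {
    p <- p + geom_hline(yintercept = c(-1, 1) * 1.96 / sqrt(n),
                        linetype = "dashed", colour = "steelblue")
  }
  p
}
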