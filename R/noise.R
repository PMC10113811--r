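#' Ambient-noise metric configuration
#'
#' The hourly noise metric is the 20th percentile of band levels computed in
#' successive non-overlapping 4 s windows, with power spectral density
#' integrated over 12-40 Hz. The low percentile deliberately excludes
#' windows containing nearby, high-level fin whale pulses so the metric
#' tracks ambient noise even during repetitive calling.
#'
#' @param window_s Analysis window length, seconds (non-overlapping).
#' @param band_low,band_high Integration band, Hz.
#' @param percentile Hourly summary percentile (0-100).
#' @param db_offset Constant added to all levels, dB (e.g. a hydrophone
#'   calibration offset to absolute re 1 uPa^2; default 0 keeps levels
#'   relative to digital full scale).
#' @return A `noise_config` list.
#' @export
noise_config <- function(window_s = 4, band_low = 12, band_high = 40,
                         percentile = 20, db_offset = 0) {
  if (!(band_low > 0 && band_low < band_high)) {
    abort("need 0 < band_low < band_high")
  }
  if (percentile <= 0 || percentile >= 100) {
    abort("percentile must be in (0, 100)")
  }
  structure(list(window_s = window_s, band_low = band_low,
                 band_high = band_high, percentile = percentile,
                 db_offset = db_offset),
            class = "noise_config")
}

#' Band levels in non-overlapping windows
#'
#' Splits the segment into successive non-overlapping windows, computes each
#' window's power spectral density (Hann taper, power-normalized), and
#' integrates the PSD over the band — bins whose centres lie in
#' `[band_low, band_high]` — to give one band level per window in dB. A
#' trailing partial window is discarded.
#'
#' @param audio An [audio_segment()] at least one window long.
#' @param cfg A [noise_config()]; the band must lie below Nyquist.
#' @return Tibble: `window_start_s`, `band_level_db`.
#' @export
band_levels <- function(audio, cfg = noise_config()) {
  fs <- audio$fs
  if (cfg$band_high > fs / 2) {
    abort(sprintf("band_high (%g Hz) above Nyquist (%g Hz)",
                  cfg$band_high, fs / 2))
  }
  nwin <- as.integer(round(cfg$window_s * fs))
  x <- audio$samples
  if (length(x) < nwin) abort("audio shorter than one analysis window")
  n_full <- length(x) %/% nwin
  w <- taper_window("hann", nwin)
  frames <- matrix(x[seq_len(n_full * nwin)], nrow = nwin) * w
  X <- stats::mvfft(frames)
  nf <- nwin %/% 2L + 1L
  psd <- Mod(X[seq_len(nf), , drop = FALSE])^2 / (fs * sum(w^2))
  psd[2:(nf - 1L), ] <- 2 * psd[2:(nf - 1L), ]
  freqs <- seq(0, nf - 1L) * fs / nwin
  df <- fs / nwin
  in_band <- freqs >= cfg$band_low & freqs <= cfg$band_high
  power <- colSums(psd[in_band, , drop = FALSE]) * df
  tibble(window_start_s = (seq_len(n_full) - 1L) * cfg$window_s,
         band_level_db = 10 * log10(power) + cfg$db_offset)
}

#' Hourly percentile of band levels
#'
#' Linear-interpolation percentile (the classic type-7 definition) of each
#' hour's band levels. Hours are assigned by the half-open convention
#' `[h, h + 1h)` relative to the segment start (or, if `utc_start` is
#' given, by absolute UTC hour).
#'
#' @param levels Tibble from [band_levels()].
#' @param cfg A [noise_config()].
#' @param utc_start Optional `POSIXct` UTC time of `window_start_s = 0`.
#' @return Tibble: `hour_index` (and `utc_hour` when `utc_start` given),
#'   `n_windows`, `p_db` (the hourly percentile level).
#' @export
hourly_percentile <- function(levels, cfg = noise_config(), utc_start = NULL) {
  if (!nrow(levels)) abort("no band levels supplied")
  out <- levels %>%
    mutate(hour_index = floor(.data$window_start_s / 3600)) %>%
    group_by(.data$hour_index) %>%
    summarise(n_windows = dplyr::n(),
              p_db = as.numeric(quantile(.data$band_level_db,
                                         cfg$percentile / 100, type = 7)),
              .groups = "drop")
  if (!is.null(utc_start)) {
    utc_start <- as.POSIXct(utc_start, tz = "UTC")
    out <- mutate(out, utc_hour = utc_start + 3600 * .data$hour_index,
                  .after = "hour_index")
  }
  out
}

#' Per-regime summaries of hourly noise levels
#'
#' @param hourly Tibble of hourly records with columns `regime` and
#'   `noise_p20_db`.
#' @return Tibble per regime: `n_hours`, `mean_db`, `sd_db`, `se_db`.
#'   Regimes present in the factor levels but absent from the data are
#'   omitted with a warning.
#' @export
regime_noise_summary <- function(hourly) {
  stopifnot(all(c("regime", "noise_p20_db") %in% names(hourly)))
  dat <- filter(hourly, !is.na(.data$noise_p20_db))
  lv <- if (is.factor(dat$regime)) levels(dat$regime) else
    c("dawn", "day", "dusk", "night")
  missing_lv <- setdiff(lv, unique(as.character(dat$regime)))
  if (length(missing_lv)) {
    warn(paste0("no hours in regime(s): ", paste(missing_lv, collapse = ", "),
                "; omitted from the summary"))
  }
  dat %>%
    group_by(regime = as.character(.data$regime)) %>%
    summarise(n_hours = dplyr::n(),
              mean_db = mean(.data$noise_p20_db),
              sd_db = sd(.data$noise_p20_db),
              se_db = sd(.data$noise_p20_db) / sqrt(dplyr::n()),
              .groups = "drop") %>%
    arrange(match(.data$regime, c("dawn", "day", "dusk", "night")))
}
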