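#' Specification of a stereotyped 20 Hz pulse train
#'
#' Defaults describe the fin whale 20 Hz pulse: a ~1 s downsweep from 42 to
#' 18 Hz repeated at stereotyped inter-pulse intervals (IPIs) of 7-26 s. The
#' optional backbeat is the lower-frequency companion pulse (23 to 13 Hz).
#'
#' @param f_start,f_end Sweep start/end frequency, Hz (`f_start > f_end > 0`).
#' @param pulse_duration Pulse length in seconds.
#' @param ipi_min,ipi_max Inter-pulse interval bounds in seconds.
#' @param ipi_mode `"uniform"` (IPIs drawn uniformly in `[ipi_min, ipi_max]`)
#'   or `"fixed"` (constant IPI, the midpoint of the bounds).
#' @param snr_db Pulse level above the ambient level in the call band, dB.
#' @param backbeat_enabled Add a backbeat after each pulse?
#' @param backbeat_f_start,backbeat_f_end Backbeat sweep frequencies, Hz.
#' @return A `pulse_spec` list.
#' @export
pulse_spec <- function(f_start = 42, f_end = 18, pulse_duration = 1.0,
                       ipi_min = 7, ipi_max = 26,
                       ipi_mode = c("uniform", "fixed"), snr_db = 12,
                       backbeat_enabled = FALSE,
                       backbeat_f_start = 23, backbeat_f_end = 13) {
  ipi_mode <- arg_match(ipi_mode)
  if (!(f_start > f_end && f_end > 0)) {
    abort("pulse_spec requires f_start > f_end > 0")
  }
  if (!(ipi_min > 0 && ipi_min <= ipi_max)) {
    abort("pulse_spec requires 0 < ipi_min <= ipi_max")
  }
  if (pulse_duration <= 0) abort("pulse_duration must be > 0")
  structure(list(f_start = f_start, f_end = f_end,
                 pulse_duration = pulse_duration,
                 ipi_min = ipi_min, ipi_max = ipi_max, ipi_mode = ipi_mode,
                 snr_db = snr_db, backbeat_enabled = backbeat_enabled,
                 backbeat_f_start = backbeat_f_start,
                 backbeat_f_end = backbeat_f_end),
            class = "pulse_spec")
}

#' Specification of coloured ambient noise
#'
#' Gaussian noise shaped by a power-law spectrum, with an optional 24 h
#' sinusoidal level modulation emulating day/night ambient-noise differences.
#' `base_level_db` is the band level (dB, relative full-scale units)
#' integrated over the 12-40 Hz analysis band.
#'
#' @param base_level_db Target 12-40 Hz band level, relative dB.
#' @param spectral_slope_db_per_octave Spectral slope (negative = red noise).
#' @param diel_amplitude_db Peak-to-trough of the 24 h level modulation, dB;
#'   0 disables.
#' @param diel_phase_hours UTC hour of the modulation peak.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(base_level_db = -45, spectral_slope_db_per_octave = -5,
                       diel_amplitude_db = 0, diel_phase_hours = 14) {
  if (diel_amplitude_db < 0) abort("diel_amplitude_db must be >= 0")
  structure(list(base_level_db = base_level_db,
                 spectral_slope_db_per_octave = spectral_slope_db_per_octave,
                 diel_amplitude_db = diel_amplitude_db,
                 diel_phase_hours = diel_phase_hours),
            class = "noise_spec")
}

#' Specification of broadband transient confusers
#'
#' Short flat-spectrum bursts spanning the full analysis band, used to
#' exercise the detector's broadband-noise rejection.
#'
#' @param rate_per_hour Expected transient count per hour (Poisson).
#' @param duration Burst duration, seconds.
#' @param bandwidth Two-element Hz interval the burst spans (flat spectrum).
#' @param level_db Burst level above ambient in the call band, dB.
#' @return A `transient_spec` list.
#' @export
transient_spec <- function(rate_per_hour = 0, duration = 0.5,
                           bandwidth = c(10, 120), level_db = 15) {
  if (rate_per_hour < 0) abort("rate_per_hour must be >= 0")
  structure(list(rate_per_hour = rate_per_hour, duration = duration,
                 bandwidth = bandwidth, level_db = level_db),
            class = "transient_spec")
}

#' Specification of an hourly presence/absence series
#'
#' Data-generating process assumed by the GEE analysis: binary hourly presence
#' whose marginal probability depends on light regime, with serial dependence
#' induced by a latent Gaussian AR1 process (Gaussian copula). The marginal
#' probability of presence in an hour of regime `r` is exactly
#' `plogis(intercept_logit + regime_logit_effects[r])`.
#'
#' @param intercept_logit Intercept on the logit scale.
#' @param regime_logit_effects Named numeric vector with entries for all of
#'   `dawn`, `day`, `dusk`, `night` (logit offsets).
#' @param ar1_rho Latent AR1 coefficient, `|ar1_rho| < 1`.
#' @param n_days Number of 24 h days to generate.
#' @param seed Integer seed; the series is deterministic given the seed.
#' @return A `presence_spec` list.
#' @export
presence_spec <- function(intercept_logit = 0,
                          regime_logit_effects = c(dawn = 0, day = 0,
                                                   dusk = 0, night = 0),
                          ar1_rho = 0, n_days = 30, seed = 1) {
  if (abs(ar1_rho) >= 1) abort("|ar1_rho| must be < 1")
  missing_lv <- setdiff(c("dawn", "day", "dusk", "night"),
                        names(regime_logit_effects))
  if (length(missing_lv)) {
    abort(paste0("regime_logit_effects is missing regime(s): ",
                 paste(missing_lv, collapse = ", ")))
  }
  structure(list(intercept_logit = intercept_logit,
                 regime_logit_effects = regime_logit_effects,
                 ar1_rho = ar1_rho, n_days = n_days, seed = seed),
            class = "presence_spec")
}

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
        rm(".Random.seed", envir = .GlobalEnv)
      }
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(code)
}

# Tukey (tapered cosine) window; `taper` is the total tapered fraction
tukey_window <- function(n, taper = 0.25) {
  if (n == 1L) return(1)
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  a <- taper
  lo <- x < a / 2
  hi <- x > 1 - a / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / a - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - x[hi]) / a - 1)))
  w
}

#' Synthesize one downswept pulse
#'
#' Linear frequency downsweep from `f_start` to `f_end` over
#' `pulse_duration`, shaped by a Tukey window (25% taper) to limit spectral
#' splatter.
#'
#' @param spec A [pulse_spec()].
#' @param fs Sampling frequency, Hz; must exceed `2 * f_start`.
#' @param amplitude Peak amplitude scale.
#' @return Numeric waveform of `round(pulse_duration * fs)` samples.
#' @export
generate_pulse <- function(spec, fs, amplitude = 1) {
  stopifnot(inherits(spec, "pulse_spec"))
  if (fs <= 2 * spec$f_start) {
    abort(sprintf("fs = %g Hz too low: need fs > 2 * f_start = %g Hz",
                  fs, 2 * spec$f_start))
  }
  n <- round(spec$pulse_duration * fs)
  t <- (seq_len(n) - 1) / fs
  k <- (spec$f_end - spec$f_start) / spec$pulse_duration  # sweep rate, Hz/s
  phase <- 2 * pi * (spec$f_start * t + 0.5 * k * t^2)
  amplitude * tukey_window(n, 0.25) * sin(phase)
}

#' Draw pulse onset times for one pulse train
#'
#' Inter-pulse intervals are constant (`ipi_mode = "fixed"`, midpoint of the
#' bounds, first onset at 0) or uniform in `[ipi_min, ipi_max]`
#' (`"uniform"`, first onset uniform in `[0, ipi_max)`). Onsets strictly
#' before `duration` are returned.
#'
#' @param spec A [pulse_spec()].
#' @param duration Train duration, seconds.
#' @param seed Integer seed.
#' @return Sorted numeric vector of onset times in seconds.
#' @export
generate_pulse_train <- function(spec, duration, seed = 1) {
  stopifnot(inherits(spec, "pulse_spec"), duration > 0)
  if (spec$ipi_mode == "fixed") {
    ipi <- (spec$ipi_min + spec$ipi_max) / 2
    times <- seq(0, duration, by = ipi)
    return(times[times < duration - 1e-9])
  }
  with_seed(seed, {
    onsets <- runif(1, 0, spec$ipi_max)
    if (onsets >= duration) return(numeric(0))
    # upper bound on pulses, then trim
    n_max <- ceiling(duration / spec$ipi_min) + 1L
    gaps <- runif(n_max, spec$ipi_min, spec$ipi_max)
    times <- onsets + c(0, cumsum(gaps))
    times[times < duration]
  })
}

# gain of the power-law synthesis spectrum at frequency f (amplitude scale),
# referenced to 20 Hz; flattened below 1 Hz to avoid a DC singularity
power_law_gain <- function(f, slope_db_per_octave, f_ref = 20) {
  f <- pmax(f, 1)
  10^(slope_db_per_octave * log2(f / f_ref) / 20)
}

# band power implied by shaping unit-variance white noise with
# power_law_gain then scaling amplitudes by `scale`
implied_band_power <- function(scale, slope, fs, band) {
  f <- seq(band[1], band[2], length.out = 2049)
  psd <- (2 / fs) * power_law_gain(f, slope)^2 * scale^2
  sum((psd[-1] + psd[-length(psd)]) / 2) * diff(f[1:2])
}

# scale so the implied 12-40 Hz band level equals base_level_db
noise_scale_for <- function(noise, fs, band = c(12, 40)) {
  unit <- implied_band_power(1, noise$spectral_slope_db_per_octave, fs, band)
  sqrt(10^(noise$base_level_db / 10) / unit)
}

# diel gain (amplitude scale) at decimal UTC hours-of-day h
diel_gain <- function(noise, h) {
  if (noise$diel_amplitude_db == 0) return(rep(1, length(h)))
  db <- (noise$diel_amplitude_db / 2) *
    cos(2 * pi * (h - noise$diel_phase_hours) / 24)
  10^(db / 20)
}

# coloured Gaussian noise via FFT shaping; unit-variance white input
synth_coloured_noise <- function(n, fs, slope_db_per_octave) {
  w <- rnorm(n)
  spec <- fft(w)
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
  g <- power_law_gain(abs(f), slope_db_per_octave)
  Re(fft(spec * g, inverse = TRUE)) / n
}

#' Render a synthetic acoustic scene with ground truth
#'
#' Builds one segment of coloured ambient noise, inserts pulse trains at the
#' signal-to-noise ratios their specs request (SNR defined in the call band
#' `[f_end, f_start]` of each train), and adds broadband transients. All
#' insertions are recorded in a ground-truth table.
#'
#' @param trains A [pulse_spec()] or list of them; `NULL` or empty for none.
#' @param noise A [noise_spec()].
#' @param transients A [transient_spec()] or `NULL`.
#' @param start_time UTC start instant (`POSIXct` or string).
#' @param duration Segment length, seconds (3600 for the one-hour files the
#'   pipeline mirrors).
#' @param fs Sampling frequency, Hz (default 250, the detection rate; use
#'   12000 to mirror a full-rate recorder).
#' @param seed Integer seed; the scene is bit-reproducible given the seed.
#' @param site Site identifier stored in the segment.
#' @return A list with elements `audio` (an [audio_segment()]) and `truth`
#'   (tibble: `kind` in `pulse`/`backbeat`/`transient`, `time_s`, `snr_db`)
#'   plus `ambient_band_db`, the ambient-only 12-40 Hz band level (dB) at
#'   mid-segment.
#' @export
render_scene <- function(trains = pulse_spec(), noise = noise_spec(),
                         transients = NULL,
                         start_time = "2014-03-01 00:00:00",
                         duration = 3600, fs = 250, seed = 1, site = "SYN") {
  stopifnot(duration > 0, fs > 0)
  if (inherits(trains, "pulse_spec")) trains <- list(trains)
  if (is.null(trains)) trains <- list()
  start_time <- as.POSIXct(start_time, tz = "UTC")
  n <- round(duration * fs)

  with_seed(seed, {
    scale <- noise_scale_for(noise, fs)
    x <- scale * synth_coloured_noise(n, fs, noise$spectral_slope_db_per_octave)

    # slowly varying diel gain, per-sample
    h0 <- as.numeric(format(start_time, "%H", tz = "UTC")) +
      as.numeric(format(start_time, "%M", tz = "UTC")) / 60
    h <- (h0 + (seq_len(n) - 1) / fs / 3600) %% 24
    g <- diel_gain(noise, h)
    x <- x * g

    band_power_at <- function(t0, band) {
      gi <- diel_gain(noise, (h0 + t0 / 3600) %% 24)
      implied_band_power(scale * gi, noise$spectral_slope_db_per_octave, fs, band)
    }

    truth <- list()
    train_seeds <- sample.int(.Machine$integer.max, max(1L, length(trains)))
    for (i in seq_along(trains)) {
      tr <- trains[[i]]
      onsets <- generate_pulse_train(tr, duration, seed = train_seeds[i])
      np <- round(tr$pulse_duration * fs)
      for (t0 in onsets) {
        i0 <- round(t0 * fs) + 1L
        if (i0 > n) next
        idx <- i0:min(i0 + np - 1L, n)
        p_amb <- band_power_at(t0, c(tr$f_end, tr$f_start))
        target_ms <- p_amb * 10^(tr$snr_db / 10)
        w <- tukey_window(np, 0.25)
        amp <- sqrt(2 * target_ms / mean(w^2))
        pulse <- generate_pulse(tr, fs, amplitude = amp)
        x[idx] <- x[idx] + pulse[seq_along(idx)]
        if (tr$backbeat_enabled) {
          bb <- pulse_spec(f_start = tr$backbeat_f_start,
                           f_end = tr$backbeat_f_end,
                           pulse_duration = tr$pulse_duration,
                           snr_db = tr$snr_db)
          tb <- t0 + 2.5
          j0 <- round(tb * fs) + 1L
          if (j0 + np - 1L <= n) {
            p_amb_bb <- band_power_at(tb, c(bb$f_end, bb$f_start))
            amp_bb <- sqrt(2 * p_amb_bb * 10^(tr$snr_db / 10) / mean(w^2))
            x[j0:(j0 + np - 1L)] <- x[j0:(j0 + np - 1L)] +
              generate_pulse(bb, fs, amplitude = amp_bb)
            truth[[length(truth) + 1L]] <-
              tibble(kind = "backbeat", time_s = tb, snr_db = tr$snr_db)
          }
        }
        truth[[length(truth) + 1L]] <-
          tibble(kind = "pulse", time_s = t0, snr_db = tr$snr_db)
      }
    }

    if (!is.null(transients) && transients$rate_per_hour > 0) {
      n_tr <- stats::rpois(1, transients$rate_per_hour * duration / 3600)
      if (n_tr > 0) {
        tt <- sort(runif(n_tr, 0, duration - transients$duration))
        nt <- round(transients$duration * fs)
        wt <- tukey_window(nt, 0.25)
        for (t0 in tt) {
          p_amb <- band_power_at(t0, c(12, 40))
          # flat-spectrum burst: fraction of its power inside 12-40 Hz
          bw <- c(max(transients$bandwidth[1], 0),
                  min(transients$bandwidth[2], fs / 2))
          frac <- (40 - 12) / diff(bw)
          target_ms <- p_amb * 10^(transients$level_db / 10) / frac
          burst <- rnorm(nt)
          # confine to the stated bandwidth with an FFT brick-wall
          bs <- fft(burst)
          fb <- c(seq(0, floor(nt / 2)), seq(-ceiling(nt / 2) + 1, -1)) * fs / nt
          bs[abs(fb) < bw[1] | abs(fb) > bw[2]] <- 0
          burst <- Re(fft(bs, inverse = TRUE)) / nt
          burst <- wt * burst / sqrt(mean(burst^2)) * sqrt(target_ms)
          i0 <- round(t0 * fs) + 1L
          idx <- i0:min(i0 + nt - 1L, n)
          x[idx] <- x[idx] + burst[seq_along(idx)]
          truth[[length(truth) + 1L]] <-
            tibble(kind = "transient", time_s = t0, snr_db = transients$level_db)
        }
      }
    }

    truth <- if (length(truth)) arrange(list_rbind(truth), .data$time_s) else
      tibble(kind = character(), time_s = numeric(), snr_db = numeric())

    mid_db <- 10 * log10(band_power_at(duration / 2, c(12, 40)))
    if (max(abs(x)) > 1) {
      abort(sprintf(
        "rendered scene clips full scale (max |amplitude| = %.2f); lower levels",
        max(abs(x))))
    }
    list(audio = audio_segment(x, fs, start_time = start_time, site = site),
         truth = truth, ambient_band_db = mid_db)
  })
}

#' Generate an hourly presence/absence series with AR1 serial dependence
#'
#' Latent standard-Gaussian AR1 series thresholded at the logistic-implied
#' quantile for each hour's regime, so marginal presence probabilities are
#' exact while serial dependence is tuned by `ar1_rho`.
#'
#' @param spec A [presence_spec()].
#' @param regimes Character vector of regime labels, either one per hour
#'   (`n_days * 24`) or a 24-hour daily template recycled across days.
#' @param start_date First UTC date of the series.
#' @param site Site identifier.
#' @return A tibble of hourly records: `site`, `utc_hour`, `date`,
#'   `day_of_year`, `hour_of_day`, `regime`, `presence`.
#' @export
generate_presence_series <- function(spec, regimes = rep(c("night", "dawn",
                                       "day", "dusk"), c(8, 2, 12, 2)),
                                     start_date = as.Date("2014-03-01"),
                                     site = "SYN") {
  stopifnot(inherits(spec, "presence_spec"))
  n <- spec$n_days * 24L
  if (length(regimes) == 24L) regimes <- rep(regimes, spec$n_days)
  if (length(regimes) != n) {
    abort(sprintf("regimes must have length 24 or n_days*24 = %d, got %d",
                  n, length(regimes)))
  }
  bad <- setdiff(unique(regimes), names(spec$regime_logit_effects))
  if (length(bad)) {
    abort(paste0("no logit effect configured for regime(s): ",
                 paste(bad, collapse = ", ")))
  }
  p <- plogis(spec$intercept_logit + spec$regime_logit_effects[regimes])
  z <- with_seed(spec$seed, {
    e <- rnorm(n)
    if (spec$ar1_rho == 0) e else {
      z <- numeric(n)
      z[1] <- e[1]
      s <- sqrt(1 - spec$ar1_rho^2)
      for (t in 2:n) z[t] <- spec$ar1_rho * z[t - 1] + s * e[t]
      z
    }
  })
  utc_hour <- as.POSIXct(start_date, tz = "UTC") + 3600 * (seq_len(n) - 1)
  tibble(
    site = site,
    utc_hour = utc_hour,
    date = as.Date(utc_hour, tz = "UTC"),
    day_of_year = as.integer(format(utc_hour, "%j", tz = "UTC")),
    hour_of_day = as.integer(format(utc_hour, "%H", tz = "UTC")),
    regime = unname(regimes),
    presence = as.integer(z <= qnorm(p))
  )
}
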