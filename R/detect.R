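#' Detector configuration
#'
#' Thresholds for the two-stage 20 Hz pulse detector: spectrogram
#' cross-correlation with broadband rejection, then time-domain envelope
#' verification. All values are tunable; the defaults are this package's own
#' working settings.
#'
#' @param xcorr_threshold Minimum normalized cross-correlation score.
#' @param min_separation_s Minimum separation between accepted candidates,
#'   seconds (default 7, the minimum stereotyped inter-pulse interval).
#' @param call_band Two-element Hz interval of the 20 Hz pulse (sweep band).
#' @param guard_band Two-element Hz interval outside the call band used by
#'   the broadband-rejection stage; must not overlap `call_band`.
#' @param broadband_ratio_max Reject candidates whose guard-band / call-band
#'   mean PSD ratio exceeds this.
#' @param envelope_band Hz interval for the envelope-verification band-pass.
#' @param envelope_snr_min_db Minimum envelope SNR, dB.
#' @param envelope_duration_bounds_s Allowed above-half-peak envelope width,
#'   seconds.
#' @return A `detector_config` list.
#' @export
detector_config <- function(xcorr_threshold = 0.3, min_separation_s = 7,
                            call_band = c(18, 42), guard_band = c(50, 100),
                            broadband_ratio_max = 0.5,
                            envelope_band = c(15, 45),
                            envelope_snr_min_db = 8,
                            envelope_duration_bounds_s = c(0.5, 2)) {
  if (min_separation_s <= 0) abort("min_separation_s must be > 0")
  if (guard_band[1] < call_band[2] && guard_band[2] > call_band[1]) {
    abort("guard_band must be disjoint from call_band")
  }
  structure(list(xcorr_threshold = xcorr_threshold,
                 min_separation_s = min_separation_s,
                 call_band = call_band, guard_band = guard_band,
                 broadband_ratio_max = broadband_ratio_max,
                 envelope_band = envelope_band,
                 envelope_snr_min_db = envelope_snr_min_db,
                 envelope_duration_bounds_s = envelope_duration_bounds_s),
            class = "detector_config")
}

#' Build the spectrogram-domain template of the canonical 20 Hz pulse
#'
#' The kernel is the PSD spectrogram of a clean synthetic downsweep
#' (42 to 18 Hz over 1 s by default), restricted to the call band, made
#' zero-mean and unit-energy so that correlation scores are comparable
#' across noise levels and bounded in \[-1, 1\].
#'
#' @param spec A [pulse_spec()] describing the sweep.
#' @param params A [spectrogram_params()] (default 250 Hz, 256-point Hann,
#'   75% overlap: ~1 Hz bins and a 0.256 s hop so that template/onset
#'   misalignment costs little correlation); its frequency resolution must
#'   resolve the sweep band.
#' @return A `pulse_template` list: `kernel` (freq x time, zero-mean,
#'   unit-norm), `band` (Hz), `freqs`, `n_cols`.
#' @export
build_template <- function(spec = pulse_spec(), params = spectrogram_params()) {
  df <- params$fs / params$nfft
  if (df >= (spec$f_start - spec$f_end)) {
    abort(sprintf(
      "frequency resolution %.2f Hz too coarse to trace a %g-%g Hz sweep",
      df, spec$f_start, spec$f_end))
  }
  pulse <- generate_pulse(spec, params$fs)
  padded <- c(pulse, numeric(params$nfft))
  sg <- compute_spectrogram(padded, params)
  band <- c(spec$f_end - 2 * df, spec$f_start + 2 * df)
  rows <- which(sg$freqs >= band[1] & sg$freqs <= band[2])
  cols <- which(sg$times <= spec$pulse_duration)
  k <- sg$psd[rows, cols, drop = FALSE]
  k <- k - mean(k)
  nrm <- sqrt(sum(k^2))
  if (nrm == 0) abort("degenerate template (all-zero kernel)")
  structure(list(kernel = k / nrm, band = band, freqs = sg$freqs[rows],
                 n_cols = length(cols), spec = spec, params = params),
            class = "pulse_template")
}

empty_events <- function() {
  tibble(time = numeric(), xcorr_score = numeric(),
         broadband_ratio = numeric(), envelope_snr_db = numeric(),
         envelope_duration_s = numeric(), accepted = logical(),
         reject_reason = character())
}

#' Spectrogram cross-correlation candidate detection
#'
#' Slides the zero-mean unit-energy template along the spectrogram's time
#' axis, computing the normalized 2-D correlation with each same-shaped
#' patch of the call band. Local maxima above `xcorr_threshold` are thinned
#' greedily by descending score (ties broken by earlier time) so that
#' retained candidates are at least `min_separation_s` apart.
#'
#' @param sgram A [compute_spectrogram()] result covering the call band.
#' @param template A [build_template()] result on the same frequency grid.
#' @param config A [detector_config()].
#' @return Tibble of candidate events: `time` (onset, segment-relative
#'   seconds), `xcorr_score`, with the remaining stage columns `NA`/`"none"`.
#' @export
xcorr_detect <- function(sgram, template, config = detector_config()) {
  rows <- match(round(template$freqs, 6), round(sgram$freqs, 6))
  if (anyNA(rows)) {
    abort("spectrogram frequency grid does not cover the template band")
  }
  P <- sgram$psd[rows, , drop = FALSE]
  K <- template$kernel
  L <- ncol(K)
  n_shift <- ncol(P) - L + 1L
  if (n_shift < 1L) return(empty_events())
  num <- numeric(n_shift); ss <- numeric(n_shift); s1 <- numeric(n_shift)
  for (j in seq_len(L)) {
    cols <- j:(j + n_shift - 1L)
    num <- num + colSums(K[, j] * P[, cols, drop = FALSE])
    ss <- ss + colSums(P[, cols, drop = FALSE]^2)
    s1 <- s1 + colSums(P[, cols, drop = FALSE])
  }
  m <- nrow(K) * L
  den <- sqrt(pmax(ss - s1^2 / m, 0))
  score <- ifelse(den > 0, num / den, 0)
  score <- pmin(pmax(score, -1), 1)

  # strict-on-the-right local maxima above threshold
  s_prev <- c(-Inf, score[-n_shift])
  s_next <- c(score[-1], -Inf)
  idx <- which(score >= s_prev & score > s_next & score >= config$xcorr_threshold)
  if (!length(idx)) return(empty_events())
  t_cand <- sgram$times[idx]
  ord <- order(-score[idx], t_cand)
  keep <- logical(length(idx))
  kept_times <- numeric(0)
  for (i in ord) {
    if (!length(kept_times) ||
        all(abs(t_cand[i] - kept_times) >= config$min_separation_s)) {
      keep[i] <- TRUE
      kept_times <- c(kept_times, t_cand[i])
    }
  }
  out <- tibble(time = t_cand[keep], xcorr_score = score[idx][keep],
                broadband_ratio = NA_real_, envelope_snr_db = NA_real_,
                envelope_duration_s = NA_real_, accepted = NA,
                reject_reason = "none")
  arrange(out, .data$time)
}

#' Broadband-noise rejection
#'
#' For each candidate, compares mean PSD in a guard band (outside the call
#' band) against mean PSD in the call band at the frame of peak call-band
#' power within 1.5 s of the candidate time — the frame that drove the
#' candidate. Broadband transients excite both bands roughly equally
#' (ratio near 1) while a true 20 Hz pulse leaves the guard band quiet;
#' candidates with ratio above `broadband_ratio_max` are flagged. Zero
#' call-band power yields an infinite ratio and a rejection.
#'
#' @param sgram The spectrogram the candidates came from.
#' @param events Candidate tibble from [xcorr_detect()].
#' @param config A [detector_config()]; `guard_band` must lie within the
#'   spectrogram's frequency range.
#' @return `events` with `broadband_ratio` filled and `reject_reason` set to
#'   `"broadband"` where the ratio test fails.
#' @export
broadband_reject <- function(sgram, events, config = detector_config()) {
  if (config$guard_band[1] > max(sgram$freqs)) {
    abort("guard_band lies above the spectrogram frequency range")
  }
  if (!nrow(events)) return(events)
  g_rows <- which(sgram$freqs >= config$guard_band[1] &
                    sgram$freqs <= config$guard_band[2])
  c_rows <- which(sgram$freqs >= config$call_band[1] &
                    sgram$freqs <= config$call_band[2])
  ratio <- map_dbl(events$time, function(t0) {
    cols <- which(sgram$times >= t0 - 1.5 & sgram$times <= t0 + 1.5)
    if (!length(cols)) cols <- which.min(abs(sgram$times - t0))
    # evaluate at the frame of peak call-band power: the frame that drove
    # the candidate, so short transients are not diluted by quiet frames
    cb <- colMeans(sgram$psd[c_rows, cols, drop = FALSE])
    j <- cols[which.max(cb)]
    cp <- mean(sgram$psd[c_rows, j])
    gp <- mean(sgram$psd[g_rows, j])
    if (cp <= 0) Inf else gp / cp
  })
  events$broadband_ratio <- ratio
  flag <- ratio > config$broadband_ratio_max
  events$reject_reason[flag & events$reject_reason == "none"] <- "broadband"
  events
}

# analytic-signal magnitude envelope via FFT
signal_envelope <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

#' Time-domain envelope verification
#'
#' Band-passes the audio to `envelope_band`, computes the analytic-signal
#' magnitude envelope, and for each surviving candidate measures (i) the
#' envelope SNR — peak within 1 s of the candidate onset over the median
#' envelope of the surrounding 30 s, excluding 2 s around every candidate —
#' and (ii) the above-half-peak envelope width. Candidates failing the SNR
#' or duration bounds are flagged `envelope_snr` / `envelope_duration`.
#'
#' @param audio The [audio_segment()] the candidates came from.
#' @param events Candidate tibble (after [broadband_reject()]).
#' @param config A [detector_config()]; `envelope_band` must lie below the
#'   Nyquist frequency.
#' @return `events` with envelope columns filled and `accepted` set.
#' @export
envelope_verify <- function(audio, events, config = detector_config()) {
  if (config$envelope_band[2] >= audio$fs / 2) {
    abort("envelope_band must lie below the Nyquist frequency")
  }
  if (!nrow(events)) {
    events$accepted <- logical(0)
    return(events)
  }
  fs <- audio$fs
  bf <- signal::butter(4, config$envelope_band / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, audio$samples)
  env <- signal_envelope(xf)
  # smooth over ~0.1 s so noise ripple does not fragment the half-peak width
  k <- max(1L, as.integer(round(0.1 * fs)))
  if (k > 1L) {
    sm <- stats::filter(env, rep(1 / k, k), sides = 2)
    env <- ifelse(is.na(sm), env, as.numeric(sm))
  }
  n <- length(env)
  dur <- n / fs
  if (dur < 30) {
    warn("segment shorter than the 30 s background window; using whole segment")
  }
  t_all <- events$time
  excl <- rep(FALSE, n)
  for (tc in t_all) {
    i <- max(1L, floor((tc - 2) * fs)):min(n, ceiling((tc + 3) * fs))
    excl[i] <- TRUE
  }
  for (k in seq_len(nrow(events))) {
    if (events$reject_reason[k] != "none") next
    t0 <- events$time[k]
    pk_idx <- max(1L, floor((t0 - 1) * fs)):min(n, ceiling((t0 + 2) * fs))
    pk <- max(env[pk_idx])
    bg_idx <- max(1L, floor((t0 - 15) * fs)):min(n, ceiling((t0 + 15) * fs))
    bg_idx <- bg_idx[!excl[bg_idx]]
    if (!length(bg_idx)) bg_idx <- seq_len(n)[!excl]
    if (!length(bg_idx)) bg_idx <- seq_len(n)
    bg <- median(env[bg_idx])
    snr <- if (bg > 0) 20 * log10(pk / bg) else Inf
    # above-half-peak width around the peak, inside a local window
    w_idx <- max(1L, floor((t0 - 2) * fs)):min(n, ceiling((t0 + 3) * fs))
    loc <- env[w_idx]
    pk_at <- which.max(loc)
    above <- loc >= pk / 2
    lo <- pk_at
    while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
    hi <- pk_at
    while (hi < length(above) && above[hi + 1L]) hi <- hi + 1L
    width <- (hi - lo + 1L) / fs
    events$envelope_snr_db[k] <- snr
    events$envelope_duration_s[k] <- width
    if (snr < config$envelope_snr_min_db) {
      events$reject_reason[k] <- "envelope_snr"
    } else if (width < config$envelope_duration_bounds_s[1] ||
               width > config$envelope_duration_bounds_s[2]) {
      events$reject_reason[k] <- "envelope_duration"
    }
  }
  events$accepted <- events$reject_reason == "none"
  events
}

#' Decimate audio to a target sampling rate
#'
#' Anti-aliased FIR decimation (cascaded stages for large factors). The
#' target rate must divide the source rate.
#'
#' @param audio An [audio_segment()].
#' @param fs_target Target sampling rate, Hz.
#' @return An [audio_segment()] at `fs_target`.
#' @export
decimate_audio <- function(audio, fs_target = 250) {
  if (audio$fs == fs_target) return(audio)
  q <- audio$fs / fs_target
  if (q != round(q)) {
    abort(sprintf("fs %g is not an integer multiple of target %g",
                  audio$fs, fs_target))
  }
  x <- audio$samples
  q <- as.integer(q)
  while (q > 1L) {
    qi <- if (q %% 8L == 0L) 8L else if (q %% 6L == 0L) 6L else
      if (q %% 5L == 0L) 5L else if (q %% 4L == 0L) 4L else
        if (q %% 3L == 0L) 3L else 2L
    x <- signal::decimate(x, qi, ftype = "fir")
    q <- q %/% qi
  }
  audio_segment(x, fs_target, start_time = audio$start_time, site = audio$site)
}

#' Detect fin whale 20 Hz pulses in one audio segment
#'
#' Full detection chain: (optional) anti-aliased decimation to the detection
#' rate, PSD spectrogram, spectrogram cross-correlation against the
#' canonical downsweep template, broadband-noise rejection, and time-domain
#' envelope verification. All candidates are returned — accepted and
#' rejected, with reasons — for auditability.
#'
#' @param audio An [audio_segment()].
#' @param config A [detector_config()].
#' @param params A [spectrogram_params()] for the detection spectrogram
#'   (default: 250 Hz, 256-point Hann, 50% overlap).
#' @param template_spec A [pulse_spec()] for the template sweep.
#' @return Tibble of detection events; columns `time` (seconds into the
#'   segment), `utc_time` (if the segment is timestamped), `xcorr_score`,
#'   `broadband_ratio`, `envelope_snr_db`, `envelope_duration_s`,
#'   `accepted`, `reject_reason`.
#' @export
detect_pulses <- function(audio, config = detector_config(),
                          params = spectrogram_params(),
                          template_spec = pulse_spec()) {
  if (audio$fs > params$fs) audio <- decimate_audio(audio, params$fs)
  sgram <- compute_spectrogram(audio, params)
  template <- build_template(template_spec, params)
  ev <- xcorr_detect(sgram, template, config)
  ev <- broadband_reject(sgram, ev, config)
  ev <- envelope_verify(audio, ev, config)
  if (!is.null(audio$start_time)) {
    ev <- mutate(ev, utc_time = audio$start_time + .data$time,
                 .after = "time")
  }
  if (!is.null(audio$site)) ev <- mutate(ev, site = audio$site, .before = 1)
  ev
}
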