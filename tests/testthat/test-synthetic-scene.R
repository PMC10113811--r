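test_that("the synthetic pulse is a 1 s downsweep through 30 Hz at midpoint", {
  p <- generate_pulse(pulse_spec(), fs = 250)
  expect_length(p, 250)
  expect_identical(generate_pulse(pulse_spec(), 250, amplitude = 0),
                   rep(0, 250))
  # instantaneous frequency via FFT peak of short slices (independent of
  # the synthesis phase formula): linear 42->18 Hz sweep passes 30 Hz at 0.5 s
  slice_peak <- function(centre_s, width_s = 0.3) {
    idx <- round((centre_s - width_s / 2) * 250):round((centre_s + width_s / 2) * 250)
    z <- p[idx] * taper_window_hann(length(idx))
    sp <- Mod(fft(c(z, numeric(4096 - length(z)))))[1:2048]
    (which.max(sp) - 1) * 250 / 4096
  }
  taper_window_hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)
  expect_lt(abs(slice_peak(0.5) - 30), 2)
  expect_gt(slice_peak(0.2), slice_peak(0.8))  # frequency decreases
  expect_error(generate_pulse(pulse_spec(), fs = 60), "too low")
})

test_that("fixed-interval trains are arithmetic and short scenes degenerate", {
  sp <- pulse_spec(ipi_mode = "fixed", ipi_min = 10, ipi_max = 10)
  expect_equal(generate_pulse_train(sp, 60), c(0, 10, 20, 30, 40, 50))
  # duration shorter than one interval: fixed mode keeps the onset at 0
  expect_equal(generate_pulse_train(sp, 0.5), 0)
})

test_that("uniform inter-pulse intervals always fall in [ipi_min, ipi_max]", {
  for (seed in 1:20) {
    sp <- pulse_spec(ipi_min = 7, ipi_max = 26)
    tt <- generate_pulse_train(sp, 1800, seed = seed)
    expect_true(all(diff(tt) >= 7 - 1e-9))
    expect_true(all(diff(tt) <= 26 + 1e-9))
    expect_false(is.unsorted(tt))
  }
})

test_that("scene rendering books every insertion and is bit-reproducible", {
  quiet <- render_scene(trains = list(), transients = NULL,
                        duration = 120, seed = 5)
  expect_identical(nrow(quiet$truth), 0L)

  sp <- pulse_spec(ipi_mode = "fixed", ipi_min = 360, ipi_max = 360)
  sc <- render_scene(sp, duration = 3600, seed = 6)
  expect_identical(sum(sc$truth$kind == "pulse"), 10L)

  sc2 <- render_scene(sp, duration = 3600, seed = 6)
  expect_identical(sc$audio$samples, sc2$audio$samples)
  expect_identical(sc$truth, sc2$truth)
})

test_that("rendered ambient noise hits the configured band level within 1 dB", {
  for (seed in c(2, 3)) {
    sc <- render_scene(trains = list(), noise = noise_spec(base_level_db = -45),
                       duration = 600, fs = 250, seed = seed)
    lv <- band_levels(sc$audio)
    expect_lt(abs(median(lv$band_level_db) - (-45)), 1)
  }
})

test_that("realized pulse SNR is within 1 dB of the requested snr_db", {
  for (snr in c(6, 12, 18)) {
    sp <- pulse_spec(ipi_mode = "fixed", ipi_min = 60, ipi_max = 60,
                     snr_db = snr)
    with_p <- render_scene(sp, duration = 180, seed = 9)
    without <- render_scene(list(), duration = 180, seed = 9)
    t0 <- with_p$truth$time_s[2]
    got <- measure_pulse_snr(with_p, without, t0)
    expect_lt(abs(got - snr), 1)
  }
})

test_that("presence marginals are calibrated and degenerate cases behave", {
  # flat case: rate ~ 0.5 over 10k+ hours, binomial 3-sigma bound
  flat <- generate_presence_series(
    presence_spec(intercept_logit = 0, ar1_rho = 0, n_days = 417, seed = 3))
  expect_lt(abs(mean(flat$presence) - 0.5), 3 * sqrt(0.25 / nrow(flat)))

  none <- generate_presence_series(
    presence_spec(intercept_logit = -30, n_days = 5, seed = 3))
  expect_identical(sum(none$presence), 0L)

  expect_error(generate_presence_series(
    presence_spec(regime_logit_effects = c(dawn = 0, day = 0, dusk = 0,
                                           night = 0), n_days = 1, seed = 1),
    regimes = rep("twilightish", 24)), "twilightish")
})

test_that("per-regime presence rates match the logistic marginals under AR1", {
  eff <- c(dawn = 0.8, day = 0, dusk = -0.5, night = 1.2)
  tab <- generate_presence_series(
    presence_spec(intercept_logit = -0.4, regime_logit_effects = eff,
                  ar1_rho = 0.6, n_days = 1700, seed = 12),
    regimes = rep(c("dawn", "day", "dusk", "night"), 6))
  by_regime <- tapply(tab$presence, tab$regime, mean)
  n_regime <- tapply(tab$presence, tab$regime, length)
  for (r in names(eff)) {
    p <- plogis(-0.4 + eff[[r]])
    # serial dependence inflates the sampling error; allow a design factor
    se <- sqrt(p * (1 - p) / n_regime[[r]]) * sqrt((1 + 0.6) / (1 - 0.6))
    expect_lt(abs(by_regime[[r]] - p), 3 * se)
  }
})

test_that("latent AR1 correlation carries into the binary series", {
  lag1 <- function(rho) {
    tab <- generate_presence_series(
      presence_spec(intercept_logit = 0, ar1_rho = rho, n_days = 200,
                    seed = 21))
    y <- tab$presence
    cor(y[-length(y)], y[-1])
  }
  expect_gt(lag1(0.8), lag1(0) + 0.2)
})
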