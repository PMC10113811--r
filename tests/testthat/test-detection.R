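test_that("the template is zero-mean, unit-energy and self-matching", {
  tpl <- build_template(pulse_spec(), spectrogram_params())
  expect_lt(abs(mean(tpl$kernel) * length(tpl$kernel)), 1e-9)
  expect_equal(sum(tpl$kernel^2), 1, tolerance = 1e-12)

  # correlating against a spectrogram of its own source pulse peaks at onset
  pulse <- generate_pulse(pulse_spec(), 250)
  x <- numeric(250 * 30)
  onset <- 10
  x[(onset * 250 + 1):(onset * 250 + 250)] <- pulse
  sg <- compute_spectrogram(x, spectrogram_params())
  ev <- xcorr_detect(sg, tpl, detector_config())
  hop <- diff(sg$times[1:2])
  expect_lte(abs(ev$time[which.max(ev$xcorr_score)] - onset), hop + 1e-9)
  expect_gt(max(ev$xcorr_score), 0.95)

  expect_error(build_template(pulse_spec(),
                              spectrogram_params(fs = 250, nfft = 8)),
               "too coarse")
})

test_that("correlation scores are bounded and an empty spectrogram yields none", {
  sg0 <- compute_spectrogram(numeric(5000), spectrogram_params())
  tpl <- build_template()
  ev0 <- xcorr_detect(sg0, tpl)
  expect_identical(nrow(ev0), 0L)

  sc <- render_scene(pulse_spec(ipi_mode = "fixed", ipi_min = 30,
                                ipi_max = 30), duration = 600, seed = 4)
  sg <- compute_spectrogram(sc$audio)
  ev <- xcorr_detect(sg, tpl)
  expect_true(all(ev$xcorr_score >= -1 & ev$xcorr_score <= 1))
})

test_that("clean pulse trains are recovered at their true onsets", {
  sp <- pulse_spec(ipi_mode = "fixed", ipi_min = 15, ipi_max = 15,
                   snr_db = 25)
  sc <- render_scene(sp, duration = 600, seed = 8)
  ev <- detect_pulses(sc$audio)
  truth <- sc$truth$time_s[sc$truth$kind == "pulse"]
  acc <- ev$time[ev$accepted]
  hop <- 256 * 0.25 / 250
  matched <- vapply(truth, function(t) any(abs(acc - t) <= hop + 1e-9),
                    logical(1))
  expect_true(all(matched))
  expect_identical(length(acc), length(truth))
})

test_that("peak thinning keeps the higher-scoring of two close candidates", {
  sp <- pulse_spec(ipi_mode = "fixed", ipi_min = 3, ipi_max = 3, snr_db = 20)
  sc <- render_scene(sp, duration = 7, seed = 10)   # onsets at 0 and 3 s
  sg <- compute_spectrogram(sc$audio)
  ev <- xcorr_detect(sg, build_template(), detector_config())
  expect_identical(nrow(ev), 1L)
})

test_that("broadband rejection separates pulses from flat transients", {
  sp <- pulse_spec(ipi_mode = "fixed", ipi_min = 60, ipi_max = 60,
                   snr_db = 15)
  sc <- render_scene(sp, duration = 300, seed = 11)
  sg <- compute_spectrogram(sc$audio)
  ev <- broadband_reject(sg, xcorr_detect(sg, build_template()),
                         detector_config())
  truth <- sc$truth$time_s[sc$truth$kind == "pulse"]
  on_pulse <- vapply(ev$time, function(t) any(abs(truth - t) <= 1),
                     logical(1))
  expect_true(all(ev$broadband_ratio[on_pulse] < 0.5))
  expect_true(all(ev$reject_reason[on_pulse] == "none"))

  sct <- render_scene(list(), transients = transient_spec(rate_per_hour = 240),
                      duration = 300, seed = 12)
  sgt <- compute_spectrogram(sct$audio)
  evt <- broadband_reject(sgt, xcorr_detect(sgt, build_template()),
                          detector_config())
  tt <- sct$truth$time_s
  trig <- vapply(evt$time, function(t) any(abs(tt - t) <= 1.5), logical(1))
  expect_gt(mean(evt$reject_reason[trig] == "broadband"), 0.8)

  # zero call-band power: infinite ratio, rejected by convention
  sg0 <- compute_spectrogram(numeric(30 * 250), spectrogram_params())
  fake <- tibble::tibble(time = 5, xcorr_score = 0.5,
                         broadband_ratio = NA_real_,
                         envelope_snr_db = NA_real_,
                         envelope_duration_s = NA_real_, accepted = NA,
                         reject_reason = "none")
  out <- broadband_reject(sg0, fake, detector_config())
  expect_identical(out$broadband_ratio, Inf)
  expect_identical(out$reject_reason, "broadband")
})

test_that("envelope verification enforces SNR and duration rules", {
  sp <- pulse_spec(ipi_mode = "fixed", ipi_min = 60, ipi_max = 60,
                   snr_db = 15)
  sc <- render_scene(sp, duration = 300, seed = 13)
  ev <- detect_pulses(sc$audio)
  truth <- sc$truth$time_s[sc$truth$kind == "pulse"]
  on_pulse <- vapply(ev$time, function(t) any(abs(truth - t) <= 1),
                     logical(1))
  expect_true(all(ev$accepted[on_pulse]))
  expect_true(all(ev$envelope_snr_db[on_pulse] > 8))

  # a candidate placed on pure noise fails the SNR rule
  noise_only <- render_scene(list(), duration = 300, seed = 14)
  fake <- tibble::tibble(time = 150, xcorr_score = 0.5,
                         broadband_ratio = 0.1,
                         envelope_snr_db = NA_real_,
                         envelope_duration_s = NA_real_, accepted = NA,
                         reject_reason = "none")
  out <- envelope_verify(noise_only$audio, fake, detector_config())
  expect_identical(out$reject_reason, "envelope_snr")

  # a long tone fails the duration rule
  tone_scene <- render_scene(list(), duration = 300, seed = 15)
  fs <- tone_scene$audio$fs
  amp <- 10 * stats::sd(tone_scene$audio$samples)
  x <- tone_scene$audio$samples
  x[(100 * fs):(110 * fs)] <- x[(100 * fs):(110 * fs)] +
    amp * sin(2 * pi * 25 * seq(0, 10, by = 1 / fs))
  seg <- audio_segment(x / max(abs(x)), fs)
  fake2 <- tibble::tibble(time = 102, xcorr_score = 0.5,
                          broadband_ratio = 0.1,
                          envelope_snr_db = NA_real_,
                          envelope_duration_s = NA_real_, accepted = NA,
                          reject_reason = "none")
  out2 <- envelope_verify(seg, fake2, detector_config())
  expect_identical(out2$reject_reason, "envelope_duration")
})

test_that("stages compose consistently and detection is deterministic", {
  sc <- render_scene(pulse_spec(snr_db = 10),
                     transients = transient_spec(rate_per_hour = 120),
                     duration = 600, seed = 16)
  ev1 <- detect_pulses(sc$audio)
  ev2 <- detect_pulses(sc$audio)
  expect_identical(ev1, ev2)
  expect_identical(sum(ev1$accepted),
                   nrow(ev1) - sum(ev1$reject_reason != "none"))
  expect_true(all(!ev1$accepted[ev1$reject_reason != "none"]))
  expect_true(all(diff(sort(ev1$time[ev1$accepted])) >= 7 - 1e-9))
})

test_that("recall is non-decreasing in pulse SNR", {
  recall_at <- function(snr) {
    hits <- 0; total <- 0
    for (seed in 31:33) {
      sp <- pulse_spec(ipi_mode = "fixed", ipi_min = 20, ipi_max = 20,
                       snr_db = snr)
      sc <- render_scene(sp, duration = 300, seed = seed)
      ev <- detect_pulses(sc$audio)
      truth <- sc$truth$time_s[sc$truth$kind == "pulse"]
      acc <- ev$time[ev$accepted]
      hits <- hits + sum(vapply(truth, function(t) any(abs(acc - t) <= 1.1),
                                logical(1)))
      total <- total + length(truth)
    }
    hits / total
  }
  r <- vapply(c(2, 8, 14), recall_at, numeric(1))
  expect_true(all(diff(r) >= 0))
  expect_gt(r[3], 0.9)
})
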