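# shared fixtures, all generated in code at test time

# presence table with known logit effects and serial dependence
make_presence_table <- function(n_days = 150,
                                effects = c(dawn = 0.8, day = 0,
                                            dusk = -0.3, night = 1.0),
                                intercept = -0.5, rho = 0.6, seed = 101,
                                regimes = rep(c("night", "dawn", "day",
                                                "dusk"), c(8, 2, 12, 2))) {
  generate_presence_series(
    presence_spec(intercept_logit = intercept, regime_logit_effects = effects,
                  ar1_rho = rho, n_days = n_days, seed = seed),
    regimes = regimes)
}

# add an uncorrelated noise covariate for model fixtures
with_noise_col <- function(tab, seed = 7) {
  set.seed(seed)
  tab$noise_p20_db <- rnorm(nrow(tab), -45, 2)
  tab
}

# measured in-band SNR of a rendered pulse: the inserted pulse is exactly
# the difference of the two scenes (same seed), so its power needs no
# filtering; the ambient in-band power comes from PSD integration over the
# call band across the whole ambient-only scene
measure_pulse_snr <- function(scene_with, scene_without, t0, band = c(18, 42),
                              dur = 1) {
  fs <- scene_with$audio$fs
  idx <- (round(t0 * fs) + 1):round((t0 + dur) * fs)
  d <- scene_with$audio$samples - scene_without$audio$samples
  ps <- mean(d[idx]^2)
  amb <- band_levels(scene_without$audio,
                     noise_config(band_low = band[1], band_high = band[2]))
  pn <- mean(10^(amb$band_level_db / 10))
  10 * log10(ps / pn)
}

# write a tiny stereo 16-bit WAV (invalid for this pipeline) for IO tests
write_stereo_wav <- function(path, fs = 250, n = 100) {
  pcm <- as.integer(rep(0, 2 * n))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 4 * n), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # stereo
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 4), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(4 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  path
}

# write a 24-bit mono WAV with given integer samples (-2^23 .. 2^23 - 1)
write_wav24 <- function(path, samples_int, fs = 250) {
  n <- length(samples_int)
  v <- ifelse(samples_int < 0, samples_int + 16777216, samples_int)
  b <- rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 3 * n), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 3), con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")
  writeBin(24L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(3 * n), con, size = 4, endian = "little")
  writeBin(as.raw(b), con)
  path
}

# p-value table for a given 6-bit significance pattern over four regimes
# (bit i set => pair i significant); pair order follows utils::combn
pattern_contrasts <- function(bits) {
  pairs <- utils::combn(c("dawn", "day", "dusk", "night"), 2)
  sig <- as.logical(bitwAnd(bits, 2^(0:5)))
  tibble::tibble(regime_i = pairs[1, ], regime_j = pairs[2, ],
                 estimate = 0, std.error = 1, statistic = 0,
                 p.value = ifelse(sig, 0.001, 0.5))
}
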