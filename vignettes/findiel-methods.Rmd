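---
title: "Methods: from hydrophone audio to diel statistics of fin whale 20 Hz presence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from hydrophone audio to diel statistics of fin whale 20 Hz presence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Fin whales (*Balaenoptera physalus*) produce a highly stereotyped call, the
"20 Hz pulse": a roughly one-second downsweep from about 42 Hz to 18 Hz,
repeated at inter-pulse intervals of 7–26 s, sometimes accompanied by a
lower "backbeat" (23 to 13 Hz). Long-term moored hydrophones record these
calls continuously, and a basic ecological question is whether calling
follows a diel (24 h) rhythm: do the animals vocalize more at night, at
dawn, during the day? Answering it requires a chain of processing steps —
detect pulses in audio, reduce detections to hourly presence/absence,
classify every hour into a light regime from the sun's altitude, control
for ambient noise (quiet nights make calls easier to detect), and test the
regime effect with a model that respects the strong serial dependence of
hourly presence.

`findiel` implements that chain end to end, together with a synthetic
acoustic-scene generator so that every stage can be verified against known
ground truth without access to field recordings.

## Pipeline stages and their assumptions

### Synthetic scenes (`render_scene`, `generate_presence_series`)

The generator emulates the statistical structure the analysis assumes, not
ocean physics:

* **Pulses** are linear frequency downsweeps (42 to 18 Hz over 1 s by
  default) under a Tukey window with 25% total taper. The paper trail for
  real pulses gives the band, duration and interval statistics but not the
  within-pulse envelope; linear sweep + Tukey taper is the simplest model
  consistent with those facts and keeps spectral splatter low.
* **Trains** draw inter-pulse intervals either fixed (midpoint of the
  bounds, first onset at 0 — convenient for exact bookkeeping in tests) or
  uniformly in [7, 26] s with the first onset uniform in [0, ipi_max).
  Onsets strictly before the segment end are kept, so a segment shorter
  than one interval carries a single onset in fixed mode.
* **Ambient noise** is Gaussian noise shaped in the frequency domain by a
  power-law spectrum (default −5 dB/octave, a reddish low-frequency ocean
  ambient), scaled so the 12–40 Hz band level equals `base_level_db`
  (default −45 dB relative to digital full scale), with an optional 24 h
  sinusoidal level modulation (`diel_amplitude_db` peak-to-trough, peak at
  `diel_phase_hours`) emulating day/night ambient differences.
* **Pulse SNR** is defined in the call band: the inserted pulse's
  mean-square amplitude equals the ambient call-band power times
  `10^(snr_db/10)`. A test verifies the realized SNR within 1 dB by
  differencing scenes rendered with and without the pulse at the same seed.
* **Broadband transients** are flat-spectrum bursts (default 10–120 Hz,
  0.5 s) that exist purely to exercise the detector's broadband rejection.
* **Hourly presence** uses a Gaussian copula: a latent standard-normal AR1
  series (coefficient `ar1_rho`) thresholded at the logistic-implied
  quantile for each hour's regime. This yields *exact* marginal presence
  probabilities `plogis(intercept + effect[regime])` with tunable serial
  dependence — precisely the marginal-model structure the GEE assumes.

What the generator does **not** emulate: propagation loss, multipath,
recorder self-noise, ice and shipping soundscapes, call-source-level
distributions, or 40 Hz calls. Passing tests therefore demonstrate that the
algorithms are correct on data satisfying their assumptions, not that the
detector would achieve the same recall on Antarctic recordings.

### Detection (`detect_pulses`)

Four stages, each auditable in the returned event table:

1. **PSD spectrogram** at the detection rate of 250 Hz (audio at higher
   rates is decimated with cascaded anti-aliased FIR stages): 256-point
   Hann windows, 75% overlap — about 1 Hz resolution and a 0.256 s hop.
   A coarser 0.512 s hop (50% overlap) was tried first; template/onset
   misalignment then puts a long lower tail on the correlation scores of
   true pulses (recall 0.92 at 12 dB SNR in the calibration scenes versus
   1.0 at 75% overlap), so the finer hop is the default. The display
   convention used for figures of real recordings (2048-point Hann at
   1200 Hz, 0.59 Hz resolution) is available through the same
   `spectrogram_params()` but is deliberately distinct from the detection
   parameters.
2. **Spectrogram cross-correlation**: a zero-mean, unit-energy kernel built
   from the PSD spectrogram of a clean synthetic downsweep is slid along
   time; the normalized 2-D correlation is bounded in [−1, 1] and
   comparable across noise levels. Local maxima above `xcorr_threshold`
   (default 0.3) are thinned greedily by descending score — ties broken by
   earlier time — so accepted candidates are at least `min_separation_s`
   apart (default 7 s, the minimum stereotyped IPI).
3. **Broadband rejection**: the guard-band (50–100 Hz) to call-band
   (18–42 Hz) mean-PSD ratio, evaluated at the frame of peak call-band
   power within 1.5 s of the candidate. Using the peak frame rather than a
   window average matters: a 0.5 s click diluted over a 1 s window can
   slip under the threshold, and correlation side-lobes sit up to ~1.5 s
   from the burst. Ratios above `broadband_ratio_max` (default 0.5) are
   flagged; zero call-band power counts as an infinite ratio and rejects.
4. **Envelope verification**: band-pass to 15–45 Hz, analytic-signal
   magnitude envelope smoothed by a 0.1 s moving average (raw envelopes
   ripple enough to fragment the half-peak width), then two rules: the
   peak within 1 s of the candidate must exceed the median background of
   the surrounding 30 s (candidates excised) by `envelope_snr_min_db`
   (default 8 dB), and the above-half-peak width must lie in
   `envelope_duration_bounds_s` (default [0.5, 2] s — long tones fail
   here).

All thresholds are this package's own tunable defaults: the original
detector the field literature defers to is not reproduced here, only the
functional stages it describes.

### Light regimes (`classify_series`)

Solar altitude comes from the standard NOAA/Meeus low-precision ephemeris
(geometric altitude, no refraction), implemented directly and vectorized;
at the poles it reproduces the negated solar declination and at an equinox
the equatorial noon sun to within a few hundredths of a degree. Each UTC
day is scanned at 1-minute steps. Dawn spans the hours of and between
nautical twilight start (first upward crossing of −12°) and sunrise; day
the hours after sunrise but before sunset; dusk from sunset to nautical
twilight end; night the rest — and the entire hour containing a sun
condition change is promoted to the twilight class. Operationally each
hour is labelled from its 61 minute-level altitudes: a minute in (−12°, 0°)
with the sun rising makes the hour dawn-eligible, falling makes it
dusk-eligible, with precedence dawn > dusk > day > night. The precedence
resolves degenerate polar cases deterministically: polar day is all day,
polar night all night, and a day spent entirely inside the twilight band
splits into dawn before and dusk after the altitude maximum, the hour
containing the maximum going to dawn. All clock arithmetic is UTC — recorder
timestamps are absolute, and regimes are functions of UTC instants.

### Ambient noise metric (`band_levels`, `hourly_percentile`)

Successive non-overlapping 4 s windows; each is Hann-tapered (with the
matching power normalization — the choice of taper is a convention, pinned
so results are bit-reproducible), Fourier transformed to a power spectral
density, and integrated over bins whose centres lie in 12–40 Hz. The hourly
summary is the 20th percentile of the 900 window levels, computed by linear
interpolation between order statistics (the classic type-7 definition;
levels 1..100 dB give 20.8 dB). The low percentile deliberately ignores the
upper tail, so an hour in which loud pulses occupy even half the windows
moves the metric by under 0.5 dB. Levels are referenced to digital full
scale; a calibration offset to absolute units can be added via
`noise_config(db_offset=)` but absolute calibration is out of scope.

### Aggregation (`hourly_presence`, `detection_days`, `regime_proportions`)

Presence is binary per hour — at least one accepted detection in the
half-open UTC hour — never a call count. Analysis conditions on *detection
days*: UTC calendar dates with presence in at least one hour. The
regime-proportion summary divides, for each detection day, the presence
hours of a regime by the hours of that regime occurring that day. The
alternative reading — each regime's share of the day's presence hours — is
available behind `denominator = "presence_hours"`; the per-regime-hours
default normalizes for the very unequal regime durations at high latitude
(an Antarctic March night may last 2 h), which makes regimes comparable.

### The GEE (`fit_gee`)

A binomial (logit) marginal model: light regime as a four-level factor
(reference `dawn` by default, configurable) and optionally the hourly
noise level entered per regime (noise × regime interaction with noise
mean-centred within site, so regime effects are evaluated at average
noise). Clusters are detection days with observations ordered by hour —
the conditioning unit is the only grouping the design defines — and the
working correlation is AR1 on the hour index, `corr = alpha^|h_s - h_t|`,
so gaps from missing hours decay the correlation accordingly. `alpha` is
re-estimated each iteration from the lag-1 moment of Pearson residuals
over adjacent-hour pairs; coefficients update by Fisher scoring with
step-halving, to a relative change of 1e-8 or 100 iterations. For
contiguous clusters the AR1 inverse is assembled as one sparse
block-tridiagonal matrix, which keeps hundreds of simulation fits cheap.
Inference always uses the robust sandwich covariance. With the
independence working correlation the estimating equations coincide with
the pooled logistic score equations, and the test suite requires equality
with `stats::glm` coefficients to 1e-6 — an exact cross-implementation
oracle.

Pairwise regime differences are Wald contrasts at average noise, reported
unadjusted at α = 0.05 (a Holm option exists but is off by default,
matching the single-α convention of the field's figures). The compact
letter display assigns letters as the maximal cliques of the
non-significance graph, enumerated exactly over the four regimes, so two
regimes share a letter precisely when their contrast is non-significant;
the suite re-verifies this against all 64 significance patterns.
Diagnostics are the within-cluster pooled Durbin–Watson statistic
(closed forms: 0 for constant residuals, `4(n-1)/n` for alternating ±1,
≈2 for white noise) and the sample autocorrelation function (lag 0
exactly 1).

## Verification scales

The automated checks run at sizes chosen to make their statistical bounds
sharp while staying cheap: detector calibration uses one-hour scenes at
250 Hz with 240 pulses at 12 dB SNR (recall ≥ 0.95), pulse-free hours
(≤ 2 false alarms) and transient-only hours (≥ 90% flagged broadband);
the light-regime partition property sweeps 50 random sites × 20 dates
including the poles; marginal calibration of the presence generator uses
over 10 000 hours per regime; CI coverage of the GEE uses 200 replicates
of 500-day series at ρ = 0.6 (the acceptance script reports a 100 × 300
version of the same quantity); and the null-calibration check uses 200
replicates of 200-day series. On a single CPU the whole suite runs in
about a minute.

One property deserves a note: with six unadjusted pairwise contrasts each
held at size 0.05, the *familywise* null rejection rate is necessarily
around 0.2 (Bonferroni bounds it by 0.30); the suite therefore asserts
per-contrast calibration — each test's size within the binomial 3σ band of
0.05 — rather than an unattainably small familywise constant.

## Known limitations

* The detector is verified on synthetic scenes only; its thresholds carry
  no claim of equivalence to the detector used on the Antarctic recordings,
  whose internals are not public in the sources this package draws on.
* Geometric solar altitude ignores atmospheric refraction (~0.5° at the
  horizon); at 1-min scanning this shifts event times by a couple of
  minutes and never changes which hour an event falls in by more than one.
* Sandwich standard errors are asymptotic in the number of detection days;
  with a few dozen days they are mildly anti-conservative.
* The manual validation passes used on real data, 40 Hz calls, backbeat
  classification and absolute hydrophone calibration are out of scope.
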