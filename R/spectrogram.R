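#' Spectrogram (STFT) parameters
#'
#' @param fs Sampling frequency, Hz.
#' @param nfft Window length in samples (also the FFT length).
#' @param window Taper name; `"hann"` or `"boxcar"`.
#' @param overlap_fraction Fractional overlap between successive windows,
#'   in `[0, 1)`.
#' @return A `spectrogram_params` list. Frequency resolution is `fs / nfft`.
#' @export
spectrogram_params <- function(fs = 250, nfft = 256, window = c("hann", "boxcar"),
                               overlap_fraction = 0.75) {
  window <- arg_match(window)
  if (nfft < 2) abort("nfft must be >= 2")
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    abort("overlap_fraction must be in [0, 1)")
  }
  structure(list(fs = fs, nfft = as.integer(nfft), window = window,
                 overlap_fraction = overlap_fraction),
            class = "spectrogram_params")
}

taper_window <- function(name, n) {
  switch(name,
    hann = 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n),  # periodic Hann
    boxcar = rep(1, n),
    abort(paste0("unknown window: ", name))
  )
}

#' Compute a power spectral density spectrogram
#'
#' Short-time Fourier transform with one-sided PSD scaling: for each frame,
#' `psd = 2 |X|^2 / (fs * sum(w^2))` (factor 2 omitted at DC and Nyquist), so
#' that the integral of the PSD over frequency equals the frame's windowed
#' mean-square amplitude.
#'
#' @param audio An [audio_segment()] (or a bare numeric vector, in which case
#'   `params$fs` is assumed).
#' @param params A [spectrogram_params()].
#' @return A `spectrogram` list: `times` (frame start seconds), `freqs`
#'   (Hz, `fs/nfft` spacing), `psd` (frequency x time matrix, power per Hz).
#' @export
compute_spectrogram <- function(audio, params = spectrogram_params()) {
  x <- if (inherits(audio, "audio_segment")) {
    if (!is.null(audio$fs) && audio$fs != params$fs) {
      abort(sprintf("audio fs (%g) != params fs (%g); decimate first",
                    audio$fs, params$fs))
    }
    audio$samples
  } else as.numeric(audio)
  nfft <- params$nfft
  if (length(x) < nfft) {
    abort(sprintf("audio (%d samples) shorter than one window (%d samples)",
                  length(x), nfft))
  }
  hop <- max(1L, as.integer(round(nfft * (1 - params$overlap_fraction))))
  starts <- seq(1L, length(x) - nfft + 1L, by = hop)
  w <- taper_window(params$window, nfft)
  frames <- vapply(starts, function(s) x[s:(s + nfft - 1L)] * w,
                   numeric(nfft))
  X <- stats::mvfft(frames)
  nf <- nfft %/% 2L + 1L
  p <- Mod(X[seq_len(nf), , drop = FALSE])^2 / (params$fs * sum(w^2))
  p[2:(nf - 1L), ] <- 2 * p[2:(nf - 1L), ]
  structure(list(
    times = (starts - 1L) / params$fs,
    freqs = seq(0, nf - 1L) * params$fs / nfft,
    psd = p,
    params = params
  ), class = "spectrogram")
}

#' @exportS3Method base::print
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d freq bins x %d frames, df = %.3f Hz, hop = %.3f s\n",
              nrow(x$psd), ncol(x$psd), diff(x$freqs[1:2]),
              if (length(x$times) > 1) diff(x$times[1:2]) else NA_real_))
  invisible(x)
}
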