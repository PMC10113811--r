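#' Timestamped mono audio segment
#'
#' Lightweight container for a single-channel waveform: the unit on which
#' detection and noise analysis operate. Samples are stored as doubles on the
#' normalized scale \[-1, 1\] (full scale of the integer PCM encoding).
#'
#' @param samples Numeric vector of samples in \[-1, 1\].
#' @param fs Sampling frequency in Hz.
#' @param start_time Optional `POSIXct` (UTC) instant of the first sample.
#' @param site Optional site identifier.
#' @return An object of class `audio_segment`.
#' @export
audio_segment <- function(samples, fs, start_time = NULL, site = NULL) {
  stopifnot(is.numeric(samples), is.numeric(fs), length(fs) == 1L, fs > 0)
  if (!is.null(start_time)) {
    start_time <- as.POSIXct(start_time, tz = "UTC")
  }
  structure(
    list(samples = as.numeric(samples), fs = fs,
         start_time = start_time, site = site),
    class = "audio_segment"
  )
}

#' @exportS3Method base::print
print.audio_segment <- function(x, ...) {
  cat(sprintf("<audio_segment> %d samples @ %g Hz (%.1f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  if (!is.null(x$start_time)) {
    cat("  start:", format(x$start_time, "%Y-%m-%d %H:%M:%S UTC"), "\n")
  }
  if (!is.null(x$site)) cat("  site: ", x$site, "\n")
  invisible(x)
}

#' Duration of an audio segment in seconds
#' @param audio An [audio_segment()].
#' @return Duration in seconds.
#' @export
audio_duration <- function(audio) length(audio$samples) / audio$fs

#' Read a mono PCM WAV file
#'
#' Reads RIFF/WAVE files with 16- or 24-bit integer PCM encoding, one channel.
#' Samples are rescaled to \[-1, 1\]. The UTC start time and site are parsed
#' from filenames of the form `<site>_<YYYYMMDDTHH>.wav` when present.
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_segment()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort(paste0(path, ": not a RIFF file"))
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort(paste0(path, ": not a WAVE file"))

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, size = 2, endian = "little"),
        channels     = readBin(body[3:4], "integer", 1, size = 2, endian = "little"),
        fs           = readBin(body[5:8], "integer", 1, size = 4, endian = "little"),
        bits         = readBin(body[15:16], "integer", 1, size = 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    abort(paste0(path, ": missing fmt or data chunk"))
  }
  if (fmt$audio_format != 1L) {
    abort(paste0(path, ": only integer PCM (format 1) is supported"))
  }
  if (fmt$channels != 1L) {
    abort(sprintf("%s: channels=%d unsupported (mono required)", path, fmt$channels))
  }
  x <- switch(as.character(fmt$bits),
    "16" = {
      n <- length(data_raw) %/% 2L
      readBin(data_raw, "integer", n, size = 2, signed = TRUE,
              endian = "little") / 32768
    },
    "24" = {
      n <- length(data_raw) %/% 3L
      b <- matrix(as.integer(data_raw[seq_len(3L * n)]), nrow = 3L)
      v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    },
    abort(sprintf("%s: %d-bit PCM unsupported (16/24 only)", path, fmt$bits))
  )
  meta <- parse_wav_name(basename(path))
  audio_segment(x, fmt$fs, start_time = meta$start_time, site = meta$site)
}

#' Write an audio segment as a 16-bit PCM mono WAV file
#'
#' @param audio An [audio_segment()] with samples in \[-1, 1\].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path) {
  stopifnot(inherits(audio, "audio_segment"))
  x <- audio$samples
  if (any(abs(x) > 1)) {
    abort(sprintf(
      "waveform clips the PCM-16 range: max |amplitude| = %.3f > 1; reduce levels",
      max(abs(x))))
  }
  pcm <- as.integer(round(pmax(pmin(x, 1 - 1 / 32768), -1) * 32768))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                  # PCM
  writeBin(1L, con, size = 2, endian = "little")                  # mono
  writeBin(as.integer(audio$fs), con, size = 4, endian = "little")
  writeBin(as.integer(audio$fs * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")                  # block align
  writeBin(16L, con, size = 2, endian = "little")                 # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Canonical hourly WAV filename `<site>_<YYYYMMDDTHH>.wav`
#' @param site Site identifier.
#' @param start_time `POSIXct` UTC hour start.
#' @return File name (no directory).
#' @export
wav_name <- function(site, start_time) {
  sprintf("%s_%s.wav", site, format(as.POSIXct(start_time, tz = "UTC"),
                                    "%Y%m%dT%H", tz = "UTC"))
}

parse_wav_name <- function(name) {
  m <- regmatches(name, regexec("^(.+)_([0-9]{8}T[0-9]{2})\\.wav$", name))[[1]]
  if (length(m) == 3L) {
    list(site = m[2],
         start_time = as.POSIXct(m[3], format = "%Y%m%dT%H", tz = "UTC"))
  } else {
    list(site = NULL, start_time = NULL)
  }
}
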