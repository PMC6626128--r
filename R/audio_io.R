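#' Construct an audio recording
#'
#' Container for a mono waveform. Amplitudes are dimensionless with nominal
#' range \[-1, 1\]; multichannel input is collapsed to mono by channel mean.
#'
#' @param samples numeric vector (or matrix, one column per channel) of
#'   amplitude values.
#' @param sample_rate_hz sampling rate in Hz; soil recordings in this
#'   workflow are expected at 44100.
#' @param source_path provenance string (file of origin), or "".
#' @return An object of class `audio_recording` with elements `samples`,
#'   `sample_rate_hz`, `source_path`.
#' @export
audio_recording <- function(samples, sample_rate_hz, source_path = "") {
  if (is.matrix(samples)) samples <- rowMeans(samples)
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop("audio_recording: samples must be non-empty", call. = FALSE)
  }
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      sample_rate_hz <= 0) {
    stop("audio_recording: sample_rate_hz must be a positive scalar",
         call. = FALSE)
  }
  structure(
    list(samples = samples, sample_rate_hz = as.numeric(sample_rate_hz),
         source_path = as.character(source_path)),
    class = "audio_recording"
  )
}

#' @export
print.audio_recording <- function(x, ...) {
  dur <- length(x$samples) / x$sample_rate_hz
  cat(sprintf("<audio_recording> %d samples @ %g Hz (%.2f s)%s\n",
              length(x$samples), x$sample_rate_hz, dur,
              if (nzchar(x$source_path)) paste0(" from ", x$source_path)
              else ""))
  invisible(x)
}

#' @export
length.audio_recording <- function(x) length(x$samples)

# ---- minimal RIFF/WAVE reader and writer -----------------------------------
# Supports 8/16/24/32-bit integer PCM (format tag 1) and 32/64-bit IEEE float
# (format tag 3), plus WAVE_FORMAT_EXTENSIBLE wrapping either. Unknown chunks
# are skipped. Only what this pipeline needs; not a general audio library.

read_wav_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    stop("not a RIFF file: ", path, call. = FALSE)
  }
  readBin(con, "integer", 1, size = 4, endian = "little")  # overall size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    stop("not a WAVE file: ", path, call. = FALSE)
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || !nzchar(id)) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(sz) == 0L) break
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        tag       = sum(as.integer(body[1:2]) * c(1L, 256L)),
        channels  = sum(as.integer(body[3:4]) * c(1L, 256L)),
        rate      = sum(as.integer(body[5:8]) * c(1, 256, 65536, 16777216)),
        bits      = sum(as.integer(body[15:16]) * c(1L, 256L))
      )
      if (fmt$tag == 65534L && sz >= 26L) {  # WAVE_FORMAT_EXTENSIBLE
        fmt$tag <- sum(as.integer(body[25:26]) * c(1L, 256L))
      }
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz)
    }
    if (sz %% 2L == 1L) readBin(con, "raw", 1L)  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("corrupt WAV (missing fmt or data chunk): ", path, call. = FALSE)
  }
  list(fmt = fmt, data = data_raw)
}

decode_pcm <- function(raw, fmt) {
  bytes <- fmt$bits %/% 8L
  n <- length(raw) %/% bytes
  if (n == 0L) stop("zero-length audio data", call. = FALSE)
  if (fmt$tag == 3L) {
    x <- readBin(raw, "double", n, size = bytes, endian = "little")
  } else if (fmt$tag == 1L) {
    if (fmt$bits == 8L) {
      # 8-bit WAV is unsigned
      x <- (as.integer(readBin(raw, "integer", n, size = 1L,
                               signed = FALSE)) - 128) / 128
    } else if (fmt$bits %in% c(16L, 32L)) {
      x <- readBin(raw, "integer", n, size = bytes, signed = TRUE,
                   endian = "little") / 2^(fmt$bits - 1L)
    } else if (fmt$bits == 24L) {
      m <- matrix(as.integer(raw[seq_len(n * 3L)]), nrow = 3L)
      v <- m[1L, ] + 256 * m[2L, ] + 65536 * m[3L, ]
      v <- ifelse(v >= 2^23, v - 2^24, v)
      x <- v / 2^23
    } else {
      stop("unsupported PCM bit depth: ", fmt$bits, call. = FALSE)
    }
  } else {
    stop("unsupported WAV format tag: ", fmt$tag, call. = FALSE)
  }
  if (fmt$channels > 1L) {
    x <- matrix(x, nrow = fmt$channels)
    x <- colMeans(x)
  }
  x
}

#' Read a WAV file into an audio recording
#'
#' Reads RIFF/WAVE PCM (8/16/24/32-bit integer) or IEEE float audio. Integer
#' PCM is scaled to \[-1, 1\]; multichannel audio is averaged to mono.
#' By default the 44.1 kHz rate used for soil monitoring is enforced, because
#' the downstream frame sizes (88.2 and 176.4 samples) are defined in samples
#' at that rate.
#'
#' @param path path to a WAV file.
#' @param expect_rate_hz required sample rate (default 44100). Set
#'   `allow_any_rate = TRUE` to accept other rates; frame sizes are then
#'   derived from the 2 ms / 4 ms frame durations instead.
#' @param allow_any_rate logical; permit sample rates other than
#'   `expect_rate_hz`.
#' @return An [audio_recording].
#' @export
load_wav <- function(path, expect_rate_hz = 44100, allow_any_rate = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  w <- read_wav_raw(path)
  x <- decode_pcm(w$data, w$fmt)
  if (length(x) == 0L) stop("zero-length audio: ", path, call. = FALSE)
  if (!allow_any_rate && w$fmt$rate != expect_rate_hz) {
    stop(sprintf("sample rate %d Hz != expected %d Hz (use allow_any_rate)",
                 w$fmt$rate, expect_rate_hz), call. = FALSE)
  }
  audio_recording(x, w$fmt$rate, source_path = path)
}

#' Write an audio recording as 16-bit PCM WAV
#'
#' Samples are clipped to \[-1, 1\] and quantised to 16-bit integer PCM.
#'
#' @param rec an [audio_recording].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path) {
  stopifnot(inherits(rec, "audio_recording"))
  pcm <- as.integer(pmax(-32768, pmin(32767, round(rec$samples * 32768))))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")    # PCM
  writeBin(1L, con, size = 2, endian = "little")    # mono
  rate <- as.integer(rec$sample_rate_hz)
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(rate * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")    # block align
  writeBin(16L, con, size = 2, endian = "little")   # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

# ---- preprocessing ----------------------------------------------------------

# Zero-phase Butterworth filtering in the frequency domain: the signal's
# spectrum is multiplied by the squared magnitude response |H(w)|^2 of the
# digital (bilinear-transformed) Butterworth cascade - exactly the
# magnitude a forward-backward (filtfilt) application has, with strictly
# zero phase, in O(n log n). The signal is zero-padded so filter ringing
# does not wrap around circularly.
#
# stages: list of list(type = "low"|"high"|"pass", fc = normalised edge(s)
# in (0, 1), Nyquist = 1, order = prototype order).
butter_mag2 <- function(w, stage) {
  t <- tan(w / 2)
  if (stage$type == "pass") {
    tl <- tan(pi * stage$fc[1] / 2)
    th <- tan(pi * stage$fc[2] / 2)
    u <- abs(t^2 - tl * th) / (t * (th - tl))
    u[t == 0 | !is.finite(t)] <- Inf
    1 / (1 + u^(2 * stage$order))
  } else {
    u <- t / tan(pi * stage$fc[1] / 2)
    if (stage$type == "low") {
      1 / (1 + u^(2 * stage$order))
    } else {
      out <- 1 / (1 + u^(-2 * stage$order))
      out[!is.finite(t)] <- 1
      out
    }
  }
}

zero_phase_filter <- function(x, stages) {
  n <- length(x)
  pad <- 8192L
  m <- stats::nextn(n + 2L * pad, c(2, 3, 5))  # even composite length
  xp <- c(rep(0, pad), x, rep(0, m - n - pad))
  half <- m %/% 2L
  w <- 2 * pi * seq.int(0L, half) / m
  h2h <- rep(1, half + 1L)
  for (st in stages) h2h <- h2h * butter_mag2(w, st)
  h2 <- c(h2h, h2h[half:2L])  # |H| is symmetric for a real filter
  y <- Re(stats::fft(stats::fft(xp) * h2, inverse = TRUE)) / m
  y[(pad + 1L):(pad + n)]
}

#' Bandpass filter a recording
#'
#' Zero-phase Butterworth filtering (forward-backward with
#' [signal::filtfilt]), retaining the 200-5000 Hz band where larval
#' stridulations carry their energy. The two edges are deliberately
#' asymmetric: a steep 4th-order high-pass rejects low-frequency soil and
#' sensor rumble hard, while the low-pass is a gentle 2nd-order slope
#' (24 dB/oct after the double pass, comparable to audio-editor defaults).
#' The gentle upper edge matters for the downstream fractal statistics: the
#' residual high-frequency shoulder is what keeps broadband background
#' noise geometrically rougher than tonal stridulation pulses; a steep
#' cutoff equalises the lag-1/2 roughness of all broadband sounds and
#' destroys the contrast the detector relies on (see the vignette).
#'
#' @param rec an [audio_recording].
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < sample_rate/2`.
#' @param hp_order,lp_order Butterworth orders of the high-pass and
#'   low-pass stages (defaults 4 and 2).
#' @return Filtered [audio_recording] of identical length.
#' @export
bandpass <- function(rec, low_hz = 200, high_hz = 5000, hp_order = 4,
                     lp_order = 2) {
  stopifnot(inherits(rec, "audio_recording"))
  nyq <- rec$sample_rate_hz / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop(sprintf("invalid band edges [%g, %g] for Nyquist %g",
                 low_hz, high_hz, nyq), call. = FALSE)
  }
  y <- zero_phase_filter(rec$samples, list(
    list(type = "high", fc = low_hz / nyq, order = hp_order),
    list(type = "low", fc = high_hz / nyq, order = lp_order)))
  audio_recording(y, rec$sample_rate_hz, rec$source_path)
}

#' Remove DC offset
#'
#' Subtracts the mean amplitude so the waveform is centred on the 0.0 line,
#' cancelling any hardware-introduced offset.
#'
#' @param rec an [audio_recording].
#' @return Centred [audio_recording].
#' @export
remove_dc <- function(rec) {
  stopifnot(inherits(rec, "audio_recording"))
  audio_recording(rec$samples - mean(rec$samples), rec$sample_rate_hz,
                  rec$source_path)
}

#' Normalise to a peak amplitude in dBFS
#'
#' Rescales so the maximum absolute sample equals `10^(peak_db/20)`
#' (0.891251 for the default -1.0 dB). Pure gain: the waveform shape is
#' unchanged, so the scale-free fractal statistics downstream are unaffected;
#' normalisation only standardises files for listening and plotting.
#'
#' @param rec an [audio_recording] with at least one nonzero sample.
#' @param peak_db target peak in dB relative to full scale (default -1.0).
#' @return Rescaled [audio_recording].
#' @export
normalize_peak <- function(rec, peak_db = -1.0) {
  stopifnot(inherits(rec, "audio_recording"))
  peak <- max(abs(rec$samples))
  if (peak == 0) {
    stop("normalize_peak: all-zero recording has no finite gain",
         call. = FALSE)
  }
  target <- 10^(peak_db / 20)
  audio_recording(rec$samples * (target / peak), rec$sample_rate_hz,
                  rec$source_path)
}

#' Standard preprocessing chain
#'
#' Applies, in fixed order: bandpass (default 200-5000 Hz), DC removal, peak
#' normalisation to -1.0 dB. Normalisation is deliberately last so the peak
#' postcondition holds exactly; with a 200 Hz high-pass in front, DC removal
#' is close to a no-op and the order of the first two steps is immaterial.
#'
#' @inheritParams bandpass
#' @inheritParams normalize_peak
#' @return Preprocessed [audio_recording]: peak `10^(peak_db/20)`,
#'   mean ~ 0, out-of-band energy strongly attenuated.
#' @export
preprocess <- function(rec, low_hz = 200, high_hz = 5000, peak_db = -1.0,
                       hp_order = 4, lp_order = 2) {
  normalize_peak(remove_dc(bandpass(rec, low_hz, high_hz, hp_order,
                                    lp_order)),
                 peak_db)
}
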