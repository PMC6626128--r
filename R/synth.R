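# Seeded synthetic soil-audio scenes with ground-truth annotations.
# All randomness goes through withr::with_seed on user-supplied seeds, so
# identical arguments give bit-identical audio.

#' Stridulation specification
#'
#' Parameter set for one synthetic stridulation. Two presets reflect the
#' two stridulation types of Melolontha larvae: the common type, a short
#' train of tonal sound bursts peaking near 1700 Hz, and the rarer type,
#' usually 4 (seldom 2 or 3) repeated ~250 ms patterns peaking at 3000 Hz.
#' M. melolontha's common stridulations are longer than M. hippocastani's;
#' the `melolontha` preset doubles the train duration.
#'
#' @param kind `"common"`, `"melolontha"` (long common variant) or `"rare"`.
#' @param carrier_hz spectral peak of the pulses (must lie within the
#'   200-5000 Hz analysis band).
#' @param pulse_ms single pulse duration. Pulses translate into 1-2
#'   frame-wide excursions on the 2 ms detection grid.
#' @param gap_ms inter-pulse gap within a pattern.
#' @param total_ms duration of one pulse-train pattern.
#' @param repeats number of repeated patterns (the rare type typically 4).
#' @param repeat_gap_ms gap between repeated patterns.
#' @return A `stridulation_spec` (named list, includes derived `n_pulses`).
#' @export
stridulation_spec <- function(kind = c("common", "melolontha", "rare"),
                              carrier_hz = NULL, pulse_ms = 4, gap_ms = 12,
                              total_ms = NULL, repeats = NULL,
                              repeat_gap_ms = 80) {
  kind <- match.arg(kind)
  if (is.null(carrier_hz)) {
    carrier_hz <- if (kind == "rare") 3000 else 1700
  }
  if (is.null(total_ms)) {
    total_ms <- switch(kind, common = 150, melolontha = 300, rare = 250)
  }
  if (is.null(repeats)) repeats <- if (kind == "rare") 4L else 1L
  if (carrier_hz < 200 || carrier_hz > 5000) {
    stop("carrier must lie inside the 200-5000 Hz passband", call. = FALSE)
  }
  n_pulses <- max(1L, floor((total_ms + gap_ms) / (pulse_ms + gap_ms)))
  structure(list(kind = kind, carrier_hz = carrier_hz, pulse_ms = pulse_ms,
                 gap_ms = gap_ms, total_ms = total_ms, n_pulses = n_pulses,
                 repeats = as.integer(repeats),
                 repeat_gap_ms = repeat_gap_ms),
            class = "stridulation_spec")
}

raised_cosine_pulse <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))

#' Synthesize one stridulation
#'
#' An amplitude-modulated pulse train: each pulse is a raised-cosine
#' windowed tone burst at the carrier frequency with small random jitter on
#' timing (+-1 ms) and amplitude (+-20%). The rare preset emits `repeats`
#' such patterns separated by `repeat_gap_ms`.
#'
#' @param spec a [stridulation_spec].
#' @param sample_rate_hz sampling rate (default 44100).
#' @param seed RNG seed; the same spec and seed give identical waveforms.
#' @return Numeric waveform segment with unit peak amplitude.
#' @export
make_stridulation <- function(spec, sample_rate_hz = 44100, seed = 1) {
  stopifnot(inherits(spec, "stridulation_spec"))
  sr <- sample_rate_hz
  np <- round(spec$pulse_ms * sr / 1000)
  hop <- (spec$pulse_ms + spec$gap_ms) * sr / 1000
  pat_len <- ceiling((spec$n_pulses - 1) * hop) + np
  rep_gap <- round(spec$repeat_gap_ms * sr / 1000)
  total <- spec$repeats * pat_len + (spec$repeats - 1L) * rep_gap +
    round(2e-3 * sr)  # headroom for timing jitter
  withr::with_seed(seed, {
    x <- numeric(total)
    env <- raised_cosine_pulse(np)
    for (r in seq_len(spec$repeats)) {
      pat0 <- (r - 1L) * (pat_len + rep_gap)
      for (k in seq_len(spec$n_pulses)) {
        jit <- round(stats::runif(1, -1e-3, 1e-3) * sr)
        start <- pat0 + round((k - 1) * hop) + jit
        start <- max(0L, min(total - np, start))
        amp <- stats::runif(1, 0.8, 1.2)
        phase <- stats::runif(1, 0, 2 * pi)
        tone <- sin(2 * pi * spec$carrier_hz * (0:(np - 1)) / sr + phase)
        idx <- (start + 1L):(start + np)
        x[idx] <- x[idx] + amp * env * tone
      }
    }
    x / max(abs(x))
  })
}

#' Synthesize an incidental larval sound
#'
#' Passively produced sounds the detector must reject: `"movement"` is an
#' extended broadband scrape (noise burst with a slowly varying envelope,
#' typically hundreds of ms); `"feeding"` is a brief click (< 20 ms damped
#' broadband transient).
#'
#' @param kind `"movement"` or `"feeding"`.
#' @param duration_ms segment duration in milliseconds.
#' @param sample_rate_hz sampling rate.
#' @param seed RNG seed.
#' @return Numeric waveform segment with unit peak amplitude.
#' @export
make_incidental <- function(kind = c("movement", "feeding"),
                            duration_ms = if (kind == "feeding") 10 else 400,
                            sample_rate_hz = 44100, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(duration_ms > 0)
  sr <- sample_rate_hz
  n <- round(duration_ms * sr / 1000)
  withr::with_seed(seed, {
    if (kind == "movement") {
      w <- stats::rnorm(n)
      bf <- signal::butter(2, c(300, 6000) / (sr / 2), type = "pass")
      w <- signal::filtfilt(bf, w)
      # slow irregular envelope: a scrape waxes and wanes
      k <- max(8L, n %/% 20L)
      env <- stats::approx(seq_len(k), abs(stats::rnorm(k)) + 0.2,
                           xout = seq(1, k, length.out = n))$y
      x <- w * env
    } else {
      # damped broadband click
      w <- stats::rnorm(n)
      x <- w * exp(-(0:(n - 1)) / (0.15 * n))
    }
    x / max(abs(x))
  })
}

# Gaussian noise with a prescribed magnitude spectrum, synthesised directly
# in the frequency domain (one inverse FFT): the real part of the inverse
# transform of a complex-Gaussian spectrum shaped by `mag` is a real
# Gaussian process with that power spectrum. Unit RMS on return.
spectral_noise <- function(n, mag_fun) {
  m <- stats::nextn(n, c(2, 3, 5))
  k <- seq.int(0L, m - 1L)
  w <- 2 * pi * pmin(k, m - k) / m
  spec <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m)) *
    mag_fun(w)
  x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n)]
  x / stats::sd(x)
}

pink_noise <- function(n) {
  spectral_noise(n, function(w) 1 / sqrt(pmax(w, 2 * pi / length(w))))
}

#' Synthetic soil background noise
#'
#' Three backgrounds: `"white"` and `"pink"` are i.i.d.-roughness reference
#' noises. The default `"soil"` preset emulates the roughness-heterogeneous
#' background of real buried-sensor recordings: a pink ambient bed, a small
#' wideband sensor hiss, and a high-band (5.5-12 kHz) crackle component
#' whose amplitude flutters quasi-periodically (~12 Hz, slow phase wander).
#' The flutter gives the per-frame fractal dimension genuine dispersion with
#' brief, widely spaced smoothness dips - the regime in which robust
#' median/md outlier detection of stridulation pulses operates. Uniformly
#' rough digital noise lacks this dispersion and is not representative of
#' field recordings (see the package vignette).
#'
#' @param n_samples length.
#' @param kind `"soil"`, `"pink"` or `"white"`.
#' @param sample_rate_hz sampling rate.
#' @param seed RNG seed.
#' @return Numeric vector, unit RMS.
#' @export
make_noise <- function(n_samples, kind = c("soil", "pink", "white"),
                       sample_rate_hz = 44100, seed = 1) {
  kind <- match.arg(kind)
  sr <- sample_rate_hz
  withr::with_seed(seed, {
    x <- switch(kind,
      white = stats::rnorm(n_samples),
      pink = pink_noise(n_samples),
      soil = {
        hb <- c(5500, 12000) / (sr / 2)
        # amplitude |H|^2: the crackle band is shaped by a zero-phase
        # (forward-backward) 2nd-order bandpass
        hf <- spectral_noise(n_samples, function(w)
          butter_mag2(w, list(type = "pass", fc = hb, order = 2)))
        ph <- cumsum(stats::rnorm(n_samples, 0, 0.3 / sqrt(sr)))
        flut <- sin(2 * pi * 12 * (0:(n_samples - 1)) / sr + 2 * pi * ph)
        pink_noise(n_samples) + 0.3 * stats::rnorm(n_samples) +
          exp(1.35 * flut) * hf
      })
    x / stats::sd(x)
  })
}

#' Generate a synthetic soil-audio scene with ground truth
#'
#' A background noise floor with stridulations and incidental larval sounds
#' placed uniformly at random (stridulations never overlap each other;
#' incidentals may overlap anything). Stridulation amplitude is set so that
#' the stridulation-segment RMS is `snr_db` above the in-band
#' (200-5000 Hz) RMS of the noise floor; incidentals are placed at
#' `incidental_snr_db`. The returned recording is raw (not preprocessed).
#'
#' @param duration_s scene length in seconds (>= 4).
#' @param n_stridulations number of stridulation events.
#' @param n_incidentals number of incidental sounds (movement/feeding mix).
#' @param snr_db stridulation-to-noise ratio in dB (default 20).
#' @param noise_kind background preset for [make_noise].
#' @param seed scene seed; drives placement and all per-event seeds.
#' @param spec [stridulation_spec] used for the stridulations.
#' @param incidental_snr_db level of incidental sounds relative to in-band
#'   noise RMS.
#' @param sample_rate_hz sampling rate.
#' @param noise_rms RMS of the raw noise floor in amplitude units.
#' @return List with `recording` (an [audio_recording]) and `annotation`
#'   (a `scene_annotation`: data frame `events` with onset_s, offset_s,
#'   kind, carrier_hz, event_seed; plus `n_stridulations`, `seed`,
#'   `snr_db`, `duration_s`).
#' @export
make_scene <- function(duration_s, n_stridulations, n_incidentals = 0,
                       snr_db = 20, noise_kind = "soil", seed = 1,
                       spec = stridulation_spec("common"),
                       incidental_snr_db = 10, sample_rate_hz = 44100,
                       noise_rms = 0.05) {
  stopifnot(duration_s >= 4)
  sr <- sample_rate_hz
  n <- round(duration_s * sr)
  noise <- noise_rms * make_noise(n, noise_kind, sr, seed = seed)
  # in-band noise RMS defines the SNR reference
  inband_rms <- stats::sd(zero_phase_filter(
    noise[seq_len(min(n, 5L * sr))], list(
      list(type = "high", fc = 200 / (sr / 2), order = 4),
      list(type = "low", fc = 5000 / (sr / 2), order = 2))))

  strid_segs <- lapply(seq_len(n_stridulations), function(i) {
    make_stridulation(spec, sr, seed = seed * 1000L + i)
  })
  seg_lens <- vapply(strid_segs, length, integer(1))
  if (n_stridulations > 0 && sum(seg_lens) > 0.5 * n) {
    stop("too many stridulation events for scene duration", call. = FALSE)
  }

  onsets <- withr::with_seed(seed + 500L, {
    place_without_overlap(n, seg_lens, max_tries = 200L)
  })
  x <- noise
  ev <- list()
  for (i in seq_len(n_stridulations)) {
    seg <- strid_segs[[i]]
    gain <- inband_rms * 10^(snr_db / 20) / sqrt(mean(seg^2))
    idx <- (onsets[i] + 1L):(onsets[i] + length(seg))
    x[idx] <- x[idx] + gain * seg
    ev[[length(ev) + 1L]] <- data.frame(
      onset_s = onsets[i] / sr, offset_s = (onsets[i] + length(seg)) / sr,
      kind = spec$kind, carrier_hz = spec$carrier_hz,
      event_seed = seed * 1000L + i, stringsAsFactors = FALSE)
  }
  if (n_incidentals > 0) {
    inc <- withr::with_seed(seed + 900L, {
      data.frame(kind = sample(c("movement", "feeding"), n_incidentals,
                               replace = TRUE),
                 pos = sample.int(n - sr, n_incidentals))
    })
    for (i in seq_len(n_incidentals)) {
      seg <- make_incidental(inc$kind[i], sample_rate_hz = sr,
                             seed = seed * 2000L + i)
      gain <- inband_rms * 10^(incidental_snr_db / 20) / sqrt(mean(seg^2))
      idx <- (inc$pos[i] + 1L):(inc$pos[i] + length(seg))
      x[idx] <- x[idx] + gain * seg
      ev[[length(ev) + 1L]] <- data.frame(
        onset_s = inc$pos[i] / sr, offset_s = (inc$pos[i] + length(seg)) / sr,
        kind = inc$kind[i], carrier_hz = NA_real_,
        event_seed = seed * 2000L + i, stringsAsFactors = FALSE)
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(onset_s = numeric(0), offset_s = numeric(0),
               kind = character(0), carrier_hz = numeric(0),
               event_seed = integer(0), stringsAsFactors = FALSE)
  events <- events[order(events$onset_s), , drop = FALSE]
  rownames(events) <- NULL
  annotation <- structure(list(events = events,
                               n_stridulations = n_stridulations,
                               seed = seed, snr_db = snr_db,
                               duration_s = duration_s),
                          class = "scene_annotation")
  list(recording = audio_recording(x, sr, sprintf("scene-seed%d", seed)),
       annotation = annotation)
}

# uniform placement of segments without mutual overlap (rejection sampling)
place_without_overlap <- function(n_total, seg_lens, max_tries = 200L) {
  k <- length(seg_lens)
  if (k == 0L) return(integer(0))
  for (try in seq_len(max_tries)) {
    onsets <- vapply(seg_lens, function(l) {
      sample.int(n_total - l, 1L)
    }, integer(1))
    o <- order(onsets)
    starts <- onsets[o]
    ends <- starts + seg_lens[o]
    if (all(starts[-1] >= ends[-k])) return(onsets)
  }
  stop("could not place events without overlap; reduce event count",
       call. = FALSE)
}

#' Which sections contain a stridulation?
#'
#' Maps a scene annotation onto the 2-s section grid used by the detector,
#' giving the ground-truth labels against which detection output is scored.
#'
#' @param annotation a `scene_annotation` from [make_scene].
#' @param n_sections number of sections the recording slices into.
#' @param section_seconds section length (default 2).
#' @return Logical vector of length `n_sections`; TRUE where any
#'   stridulation event overlaps the section.
#' @export
stridulation_sections <- function(annotation, n_sections,
                                  section_seconds = 2.0) {
  ev <- annotation$events
  ev <- ev[ev$kind %in% c("common", "melolontha", "rare"), , drop = FALSE]
  out <- logical(n_sections)
  for (i in seq_len(nrow(ev))) {
    first <- max(1L, floor(ev$onset_s[i] / section_seconds) + 1L)
    last <- min(n_sections, floor(ev$offset_s[i] / section_seconds) + 1L)
    if (first <= n_sections) out[first:last] <- TRUE
  }
  out
}

#' Write a scene annotation as CSV
#'
#' @param annotation a `scene_annotation`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.csv(annotation$events, path, row.names = FALSE)
  invisible(path)
}
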