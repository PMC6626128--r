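# Independent brute-force reference for the threshold / run-length /
# clustering chain, written as plain loops so it shares no code with the
# package implementation.

brute_detect <- function(sfd_vals, threshold = -4, max_run = 2,
                         max_gap = 10) {
  cand <- integer(0)
  for (i in seq_along(sfd_vals)) {
    if (sfd_vals[i] < threshold) cand <- c(cand, i)
  }
  # group candidates into maximal runs of consecutive indices
  peaks <- integer(0)
  i <- 1
  while (i <= length(cand)) {
    j <- i
    while (j < length(cand) && cand[j + 1] == cand[j] + 1) j <- j + 1
    if (j - i + 1 <= max_run) peaks <- c(peaks, cand[i])
    i <- j + 1
  }
  # group peaks into clusters with all internal gaps < max_gap
  events <- list()
  singles <- 0
  i <- 1
  while (i <= length(peaks)) {
    j <- i
    while (j < length(peaks) && peaks[j + 1] - peaks[j] < max_gap) j <- j + 1
    if (j > i) {
      events[[length(events) + 1]] <- peaks[i:j]
    } else {
      singles <- singles + 1
    }
    i <- j + 1
  }
  list(peaks = peaks, events = events, singles = singles)
}

# deterministic mono test tone
sine_recording <- function(freq_hz, duration_s = 2, sr = 44100,
                           amplitude = 0.5) {
  audio_recording(amplitude * sin(2 * pi * freq_hz *
                                    (0:(duration_s * sr - 1)) / sr), sr)
}

make_section <- function(samples, index = 1L, sr = 44100) {
  structure(list(index = index, start_sample = (index - 1L) * length(samples),
                 samples = samples, sample_rate_hz = sr),
            class = "strid_section")
}
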