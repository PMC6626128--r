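#' Threshold-crossing candidate frames
#'
#' Frames whose summed fractal distance falls strictly below the detection
#' threshold (default -4.0). Values equal to the threshold are excluded.
#' Degenerate sections yield no candidates.
#'
#' @param x an `sfd_series` from [sfd], or a numeric SFD vector.
#' @param threshold vertical SFD threshold (default -4.0).
#' @return Sorted integer vector of 1-based frame indices; attribute
#'   `degenerate` is TRUE when the section was excluded.
#' @export
threshold_candidates <- function(x, threshold = -4.0) {
  if (inherits(x, "sfd_series")) {
    if (x$degenerate) {
      return(structure(integer(0), degenerate = TRUE))
    }
    x <- x$values
  }
  structure(which(x < threshold), degenerate = FALSE)
}

#' Run-length filter and peak collapsing
#'
#' Stridulation pulses cross the threshold for only 1-2 adjacent frames;
#' wider excursions are movement sounds or interference. Maximal runs of
#' consecutive candidate frames longer than `max_run` are discarded
#' entirely; each surviving run is collapsed to its first frame index, so
#' that one peak represents one pulse.
#'
#' @param candidates sorted unique integer frame indices.
#' @param max_run maximum run length kept (default 2).
#' @return Sorted integer vector of surviving peak frame indices.
#' @export
filter_runs <- function(candidates, max_run = 2) {
  candidates <- as.integer(candidates)
  if (length(candidates) == 0L) return(integer(0))
  grp <- cumsum(c(1L, as.integer(diff(candidates) != 1L)))
  len <- tabulate(grp)
  keep_first <- candidates[!duplicated(grp)]
  keep_first[len[unique(grp)] <= max_run]
}

#' Inter-peak intervals (TI)
#'
#' First differences, in frames, between consecutive surviving peaks within
#' one section. Intervals never span section boundaries; fewer than two
#' peaks give an empty result.
#'
#' @param peaks sorted integer peak frame indices.
#' @return Integer vector of intervals.
#' @export
intervals <- function(peaks) {
  if (length(peaks) < 2L) return(integer(0))
  diff(as.integer(peaks))
}

#' Cluster peaks into stridulation events
#'
#' Peaks spaced apart by strictly fewer than `max_gap` frames belong to the
#' same cluster; maximal clusters with at least two peaks are stridulation
#' events (the rhythmic pulse train of one stridulation). Singleton
#' clusters are not events — they are tallied separately as the
#' single-peak category.
#'
#' @param peaks sorted integer peak frame indices.
#' @param max_gap clustering gap in frames; internal gaps must be
#'   `< max_gap` (default 10, strict).
#' @return List with `events` (list of lists: `member_peaks`, `ti_values`)
#'   and `n_singletons`.
#' @export
cluster_events <- function(peaks, max_gap = 10) {
  peaks <- as.integer(peaks)
  if (length(peaks) == 0L) return(list(events = list(), n_singletons = 0L))
  grp <- cumsum(c(1L, as.integer(diff(peaks) >= max_gap)))
  events <- list()
  n_single <- 0L
  for (g in unique(grp)) {
    members <- peaks[grp == g]
    if (length(members) >= 2L) {
      events[[length(events) + 1L]] <-
        list(member_peaks = members, ti_values = diff(members))
    } else {
      n_single <- n_single + 1L
    }
  }
  list(events = events, n_singletons = n_single)
}

#' Histogram of inter-peak intervals
#'
#' @param ti integer vector of intervals (frames), aggregated per file.
#' @param max_k largest interval reported individually (default 50; larger
#'   intervals are dropped from the histogram — they never contribute to
#'   STRAC anyway).
#' @return Named integer vector `counts` with names "1".."max_k".
#' @export
ti_histogram <- function(ti, max_k = 50) {
  counts <- tabulate(ti[ti >= 1 & ti <= max_k], nbins = max_k)
  names(counts) <- as.character(seq_len(max_k))
  counts
}

#' Stridulation activity (STRAC)
#'
#' Semi-quantitative per-file activity score: intervals of 1 to `k_max`
#' frames are multiplied by their frequencies and the products summed,
#' \deqn{STRAC = \sum_{k=1}^{k_{max}} k \, n_k.}
#' Intervals above `k_max` (default 10) are ignored — they separate events
#' rather than pulses within an event.
#'
#' @param ti integer vector of TI values, or a histogram from
#'   [ti_histogram].
#' @param k_max largest interval included, inclusive (default 10).
#' @return Non-negative numeric STRAC value.
#' @export
strac <- function(ti, k_max = 10) {
  if (!is.null(names(ti))) {
    k <- as.integer(names(ti))
    sum(k[k <= k_max] * ti[k <= k_max])
  } else {
    sum(ti[ti >= 1 & ti <= k_max])
  }
}

#' Run the full detection pipeline on one recording
#'
#' Per 2-second section: summed fractal distance, vertical threshold,
#' run-length filter, and interval clustering; then a file-level TI
#' histogram and STRAC. By default the recording is preprocessed first
#' (bandpass, DC removal, peak normalisation); pass
#' `apply_preprocess = FALSE` for already-preprocessed audio.
#'
#' @param rec an [audio_recording].
#' @param config a [pipeline_config].
#' @param apply_preprocess logical; run [preprocess] first (default TRUE).
#' @param file_id identifier used in reports (defaults to the recording's
#'   source path).
#' @return A `strac_report`: list with `file_id`, `strac`, `n_sections`,
#'   `n_sections_with_events`, `n_sections_single_peak` (>= 1 surviving
#'   peak but no event), `n_degenerate`, `ti_histogram`, and `events`
#'   (data frame: one row per detected event).
#' @export
analyze_recording <- function(rec, config = pipeline_config(),
                              apply_preprocess = TRUE,
                              file_id = rec$source_path) {
  stopifnot(inherits(rec, "audio_recording"))
  if (apply_preprocess) {
    rec <- preprocess(rec, config$low_hz, config$high_hz, config$peak_db,
                      config$hp_order, config$lp_order)
  }
  frame_sizes <- config$frame_ms * rec$sample_rate_hz / 1000
  sections <- slice_sections(rec, config$section_seconds)
  n_events_sections <- 0L
  n_single_sections <- 0L
  n_degenerate <- 0L
  all_ti <- integer(0)
  ev_rows <- list()
  for (sec in sections) {
    s <- sfd(sec, frame_sizes, config$lags)
    if (s$degenerate) {
      n_degenerate <- n_degenerate + 1L
      next
    }
    cand <- threshold_candidates(s, config$sfd_threshold)
    peaks <- filter_runs(cand, config$max_run)
    cl <- cluster_events(peaks, config$max_gap)
    if (length(cl$events) > 0L) {
      n_events_sections <- n_events_sections + 1L
    } else if (length(peaks) > 0L) {
      n_single_sections <- n_single_sections + 1L
    }
    sec_ti <- if (identical(config$ti_source, "events_only")) {
      unlist(lapply(cl$events, `[[`, "ti_values"), use.names = FALSE)
    } else {
      intervals(peaks)
    }
    all_ti <- c(all_ti, sec_ti)
    for (k in seq_along(cl$events)) {
      ev <- cl$events[[k]]
      ev_rows[[length(ev_rows) + 1L]] <- data.frame(
        file_id = file_id,
        section_index = sec$index,
        section_start_s = sec$start_sample / rec$sample_rate_hz,
        event_index = k,
        n_peaks = length(ev$member_peaks),
        peak_frames = paste(ev$member_peaks, collapse = ";"),
        ti_values = paste(ev$ti_values, collapse = ";"),
        stringsAsFactors = FALSE
      )
    }
  }
  hist <- ti_histogram(all_ti, max_k = 50)
  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else
    data.frame(file_id = character(0), section_index = integer(0),
               section_start_s = numeric(0), event_index = integer(0),
               n_peaks = integer(0), peak_frames = character(0),
               ti_values = character(0), stringsAsFactors = FALSE)
  structure(list(
    file_id = file_id,
    strac = strac(hist, config$strac_k_max),
    n_sections = length(sections),
    n_sections_with_events = n_events_sections,
    n_sections_single_peak = n_single_sections,
    n_degenerate = n_degenerate,
    ti_histogram = hist,
    events = events
  ), class = "strac_report")
}

#' @export
print.strac_report <- function(x, ...) {
  cat(sprintf("<strac_report> %s\n", x$file_id))
  cat(sprintf("  sections: %d (with events %d, single-peak %d, degenerate %d)\n",
              x$n_sections, x$n_sections_with_events,
              x$n_sections_single_peak, x$n_degenerate))
  cat(sprintf("  events: %d   STRAC: %g\n", nrow(x$events), x$strac))
  invisible(x)
}
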