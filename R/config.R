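#' Pipeline configuration
#'
#' All tunables of the detection pipeline in one place. The defaults are the
#' constants of the published routine: 200-5000 Hz band, -1.0 dB peak, 2-s
#' sections, 2 ms and 4 ms frames, madogram lags {1, 2}, SFD threshold
#' -4.0, maximum run length 2, cluster gap 10 (strict `<`), STRAC interval
#' cap 10 (inclusive). The cluster gap and the STRAC cap are deliberately
#' independent settings.
#'
#' @param low_hz,high_hz bandpass edges (Hz).
#' @param peak_db normalisation target peak (dBFS).
#' @param section_seconds analysis section length (s).
#' @param frame_ms the two frame durations (ms), fine first.
#' @param lags madogram lag set.
#' @param sfd_threshold vertical SFD detection threshold.
#' @param max_run maximum below-threshold run length kept (frames).
#' @param max_gap within-event peak spacing bound (frames, strict `<`).
#' @param strac_k_max largest TI included in STRAC (inclusive).
#' @param ti_source `"all_peaks"` (intervals between all surviving peaks in
#'   a section) or `"events_only"` (intervals inside clustered events only).
#'   Intervals above `strac_k_max` are ignored by STRAC either way, so the
#'   choice matters only for the reported histogram tail.
#' @param hp_order,lp_order Butterworth orders of the bandpass edges (see
#'   [bandpass] for why the low-pass is deliberately gentle).
#' @param seed default seed for seeded operations.
#' @return A `pipeline_config` (named list).
#' @export
pipeline_config <- function(low_hz = 200, high_hz = 5000, peak_db = -1.0,
                            section_seconds = 2.0, frame_ms = c(2, 4),
                            lags = c(1, 2), sfd_threshold = -4.0,
                            max_run = 2, max_gap = 10, strac_k_max = 10,
                            ti_source = c("all_peaks", "events_only"),
                            hp_order = 4, lp_order = 2, seed = 1) {
  ti_source <- match.arg(ti_source)
  stopifnot(low_hz > 0, low_hz < high_hz, section_seconds > 0,
            length(frame_ms) == 2L, frame_ms[1] < frame_ms[2],
            length(lags) >= 2L, max_run >= 1, max_gap >= 1,
            strac_k_max >= 1)
  structure(list(
    low_hz = low_hz, high_hz = high_hz, peak_db = peak_db,
    section_seconds = section_seconds, frame_ms = frame_ms, lags = lags,
    sfd_threshold = sfd_threshold, max_run = max_run, max_gap = max_gap,
    strac_k_max = strac_k_max, ti_source = ti_source,
    hp_order = hp_order, lp_order = lp_order, seed = seed
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Round-trips losslessly: unknown keys are rejected, missing keys fall back
#' to the defaults of [pipeline_config].
#'
#' @param path YAML file path.
#' @param config a [pipeline_config].
#' @return `read_config` returns a [pipeline_config]; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
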