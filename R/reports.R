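#' Run the detection pipeline over a batch of WAV files
#'
#' Applies [analyze_recording] to each file, in deterministic (sorted-path)
#' order. An unreadable file is recorded as a failed row and the batch
#' continues; if every file fails, an error is raised.
#'
#' @param paths character vector of WAV file paths (>= 1).
#' @param config a [pipeline_config].
#' @param apply_preprocess run [preprocess] on each file (default TRUE).
#' @return A `batch_summary`: list with `reports` (named list of
#'   `strac_report`s), `summary` (one data frame row per file: file_id,
#'   ok, n_sections, n_sections_with_events, n_sections_single_peak,
#'   n_degenerate, n_events, strac), `totals` (column sums over successful
#'   rows) and `config`.
#' @export
run_batch <- function(paths, config = pipeline_config(),
                      apply_preprocess = TRUE) {
  if (length(paths) < 1L) stop("no input files given", call. = FALSE)
  paths <- sort(paths)
  reports <- list()
  rows <- list()
  for (p in paths) {
    res <- tryCatch({
      rec <- load_wav(p)
      analyze_recording(rec, config, apply_preprocess = apply_preprocess,
                        file_id = p)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("skipping %s: %s", p, conditionMessage(res)),
              call. = FALSE)
      rows[[p]] <- data.frame(
        file_id = p, ok = FALSE, n_sections = NA_integer_,
        n_sections_with_events = NA_integer_,
        n_sections_single_peak = NA_integer_, n_degenerate = NA_integer_,
        n_events = NA_integer_, strac = NA_real_, stringsAsFactors = FALSE)
    } else {
      reports[[p]] <- res
      rows[[p]] <- data.frame(
        file_id = p, ok = TRUE, n_sections = res$n_sections,
        n_sections_with_events = res$n_sections_with_events,
        n_sections_single_peak = res$n_sections_single_peak,
        n_degenerate = res$n_degenerate, n_events = nrow(res$events),
        strac = res$strac, stringsAsFactors = FALSE)
    }
  }
  if (length(reports) == 0L) {
    stop("all input files failed to analyse", call. = FALSE)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  ok <- summary[summary$ok, , drop = FALSE]
  totals <- as.list(colSums(ok[, c("n_sections", "n_sections_with_events",
                                   "n_sections_single_peak", "n_degenerate",
                                   "n_events", "strac")]))
  structure(list(reports = reports, summary = summary, totals = totals,
                 config = config),
            class = "batch_summary")
}

#' Write detection reports to CSV and JSON
#'
#' The CSV holds one row per detected event (file_id, section_index,
#' section_start_s, event_index, n_peaks, peak_frames, ti_values). The JSON
#' holds the per-file summaries - section category counts, the TI histogram
#' (intervals 1-50) and STRAC - plus the full pipeline configuration for
#' provenance.
#'
#' @param batch a `batch_summary` from [run_batch] (a single `strac_report`
#'   is also accepted).
#' @param csv_path,json_path output paths; either may be `NULL` to skip.
#' @return Invisibly, a list of the paths written.
#' @export
write_reports <- function(batch, csv_path = NULL, json_path = NULL) {
  if (inherits(batch, "strac_report")) {
    batch <- structure(list(reports = stats::setNames(list(batch),
                                                      batch$file_id),
                            summary = NULL, totals = NULL,
                            config = pipeline_config()),
                       class = "batch_summary")
  }
  stopifnot(inherits(batch, "batch_summary"))
  written <- list()
  if (!is.null(csv_path)) {
    events <- do.call(rbind, lapply(batch$reports, `[[`, "events"))
    if (is.null(events)) {
      events <- data.frame(file_id = character(0))
    }
    rownames(events) <- NULL
    utils::write.csv(events, csv_path, row.names = FALSE)
    written$csv <- csv_path
  }
  if (!is.null(json_path)) {
    payload <- list(
      files = lapply(unname(batch$reports), function(r) {
        hist <- r$ti_histogram[r$ti_histogram > 0]
        list(file_id = r$file_id, n_sections = r$n_sections,
             n_sections_with_events = r$n_sections_with_events,
             n_sections_single_peak = r$n_sections_single_peak,
             n_degenerate = r$n_degenerate,
             ti_histogram = as.list(hist),
             strac = r$strac)
      }),
      config = unclass(batch$config)
    )
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written$json <- json_path
  }
  invisible(written)
}

#' Detection-outcome bookkeeping
#'
#' Consistency arithmetic for the three detection outcomes of
#' stridulation-bearing sections: identified by the routine (>= 1 peak
#' cluster), single-peak only, and undetected. Computes the total, each
#' category's percentage, and the equivalent recording time of the
#' stridulation-bearing sections.
#'
#' @param n_identified,n_single_peak,n_undetected category counts.
#' @param section_seconds section length (default 2).
#' @return List with `n_total`, `pct_identified`, `pct_single_peak`,
#'   `pct_undetected` (rounded to whole percent) and `total_minutes`.
#' @export
outcome_summary <- function(n_identified, n_single_peak, n_undetected,
                            section_seconds = 2.0) {
  n_total <- n_identified + n_single_peak + n_undetected
  pct <- function(k) round(100 * k / n_total)
  list(n_total = n_total,
       pct_identified = pct(n_identified),
       pct_single_peak = pct(n_single_peak),
       pct_undetected = pct(n_undetected),
       total_minutes = n_total * section_seconds / 60)
}

#' @export
print.batch_summary <- function(x, ...) {
  cat(sprintf("<batch_summary> %d file(s)\n", nrow(x$summary)))
  print(x$summary)
  invisible(x)
}
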