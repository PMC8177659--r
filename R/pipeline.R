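#' Pipeline configuration
#'
#' Collects every stage's settings in one object. Defaults reproduce the
#' standard screen: Kubios-style "strong" correction, 20-200 bpm
#' physiological limits, 5-minute windows and retention of windows with at
#' most 5% flats/stairs and no Active beats.
#'
#' @param correction a [correction_config()], or `NULL` to skip the
#'   correction stage (for pre-corrected input).
#' @param min_bpm,max_bpm physiological heart-rate limits.
#' @param window_s window length, s.
#' @param retention a [retention_policy()].
#' @param stair_min_diffs minimum identical successive differences for a
#'   stair.
#' @param tolerance_ms equality tolerance for flats/stairs detection.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(correction = correction_config(),
                            min_bpm = 20, max_bpm = 200,
                            window_s = 300,
                            retention = retention_policy(),
                            stair_min_diffs = 3,
                            tolerance_ms = 0) {
  if (!is.null(correction)) stopifnot(inherits(correction, "correction_config"))
  stopifnot(inherits(retention, "retention_policy"))
  structure(list(correction = correction, min_bpm = min_bpm,
                 max_bpm = max_bpm, window_s = window_s,
                 retention = retention,
                 stair_min_diffs = stair_min_diffs,
                 tolerance_ms = tolerance_ms),
            class = "pipeline_config")
}

#' Run the full QC and resting-HRV pipeline
#'
#' For each input trace: artefact correction ([correct_artefacts()]),
#' flats/stairs/limits annotation ([annotate_trace()]), activity matching
#' ([match_activity()], when an activity series is supplied), window
#' summaries ([summarize_windows()]) and retention filtering
#' ([filter_windows()]). Classification matrices (flats and stairs vs
#' corrected) are pooled over all input traces' beats. Every correction
#' event and window rejection is appended to a structured QC log (one event
#' per line).
#'
#' @param traces a single [ibi_trace], a list of them, or a character
#'   vector of canonical trace file paths.
#' @param activities optional: a single [activity_series], a list parallel
#'   to `traces` (`NULL` entries allowed), or a character vector of
#'   activity file paths.
#' @param config a [pipeline_config()].
#' @param output_dir optional directory; when given, per-trace annotated
#'   trace files and run tables, the pooled window covariate table, the
#'   retained-window rMSSD table and the QC log are written there.
#' @return a list: `traces` (annotated), `runs` (per-trace run tables),
#'   `windows` (all window summaries, pooled), `retained`, `rejected`,
#'   `matrices` (list `flat`, `stair`), `qc_log` (character vector).
#' @export
run_pipeline <- function(traces, activities = NULL,
                         config = pipeline_config(), output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(traces, "ibi_trace")) traces <- list(traces)
  if (is.character(traces)) traces <- lapply(traces, read_trace)
  if (inherits(activities, "activity_series")) activities <- list(activities)
  if (is.character(activities)) activities <- lapply(activities, read_activity)
  if (!is.null(activities) && length(activities) != length(traces))
    stop("activities must parallel traces")

  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))
  out_traces <- list(); out_runs <- list(); out_windows <- list()
  for (k in seq_along(traces)) {
    tr <- traces[[k]]
    id <- if (nzchar(tr$individual_id)) tr$individual_id else paste0("trace", k)
    if (!is.null(config$correction)) {
      tr <- correct_artefacts(tr, config$correction)
      ev <- tr$meta$correction_events
      if (!is.null(ev)) for (i in seq_len(nrow(ev)))
        note(id, " correction ", ev$type[i], " beat=", ev$beat_index[i],
             " ibi=", ev$ibi_before[i], " n_out=", ev$n_out[i])
    }
    ann <- annotate_trace(tr, tolerance_ms = config$tolerance_ms,
                          min_diffs = config$stair_min_diffs,
                          min_bpm = config$min_bpm, max_bpm = config$max_bpm)
    tr <- ann$trace
    if (!is.null(activities) && !is.null(activities[[k]]))
      tr <- match_activity(tr, activities[[k]])
    w <- summarize_windows(tr, config$window_s)
    out_traces[[k]] <- tr
    out_runs[[k]] <- ann$runs
    out_windows[[k]] <- w
    note(id, " windows=", nrow(w), " beats=", n_beats(tr),
         " flats=", sum(tr$beats$flat), " stairs=", sum(tr$beats$stair),
         " corrected=", sum(tr$beats$corrected))
  }
  windows <- do.call(rbind, out_windows)
  filt <- filter_windows(windows, config$retention)
  if (nrow(filt$rejected)) for (i in seq_len(nrow(filt$rejected)))
    note(filt$rejected$individual_id[i], " reject window=",
         filt$rejected$window_index[i], " reason=", filt$rejected$reason[i])
  matrices <- list(flat = classification_matrix(out_traces, "flat"),
                   stair = classification_matrix(out_traces, "stair"))

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(out_traces)) {
      stem <- file.path(output_dir, sprintf("trace%03d", k))
      write_trace(out_traces[[k]], paste0(stem, ".csv"))
      utils::write.csv(out_runs[[k]], paste0(stem, "_runs.csv"),
                       row.names = FALSE, quote = FALSE)
    }
    export_covariate_table(windows, file.path(output_dir, "windows.csv"))
    utils::write.csv(
      filt$retained[, c("individual_id", "tag_id", "window_index",
                        "mean_hr_bpm", "rmssd_ms")],
      file.path(output_dir, "rmssd_retained.csv"),
      row.names = FALSE, quote = FALSE)
    writeLines(log, file.path(output_dir, "qc_log.txt"))
  }
  list(traces = out_traces, runs = out_runs, windows = windows,
       retained = filt$retained, rejected = filt$rejected,
       matrices = matrices, qc_log = log)
}
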