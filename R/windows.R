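#' Time-match activity labels onto beats
#'
#' Each beat receives the label of the integer second containing its beat
#' time (trace and activity series must share the session clock). Seconds
#' absent from the series yield `Unknown`.
#'
#' @param trace an [ibi_trace].
#' @param activity an [activity_series].
#' @return the trace with its `activity` column replaced.
#' @export
match_activity <- function(trace, activity) {
  validate_ibi_trace(trace)
  sec <- floor(trace$beats$beat_time_s)
  idx <- match(sec, activity$second)
  lab <- ifelse(is.na(idx), "Unknown", activity$label[idx])
  trace$beats$activity <- lab
  trace
}

#' Assign beats to sequential fixed-length windows
#'
#' Windows are consecutive half-open clock intervals `[k*window_s,
#' (k+1)*window_s)`; a beat belongs to the window containing its beat time
#' (a beat at exactly a boundary starts the next window). The trailing
#' partial window - any span not fully covered by the trace - is discarded.
#'
#' @param trace an [ibi_trace].
#' @param window_s window length in seconds (default 300, i.e. 5 min).
#' @return integer vector over beats: 1-based window index, `NA` for beats
#'   in the discarded trailing partial window.
#' @export
assign_windows <- function(trace, window_s = 300) {
  validate_ibi_trace(trace)
  if (window_s <= 0) stop("window_s must be positive")
  t <- trace$beats$beat_time_s
  total <- if (length(t)) t[length(t)] else 0
  n_full <- floor(total / window_s)
  w <- floor(t / window_s) + 1L
  w[w > n_full] <- NA_integer_
  as.integer(w)
}

#' Summarise a trace into per-window QC and HRV statistics
#'
#' Splits the trace into sequential windows (see [assign_windows()]) and
#' computes, per non-empty window: beat count, counts of each QC flag, the
#' percentage of beats flagged flat or stair (`pct_flats_stairs`, counted
#' as the union of the two flags), the percentage corrected
#' (`pct_artefact`), the percentage of beats whose matched behavioural
#' label is Active (`pct_active`, computed over beats with known labels;
#' `NA` when every label is Unknown), mean heart rate `60000 /
#' mean(ibi_ms)` and [rmssd()] (out-of-bounds beats excluded). Trace
#' covariates are carried onto every window, with `time_of_day` advanced to
#' the window start.
#'
#' @param trace an annotated [ibi_trace].
#' @param window_s window length, s.
#' @return a data frame of class `trace_windows`, one row per window.
#' @export
summarize_windows <- function(trace, window_s = 300) {
  w <- assign_windows(trace, window_s)
  b <- trace$beats
  idx <- which(!is.na(w))
  out <- lapply(unique(w[idx]), function(k) {
    summarize_window_beats(b[w %in% k, , drop = FALSE], k, window_s, trace)
  })
  res <- if (length(out)) do.call(rbind, out) else
    summarize_window_beats(b[0, , drop = FALSE], 1L, window_s, trace)[0, ]
  rownames(res) <- NULL
  class(res) <- c("trace_windows", "data.frame")
  res
}

summarize_window_beats <- function(beats, k, window_s, trace) {
  n <- nrow(beats)
  known <- beats$activity != "Unknown"
  cov <- trace$covariates
  start_s <- (k - 1) * window_s
  tod <- cov$time_of_day
  if (!is.null(tod)) tod <- (tod + start_s / 86400) %% 1
  data.frame(
    individual_id = trace$individual_id,
    tag_id = trace$tag_id,
    window_index = as.integer(k),
    start_s = start_s,
    end_s = k * window_s,
    n_beats = n,
    n_corrected = sum(beats$corrected),
    n_flats = sum(beats$flat),
    n_stairs = sum(beats$stair),
    n_out_of_bounds = sum(beats$out_of_bounds),
    pct_artefact = 100 * sum(beats$corrected) / n,
    pct_flats_stairs = 100 * sum(beats$flat | beats$stair) / n,
    pct_active = if (any(known))
      100 * sum(beats$activity[known] == "Active") / sum(known)
    else NA_real_,
    mean_hr_bpm = 60000 / mean(beats$ibi_ms),
    rmssd_ms = suppressWarnings(
      rmssd(beats$ibi_ms, exclude = beats$out_of_bounds)),
    day_of_year = cov$day_of_year %||% NA_real_,
    time_of_day = tod %||% NA_real_,
    deploy_day = cov$deploy_day %||% NA_real_,
    mass_kg = cov$mass_kg %||% NA_real_,
    temperature_c = cov$temperature_c %||% NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Retention policy for resting-HRV windows
#'
#' Thresholds a window must satisfy to be retained for resting-HRV
#' estimation. Defaults follow the recommended screen: at most 5% of beats
#' flagged flat or stair ("up to 5%" is inclusive) and no Active beats at
#' all (resting windows require minimal motor activity; relax via
#' `max_pct_active`). `NA` for any threshold disables that criterion;
#' windows with unknown activity (`pct_active = NA`) fail an activity
#' criterion unless it is disabled.
#'
#' @param max_pct_flats_stairs maximum percent of beats flagged flat/stair.
#' @param max_pct_active maximum percent Active beats.
#' @param max_pct_artefact maximum percent corrected beats (`NA`: no limit).
#' @param min_beats minimum beats per window.
#' @return a list of class `retention_policy`.
#' @export
retention_policy <- function(max_pct_flats_stairs = 5, max_pct_active = 0,
                             max_pct_artefact = NA, min_beats = 2) {
  for (v in c(max_pct_flats_stairs, max_pct_active, max_pct_artefact))
    if (!is.na(v) && (v < 0 || v > 100))
      stop("percentage thresholds must be in [0, 100]")
  structure(list(max_pct_flats_stairs = max_pct_flats_stairs,
                 max_pct_active = max_pct_active,
                 max_pct_artefact = max_pct_artefact,
                 min_beats = min_beats),
            class = "retention_policy")
}

#' Filter windows by a retention policy
#'
#' Criteria are checked in a fixed order (`min_beats`, `flats_stairs`,
#' `artefact`, `activity`) and each rejected window carries the first
#' criterion it failed.
#'
#' @param windows a `trace_windows` data frame from [summarize_windows()].
#' @param policy a [retention_policy()].
#' @return a list with `retained` (rows passing every criterion) and
#'   `rejected` (failing rows with an extra `reason` column).
#' @export
filter_windows <- function(windows, policy = retention_policy()) {
  stopifnot(is.data.frame(windows))
  reason <- rep(NA_character_, nrow(windows))
  fail <- function(cur, cond, why) ifelse(is.na(cur) & cond, why, cur)
  reason <- fail(reason, windows$n_beats < policy$min_beats, "min_beats")
  if (!is.na(policy$max_pct_flats_stairs))
    reason <- fail(reason,
                   windows$pct_flats_stairs > policy$max_pct_flats_stairs,
                   "flats_stairs")
  if (!is.na(policy$max_pct_artefact))
    reason <- fail(reason, windows$pct_artefact > policy$max_pct_artefact,
                   "artefact")
  if (!is.na(policy$max_pct_active))
    reason <- fail(reason,
                   is.na(windows$pct_active) |
                     windows$pct_active > policy$max_pct_active,
                   "activity")
  keep <- is.na(reason)
  rejected <- windows[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  list(retained = windows[keep, , drop = FALSE], rejected = rejected)
}

#' Export a window covariate table
#'
#' Writes one comma-delimited row per window with identifiers, error
#' counts/percentages, HRV summaries and covariates - the input table for
#' downstream determinant modelling (e.g. additive mixed models, which are
#' outside this package). Column order is fixed and equals the column order
#' of [summarize_windows()]; missing covariates are written as empty
#' fields.
#'
#' @param windows a `trace_windows` data frame (possibly several traces'
#'   windows bound together).
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
export_covariate_table <- function(windows, path) {
  utils::write.csv(as.data.frame(windows), path, row.names = FALSE,
                   na = "", quote = FALSE)
  invisible(path)
}
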