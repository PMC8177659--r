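#' ibiqc: quality control and resting HRV for telemetered inter-beat intervals
#'
#' The package works on beat-per-row inter-beat-interval (IBI) streams as
#' produced by externally mounted heart-rate belts on free-ranging animals.
#' The central object is the [ibi_trace]: an ordered sequence of beats, each
#' carrying its IBI in milliseconds and quality-control flags (`corrected`,
#' `flat`, `stair`, `out_of_bounds`) plus an activity label. Around it the
#' package provides artefact-correction emulation ([correct_artefacts()]),
#' flats/stairs detection ([detect_flats()], [detect_stairs()]), 5-minute
#' windowing with activity matching ([summarize_windows()]), rMSSD and
#' agreement statistics ([rmssd()], [bland_altman()],
#' [classification_matrix()]), synthetic trace generation
#' ([generate_clean_trace()], [corrupt_trace()]) and a Monte-Carlo
#' error-injection study ([run_injection_study()]).
#'
#' @keywords internal
"_PACKAGE"

ACTIVITY_LEVELS <- c("Inactive", "Active", "Unknown")
COVARIATE_NAMES <- c("day_of_year", "time_of_day", "deploy_day",
                     "mass_kg", "temperature_c")

#' Construct an IBI trace
#'
#' An `ibi_trace` is an ordered series of heartbeats. Each beat records the
#' interval (in ms) that *ends* at its R peak, so beat times are the
#' cumulative sum of IBIs from the session start: the first beat's time is
#' its own IBI divided by 1000.
#'
#' @param ibi_ms numeric vector of positive inter-beat intervals in
#'   milliseconds. Device-native values are integer ms (1000 Hz sampling);
#'   real values are accepted.
#' @param beat_time_s optional beat times in seconds since session start.
#'   Recomputed as `cumsum(ibi_ms)/1000` when omitted; when supplied they
#'   must agree with that cumulative sum to within 1e-6 s.
#' @param corrected,flat,stair,out_of_bounds logical QC flags, recycled to
#'   the number of beats. `corrected` marks IBIs replaced or derived by the
#'   artefact-correction step; `flat`/`stair` mark interpolation artefacts;
#'   `out_of_bounds` marks beats outside physiological heart-rate limits.
#' @param activity per-beat behavioural label, one of `"Inactive"`,
#'   `"Active"`, `"Unknown"`.
#' @param individual_id,tag_id animal and device identifiers.
#' @param session_start optional ISO-8601 timestamp string for the session
#'   origin (kept as metadata only; all analysis uses seconds since start).
#' @param covariates named list of optional per-trace covariates:
#'   `day_of_year` (days since Jan 1), `time_of_day` (fraction of 24 h in
#'   \[0,1)), `deploy_day` (days since device attachment), `mass_kg`,
#'   `temperature_c`.
#' @return an object of class `ibi_trace`.
#' @examples
#' tr <- ibi_trace(c(500, 510, 505))
#' tr$beats$beat_time_s  # 0.500 1.010 1.515
#' @export
ibi_trace <- function(ibi_ms, beat_time_s = NULL,
                      corrected = FALSE, flat = FALSE, stair = FALSE,
                      out_of_bounds = FALSE, activity = "Unknown",
                      individual_id = "", tag_id = "",
                      session_start = NA_character_,
                      covariates = list()) {
  n <- length(ibi_ms)
  beats <- data.frame(
    beat_time_s   = if (is.null(beat_time_s)) cumsum(as.numeric(ibi_ms)) / 1000
                    else as.numeric(beat_time_s),
    ibi_ms        = as.numeric(ibi_ms),
    corrected     = rep_len(as.logical(corrected), n),
    flat          = rep_len(as.logical(flat), n),
    stair         = rep_len(as.logical(stair), n),
    out_of_bounds = rep_len(as.logical(out_of_bounds), n),
    activity      = rep_len(as.character(activity), n),
    stringsAsFactors = FALSE
  )
  tr <- structure(
    list(beats = beats,
         individual_id = as.character(individual_id),
         tag_id = as.character(tag_id),
         session_start = session_start,
         covariates = covariates,
         meta = list()),
    class = "ibi_trace"
  )
  validate_ibi_trace(tr)
  tr
}

#' Validate an IBI trace
#'
#' Checks the structural invariants: positive IBIs, strictly increasing beat
#' times equal to the cumulative IBI sum (within 1e-6 s), known activity
#' labels and recognised covariate names.
#'
#' @param trace an `ibi_trace`.
#' @return the trace, invisibly; errors on violation.
#' @export
validate_ibi_trace <- function(trace) {
  stopifnot(inherits(trace, "ibi_trace"))
  b <- trace$beats
  if (any(!is.finite(b$ibi_ms)) || any(b$ibi_ms <= 0))
    stop("ibi_ms must be positive and finite")
  if (nrow(b) > 1 && any(diff(b$beat_time_s) <= 0))
    stop("beat_time_s must be strictly increasing")
  dev <- abs(b$beat_time_s - cumsum(b$ibi_ms) / 1000)
  if (length(dev) && max(dev) > 1e-6)
    stop("beat_time_s must equal cumulative sum of ibi_ms/1000 (max deviation ",
         format(max(dev)), " s)")
  if (!all(b$activity %in% ACTIVITY_LEVELS))
    stop("activity labels must be one of: ",
         paste(ACTIVITY_LEVELS, collapse = ", "))
  bad <- setdiff(names(trace$covariates), COVARIATE_NAMES)
  if (length(bad))
    stop("unknown covariates: ", paste(bad, collapse = ", "))
  invisible(trace)
}

#' @export
print.ibi_trace <- function(x, ...) {
  b <- x$beats
  cat(sprintf("<ibi_trace> %d beats, %.1f s", nrow(b),
              if (nrow(b)) b$beat_time_s[nrow(b)] else 0))
  if (nzchar(x$individual_id)) cat(", individual ", x$individual_id, sep = "")
  if (nzchar(x$tag_id)) cat(", tag ", x$tag_id, sep = "")
  cat("\n")
  flags <- c(corrected = sum(b$corrected), flat = sum(b$flat),
             stair = sum(b$stair), out_of_bounds = sum(b$out_of_bounds))
  if (any(flags > 0))
    cat("  flags:", paste(names(flags)[flags > 0], flags[flags > 0],
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of beats in a trace
#' @param trace an `ibi_trace`.
#' @return integer beat count.
#' @export
n_beats <- function(trace) nrow(trace$beats)

#' Construct a per-second activity series
#'
#' Holds the output of a behavioural classifier: one `Inactive`/`Active`
#' label per integer second since session start.
#'
#' @param second integer seconds since session start, non-negative and
#'   strictly increasing.
#' @param label character vector of labels, one of `"Inactive"`, `"Active"`.
#' @return a data frame of class `activity_series` with columns `second`,
#'   `label`.
#' @export
activity_series <- function(second, label) {
  second <- as.integer(second)
  label <- as.character(label)
  if (length(second) != length(label))
    stop("second and label must have equal length")
  if (length(second)) {
    if (any(second < 0)) stop("second must be non-negative")
    if (any(duplicated(second))) stop("duplicate second in activity series")
    if (is.unsorted(second, strictly = TRUE))
      stop("second must be strictly increasing")
  }
  if (!all(label %in% c("Inactive", "Active")))
    stop("activity labels must be 'Inactive' or 'Active'")
  structure(data.frame(second = second, label = label,
                       stringsAsFactors = FALSE),
            class = c("activity_series", "data.frame"))
}
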