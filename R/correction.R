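#' Configuration for the artefact-correction emulator
#'
#' Parameters of the running-median threshold detector used by
#' [correct_artefacts()]. An IBI is extreme when it deviates from the local
#' running median by more than `deviation_threshold` times that median
#' (a Kubios-style "strong" setting by default), or falls outside the hard
#' physiological backstop bounds, which catch extremes in pathological
#' windows where the median itself is corrupt.
#'
#' @param local_window_beats odd integer >= 5; span of the running median.
#' @param deviation_threshold fraction in (0, 1).
#' @param max_merge_span maximum number of consecutive extreme-short IBIs
#'   merged into one beat (spurious-beat deletion).
#' @param hard_min_ms,hard_max_ms absolute bounds, ms (defaults 300/3000,
#'   i.e. 200 and 20 bpm).
#' @return a list of class `correction_config`.
#' @export
correction_config <- function(local_window_beats = 7,
                              deviation_threshold = 0.25,
                              max_merge_span = 3,
                              hard_min_ms = 300, hard_max_ms = 3000) {
  if (local_window_beats < 5 || local_window_beats %% 2 == 0)
    stop("local_window_beats must be an odd integer >= 5")
  if (deviation_threshold <= 0 || deviation_threshold >= 1)
    stop("deviation_threshold must be in (0, 1)")
  if (max_merge_span < 2) stop("max_merge_span must be >= 2")
  if (hard_min_ms >= hard_max_ms) stop("hard_min_ms must be < hard_max_ms")
  structure(list(local_window_beats = as.integer(local_window_beats),
                 deviation_threshold = deviation_threshold,
                 max_merge_span = as.integer(max_merge_span),
                 hard_min_ms = hard_min_ms, hard_max_ms = hard_max_ms),
            class = "correction_config")
}

#' Emulate device-software artefact correction
#'
#' Reproduces the behaviour heart-rate belt software applies to raw IBI
#' streams before export: it detects extreme values against a running
#' median and either deletes spurious extra beats (a run of extreme-short
#' IBIs whose sum matches the local median is merged back into one beat) or
#' interpolates for potentially missing beats (an extreme-long IBI of
#' duration D is replaced by `m = round(D / local median)` beats). Every
#' replaced or derived IBI carries `corrected = TRUE`.
#'
#' Multi-beat interpolation across a gap follows the two shapes observed in
#' real corrected traces: when the anchor IBIs on both sides of the gap are
#' equal (or no usable anchors exist) the fill is constant, producing a
#' *flat*; when they differ the fill ramps with a constant integer step
#' between the anchor values, producing a *stair*. Elapsed time is
#' conserved exactly: any integer-ms remainder of a fill is absorbed by the
#' last filled beat.
#'
#' @param trace a raw [ibi_trace] with no `corrected` flags set.
#' @param config a [correction_config()].
#' @return the corrected [ibi_trace]; `$meta$correction_skipped` is `TRUE`
#'   when the trace was shorter than the running-median window (a warning
#'   is also raised and the trace returned unchanged), and
#'   `$meta$correction_events` is a data frame logging each event
#'   (`beat_index` in the input trace, `type`, `ibi_before`, `n_out`).
#' @examples
#' cfg <- correction_config(local_window_beats = 5)
#' correct_artefacts(ibi_trace(c(500, 500, 1000, 500, 500)), cfg)$beats$ibi_ms
#' # 500 500 500 500 500 500  (the 1000 ms gap split into two beats)
#' @export
correct_artefacts <- function(trace, config = correction_config()) {
  validate_ibi_trace(trace)
  if (any(trace$beats$corrected))
    stop("trace already carries corrected flags")
  x <- trace$beats$ibi_ms
  n <- length(x)
  if (n < config$local_window_beats) {
    warning("trace shorter than local_window_beats; correction skipped")
    trace$meta$correction_skipped <- TRUE
    return(trace)
  }
  thr <- config$deviation_threshold
  med <- stats::runmed(x, config$local_window_beats, endrule = "median")
  short <- x < (1 - thr) * med | x < config$hard_min_ms
  long <- x > (1 + thr) * med | x > config$hard_max_ms
  valid <- !short & !long

  out_ibi <- numeric(0)
  out_corr <- logical(0)
  events <- list()
  last_valid <- NA_real_  # most recent untouched IBI value
  i <- 1
  while (i <= n) {
    if (short[i]) {
      j <- i
      while (j < n && short[j + 1]) j <- j + 1
      L <- j - i + 1
      s <- sum(x[i:j])
      if (L <= config$max_merge_span && abs(s - med[i]) <= thr * med[i]) {
        out_ibi <- c(out_ibi, s)
        out_corr <- c(out_corr, TRUE)
        events[[length(events) + 1]] <-
          data.frame(beat_index = i, type = "merge", ibi_before = s,
                     n_out = 1L)
      } else {
        # uncorrectable short run: leave in place (physiological-limit
        # screening will flag residual extremes)
        out_ibi <- c(out_ibi, x[i:j])
        out_corr <- c(out_corr, rep(FALSE, L))
      }
      i <- j + 1
    } else if (long[i]) {
      D <- x[i]
      m <- round(D / med[i])  # round half to even: deterministic, scale-free
      if (m < 2) {
        out_ibi <- c(out_ibi, D)
        out_corr <- c(out_corr, TRUE)
        events[[length(events) + 1]] <-
          data.frame(beat_index = i, type = "long_kept", ibi_before = D,
                     n_out = 1L)
      } else {
        k <- i + 1
        while (k <= n && !valid[k]) k <- k + 1
        next_valid <- if (k <= n) x[k] else NA_real_
        fill <- interpolate_gap(D, m, last_valid, next_valid)
        out_ibi <- c(out_ibi, fill)
        out_corr <- c(out_corr, rep(TRUE, m))
        events[[length(events) + 1]] <-
          data.frame(beat_index = i, type = "interpolate", ibi_before = D,
                     n_out = as.integer(m))
      }
      i <- i + 1
    } else {
      out_ibi <- c(out_ibi, x[i])
      out_corr <- c(out_corr, FALSE)
      last_valid <- x[i]
      i <- i + 1
    }
  }
  out <- ibi_trace(out_ibi, corrected = out_corr,
                   individual_id = trace$individual_id,
                   tag_id = trace$tag_id,
                   session_start = trace$session_start,
                   covariates = trace$covariates)
  out$meta$correction_skipped <- FALSE
  out$meta$correction_events <- if (length(events))
    do.call(rbind, events)
  else
    data.frame(beat_index = integer(0), type = character(0),
               ibi_before = numeric(0), n_out = integer(0))
  out
}

# Fill an extreme-long IBI of duration D with m integer-ms beats summing to
# exactly D. Equal (or missing) anchors give a constant fill; differing
# anchors give a ramp with constant integer step between the anchor values,
# shifted by a constant to conserve duration, with any residual (< m ms)
# absorbed by the last beat.
interpolate_gap <- function(D, m, prev_anchor, next_anchor) {
  ramp_ok <- !is.na(prev_anchor) && !is.na(next_anchor) &&
    prev_anchor != next_anchor
  if (ramp_ok) {
    s <- round((next_anchor - prev_anchor) / (m + 1))
    if (s != 0) {
      v <- prev_anchor + s * seq_len(m)
      delta <- round((D - sum(v)) / m)
      v <- v + delta
      v[m] <- v[m] + (D - sum(v))
      if (all(v > 0)) return(v)
    }
  }
  v <- rep(floor(D / m), m)
  v[m] <- v[m] + (D - sum(v))
  v
}
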