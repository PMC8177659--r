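#' Detect flats (runs of identical IBI values)
#'
#' A *flat* is a maximal run of two or more consecutive identical IBI
#' values, the signature of constant interpolation over missing beats.
#' Every beat belonging to a run is flagged `flat = TRUE` (optionally the
#' run head can be left unflagged). Equality defaults to exact comparison,
#' appropriate for integer-ms device data; a tolerance is available for
#' real-valued series, where values are chained (each consecutive pair must
#' agree within tolerance).
#'
#' @param trace an [ibi_trace].
#' @param tolerance_ms non-negative equality tolerance, ms.
#' @param flag_run_head flag the first beat of each run too (default); with
#'   `FALSE` only the second and later beats of a run are flagged.
#' @return a list with `trace` (flags updated; pre-existing flat flags are
#'   replaced) and `runs`, a data frame with one row per maximal run:
#'   `kind`, `start_index` (1-based beat index), `length` (beats),
#'   `step_ms` (always 0 for flats).
#' @examples
#' detect_flats(ibi_trace(c(502, 502, 503)))$runs
#' @export
detect_flats <- function(trace, tolerance_ms = 0, flag_run_head = TRUE) {
  validate_ibi_trace(trace)
  if (tolerance_ms < 0) stop("tolerance_ms must be non-negative")
  x <- trace$beats$ibi_ms
  n <- length(x)
  runs <- empty_runs()
  flag <- rep(FALSE, n)
  if (n >= 2) {
    eq <- abs(diff(x)) <= tolerance_ms
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      i <- starts[k]            # first equal *difference* -> beats i..ends[k]+1
      len <- r$lengths[k] + 1
      runs <- rbind(runs, data.frame(kind = "flat", start_index = i,
                                     length = len, step_ms = 0))
      from <- if (flag_run_head) i else i + 1
      flag[from:(i + len - 1)] <- TRUE
    }
  }
  trace$beats$flat <- flag
  list(trace = trace, runs = runs)
}

#' Detect stairs (runs of identical non-zero successive differences)
#'
#' A *stair* is a maximal run of more than two identical, non-zero
#' differences between successive IBIs - the signature of linear
#' interpolation over missing beats. With the default `min_diffs = 3`
#' ("more than two"), a stair spans at least 4 beats. All beats
#' participating in the run (number of differences + 1) are flagged
#' `stair = TRUE`.
#'
#' @inheritParams detect_flats
#' @param min_diffs minimum number of identical successive differences
#'   (default 3; set 2 for the laxer >=3-beat reading).
#' @return as [detect_flats()]; `step_ms` is the common difference.
#' @examples
#' detect_stairs(ibi_trace(c(800, 790, 780, 770)))$runs  # one run, step -10
#' @export
detect_stairs <- function(trace, tolerance_ms = 0, min_diffs = 3,
                          flag_run_head = TRUE) {
  validate_ibi_trace(trace)
  if (tolerance_ms < 0) stop("tolerance_ms must be non-negative")
  if (min_diffs < 2) stop("min_diffs must be >= 2")
  x <- trace$beats$ibi_ms
  n <- length(x)
  runs <- empty_runs()
  flag <- rep(FALSE, n)
  if (n >= min_diffs + 1) {
    d <- diff(x)
    nz <- abs(d) > tolerance_ms
    same <- c(FALSE, abs(diff(d)) <= tolerance_ms) & nz &
      c(FALSE, nz[-length(nz)])
    # group maximal chains of equal consecutive non-zero differences
    grp_break <- !same
    grp <- cumsum(grp_break)
    for (g in unique(grp[nz])) {
      idx <- which(grp == g & nz)
      if (length(idx) >= min_diffs) {
        i <- idx[1]             # first difference -> beats i .. i+length(idx)
        len <- length(idx) + 1
        runs <- rbind(runs, data.frame(kind = "stair", start_index = i,
                                       length = len,
                                       step_ms = mean(d[idx])))
        from <- if (flag_run_head) i else i + 1
        flag[from:(i + len - 1)] <- TRUE
      }
    }
    if (nrow(runs) > 1) runs <- runs[order(runs$start_index), ]
  }
  trace$beats$stair <- flag
  rownames(runs) <- NULL
  list(trace = trace, runs = runs)
}

empty_runs <- function() {
  data.frame(kind = character(0), start_index = integer(0),
             length = integer(0), step_ms = numeric(0))
}

#' Flag beats outside physiological heart-rate limits
#'
#' Marks `out_of_bounds = TRUE` for any IBI implying a heart rate below
#' `min_bpm` or above `max_bpm`. The defaults (20-200 bpm, i.e. IBIs
#' outside 300-3000 ms) span the plausible on-land range for grey seals,
#' deliberately wider than typical human settings.
#'
#' @param trace an [ibi_trace].
#' @param min_bpm,max_bpm acceptable heart-rate range, beats per minute.
#' @return the trace with `out_of_bounds` flags replaced.
#' @export
apply_physiological_limits <- function(trace, min_bpm = 20, max_bpm = 200) {
  validate_ibi_trace(trace)
  if (min_bpm <= 0 || min_bpm >= max_bpm)
    stop("need 0 < min_bpm < max_bpm")
  x <- trace$beats$ibi_ms
  trace$beats$out_of_bounds <- x > 60000 / min_bpm | x < 60000 / max_bpm
  trace
}

#' Annotate a trace with flats, stairs and physiological limits
#'
#' Convenience wrapper running [detect_flats()], [detect_stairs()] and
#' [apply_physiological_limits()] in sequence. Flats and stairs are
#' annotations only: they are flagged, never altered.
#'
#' @inheritParams detect_stairs
#' @param min_bpm,max_bpm passed to [apply_physiological_limits()].
#' @return a list with `trace` (all three flag sets updated) and `runs`
#'   (flat and stair runs combined, ordered by start index).
#' @export
annotate_trace <- function(trace, tolerance_ms = 0, min_diffs = 3,
                           flag_run_head = TRUE,
                           min_bpm = 20, max_bpm = 200) {
  fl <- detect_flats(trace, tolerance_ms, flag_run_head)
  st <- detect_stairs(fl$trace, tolerance_ms, min_diffs, flag_run_head)
  out <- apply_physiological_limits(st$trace, min_bpm, max_bpm)
  runs <- rbind(fl$runs, st$runs)
  if (nrow(runs) > 1) runs <- runs[order(runs$start_index), ]
  rownames(runs) <- NULL
  list(trace = out, runs = runs)
}
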