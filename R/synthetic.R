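#' Generate a clean synthetic IBI trace
#'
#' Emulates a resting-seal IBI series as an AR(1) Gaussian process around a
#' mean interval, optionally with a sinusoidal respiratory-sinus-arrhythmia
#' (RSA) component, rounded to integer milliseconds as a 1000 Hz device
#' would report. The AR(1) innovation SD is chosen from the closed form so
#' that, with `rsa_amplitude_ms = 0`, the process rMSSD
#' `sqrt(2 * sigma_x^2 * (1 - phi))` (with stationary variance
#' `sigma_x^2 = sigma_eps^2 / (1 - phi^2)`) equals `target_rmssd_ms`.
#'
#' Defaults describe the resting range observed in lactating grey seals:
#' mean heart rates of roughly 40-125 bpm (mean IBI 480-1500 ms) and rMSSD
#' of 60-110 ms.
#'
#' @param duration_s trace duration in seconds (beats are generated until
#'   the cumulative IBI sum reaches it).
#' @param mean_ibi_ms mean inter-beat interval, ms.
#' @param target_rmssd_ms target rMSSD of the AR component, ms.
#' @param ar_coefficient lag-1 autocorrelation phi in \[0, 1).
#' @param rsa_amplitude_ms amplitude of the sinusoidal RSA component, ms.
#' @param rsa_period_s period of the RSA component, s.
#' @param seed integer seed; identical seeds give identical traces.
#' @param individual_id,tag_id,covariates passed to [ibi_trace()].
#' @return an [ibi_trace] with all flags false.
#' @examples
#' tr <- generate_clean_trace(300, mean_ibi_ms = 700, target_rmssd_ms = 90,
#'                            seed = 1)
#' rmssd(tr)
#' @export
generate_clean_trace <- function(duration_s, mean_ibi_ms = 800,
                                 target_rmssd_ms = 90,
                                 ar_coefficient = 0.5,
                                 rsa_amplitude_ms = 0, rsa_period_s = 10,
                                 seed = 1,
                                 individual_id = "", tag_id = "",
                                 covariates = list()) {
  if (duration_s <= 0) stop("duration_s must be positive")
  if (mean_ibi_ms <= 0) stop("mean_ibi_ms must be positive")
  if (target_rmssd_ms < 0) stop("target_rmssd_ms must be non-negative")
  if (ar_coefficient < 0 || ar_coefficient >= 1)
    stop("ar_coefficient must be in [0, 1)")
  if (rsa_amplitude_ms < 0) stop("rsa_amplitude_ms must be non-negative")
  if (rsa_period_s <= 0) stop("rsa_period_s must be positive")
  phi <- ar_coefficient
  # closed-form inversion: rMSSD^2 = 2 * sigma_x^2 * (1 - phi)
  sigma_x2 <- target_rmssd_ms^2 / (2 * (1 - phi))
  sigma_eps2 <- sigma_x2 * (1 - phi^2)
  if (sigma_eps2 < 0) stop("parameters imply negative innovation variance")

  with_seed(seed, {
    n_guess <- ceiling(duration_s * 1000 / mean_ibi_ms * 1.25) + 20
    repeat {
      eps <- stats::rnorm(n_guess, 0, sqrt(sigma_eps2))
      x <- as.numeric(stats::filter(eps, phi, method = "recursive",
                                    init = stats::rnorm(1, 0, sqrt(sigma_x2))))
      if (rsa_amplitude_ms > 0) {
        ibi <- numeric(n_guess)
        t_ms <- 0
        for (k in seq_len(n_guess)) {
          rsa <- rsa_amplitude_ms * sin(2 * pi * (t_ms / 1000) / rsa_period_s)
          ibi[k] <- max(300, round(mean_ibi_ms + rsa + x[k]))
          t_ms <- t_ms + ibi[k]
        }
      } else {
        ibi <- pmax(300, round(mean_ibi_ms + x))
      }
      if (sum(ibi) >= duration_s * 1000) break
      n_guess <- ceiling(n_guess * 1.5)
    }
    n <- which(cumsum(ibi) >= duration_s * 1000)[1]
    ibi_trace(ibi[seq_len(n)], individual_id = individual_id,
              tag_id = tag_id, covariates = covariates)
  })
}

# run code with a local RNG state seeded by `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Corrupt a clean trace with realistic telemetry error processes
#'
#' Applies, in order: transmission-dropout bursts (all R peaks inside a
#' burst window are lost, leaving one long IBI spanning the gap, exactly as
#' a receiver sees a gap between the last and next received beats), missed
#' beats (an undetected R peak merges its IBI into the next) and spurious
#' beats (an interval split at a uniform fraction in (0.2, 0.8), so the two
#' halves are individually detectable as short IBIs). Elapsed time is
#' conserved exactly: operations delete or insert R peaks and IBIs are
#' re-derived from the surviving peak times (integer ms).
#'
#' @param trace a clean [ibi_trace] (no flags set).
#' @param p_missed_beat per-beat probability of an undetected beat.
#' @param p_spurious_beat per-interval probability of a spurious extra beat.
#' @param dropout_rate_per_min expected number of dropout bursts per minute
#'   (Poisson).
#' @param dropout_mean_s mean burst length, s (exponential).
#' @param seed integer seed.
#' @return a list with `device` (the corrupted [ibi_trace], integer-ms IBIs)
#'   and `origin`, a character vector over output beats with values
#'   `"genuine"`, `"merged"`, `"split"` or `"gap"` (gap takes precedence
#'   over merged when both apply to an interval).
#' @export
corrupt_trace <- function(trace, p_missed_beat = 0, p_spurious_beat = 0,
                          dropout_rate_per_min = 0, dropout_mean_s = 3,
                          seed = 1) {
  validate_ibi_trace(trace)
  b <- trace$beats
  if (any(b$corrected | b$flat | b$stair | b$out_of_bounds))
    stop("corrupt_trace expects a clean trace with no QC flags set")
  if (p_missed_beat < 0 || p_missed_beat >= 1 ||
      p_spurious_beat < 0 || p_spurious_beat >= 1)
    stop("beat error probabilities must be in [0, 1)")
  if (dropout_rate_per_min < 0 || dropout_mean_s <= 0)
    stop("dropout_rate_per_min must be >= 0 and dropout_mean_s > 0")
  n <- nrow(b)
  if (n < 2) stop("trace too short to corrupt")

  with_seed(seed, {
    # R-peak times in integer ms; peak k ends IBI k. The session origin
    # (time 0) and the final peak are always retained.
    peaks <- round(cumsum(b$ibi_ms))
    total_s <- peaks[n] / 1000
    status <- rep("genuine", n)  # per-peak fate for peaks 1..n

    # dropout bursts: lose every interior peak inside [start, start+len)
    n_bursts <- stats::rpois(1, dropout_rate_per_min * total_s / 60)
    if (n_bursts > 0) {
      starts <- stats::runif(n_bursts, 0, total_s) * 1000
      lens <- stats::rexp(n_bursts, 1 / dropout_mean_s) * 1000
      for (i in seq_len(n_bursts)) {
        hit <- which(peaks >= starts[i] & peaks < starts[i] + lens[i])
        hit <- setdiff(hit, n)
        status[hit] <- "gap"
      }
    }

    # missed beats: each still-present interior peak lost with p_missed
    interior <- which(status == "genuine")
    interior <- setdiff(interior, n)
    if (p_missed_beat > 0 && length(interior)) {
      lost <- interior[stats::runif(length(interior)) < p_missed_beat]
      status[lost] <- "missed"
    }

    keep <- status == "genuine"
    keep[n] <- TRUE
    kept_times <- peaks[keep]
    # origin of each surviving interval: what was lost inside it
    lost_status <- status[!keep]
    lost_times <- peaks[!keep]
    origin <- rep("genuine", length(kept_times))
    if (length(lost_times)) {
      slot <- findInterval(lost_times, c(0, kept_times), left.open = TRUE)
      for (s in unique(slot)) {
        kinds <- lost_status[slot == s]
        origin[s] <- if (any(kinds == "gap")) "gap" else "merged"
      }
    }

    # spurious beats: split surviving genuine intervals
    if (p_spurious_beat > 0) {
      bounds <- c(0, kept_times)
      cand <- which(origin == "genuine")
      split_at <- cand[stats::runif(length(cand)) < p_spurious_beat]
      if (length(split_at)) {
        u <- stats::runif(length(split_at), 0.2, 0.8)
        new_times <- round(bounds[split_at] +
                           u * (bounds[split_at + 1] - bounds[split_at]))
        all_times <- c(kept_times, new_times)
        all_origin <- c(origin, rep("split", length(new_times)))
        ord <- order(all_times)
        kept_times <- all_times[ord]
        origin <- all_origin[ord]
        # both halves of a split interval are "split"
        origin[match(new_times, kept_times) + 1] <- "split"
      }
    }

    ibi <- diff(c(0, kept_times))
    if (any(ibi <= 0)) {  # degenerate split rounding; drop zero-length IBIs
      keep2 <- ibi > 0
      kept_times <- kept_times[keep2]
      origin <- origin[keep2]
      ibi <- diff(c(0, kept_times))
    }
    device <- ibi_trace(ibi, individual_id = trace$individual_id,
                        tag_id = trace$tag_id,
                        session_start = trace$session_start,
                        covariates = trace$covariates)
    list(device = device, origin = origin)
  })
}

#' Generate a paired reference IBI stream
#'
#' Emulates an independent reference measurement of the same heartbeats
#' (e.g. IBIs read off a concurrent ECG): every R-peak time is perturbed by
#' independent Gaussian timing noise and IBIs are recomputed from the
#' perturbed times, optionally with a constant additive bias on all IBIs.
#' Note the variance algebra: with timing noise SD `s` on both endpoints of
#' an interval, paired IBI differences (test minus reference) have SD
#' `sqrt(2) * s`.
#'
#' @param trace an [ibi_trace].
#' @param jitter_sd_ms per-peak timing noise SD, ms.
#' @param seed integer seed.
#' @param bias_ms systematic test-minus-reference difference, ms; subtracted
#'   from every reference IBI so that paired differences centre on it.
#' @return an [ibi_trace] with real-valued IBIs (reference measurements are
#'   not quantised to device resolution).
#' @export
generate_reference_pair <- function(trace, jitter_sd_ms = 0, seed = 1,
                                    bias_ms = 0) {
  validate_ibi_trace(trace)
  if (jitter_sd_ms < 0) stop("jitter_sd_ms must be non-negative")
  b <- trace$beats
  with_seed(seed, {
    times <- c(0, cumsum(b$ibi_ms)) +
      c(0, stats::rnorm(nrow(b), 0, jitter_sd_ms))
    ibi <- diff(times) - bias_ms  # reference = test - bias => test - ref = bias
    if (any(ibi <= 0))
      stop("jitter too large relative to IBIs: non-positive reference IBI")
    ibi_trace(ibi, individual_id = trace$individual_id,
              tag_id = trace$tag_id, session_start = trace$session_start,
              covariates = trace$covariates)
  })
}

#' Generate a synthetic per-second activity series
#'
#' Alternating Inactive/Active bouts with exponentially distributed
#' lengths. Inactive bouts have mean `bout_mean_s`; Active bout means are
#' scaled so the long-run Active fraction equals `p_active`.
#'
#' @param duration_s series length, s.
#' @param bout_mean_s mean Inactive bout length, s.
#' @param p_active long-run fraction of seconds labelled Active, in \[0,1\].
#' @param seed integer seed.
#' @return an [activity_series] covering seconds `0:(duration_s - 1)`.
#' @export
generate_activity <- function(duration_s, bout_mean_s = 60, p_active = 0.3,
                              seed = 1) {
  if (p_active < 0 || p_active > 1) stop("p_active must be in [0, 1]")
  if (duration_s <= 0) stop("duration_s must be positive")
  secs <- seq.int(0, floor(duration_s) - 1)
  if (p_active == 0)
    return(activity_series(secs, rep("Inactive", length(secs))))
  if (p_active == 1)
    return(activity_series(secs, rep("Active", length(secs))))
  mean_inactive <- bout_mean_s
  mean_active <- bout_mean_s * p_active / (1 - p_active)
  with_seed(seed, {
    t_end <- numeric(0)
    lab <- character(0)
    t <- 0
    state <- if (stats::runif(1) < p_active) "Active" else "Inactive"
    while (t < duration_s) {
      len <- stats::rexp(1, 1 / if (state == "Active") mean_active
                              else mean_inactive)
      t <- t + len
      t_end <- c(t_end, t)
      lab <- c(lab, state)
      state <- if (state == "Active") "Inactive" else "Active"
    }
    idx <- findInterval(secs, c(0, t_end), left.open = FALSE,
                        rightmost.closed = TRUE)
    idx <- pmin(pmax(idx, 1), length(lab))
    activity_series(secs, lab[idx])
  })
}

#' Select an error-free synthetic trace
#'
#' Repeatedly generates clean traces (varying the seed offset) until one
#' contains no detectable flats, stairs or out-of-bounds beats - the
#' synthetic analogue of selecting "perfect" field traces with zero
#' artefacts before an error-injection experiment. Integer-ms rounding makes
#' chance equal-neighbour IBIs (length-2 flats) common enough that rejection
#' sampling is needed.
#'
#' @inheritParams generate_clean_trace
#' @param max_tries candidate traces to examine before giving up.
#' @param ... further arguments to [generate_clean_trace()].
#' @return an [ibi_trace] with zero detected flats/stairs.
#' @export
select_error_free_trace <- function(duration_s, seed = 1, max_tries = 200,
                                    ...) {
  for (k in seq_len(max_tries)) {
    tr <- generate_clean_trace(duration_s, seed = seed + (k - 1) * 1000L, ...)
    fl <- detect_flats(tr)
    st <- detect_stairs(tr)
    lim <- apply_physiological_limits(tr)
    if (nrow(fl$runs) == 0 && nrow(st$runs) == 0 &&
        !any(lim$beats$out_of_bounds))
      return(tr)
  }
  stop("no error-free trace found in ", max_tries, " tries; ",
       "consider a shorter duration or larger target rMSSD")
}
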