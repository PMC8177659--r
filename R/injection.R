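#' Inject a single flat step into an IBI sequence
#'
#' Copies a uniformly chosen IBI onto its successor, creating (at least)
#' two consecutive identical values.
#'
#' @param ibis numeric IBI vector, length >= 2.
#' @param index optional 1-based index `i` in `1:(n-1)`; drawn uniformly
#'   when omitted (consuming one RNG draw).
#' @return the modified vector.
#' @export
inject_flat_step <- function(ibis, index = NULL) {
  n <- length(ibis)
  if (n < 2) stop("need at least 2 beats")
  i <- if (is.null(index)) sample.int(n - 1L, 1L) else as.integer(index)
  if (i < 1 || i > n - 1) stop("index out of range")
  ibis[i + 1L] <- ibis[i]
  ibis
}

#' Inject a single stair block into an IBI sequence
#'
#' Chooses two anchor indices `i < j` with `j - i >= 2` (uniformly over
#' valid pairs when omitted) and replaces every intervening IBI with the
#' linear interpolation between the anchor values. Fill values are kept
#' real-valued so successive differences are exactly equal; equal anchors
#' degenerate to a flat block.
#'
#' @param ibis numeric IBI vector, length >= 4.
#' @param i,j optional anchor indices.
#' @return the modified vector.
#' @examples
#' inject_stair_block(c(600, 0, 0, 660), i = 1, j = 4)  # 600 620 640 660
#' @export
inject_stair_block <- function(ibis, i = NULL, j = NULL) {
  n <- length(ibis)
  if (n < 4) stop("need at least 4 beats")
  if (is.null(i) || is.null(j)) {
    repeat {
      p <- sort(sample.int(n, 2L))
      if (p[2] - p[1] >= 2) break
    }
    i <- p[1]; j <- p[2]
  }
  if (i >= j || j - i < 2 || i < 1 || j > n) stop("need 1 <= i < j <= n, j - i >= 2")
  step <- (ibis[j] - ibis[i]) / (j - i)
  ibis[(i + 1):(j - 1)] <- ibis[i] + step * seq_len(j - i - 1)
  ibis
}

# fraction of beats inside runs of >= 2 equal consecutive IBIs
flat_fraction <- function(x) {
  e <- diff(x) == 0
  mean(c(e, FALSE) | c(FALSE, e))
}

#' Monte-Carlo study of rMSSD bias from injected flats or stairs
#'
#' Repeatedly contaminates a clean trace with progressively more flats
#' (IBI-copy steps) or stairs (linear-interpolation blocks), recording
#' after every step the realised contamination proportion and the rMSSD of
#' the copy. For flats the proportion is the fraction of beats *detected*
#' in flat runs (injections can merge into longer runs, and contamination
#' is a state of the trace, not a count of actions); for stairs it is the
#' cumulative fraction of beats replaced by interpolation (blocks whose
#' anchors happen to be equal still contaminate the trace even though the
#' fill degenerates to a flat shape). Results across runs are pooled into
#' proportion bins.
#'
#' Schedules per run: *flats* take `floor(n/2)` random copy steps and then
#' record the absorbing state of the copy process (all values equal to the
#' first IBI - the almost-sure limit of continuing the recursion), so every
#' run realises the 100%-contamination endpoint, where rMSSD is exactly 0.
#' *Stairs* inject random blocks until the replaced fraction saturates
#' (reaches `max_proportion`, or the iteration cap) and finish with the
#' maximal block spanning the whole trace, so the 100%-contamination
#' endpoint is the single full ramp, whose rMSSD
#' `|IBI_n - IBI_1| / (n - 1)` is effectively 0 on the HRV scale.
#'
#' @param trace a clean [ibi_trace]: zero corrected/flat/stair flags (use
#'   [select_error_free_trace()] to obtain one).
#' @param kind `"flat"` or `"stair"`.
#' @param n_runs Monte-Carlo runs (1000 reproduces the reference study
#'   size).
#' @param seed integer seed; identical seeds give identical curves.
#' @param bin_width proportion bin width.
#' @param max_proportion replaced-beat fraction at which stair-block
#'   accumulation stops (coverage beyond this point stalls while waiting
#'   for rarely-hit positions); the run then ends with the full-span
#'   block.
#' @param max_iter_stairs safety cap on stair blocks per run.
#' @return an `injection_curve`: list with `kind`, `bins` (data frame
#'   `proportion` = bin upper edge, `mean_rmssd_ms`, `lo`/`hi` = 2.5 and
#'   97.5 percentiles over pooled observations, `n_obs`), `base_rmssd_ms`,
#'   `n_runs`, `seed`.
#' @export
run_injection_study <- function(trace, kind = c("flat", "stair"),
                                n_runs = 1000, seed = 1, bin_width = 0.01,
                                max_proportion = 0.95,
                                max_iter_stairs = 500) {
  kind <- match.arg(kind)
  validate_ibi_trace(trace)
  b <- trace$beats
  if (any(b$corrected | b$flat | b$stair))
    stop("injection requires a trace with zero corrected, flat or stair ",
         "flags (an error-free base trace)")
  x0 <- b$ibi_ms
  n <- length(x0)
  if (n < 4) stop("trace too short for injection study")
  base <- rmssd(x0)

  with_seed(seed, {
    props <- list(); vals <- list()
    for (r in seq_len(n_runs)) {
      if (kind == "flat") {
        x <- x0
        steps <- floor(n / 2)
        p <- numeric(steps + 1); v <- numeric(steps + 1)
        idx <- sample.int(n - 1L, steps, replace = TRUE)
        for (s in seq_len(steps)) {
          x[idx[s] + 1L] <- x[idx[s]]
          p[s] <- flat_fraction(x)
          v[s] <- sqrt(mean(diff(x)^2))
        }
        # absorbing state of the copy process: all values equal the first
        x[] <- x[1]
        p[steps + 1] <- flat_fraction(x)
        v[steps + 1] <- sqrt(mean(diff(x)^2))
      } else {
        x <- x0
        replaced <- rep(FALSE, n)
        p <- numeric(0); v <- numeric(0)
        it <- 0
        repeat {
          it <- it + 1
          repeat {
            pr <- sort(sample.int(n, 2L))
            if (pr[2] - pr[1] >= 2) break
          }
          x <- inject_stair_block(x, i = pr[1], j = pr[2])
          replaced[(pr[1] + 1):(pr[2] - 1)] <- TRUE
          p <- c(p, mean(replaced))
          v <- c(v, sqrt(mean(diff(x)^2)))
          if (p[length(p)] >= max_proportion || it >= max_iter_stairs) break
        }
        # finish with the maximal block: the single full-trace ramp,
        # replacing every interior beat
        x <- inject_stair_block(x, i = 1L, j = n)
        replaced[2:(n - 1)] <- TRUE
        p <- c(p, mean(replaced))
        v <- c(v, sqrt(mean(diff(x)^2)))
      }
      props[[r]] <- p
      vals[[r]] <- v
    }
    p_all <- unlist(props)
    v_all <- unlist(vals)
    # bin by upper edge; proportion 0 (never produced by an injection step)
    # is represented by the uncontaminated base value
    bin <- ceiling(round(p_all / bin_width, 9))
    agg <- function(f) vapply(split(v_all, bin), f, numeric(1))
    mean_v <- agg(mean)
    lo <- agg(function(z) stats::quantile(z, 0.025, names = FALSE))
    hi <- agg(function(z) stats::quantile(z, 0.975, names = FALSE))
    n_obs <- vapply(split(v_all, bin), length, numeric(1))
    bins <- data.frame(
      proportion = c(0, as.numeric(names(mean_v)) * bin_width),
      mean_rmssd_ms = c(base, unname(mean_v)),
      lo = c(base, unname(lo)),
      hi = c(base, unname(hi)),
      n_obs = c(n_runs, unname(n_obs)))
    bins <- bins[order(bins$proportion), ]
    rownames(bins) <- NULL
    structure(list(kind = kind, bins = bins, base_rmssd_ms = base,
                   n_runs = n_runs, seed = seed, bin_width = bin_width),
              class = "injection_curve")
  })
}

#' @export
print.injection_curve <- function(x, ...) {
  cat(sprintf("<injection_curve> kind = %s, %d runs, base rMSSD %.1f ms\n",
              x$kind, x$n_runs, x$base_rmssd_ms))
  cat(sprintf("  %d proportion bins (width %.2f), rMSSD %.2f ms at the highest bin\n",
              nrow(x$bins), x$bin_width,
              x$bins$mean_rmssd_ms[nrow(x$bins)]))
  invisible(x)
}

#' Mean rMSSD of an injection curve at a given contamination level
#'
#' Convenience lookup: the binned mean at the bin whose upper edge equals
#' `proportion` (the bin covering `(proportion - bin_width, proportion]`).
#'
#' @param curve an `injection_curve`.
#' @param proportion contamination proportion in (0, 1\].
#' @return mean rMSSD in ms, or `NA` if the bin is empty.
#' @export
curve_at <- function(curve, proportion) {
  stopifnot(inherits(curve, "injection_curve"))
  i <- which(abs(curve$bins$proportion - proportion) < 1e-9)
  if (!length(i)) return(NA_real_)
  curve$bins$mean_rmssd_ms[i]
}
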