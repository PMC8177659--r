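#' Root mean square of successive differences (rMSSD)
#'
#' The time-domain resting-HRV statistic
#' \deqn{\mathrm{rMSSD} = \sqrt{\frac{1}{N-1} \sum_{j=1}^{N-1}
#'   \Delta \mathrm{IBI}_j^2}}
#' where the differences are taken between adjacent IBI values. Beats
#' flagged out-of-bounds are excluded *before* differencing and the
#' exclusion splits the difference chain: no difference is taken across an
#' excluded beat (bridging a gap would create spurious large differences).
#' The divisor is the number of differences actually taken.
#'
#' @param x numeric vector of IBIs in ms, or an [ibi_trace] (whose
#'   `out_of_bounds` flags are then used as `exclude`).
#' @param exclude optional logical vector marking beats to exclude.
#' @return rMSSD in ms; `NA` with a warning when fewer than two usable
#'   adjacent beats remain.
#' @examples
#' rmssd(c(500, 510, 500, 510))  # 10
#' @export
rmssd <- function(x, exclude = NULL) {
  if (inherits(x, "ibi_trace")) {
    exclude <- x$beats$out_of_bounds
    x <- x$beats$ibi_ms
  }
  n <- length(x)
  if (is.null(exclude)) exclude <- rep(FALSE, n)
  stopifnot(length(exclude) == n)
  if (n < 2) {
    warning("fewer than 2 beats: rMSSD undefined")
    return(NA_real_)
  }
  keep <- !exclude
  ok <- keep[-n] & keep[-1]       # difference j uses beats j and j+1
  d <- diff(x)[ok]
  if (length(d) < 1) {
    warning("fewer than 2 usable adjacent beats: rMSSD undefined")
    return(NA_real_)
  }
  sqrt(sum(d^2) / length(d))
}

#' Cross-tabulate device corrections against flats or stairs
#'
#' Builds the 2x2 agreement matrix between the device software's artefact
#' flags (`corrected`) and the package's flat or stair flags, over all
#' beats of one trace or a pooled set of traces. Cells: `a` flagged and
#' corrected, `b` flagged only, `c` corrected only, `d` neither.
#'
#' @param x an [ibi_trace], or a list of traces to pool.
#' @param kind `"flat"` or `"stair"`: which annotation to cross-tabulate.
#' @return a `classification_matrix` object; see
#'   [matrix_percentages()] for the derived percentages.
#' @export
classification_matrix <- function(x, kind = c("flat", "stair")) {
  kind <- match.arg(kind)
  traces <- if (inherits(x, "ibi_trace")) list(x) else x
  a <- b <- c_ <- d <- 0
  for (tr in traces) {
    stopifnot(inherits(tr, "ibi_trace"))
    flg <- tr$beats[[kind]]
    cor <- tr$beats$corrected
    a <- a + sum(flg & cor)
    b <- b + sum(flg & !cor)
    c_ <- c_ + sum(!flg & cor)
    d <- d + sum(!flg & !cor)
  }
  classification_matrix_from_counts(a, b, c_, d, kind)
}

#' Build a classification matrix directly from cell counts
#'
#' @param a flagged (flat/stair) and corrected.
#' @param b flagged, not corrected.
#' @param c not flagged, corrected.
#' @param d neither.
#' @param kind `"flat"` or `"stair"`.
#' @return a `classification_matrix`: list with the cells, marginal totals
#'   (`n_flagged`, `n_corrected`, `n_total`) and `kind`.
#' @export
classification_matrix_from_counts <- function(a, b, c, d,
                                              kind = c("flat", "stair")) {
  kind <- match.arg(kind)
  for (v in c(a, b, c, d)) if (is.na(v) || v < 0) stop("cells must be >= 0")
  structure(list(a = a, b = b, c = c, d = d, kind = kind,
                 n_flagged = a + b, n_corrected = a + c,
                 n_total = a + b + c + d),
            class = "classification_matrix")
}

#' Derived percentages of a classification matrix
#'
#' Three reporting percentages: the share of corrected IBIs that are
#' flagged (`pct_of_corrected_flagged = 100 a/(a+c)`), the share of
#' non-corrected IBIs that are flagged (`pct_of_noncorrected_flagged =
#' 100 b/(b+d)`) and the share of flagged IBIs that were corrected
#' (`pct_of_flagged_corrected = 100 a/(a+b)`). A percentage with a zero
#' denominator is `NA`.
#'
#' @param m a `classification_matrix`.
#' @param rounded round for reporting: 1 decimal place, 2 below 0.1%
#'   (round half to even).
#' @return named numeric vector of the three percentages.
#' @export
matrix_percentages <- function(m, rounded = FALSE) {
  stopifnot(inherits(m, "classification_matrix"))
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  out <- c(pct_of_corrected_flagged = pct(m$a, m$a + m$c),
           pct_of_noncorrected_flagged = pct(m$b, m$b + m$d),
           pct_of_flagged_corrected = pct(m$a, m$a + m$b))
  if (rounded)
    out <- vapply(out, function(p)
      if (is.na(p)) p else round(p, if (p < 0.1) 2 else 1), numeric(1))
  out
}

#' @export
print.classification_matrix <- function(x, ...) {
  lab <- if (x$kind == "flat") c("Flat", "Non-flat") else
    c("Stair", "Non-stair")
  m <- matrix(c(x$a, x$b, x$a + x$b, x$c, x$d, x$c + x$d,
                x$a + x$c, x$b + x$d, x$n_total),
              nrow = 3, byrow = TRUE,
              dimnames = list(c(lab, "Total"),
                              c("Corrected", "Non-corrected", "Total")))
  cat(sprintf("<classification_matrix: %s vs corrected, n = %d>\n",
              x$kind, x$n_total))
  print(m)
  p <- matrix_percentages(x, rounded = TRUE)
  cat(sprintf("  %% of corrected flagged: %s | %% of flagged corrected: %s | %% of non-corrected flagged: %s\n",
              p[1], p[3], p[2]))
  invisible(x)
}

#' Temporally match beats between two IBI streams
#'
#' Greedy nearest-neighbour matching on beat times for streams sharing a
#' common clock (synchronised to well under one inter-beat interval).
#' Candidate pairs within `max_offset_s` are accepted in order of
#' increasing time offset; each beat is used at most once; unmatched beats
#' are dropped and counted.
#'
#' @param test,reference two [ibi_trace]s on the same session clock.
#' @param max_offset_s maximum |time difference| for a valid pair, s.
#' @return a data frame with `test_index`, `ref_index`, `test_ibi_ms`,
#'   `ref_ibi_ms`, `dt_s`, ordered by test beat; attributes
#'   `n_test_unmatched` and `n_ref_unmatched` carry the dropped counts. A
#'   warning is raised when no pairs exist.
#' @export
match_beats <- function(test, reference, max_offset_s = 0.25) {
  validate_ibi_trace(test)
  validate_ibi_trace(reference)
  tt <- test$beats$beat_time_s
  rt <- reference$beats$beat_time_s
  cand_i <- integer(0); cand_j <- integer(0); cand_dt <- numeric(0)
  if (length(tt) && length(rt)) {
    pos <- findInterval(tt, rt)
    for (off in 0:1) {
      j <- pos + off
      okj <- j >= 1 & j <= length(rt)
      dt <- abs(tt[okj] - rt[j[okj]])
      sel <- dt <= max_offset_s
      cand_i <- c(cand_i, which(okj)[sel])
      cand_j <- c(cand_j, j[okj][sel])
      cand_dt <- c(cand_dt, dt[sel])
    }
  }
  ord <- order(cand_dt)
  used_t <- rep(FALSE, length(tt))
  used_r <- rep(FALSE, length(rt))
  pi <- integer(0); pj <- integer(0); pdt <- numeric(0)
  for (k in ord) {
    i <- cand_i[k]; j <- cand_j[k]
    if (!used_t[i] && !used_r[j]) {
      used_t[i] <- TRUE; used_r[j] <- TRUE
      pi <- c(pi, i); pj <- c(pj, j); pdt <- c(pdt, cand_dt[k])
    }
  }
  if (!length(pi)) warning("no overlapping beats within max_offset_s")
  o <- order(pi)
  out <- data.frame(test_index = pi[o], ref_index = pj[o],
                    test_ibi_ms = test$beats$ibi_ms[pi[o]],
                    ref_ibi_ms = reference$beats$ibi_ms[pj[o]],
                    dt_s = pdt[o])
  attr(out, "n_test_unmatched") <- sum(!used_t)
  attr(out, "n_ref_unmatched") <- sum(!used_r)
  out
}

#' Bland-Altman agreement between paired IBI measurements
#'
#' Computes the mean difference (bias), the 95% limits of agreement (bias
#' +/- 1.96 SD of the differences) and their 95% confidence intervals using
#' the classic approximations: CI of the bias from `sd/sqrt(n)` with a t
#' quantile, CI of each limit from `sd * sqrt(3/n)`.
#'
#' @param test,reference paired measurements (equal length, >= 3), ms; or
#'   `test` may be the pair data frame from [match_beats()].
#' @return an object of class `bland_altman`: `n_pairs`, `bias_ms`,
#'   `sd_diff_ms`, `loa_lower_ms`, `loa_upper_ms`, `ci_bias`,
#'   `ci_loa_lower`, `ci_loa_upper` (each CI a length-2 vector).
#' @examples
#' ba <- bland_altman(c(502, 498), c(500, 500))
#' ba$loa_upper_ms  # 5.5437
#' @export
bland_altman <- function(test, reference = NULL) {
  if (is.data.frame(test) && is.null(reference)) {
    reference <- test$ref_ibi_ms
    test <- test$test_ibi_ms
  }
  stopifnot(length(test) == length(reference))
  d <- test - reference
  n <- length(d)
  if (n < 2) stop("need at least 2 pairs")
  bias <- mean(d)
  s <- stats::sd(d)
  tq <- stats::qt(0.975, n - 1)
  loa <- bias + c(-1, 1) * 1.96 * s
  se_bias <- s / sqrt(n)
  se_loa <- s * sqrt(3 / n)
  structure(list(n_pairs = n, bias_ms = bias, sd_diff_ms = s,
                 loa_lower_ms = loa[1], loa_upper_ms = loa[2],
                 ci_bias = bias + c(-1, 1) * tq * se_bias,
                 ci_loa_lower = loa[1] + c(-1, 1) * tq * se_loa,
                 ci_loa_upper = loa[2] + c(-1, 1) * tq * se_loa),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d pairs\n", x$n_pairs))
  cat(sprintf("  bias %.2f ms (95%% CI %.2f to %.2f)\n",
              x$bias_ms, x$ci_bias[1], x$ci_bias[2]))
  cat(sprintf("  limits of agreement %.2f to %.2f ms\n",
              x$loa_lower_ms, x$loa_upper_ms))
  cat(sprintf("    lower LoA CI %.2f to %.2f; upper LoA CI %.2f to %.2f\n",
              x$ci_loa_lower[1], x$ci_loa_lower[2],
              x$ci_loa_upper[1], x$ci_loa_upper[2]))
  invisible(x)
}
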