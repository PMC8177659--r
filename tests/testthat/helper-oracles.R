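# Independent brute-force oracles used to check the fast implementations.

# all maximal runs of >= 2 equal consecutive values, by exhaustive interval
# enumeration
oracle_flat_runs <- function(x) {
  n <- length(x)
  out <- list()
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (all(x[i:j] == x[i]) &&
            (i == 1 || x[i - 1] != x[i]) &&
            (j == n || x[j + 1] != x[i])) {
          out[[length(out) + 1]] <-
            data.frame(start_index = i, length = j - i + 1)
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(start_index = integer(0), length = integer(0))
}

# all maximal runs of >= min_diffs equal non-zero successive differences
oracle_stair_runs <- function(x, min_diffs = 3) {
  d <- diff(x)
  m <- length(d)
  out <- list()
  if (m >= min_diffs) {
    for (i in 1:(m - min_diffs + 1)) {
      for (j in (i + min_diffs - 1):m) {
        if (all(d[i:j] == d[i]) && d[i] != 0 &&
            (i == 1 || d[i - 1] != d[i]) &&
            (j == m || d[j + 1] != d[i])) {
          out[[length(out) + 1]] <-
            data.frame(start_index = i, length = j - i + 2,
                       step_ms = d[i])
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(start_index = integer(0), length = integer(0),
               step_ms = numeric(0))
}

# beat flags implied by a run table
runs_to_flags <- function(runs, n) {
  flag <- rep(FALSE, n)
  for (k in seq_len(nrow(runs)))
    flag[runs$start_index[k]:(runs$start_index[k] + runs$length[k] - 1)] <- TRUE
  flag
}

# direct evaluation of the rMSSD formula, no exclusions
oracle_rmssd <- function(x) {
  s <- 0
  for (j in 1:(length(x) - 1)) s <- s + (x[j + 1] - x[j])^2
  sqrt(s / (length(x) - 1))
}

# every integer sequence of length 1..max_len over the given alphabet
all_sequences <- function(alphabet, max_len) {
  out <- list()
  for (len in 1:max_len) {
    g <- do.call(expand.grid, rep(list(alphabet), len))
    for (r in seq_len(nrow(g))) out[[length(out) + 1]] <- as.numeric(g[r, ])
  }
  out
}

random_ibis <- function(n, lo = 495, hi = 505) sample(lo:hi, n, replace = TRUE)
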