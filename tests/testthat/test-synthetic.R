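test_that("clean-trace generation is deterministic and hits the target rMSSD", {
  a <- generate_clean_trace(300, 700, 90, 0.5, seed = 11)
  b <- generate_clean_trace(300, 700, 90, 0.5, seed = 11)
  expect_identical(a$beats, b$beats)
  c <- generate_clean_trace(300, 700, 90, 0.5, seed = 12)
  expect_false(identical(a$beats$ibi_ms, c$beats$ibi_ms))

  # zero variability: constant trace
  z <- generate_clean_trace(60, 800, 0, 0, seed = 1)
  expect_true(all(z$beats$ibi_ms == 800))
  expect_equal(rmssd(z), 0)

  # white-noise closed form sqrt(2 sigma^2): sample rMSSD within 5% of
  # target when averaged over seeds (3000 beats each)
  vals <- vapply(1:20, function(s)
    rmssd(generate_clean_trace(2100, 700, 100, 0, seed = s)), numeric(1))
  expect_lt(abs(mean(vals) - 100) / 100, 0.05)

  # AR(1) closed form sqrt(2 sigma_x^2 (1 - phi)) holds too
  vals <- vapply(1:20, function(s)
    rmssd(generate_clean_trace(2100, 700, 100, 0.6, seed = s)), numeric(1))
  expect_lt(abs(mean(vals) - 100) / 100, 0.05)
})

test_that("RSA component adds a periodic term without breaking validity", {
  tr <- generate_clean_trace(300, 700, 50, 0.3, rsa_amplitude_ms = 40,
                             rsa_period_s = 10, seed = 4)
  expect_silent(validate_ibi_trace(tr))
  # RSA inflates successive variability above the AR-only target
  tr0 <- generate_clean_trace(300, 700, 50, 0.3, seed = 4)
  expect_gt(rmssd(tr), rmssd(tr0))
})

test_that("corruption with zero rates is the identity", {
  tr <- generate_clean_trace(120, 700, 90, 0.5, seed = 2)
  out <- corrupt_trace(tr, seed = 5)
  expect_equal(out$device$beats$ibi_ms, round(tr$beats$ibi_ms))
  expect_true(all(out$origin == "genuine"))
})

test_that("corruption conserves elapsed time and reuses original peak times", {
  for (s in 1:5) {
    tr <- generate_clean_trace(300, 650, 80, 0.5, seed = s)
    out <- corrupt_trace(tr, p_missed_beat = 0.03, p_spurious_beat = 0.03,
                         dropout_rate_per_min = 1, dropout_mean_s = 3,
                         seed = s + 100)
    expect_equal(sum(out$device$beats$ibi_ms), sum(tr$beats$ibi_ms))
    expect_equal(length(out$origin), n_beats(out$device))
    # beats not involved in a split end at original peak times (merges and
    # gaps only delete peaks), so merged IBIs are exact sums of originals
    orig_peaks <- round(cumsum(tr$beats$ibi_ms))
    dev_peaks <- round(cumsum(out$device$beats$ibi_ms))
    expect_true(all(dev_peaks[out$origin != "split"] %in% orig_peaks))
    expect_true(all(c("merged", "gap", "split") %in% out$origin))
  }
})

test_that("merged-beat count matches the binomial expectation", {
  tr <- generate_clean_trace(600, 600, 70, 0.5, seed = 3)
  n <- n_beats(tr)
  p <- 0.02
  counts <- vapply(1:50, function(s) {
    out <- corrupt_trace(tr, p_missed_beat = p, seed = s)
    sum(out$origin == "merged")
  }, numeric(1))
  expected <- p * (n - 1)   # interior peaks eligible
  tol <- 3 * sqrt(p * (1 - p) * (n - 1) / 50)
  expect_lt(abs(mean(counts) - expected), tol)
})

test_that("reference pair reproduces the paired-difference variance algebra", {
  tr <- generate_clean_trace(120, 700, 90, 0.5, seed = 6)
  ref <- generate_reference_pair(tr, jitter_sd_ms = 0, seed = 1)
  expect_equal(ref$beats$ibi_ms, tr$beats$ibi_ms)

  ref <- generate_reference_pair(tr, jitter_sd_ms = 0, seed = 1,
                                 bias_ms = 0.9)
  expect_equal(tr$beats$ibi_ms - ref$beats$ibi_ms,
               rep(0.9, n_beats(tr)))

  # jitter on both interval endpoints: diff SD = sqrt(2) * jitter
  tr <- generate_clean_trace(2500, 700, 90, 0.5, seed = 7)
  sds <- vapply(1:10, function(s) {
    ref <- generate_reference_pair(tr, jitter_sd_ms = 4, seed = s)
    sd(tr$beats$ibi_ms - ref$beats$ibi_ms)
  }, numeric(1))
  expect_lt(abs(mean(sds) - sqrt(2) * 4) / (sqrt(2) * 4), 0.1)
})

test_that("synthetic activity matches the requested long-run fraction", {
  a0 <- generate_activity(500, p_active = 0, seed = 1)
  expect_true(all(a0$label == "Inactive"))
  a1 <- generate_activity(500, p_active = 1, seed = 1)
  expect_true(all(a1$label == "Active"))
  expect_equal(a1$second, 0:499)

  a <- generate_activity(1e5, bout_mean_s = 60, p_active = 0.3, seed = 2)
  expect_lt(abs(mean(a$label == "Active") - 0.3), 0.03)
  expect_identical(generate_activity(1000, 60, 0.3, seed = 9),
                   generate_activity(1000, 60, 0.3, seed = 9))
})

test_that("error-free trace selection yields zero detectable artefacts", {
  tr <- select_error_free_trace(300, seed = 21, mean_ibi_ms = 700,
                                target_rmssd_ms = 100)
  expect_equal(nrow(detect_flats(tr)$runs), 0)
  expect_equal(nrow(detect_stairs(tr)$runs), 0)
})
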