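test_that("window assignment uses half-open 5-min intervals and drops the partial tail", {
  # 600 s of constant 500 ms beats -> two full windows; the beat landing
  # exactly on the 300 s boundary opens window 2, and the final beat at
  # exactly 600 s falls outside the covered span
  tr <- ibi_trace(rep(500, 1200))
  w <- assign_windows(tr)
  expect_equal(sum(w == 1, na.rm = TRUE), 599)
  expect_equal(sum(w == 2, na.rm = TRUE), 600)
  expect_equal(sum(is.na(w)), 1)

  # 8 minutes -> one full window, the 3-min remainder dropped
  tr <- ibi_trace(rep(500, 960))
  w <- assign_windows(tr)
  expect_equal(max(w, na.rm = TRUE), 1)
  expect_equal(sum(is.na(w)), 361)

  # a beat at exactly 300.0 s opens the second window (half-open intervals)
  tr <- ibi_trace(rep(500, 1320))  # 660 s total
  w <- assign_windows(tr)
  expect_equal(tr$beats$beat_time_s[600], 300)
  expect_equal(w[600], 2L)
  expect_equal(w[599], 1L)
})

test_that("every beat of a fully covered span appears in exactly one window", {
  set.seed(5)
  tr <- generate_clean_trace(910, 700, 80, 0.5, seed = 31)
  w <- assign_windows(tr)
  t <- tr$beats$beat_time_s
  full <- floor(t[length(t)] / 300)
  in_span <- t < full * 300
  expect_true(all(!is.na(w[in_span])))
  expect_true(all(is.na(w[!in_span])))
  for (k in seq_len(full)) {
    idx <- which(w == k)
    expect_true(all(t[idx] >= (k - 1) * 300 & t[idx] < k * 300))
  }
})

test_that("activity matching picks the label of the containing second", {
  act <- activity_series(c(12L, 14L), c("Active", "Inactive"))
  tr <- ibi_trace(c(12400, 1600, 1000), beat_time_s = c(12.4, 14.0, 15.0))
  tr <- match_activity(tr, act)
  expect_equal(tr$beats$activity, c("Active", "Inactive", "Unknown"))
})

test_that("matched Active fraction tracks the generator's p_active", {
  # renewal-process variance of the realised fraction needs a long series
  tr <- generate_clean_trace(20000, 700, 80, 0.5, seed = 17)
  act <- generate_activity(20000, bout_mean_s = 60, p_active = 0.3, seed = 18)
  tr <- match_activity(tr, act)
  expect_lt(abs(mean(tr$beats$activity == "Active") - 0.3), 0.05)
})

test_that("window summaries count flags and compute HR/rMSSD correctly", {
  # constant 500 ms rhythm: window 2 holds exactly 600 beats; flag 30 of
  # them flat -> 5.0% flats, HR 120, rMSSD 0
  flat <- rep(FALSE, 1250)
  flat[700:729] <- TRUE
  tr <- ibi_trace(rep(500, 1250), flat = flat)
  w <- summarize_windows(tr)
  expect_equal(nrow(w), 2)
  expect_equal(w$n_beats[2], 600)
  expect_equal(w$n_flats[2], 30)
  expect_equal(w$pct_flats_stairs[2], 5.0)
  expect_equal(w$mean_hr_bpm, c(120, 120))
  expect_equal(w$rmssd_ms, c(0, 0))
  expect_true(all(is.na(w$pct_active)))

  # tally oracle on random flags and labels
  set.seed(61)
  n <- 620
  tr <- ibi_trace(rep(500, n),
                  corrected = runif(n) < 0.2, flat = runif(n) < 0.1,
                  stair = runif(n) < 0.1,
                  activity = sample(c("Inactive", "Active", "Unknown"), n,
                                    replace = TRUE, prob = c(0.5, 0.3, 0.2)))
  w <- summarize_windows(tr)
  idx <- which(!is.na(assign_windows(tr)))
  b <- tr$beats[idx, ]
  m <- nrow(b)
  expect_equal(w$n_beats, m)
  expect_equal(w$n_corrected, sum(b$corrected))
  expect_equal(w$pct_artefact, 100 * sum(b$corrected) / m)
  expect_equal(w$pct_flats_stairs, 100 * sum(b$flat | b$stair) / m)
  known <- b$activity != "Unknown"
  expect_equal(w$pct_active, 100 * sum(b$activity == "Active") / sum(known))
})

test_that("covariates propagate to windows with time-of-day advanced", {
  tr <- ibi_trace(rep(500, 1250), individual_id = "A", tag_id = "T",
                  covariates = list(day_of_year = 310, time_of_day = 0.5,
                                    deploy_day = 3, mass_kg = 140,
                                    temperature_c = 6))
  w <- summarize_windows(tr)
  expect_equal(w$day_of_year, c(310, 310))
  expect_equal(w$time_of_day, 0.5 + c(0, 300) / 86400)
  expect_equal(w$start_s, c(0, 300))
  expect_equal(w$end_s - w$start_s, c(300, 300))
})

test_that("retention filtering is boundary-inclusive and reports first failure", {
  w <- data.frame(individual_id = "A", tag_id = "T", window_index = 1:4,
                  n_beats = c(600, 600, 600, 1),
                  pct_flats_stairs = c(5.0, 5.1, 2, 0),
                  pct_artefact = c(10, 10, 10, 0),
                  pct_active = c(0, 0, NA, 0))
  f <- filter_windows(w, retention_policy())
  expect_equal(f$retained$window_index, 1)
  expect_equal(f$rejected$reason[f$rejected$window_index == 2], "flats_stairs")
  expect_equal(f$rejected$reason[f$rejected$window_index == 3], "activity")
  expect_equal(f$rejected$reason[f$rejected$window_index == 4], "min_beats")
  # disabling the activity criterion admits unknown-activity windows
  f2 <- filter_windows(w, retention_policy(max_pct_active = NA))
  expect_true(3 %in% f2$retained$window_index)
})

test_that("tightening any threshold never enlarges the retained set", {
  set.seed(77)
  w <- data.frame(individual_id = "A", tag_id = "T", window_index = 1:200,
                  n_beats = sample(200:700, 200, replace = TRUE),
                  pct_flats_stairs = runif(200, 0, 15),
                  pct_artefact = runif(200, 0, 40),
                  pct_active = runif(200, 0, 30))
  loose <- retention_policy(max_pct_flats_stairs = 10, max_pct_active = 20,
                            max_pct_artefact = 30)
  kept_loose <- filter_windows(w, loose)$retained$window_index
  for (tight in list(retention_policy(5, 20, 30),
                     retention_policy(10, 5, 30),
                     retention_policy(10, 20, 15),
                     retention_policy(10, 20, 30, min_beats = 400))) {
    kept <- filter_windows(w, tight)$retained$window_index
    expect_true(all(kept %in% kept_loose))
  }
  # brute-force filter oracle
  keep <- w$n_beats >= 2 & w$pct_flats_stairs <= 10 & w$pct_active <= 20 &
    w$pct_artefact <= 30
  expect_equal(kept_loose, w$window_index[keep])
})

test_that("covariate table round-trips through its fixed column order", {
  tr <- generate_clean_trace(650, 700, 80, 0.5, seed = 19,
                             individual_id = "S1", tag_id = "T1",
                             covariates = list(day_of_year = 300,
                                               time_of_day = 0.25,
                                               deploy_day = 2,
                                               mass_kg = 150,
                                               temperature_c = 8))
  w <- summarize_windows(annotate_trace(tr)$trace)
  f <- withr::local_tempfile()
  export_covariate_table(w, f)
  back <- utils::read.csv(f)
  expect_equal(names(back), names(w))
  for (col in setdiff(names(w), c("individual_id", "tag_id")))
    expect_equal(as.numeric(back[[col]]), as.numeric(w[[col]]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(nrow(back), nrow(w))
})
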