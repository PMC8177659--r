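test_that("rMSSD matches its closed form and the brute-force formula", {
  expect_equal(rmssd(rep(640, 50)), 0)
  expect_equal(rmssd(c(500, 510, 500, 510)), 10)
  set.seed(8)
  for (case in 1:1000) {
    x <- runif(sample(3:300, 1), 400, 1200)
    expect_equal(rmssd(x), oracle_rmssd(x), tolerance = 1e-9)
  }
})

test_that("rMSSD is translation-invariant and scales linearly", {
  set.seed(9)
  for (case in 1:50) {
    x <- runif(100, 500, 900)
    expect_equal(rmssd(x + 123.4), rmssd(x), tolerance = 1e-9)
    expect_equal(rmssd(3.7 * x), 3.7 * rmssd(x), tolerance = 1e-9)
  }
})

test_that("out-of-bounds exclusion splits the difference chain", {
  x <- c(500, 510, 4000, 505, 515)
  excl <- c(FALSE, FALSE, TRUE, FALSE, FALSE)
  # usable differences: (510-500) and (515-505); none across the excluded beat
  expect_equal(rmssd(x, exclude = excl), sqrt((10^2 + 10^2) / 2))
  tr <- apply_physiological_limits(ibi_trace(x))
  expect_equal(rmssd(tr), sqrt((10^2 + 10^2) / 2))
  # too few usable beats -> NA with a warning
  expect_warning(v <- rmssd(c(500, 600), exclude = c(TRUE, FALSE)))
  expect_true(is.na(v))
  expect_warning(v2 <- rmssd(numeric(0)))
  expect_true(is.na(v2))
})

test_that("classification matrices cross-tabulate flags against corrections", {
  set.seed(10)
  n <- 5000
  tr <- ibi_trace(rep(500, n), corrected = runif(n) < 0.3,
                  flat = runif(n) < 0.2, stair = runif(n) < 0.05)
  for (kind in c("flat", "stair")) {
    m <- classification_matrix(tr, kind)
    flg <- tr$beats[[kind]]
    cor <- tr$beats$corrected
    expect_equal(m$a, sum(flg & cor))
    expect_equal(m$b, sum(flg & !cor))
    expect_equal(m$c, sum(!flg & cor))
    expect_equal(m$d, sum(!flg & !cor))
    expect_equal(m$n_total, n)
    p <- matrix_percentages(m)
    expect_equal(p[["pct_of_corrected_flagged"]], 100 * m$a / (m$a + m$c))
    expect_equal(p[["pct_of_flagged_corrected"]], 100 * m$a / (m$a + m$b))
  }
  # pooling over traces adds cells
  m1 <- classification_matrix(list(tr, tr), "flat")
  expect_equal(m1$n_total, 2 * n)
})

test_that("zero-denominator percentages are reported absent", {
  tr <- ibi_trace(rep(500, 10))
  m <- classification_matrix(tr, "flat")
  expect_equal(c(m$a, m$b, m$c, m$d), c(0, 0, 0, 10))
  p <- matrix_percentages(m)
  expect_true(is.na(p[["pct_of_corrected_flagged"]]))
  expect_true(is.na(p[["pct_of_flagged_corrected"]]))
  expect_equal(p[["pct_of_noncorrected_flagged"]], 0)
})

test_that("reporting percentages round to 1 dp, 2 dp below 0.1%", {
  m <- classification_matrix_from_counts(99015, 227, 1707890, 2190548, "stair")
  p <- matrix_percentages(m, rounded = TRUE)
  expect_equal(p[["pct_of_corrected_flagged"]], 5.5)
  expect_equal(p[["pct_of_noncorrected_flagged"]], 0.01)
  expect_equal(p[["pct_of_flagged_corrected"]], 99.8)
})

test_that("beat matching pairs identical streams completely and respects the offset", {
  tr <- generate_clean_trace(120, 700, 90, 0.5, seed = 13)
  pairs <- match_beats(tr, tr)
  expect_equal(nrow(pairs), n_beats(tr))
  expect_equal(attr(pairs, "n_test_unmatched"), 0)
  expect_true(all(pairs$dt_s == 0))

  # a 0.5 s clock shift with 0.25 s tolerance leaves nothing to pair
  # (1000 ms rhythm so both same-index and neighbour offsets exceed 0.25 s;
  # the shift is realised by lengthening the first IBI by 500 ms)
  tr1k <- generate_clean_trace(120, 1000, 30, 0.5, seed = 14)
  ibis2 <- tr1k$beats$ibi_ms
  ibis2[1] <- ibis2[1] + 500
  shifted <- ibi_trace(ibis2)
  expect_warning(p2 <- match_beats(tr1k, shifted), "no overlapping")
  expect_equal(nrow(p2), 0)

  # realistic timing jitter: nearly all beats still pair up
  ref <- generate_reference_pair(tr, jitter_sd_ms = 50, seed = 3)
  p3 <- match_beats(tr, ref)
  expect_gte(nrow(p3) / n_beats(tr), 0.99)
})

test_that("Bland-Altman reproduces hand-computed and degenerate cases", {
  ba <- bland_altman(c(500, 600, 700), c(500, 600, 700))
  expect_equal(ba$bias_ms, 0)
  expect_equal(ba$loa_lower_ms, 0)
  expect_equal(ba$loa_upper_ms, 0)

  # differences {+2, -2}: sd = 2.828427, LoA = +/- 5.5437
  ba <- bland_altman(c(502, 498), c(500, 500))
  expect_equal(ba$bias_ms, 0)
  expect_equal(ba$sd_diff_ms, sqrt(8))
  expect_equal(ba$loa_upper_ms, 5.5437, tolerance = 1e-4)
  expect_equal(ba$loa_lower_ms, -5.5437, tolerance = 1e-4)

  # constant offset: bias exactly c with zero-width limits
  x <- runif(100, 500, 900)
  ba <- bland_altman(x + 0.9, x)
  expect_equal(ba$bias_ms, 0.9)
  expect_equal(ba$loa_lower_ms, ba$loa_upper_ms)
  expect_error(bland_altman(500, 500), "2 pairs")
})

test_that("Bland-Altman CI formulas follow the classic approximations", {
  set.seed(14)
  d <- rnorm(200, 1, 5)
  ba <- bland_altman(d + 600, rep(600, 200))
  n <- 200
  expect_equal(ba$ci_bias,
               mean(d) + c(-1, 1) * qt(0.975, n - 1) * sd(d) / sqrt(n))
  expect_equal(ba$ci_loa_upper,
               mean(d) + 1.96 * sd(d) +
                 c(-1, 1) * qt(0.975, n - 1) * sd(d) * sqrt(3 / n))
  expect_true(ba$loa_lower_ms <= ba$bias_ms && ba$bias_ms <= ba$loa_upper_ms)
})
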