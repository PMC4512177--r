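test_that("peak collection keeps the signed extremum of the window", {
  time_ms <- 0:1999
  trials <- tibble::tibble(
    kind = factor(c("paired", "cs_only", "paired"),
                  eyeblinkr:::kind_levels),
    cs_onset_ms = 1000, valid = TRUE, early_movement = FALSE)
  tr <- matrix(0, 3, 2000)
  tr[1, 1150] <- 0.4; tr[1, 1200] <- -0.05  # closing dominates
  tr[2, 1180] <- -0.2; tr[2, 1160] <- 0.05  # opening dominates, sign kept
  # trial 3: pure zero trace
  samp <- collect_peak_amplitudes(tr, time_ms, trials)
  expect_equal(samp$values, c(0.4, -0.2, 0))
  expect_equal(samp$n_trials, 3L)
})

test_that("peak collection windows differ by trial kind and skip non-CS trials", {
  time_ms <- 0:1999
  trials <- tibble::tibble(
    kind = factor(c("paired", "cs_only", "us_only"),
                  eyeblinkr:::kind_levels),
    cs_onset_ms = c(1000, 1000, NA), valid = TRUE, early_movement = FALSE)
  tr <- matrix(0, 3, 2000)
  tr[1, 1270] <- 0.9  # 270 ms: outside the paired window (100-250)
  tr[1, 1200] <- 0.3
  tr[2, 1270] <- 0.9  # inside the cs_only window (100-280)
  samp <- collect_peak_amplitudes(tr, time_ms, trials)
  expect_equal(samp$values, c(0.3, 0.9))  # us_only trial dropped
  # invalid trials are skipped
  trials$valid[1] <- FALSE
  expect_equal(collect_peak_amplitudes(tr, time_ms, trials)$values, 0.9)
  trials$valid <- FALSE
  expect_error(collect_peak_amplitudes(tr, time_ms, trials), "no included")
})

test_that("histogram tiles a zero-centered bin of the printed edges", {
  h <- build_histogram(c(0, 0.006, -0.012, 0.0124), bin_width = 0.025)
  # everything lies in the zero bin spanning [-0.0125, 0.0125)
  expect_equal(sum(h$counts[h$centers == 0]), 4)
  expect_equal(h$total, 4)
  # symmetric values land in symmetric bins
  h2 <- build_histogram(c(-0.03, 0.03), bin_width = 0.025)
  expect_equal(h2$counts[abs(h2$centers + 0.025) < 1e-9],
               h2$counts[abs(h2$centers - 0.025) < 1e-9])
  # 0.0125 belongs to the bin above zero (left-closed bins)
  h3 <- build_histogram(c(0.0125), bin_width = 0.025)
  expect_equal(h3$centers[h3$counts == 1], 0.025)
  expect_error(build_histogram(1:3, bin_width = 0), "positive")
})

test_that("reflection handles the degenerate textbook cases", {
  # perfectly symmetric histogram: probability 0, amplitude undefined
  h <- hist_from_counts(c(5, 3, 8, 3, 5), kmin = -2)
  d <- reflect_and_decompose(h)
  expect_equal(d$probability, 0)
  expect_true(is.na(d$amplitude))
  # all mass in one far-positive bin: probability 1, amplitude = center
  h2 <- hist_from_counts(c(0, rep(0, 19), 200), kmin = 0)
  d2 <- reflect_and_decompose(h2)
  expect_equal(d2$failure_rate, 0)
  expect_equal(d2$probability, 1)
  expect_equal(d2$amplitude, 0.5)
  expect_error(reflect_and_decompose(hist_from_counts(0, kmin = 0)),
               "empty")
})

test_that("reflection matches the brute-force oracle on random histograms", {
  set.seed(21)
  for (i in 1:200) {
    nb <- sample(1:8, 1)
    kmin <- -sample(0:(nb - 1), 1)  # zero bin always included
    counts <- sample(0:20, nb, replace = TRUE)
    if (sum(counts) == 0) counts[1] <- 1
    h <- hist_from_counts(counts, kmin = kmin)
    d <- reflect_and_decompose(h)
    o <- oracle_decompose(h$centers, h$counts, h$bin_width)
    expect_equal(d$probability, o$probability, tolerance = 1e-12)
    expect_equal(d$failure_rate, o$failure_rate, tolerance = 1e-12)
    if (is.na(o$amplitude)) expect_true(is.na(d$amplitude))
    else expect_equal(d$amplitude, o$amplitude, tolerance = 1e-12)
  }
})

test_that("decomposition recovers a seeded two-component mixture", {
  set.seed(33)
  n <- 1000
  resp <- runif(n) < 0.4
  vals <- ifelse(resp, rnorm(n, 0.40, 0.05), rnorm(n, 0, 0.02))
  d <- reflect_and_decompose(build_histogram(vals))
  # oracle: direct ground-truth label counting
  expect_equal(d$probability, mean(resp), tolerance = 0.05)
  expect_equal(d$amplitude, 0.40, tolerance = 0.03)
})

test_that("adding a far-positive sample never decreases probability", {
  set.seed(34)
  for (i in 1:50) {
    vals <- rnorm(50, 0.1, 0.15)
    p0 <- reflect_and_decompose(build_histogram(vals))$probability
    p1 <- reflect_and_decompose(build_histogram(c(vals, 0.9)))$probability
    expect_gte(p1, p0 - 1e-12)
  }
})

test_that("zero-bin assignment option shifts mass as documented", {
  h <- hist_from_counts(c(2, 10, 8), kmin = -1)
  d_non <- reflect_and_decompose(h, zero_bin = "nonresponse")
  d_spl <- reflect_and_decompose(h, zero_bin = "split")
  expect_equal(d_non$failure_rate, (10 + 2 * 2) / 20)
  expect_equal(d_spl$failure_rate, (5 + 2 * 2) / 20)
  expect_gt(d_spl$probability, d_non$probability)
  # split leaves response mass at amplitude zero, diluting the mean
  expect_lt(d_spl$amplitude, d_non$amplitude)
})

test_that("session metrics report the classical %CR alongside the decomposition", {
  expect_equal(session_metrics(rep(0.10, 50))$percent_cr, 0)
  expect_equal(session_metrics(rep(0.30, 50))$percent_cr, 100)
  expect_equal(session_metrics(rep(0.15, 50))$percent_cr, 0)  # strict
  # %CR approximates decomposition probability when the components separate
  set.seed(35)
  pk <- simulate_session_peaks(2000, 0.5, 0.4, 0.05, 0.03)
  m <- session_metrics(pk$values)
  expect_lt(abs(m$percent_cr - 100 * m$probability), 6)
  expect_error(session_metrics(numeric(0)), "empty")
})

test_that("trace-level decomposition tracks simulated ground truth", {
  cfg <- simulation_config(amp_sd = 0.05, opening_prob = 0)
  proto <- protocol_config(blocks_per_session = 10)
  sched <- build_acquisition_schedule(proto, seed = 6)
  out <- withr::with_seed(61, eyeblinkr:::simulate_session_traces(
    sched, list(p = 0.5, amp_mean = 0.4), cfg, proto))
  trials <- out$sched
  trials$subject <- "s"; trials$group <- "g"; trials$age_days <- 90
  coh <- normalize_cohort(make_cohort(out$traces, trials,
                                      protocol = proto, config = cfg))
  met <- decompose_cohort(coh)
  truth <- mean(trials$gt_is_response)
  expect_lt(abs(met$probability - truth), 0.08)
  expect_lt(abs(met$amplitude - mean(trials$gt_amplitude, na.rm = TRUE)),
            0.05)
})
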