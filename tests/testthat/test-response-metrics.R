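test_that("CR scoring applies the 0.15/0.05 threshold rules", {
  time_ms <- 0:1999
  cs <- 1000
  quiet <- numeric(2000)
  # peak 0.20 at 250 ms, quiet early window -> cr
  x <- quiet; x[1200:1300] <- 0.20
  expect_equal(classify_cr(x, time_ms, cs), "cr")
  # early movement 0.06 at 50 ms -> excluded regardless of later peak
  x2 <- x; x2[1051] <- 0.06
  expect_equal(classify_cr(x2, time_ms, cs), "excluded")
  # peak 0.10 -> none
  x3 <- quiet; x3[1200:1300] <- 0.10
  expect_equal(classify_cr(x3, time_ms, cs), "none")
  # boundary: exactly 0.15 does not score (strict)
  x4 <- quiet; x4[1200] <- 0.15
  expect_equal(classify_cr(x4, time_ms, cs), "none")
  expect_error(classify_cr(x, time_ms, cs, kind = "paired"), "unpaired")
})

test_that("raising the CR threshold never converts none into cr", {
  time_ms <- 0:1999
  set.seed(41)
  for (i in 1:20) {
    x <- numeric(2000)
    x[1100:1400] <- runif(1, 0, 0.4) * sin(seq(0, pi, length.out = 301))
    lo <- classify_cr(x, time_ms, 1000, cr_threshold = 0.15)
    hi <- classify_cr(x, time_ms, 1000, cr_threshold = 0.25)
    if (hi == "cr") expect_equal(lo, "cr")
  }
})

test_that("CR timing on a deterministic ramp matches arithmetic", {
  time_ms <- 0:1999
  # linear ramp 0 -> 0.4 over 100-300 ms post-CS, held to 400 ms
  x <- ramp_trace(time_ms, 1100, 1300, 0.4, hold_end = 1400)
  m <- cr_timing(x, time_ms, 1000, smooth_width_ms = 0)
  # 10% at 120 ms, 90% at 280 ms -> rise 160 ms
  expect_equal(m$rise_time_10_90_ms, 160, tolerance = 1)
  # tied peak plateau resolves to the earliest sample
  expect_equal(m$peak_latency_ms, 300, tolerance = 1)
  expect_equal(m$peak_amplitude, 0.4)
  expect_equal(m$onset_latency_ms, 100, tolerance = 2)
})

test_that("onset detection finds a constructed concavity change", {
  time_ms <- 0:1999
  # zero until 140 ms post-CS, then quadratic rise
  x <- numeric(2000)
  t_rel <- time_ms - 1000
  sel <- t_rel >= 140
  x[sel] <- pmin(0.5, 1e-5 * (t_rel[sel] - 140)^2)
  m <- cr_timing(x, time_ms, 1000, smooth_width_ms = 0)
  expect_equal(m$onset_latency_ms, 140, tolerance = 3)
  expect_false(m$onset_fallback)
})

test_that("timing metrics are time-shift equivariant and scale invariant", {
  time_ms <- 0:1999
  x <- numeric(2000)
  t_rel <- time_ms - 1000
  sel <- t_rel >= 150 & t_rel <= 260
  x[sel] <- 0.4 * sin(pi / 2 * (t_rel[sel] - 150) / 110)^2
  m0 <- cr_timing(x, time_ms, 1000)
  # shift the whole trace by 37 ms
  xs <- c(numeric(37), x[1:(2000 - 37)])
  m1 <- cr_timing(xs, time_ms, 1000 + 37)
  expect_equal(m1$onset_latency_ms, m0$onset_latency_ms, tolerance = 1)
  expect_equal(m1$peak_latency_ms, m0$peak_latency_ms, tolerance = 1)
  # scaling the amplitude leaves all latencies unchanged
  m2 <- cr_timing(0.5 * x, time_ms, 1000)
  expect_equal(m2$onset_latency_ms, m0$onset_latency_ms)
  expect_equal(m2$rise_time_10_90_ms, m0$rise_time_10_90_ms)
  expect_equal(m2$peak_latency_ms, m0$peak_latency_ms)
  expect_equal(m2$peak_amplitude, 0.5 * m0$peak_amplitude)
})

test_that("UR metrics on a deterministic ramp match arithmetic", {
  time_ms <- 0:1999
  # zero until 20 ms post-US (US at 1250), linear to 1.0 at 60 ms, decay
  t_rel <- time_ms - 1250
  x <- numeric(2000)
  ris <- t_rel >= 20 & t_rel <= 60
  x[ris] <- (t_rel[ris] - 20) / 40
  x[t_rel > 60] <- exp(-(t_rel[t_rel > 60] - 60) / 150)
  m <- ur_metrics(x, time_ms, 1250, smooth_width_ms = 0)
  expect_equal(m$latency_ms, 20, tolerance = 2)
  # 10% at 24 ms, 90% at 56 ms -> rise 32 ms
  expect_equal(m$rise_time_ms, 32, tolerance = 1)
  expect_equal(m$peak_amplitude, 1, tolerance = 1e-9)
  # scaled copy: identical timing after normalization-free analysis
  m2 <- ur_metrics(0.5 * x, time_ms, 1250, smooth_width_ms = 0)
  expect_equal(m2$latency_ms, m$latency_ms)
  expect_equal(m2$rise_time_ms, m$rise_time_ms)
  # flat trace: undetected UR
  expect_error(ur_metrics(numeric(2000), time_ms, 1250), "no UR")
})

test_that("simulated UR latency is recovered within 3 ms", {
  cfg <- simulation_config()
  set.seed(43)
  lat <- replicate(100, {
    tr <- simulate_trace(list(kind = "paired"), list(p = 0, amp_mean = 0),
                         cfg)
    nt <- normalize_trial(tr$samples, tr$time_ms, 1000, 1250)
    ur_metrics(nt$samples, tr$time_ms, 1250)$latency_ms
  })
  expect_lt(abs(mean(lat) - cfg$ur_latency_mean_ms), 3)
})

test_that("UR velocity scales with UR magnitude as generated", {
  # unnormalized ramps of varying amplitude, fixed 40 ms rise:
  # peak velocity = amplitude / 40 per ms
  time_ms <- 0:1999
  t_rel <- time_ms - 1250
  amps <- seq(0.5, 2, length.out = 12)
  est <- t(sapply(amps, function(a) {
    x <- numeric(2000)
    ris <- t_rel >= 20 & t_rel <= 60
    x[ris] <- a * (t_rel[ris] - 20) / 40
    x[t_rel > 60] <- a * exp(-(t_rel[t_rel > 60] - 60) / 150)
    m <- ur_metrics(x, time_ms, 1250, smooth_width_ms = 0)
    c(amp = m$peak_amplitude, vel = m$peak_velocity)
  }))
  fit <- stats::lm(vel ~ amp, data = as.data.frame(est))
  expect_equal(unname(stats::coef(fit)["amp"]), 1 / 40, tolerance = 0.02)
})

test_that("photic opening detection follows the 5% / not-before rule", {
  time_ms <- 0:1999
  cs <- 1000
  dip <- function(at, depth) {
    x <- numeric(2000); x[(1000 + at - 10):(1000 + at + 10)] <- depth; x
  }
  ev <- detect_photic_opening(dip(150, -0.08), time_ms, cs)
  expect_true(ev$detected)
  expect_equal(ev$depth, -0.08)
  expect_equal(ev$time_ms, 150, tolerance = 11)
  # dip before 70 ms vetoes detection
  x2 <- dip(150, -0.08); x2[1040:1060] <- -0.08
  expect_false(detect_photic_opening(x2, time_ms, cs)$detected)
  expect_false(detect_photic_opening(dip(50, -0.08), time_ms, cs)$detected)
  # sub-threshold dip
  expect_false(detect_photic_opening(dip(150, -0.03), time_ms, cs)$detected)
  # gated off once the session has CRs
  expect_false(detect_photic_opening(dip(150, -0.08), time_ms, cs,
                                     session_has_crs = TRUE)$detected)
})

test_that("per-trial metrics table integrates detectors over a session", {
  spec <- tiny_cohort_spec(master_seed = 31, blocks = 3, n_acq = 1,
                           n_ext = 0, n_reacq = 0, p_max = 0.9,
                           opening_prob = 0)
  coh <- simulate_cohort(spec, phases = "acquisition")
  coh <- normalize_cohort(coh)
  tm <- trial_response_metrics(coh)
  expect_equal(nrow(tm), 30)
  cs_rows <- tm$kind == "cs_only" & coh$trials$valid
  expect_true(all(tm$status[cs_rows] %in% c("cr", "none", "excluded")))
  expect_true(all(is.na(tm$status[tm$kind != "cs_only"])))
  # CR rows have timing fields; UR rows have UR fields
  cr_rows <- which(tm$status == "cr")
  if (length(cr_rows)) {
    expect_true(all(is.finite(tm$onset_latency_ms[cr_rows])))
    expect_true(all(tm$onset_latency_ms[cr_rows] <=
                      tm$peak_latency_ms[cr_rows]))
  }
  paired_ok <- tm$kind == "paired" & !is.na(tm$ur_latency_ms)
  expect_gt(sum(paired_ok), 0)
  expect_true(all(tm$ur_latency_ms[paired_ok] >= 0 &
                    tm$ur_latency_ms[paired_ok] <= 75))
})
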