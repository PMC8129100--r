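test_that("AsLS baseline is exact on constants and lines, and ignores spikes", {
  n <- 200
  const <- rep(7.5, n)
  expect_equal(asls_baseline(const), const, tolerance = 1e-5)
  ramp <- seq(10, 60, length.out = n)
  b <- asls_baseline(ramp)
  expect_lt(max(abs(b - ramp)), 0.01 * diff(range(ramp)))
  spiky <- ramp
  at <- c(40, 90, 150)
  spike_h <- 100
  for (a in at) spiky[a:(a + 3)] <- spiky[a:(a + 3)] + spike_h
  bs <- asls_baseline(spiky, p = 0.01)
  expect_lt(max(abs(bs[at] - ramp[at])), 0.05 * spike_h)
  expect_error(asls_baseline(1:5), "at least 10")
  expect_error(asls_baseline(ramp, lambda = -1), "lambda")
  expect_error(asls_baseline(ramp, p = 1.5), "p must")
})

test_that("dF/F is the baseline-relative change", {
  expect_equal(dff(c(5, 5, 5), c(5, 5, 5)), c(0, 0, 0))
  expect_equal(dff(c(10, 10), c(5, 5)), c(1, 1))
  expect_equal(dff(156.8, 87.7), (156.8 - 87.7) / 87.7)
  expect_error(dff(c(1, 2), c(1, 0)), "index 2")
})

test_that("burst detection finds planted pulses with correct metrics", {
  set.seed(2)
  n <- 600
  noise <- rnorm(n, 0, 0.02)
  y <- noise
  y[101:110] <- 5 * sd(noise) + 1 # 10-frame rectangular pulse
  det <- detect_bursts(y, frame_interval = 0.2)
  expect_equal(nrow(det$bursts), 1)
  expect_equal(det$bursts$duration_s, 2.0)
  expect_equal(det$bursts$onset_s, 100 * 0.2)
  # all-subthreshold noise
  det0 <- detect_bursts(noise, frame_interval = 0.2)
  expect_equal(nrow(det0$bursts), 0)
  expect_equal(det0$active_time_fraction, 0)
  # triangular pulse: trapezoidal AUC approximates the closed-form area
  h <- 3; w_frames <- 40
  tri <- c(rep(0, 100), h * (1 - abs(seq(-1, 1, length.out = w_frames))),
           rep(0, 100)) + rnorm(240, 0, 1e-3)
  dtri <- detect_bursts(tri, frame_interval = 0.2)
  expect_equal(nrow(dtri$bursts), 1)
  area <- h * (w_frames * 0.2) / 2
  expect_lt(abs(dtri$bursts$auc - area), 2 * h * 0.2)
})

test_that("burst counts are scale-invariant and times partition the trace", {
  set.seed(4)
  y <- rnorm(500, 0, 0.05)
  y[c(50:70, 200:240, 400:410)] <- y[c(50:70, 200:240, 400:410)] + 2
  d1 <- detect_bursts(y)
  d2 <- detect_bursts(17.3 * y)
  expect_equal(nrow(d1$bursts), nrow(d2$bursts))
  expect_equal(d1$bursts$duration_s, d2$bursts$duration_s)
  total_active <- sum(d1$bursts$duration_s)
  expect_equal(total_active / (500 * 0.2), d1$active_time_fraction,
               tolerance = 1e-12)
  expect_warning(detect_bursts(rep(1, 50)), "zero-variance")
})

test_that("segment baseline profile normalises to the brightest segment", {
  mk <- function(level) fluorescence_trace(rep(level, 120) +
                                             sin(1:120 / 10) * 0.001)
  prof <- segment_baseline_profile(list(mk(100), mk(100), mk(100)))
  expect_equal(prof, rep(1, 3), tolerance = 1e-6)
  prof2 <- segment_baseline_profile(list(mk(100), mk(90), mk(80)))
  expect_equal(prof2, c(1, 0.9, 0.8), tolerance = 1e-3)
})

test_that("an edge-high brightness gradient appears in the recovered profile", {
  # seven segments whose baseline falls from edges toward the centre
  levels <- c(100, 95, 90, 86, 90, 95, 100)
  traces <- lapply(seq_along(levels), function(q) {
    tr <- make_ca_trace(n_frames = 400, baseline_level = levels[q],
                        drift_amplitude = 0.5,
                        burst_onsets_s = c(20, 50),
                        burst_durations_s = c(5, 8),
                        burst_amplitudes = c(1.5, 2), noise_sd = 0.3,
                        seed = 100 + q)
    tr$trace
  })
  prof <- segment_baseline_profile(traces)
  expect_equal(which.min(prof), 4)
  expect_true(all(diff(prof[1:4]) < 0))
  expect_true(all(diff(prof[4:7]) > 0))
})

test_that("initiation points require the persistence window and re-arm below threshold", {
  fs <- 6000
  y <- rep(0, fs) # one second
  y[1001:1300] <- 10 # 50 ms pulse
  t1 <- burst_initiation_time(lfp_trace(y, fs), threshold = 5)
  expect_equal(t1, 1000 / fs)
  y5 <- rep(0, fs)
  y5[1001:1030] <- 10 # 5 ms only
  expect_length(burst_initiation_time(lfp_trace(y5, fs), threshold = 5), 0)
  y2 <- rep(0, fs)
  y2[1001:1200] <- 10
  y2[3001:3200] <- 10
  t2 <- burst_initiation_time(lfp_trace(y2, fs), threshold = 5)
  expect_equal(t2, c(1000, 3000) / fs)
  expect_true(all(diff(t2) > 0))
  expect_error(burst_initiation_time(lfp_trace(y, fs), threshold = 5,
                                     persistence = 1e-5), "persistence")
  expect_error(burst_initiation_time(lfp_trace(y, fs), threshold = 0),
               "threshold")
})

test_that("initiation delays recover a constant channel shift", {
  pair <- make_lfp_pair(n_bursts = 8, center_lead_s = 0.03, noise_sd = 0.5,
                        burst_amplitude = 50, seed = 3)
  res <- initiation_delay(pair$edge, pair$center, thresholds = 10)
  expect_equal(res$n_matched, 8)
  expect_equal(res$delays, rep(0.03, 8), tolerance = 1 / 6000 + 1e-9)
  expect_equal(res$center_leading_fraction, 1)
  # identical traces: all delays zero, ties excluded from the fraction
  res0 <- initiation_delay(pair$center, pair$center, thresholds = 10)
  expect_true(all(res0$delays == 0))
  expect_true(is.na(res0$center_leading_fraction))
})

test_that("the band-stop chain attenuates mains hum by 40 dB", {
  fs <- 6000
  t <- seq(0, 2, by = 1 / fs)
  hum <- lfp_trace(sin(2 * pi * 60 * t), fs)
  filtered <- lfp_preprocess(hum)
  mid <- seq(fs / 2, 3 * fs / 2) # avoid filter edge transients
  atten_db <- 20 * log10(sd(filtered$values[mid]) / sd(hum$values[mid]))
  expect_lt(atten_db, -40)
})

test_that("the silent-segment threshold picks the quietest window's std", {
  fs <- 6000
  set.seed(11)
  y <- rnorm(3 * fs, 0, 4)
  quiet <- 10001:10600 # 100 ms of low variance
  y[quiet] <- rnorm(600, 0, 0.3)
  thr <- silent_threshold(lfp_trace(y, fs))
  expect_lt(thr, 0.4)
  expect_gt(thr, 0.2)
})
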