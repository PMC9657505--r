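test_that("R-peak detection recovers clean simulated beats exactly", {
  fs <- 1000
  tl <- generate_beat_times(60, 60, 0)
  ann <- detect_r_peaks(synthesize_ecg(tl, fs = fs), fs)
  expect_equal(nrow(ann), 60)
  expect_true(all(abs(ann$r_time_s - tl$beat_time_s) <= 0.005))

  # detection count equals truth across the physiological range
  for (hr in c(40, 100, 180)) {
    tlh <- generate_beat_times(60, hr, 0)
    annh <- detect_r_peaks(synthesize_ecg(tlh, fs = fs), fs)
    expect_equal(nrow(annh), nrow(tlh))
  }

  # heart rate within +/-5% at 75 BPM
  tl75 <- generate_beat_times(60, 75, 0)
  ann75 <- detect_r_peaks(synthesize_ecg(tl75, fs = fs), fs)
  hr <- 60 / mean(diff(ann75$r_time_s))
  expect_lte(abs(hr - 75) / 75, 0.05)

  # flat signal -> zero beats, not an error; too-short signal errors
  expect_equal(nrow(detect_r_peaks(numeric(5000), fs)), 0)
  expect_error(detect_r_peaks(numeric(100), fs),
               class = "pttkit_analysis_error")
})

test_that("detection respects refractory, scale and shift properties", {
  fs <- 1000
  tl <- generate_beat_times(40, 90, 0.03, seed = 5)
  x <- synthesize_ecg(tl, fs = fs)
  ann <- detect_r_peaks(x, fs)
  # refractory guarantee
  expect_true(all(diff(ann$r_time_s) >= 0.2))

  # amplitude-scale invariance
  for (a in c(0.01, 3, 1000)) {
    expect_equal(detect_r_peaks(a * x, fs)$r_time_s, ann$r_time_s)
  }

  # time-shift equivariance (interior beats; k-sample shift)
  k <- 500L
  xs <- c(numeric(k), x)
  anns <- detect_r_peaks(xs, fs)
  expect_equal(nrow(anns), nrow(ann))
  expect_equal(anns$r_time_s, ann$r_time_s + k / fs, tolerance = 1e-9)
})

test_that("heart-rate series reports the windowed rate once per second", {
  ann <- annotation_from_times(seq(0.5, 60, by = 1))
  hr <- heart_rate_series(ann)
  expect_true(all(hr$hr_bpm == 60))
  expect_equal(diff(hr$time_s), rep(1, nrow(hr) - 1))

  ann2 <- annotation_from_times(seq(0.4, 60, by = 0.8))
  expect_true(all(abs(heart_rate_series(ann2)$hr_bpm - 75) < 1e-9))

  # step 60 -> 80 BPM transitions monotonically between plateaus
  step_times <- c(seq(0.5, 29.5, by = 1), seq(30.25, 60, by = 0.75))
  hs <- heart_rate_series(annotation_from_times(step_times))
  early <- hs$hr_bpm[hs$time_s <= 25]
  late <- hs$hr_bpm[hs$time_s >= 45]
  mid <- hs$hr_bpm[hs$time_s > 25 & hs$time_s < 45]
  expect_true(all(abs(early - 60) < 1))
  expect_true(all(abs(late - 80) < 1))
  expect_true(all(diff(mid) >= -1e-9))

  expect_error(heart_rate_series(annotation_from_times(1)),
               class = "pttkit_analysis_error")
})

test_that("HRV metrics match their definitions", {
  # constant RR: both zero
  h0 <- hrv_metrics(annotation_from_times(seq(0, 30, by = 1)))
  expect_equal(h0$sdnn_ms, 0)
  expect_equal(h0$rmssd_ms, 0)
  expect_equal(h0$mean_hr_bpm, 60)

  # alternating 0.8/1.0 s: RMSSD exactly 200 ms
  times <- cumsum(c(0, rep(c(0.8, 1.0), 20)))
  h1 <- hrv_metrics(annotation_from_times(times))
  expect_equal(h1$rmssd_ms, 200, tolerance = 1e-9)

  # sampling-distribution oracle: SDNN within 15% of a 20 ms jitter at n >= 300
  tl <- generate_beat_times(300, 70, 0.020, seed = 8)
  expect_gte(nrow(tl), 300)
  h2 <- hrv_metrics(annotation_from_times(tl$beat_time_s))
  expect_lt(abs(h2$sdnn_ms - 20) / 20, 0.15)

  expect_error(hrv_metrics(annotation_from_times(c(0, 1))),
               class = "pttkit_analysis_error")
})

test_that("PPG fiducials satisfy ordering and canonical timing windows", {
  fs <- 1000
  pulse <- synthesize_ppg(0, ptt = 0.25, fs = fs, duration = 2)
  fid <- detect_ppg_fiducials(pulse, fs)
  expect_equal(nrow(fid), 1)
  expect_true(fid$onset_s < fid$inflection_s)
  expect_true(fid$inflection_s < fid$peak_s)
  expect_true(fid$peak_s < fid$dicrotic_s)

  # canonical morphology windows
  expect_gte(fid$peak_s - fid$onset_s, 0.10)
  expect_lte(fid$peak_s - fid$onset_s, 0.15)
  expect_gte(fid$dicrotic_s - fid$onset_s, 0.35)
  expect_lte(fid$dicrotic_s - fid$onset_s, 0.45)

  # inflection on a clean simulated recording within 3 ms of ground truth
  sim <- simulate_recording(30, mean_hr = 68, rr_jitter_sd = 0.02, seed = 13)
  ppg <- condition_signal(as.numeric(sim$recording$frames$ppg_green), fs,
                          ppg_filter_spec())
  fids <- detect_ppg_fiducials(ppg, fs)
  tr <- sim$truth
  truth_inf <- tr$beat_time_s + tr$ptt_s
  idx <- vapply(fids$inflection_s,
                function(x) which.min(abs(truth_inf - x)), integer(1))
  expect_true(all(abs(fids$inflection_s - truth_inf[idx]) <= 0.003))

  # degenerate input
  expect_equal(nrow(detect_ppg_fiducials(numeric(2000), fs)), 0)
})

test_that("fiducial times are invariant to amplitude scaling and shifts", {
  fs <- 1000
  sim <- simulate_recording(20, mean_hr = 72, rr_jitter_sd = 0.01, seed = 21)
  ppg <- condition_signal(as.numeric(sim$recording$frames$ppg_green), fs,
                          ppg_filter_spec())
  fid <- detect_ppg_fiducials(ppg, fs)
  for (a in c(0.5, 40)) {
    fs2 <- detect_ppg_fiducials(a * ppg, fs)
    expect_equal(fs2$inflection_s, fid$inflection_s, tolerance = 1e-9)
    expect_equal(fs2$peak_s, fid$peak_s)
  }
  k <- 250L
  fid_k <- detect_ppg_fiducials(c(rep(ppg[1], k), ppg), fs)
  expect_equal(nrow(fid_k), nrow(fid))
  expect_equal(fid_k$inflection_s, fid$inflection_s + k / fs, tolerance = 1e-6)
})
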