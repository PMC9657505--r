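test_that("beat timelines honour the nominal rate and refractory floor", {
  tl <- generate_beat_times(60, mean_hr = 60, rr_jitter_sd = 0)
  expect_equal(nrow(tl), 60)
  expect_equal(diff(tl$beat_time_s), rep(1, 59), tolerance = 1e-12)

  tl2 <- generate_beat_times(120, mean_hr = 75, rr_jitter_sd = 0)
  expect_equal(nrow(tl2), 150)
  expect_equal(unique(round(diff(tl2$beat_time_s), 12)), 0.8)

  # sample-mean oracle: with jitter, mean RR within 1% of 60/70
  tl3 <- generate_beat_times(600, mean_hr = 70, rr_jitter_sd = 0.02, seed = 1)
  expect_lt(abs(mean(diff(tl3$beat_time_s)) - 60 / 70) / (60 / 70), 0.01)

  # refractory floor and monotonicity under heavy jitter
  tl4 <- generate_beat_times(120, mean_hr = 180, rr_jitter_sd = 0.2, seed = 3)
  expect_true(all(diff(tl4$beat_time_s) >= 0.3 - 1e-12))

  expect_error(generate_beat_times(-5, 60), class = "pttkit_param_error")
  expect_error(generate_beat_times(60, 250), class = "pttkit_param_error")
  expect_error(generate_beat_times(60, 10), class = "pttkit_param_error")
})

test_that("timelines are deterministic given the seed", {
  a <- generate_beat_times(300, 70, 0.03, seed = 42)
  b <- generate_beat_times(300, 70, 0.03, seed = 42)
  c <- generate_beat_times(300, 70, 0.03, seed = 43)
  expect_identical(a$beat_time_s, b$beat_time_s)
  expect_false(identical(a$beat_time_s, c$beat_time_s))
})

test_that("ECG synthesis places the R maximum on the beat time", {
  x <- synthesize_ecg(1.0, fs = 1000, duration = 2)
  expect_equal(which.max(x) - 1L, 1000L)  # 0-based sample index

  # peak-count oracle: 10 s at 60 BPM -> exactly 10 peaks above 0.8 R
  tl <- generate_beat_times(10, 60, 0)
  y <- synthesize_ecg(tl, fs = 1000)
  n <- length(y)
  loc <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  expect_equal(sum(y[loc] > 0.8), 10)

  # empty timeline -> all-zero signal of requested length
  z <- synthesize_ecg(numeric(0), fs = 1000, duration = 5)
  expect_equal(z, numeric(5000))

  # overlapping complexes rejected
  expect_error(synthesize_ecg(c(1, 1.2), fs = 1000),
               class = "pttkit_timeline_error")
})

test_that("PTT ground truth follows the event model in closed form", {
  tl <- generate_beat_times(60, 60, 0)
  expect_equal(ptt_ground_truth(tl, 0.25), rep(0.25, 60))

  ev <- vaso_event(t_on = 10, t_off = 400, delta = -0.03,
                   tau_on = 30, tau_recovery = 60)
  # onset contributes zero at its own start
  expect_equal(ptt_ground_truth(10, 0.25, ev), 0.25)
  # closed form at t_on + tau_on
  expect_equal(ptt_ground_truth(40, 0.25, ev),
               0.25 - 0.03 * (1 - exp(-1)), tolerance = 1e-12)

  expect_error(
    ptt_ground_truth(40, 0.05, vaso_event(10, 400, -0.3, 1, 1)),
    class = "pttkit_param_error"
  )
  expect_error(ptt_ground_truth(tl, 0.7), class = "pttkit_param_error")
})

test_that("vaso events superpose linearly", {
  e1 <- vaso_event(100, 200, -0.02, 20, 40)
  e2 <- vaso_event(400, 500, -0.01, 10, 80)
  t <- seq(0, 700, by = 7)
  expect_equal(vaso_response(t, list(e1, e2)),
               vaso_response(t, e1) + vaso_response(t, e2), tolerance = 1e-14)
  # recovery is continuous at t_off
  eps <- 1e-9
  expect_equal(vaso_response(200 - eps, e1), vaso_response(200 + eps, e1),
               tolerance = 1e-6)
})

test_that("PPG pulses put the max-slope inflection at beat + PTT", {
  x <- synthesize_ppg(0, ptt = 0.25, fs = 1000, duration = 2)
  d <- diff(x)
  expect_lte(abs((which.max(d) - 0.5) / 1000 - 0.25), 1 / 1000)

  # numerical check across a train with varying PTT
  tl <- generate_beat_times(20, 70, 0.02, seed = 2)
  ptt <- seq(0.20, 0.30, length.out = nrow(tl))
  y <- synthesize_ppg(tl, ptt, fs = 1000)
  for (i in c(3, 10, 18)) {
    t0 <- tl$beat_time_s[i] + ptt[i]
    win <- round((t0 + c(-0.05, 0.05)) * 1000)
    d <- diff(y[win[1]:win[2]])
    t_inf <- (win[1] + which.max(d) - 1 - 0.5) / 1000
    expect_lte(abs(t_inf - t0), 1 / 1000)
  }

  expect_error(synthesize_ppg(tl, ptt[-1], fs = 1000),
               class = "pttkit_param_error")
})

test_that("noise injection matches its specification", {
  x <- sin(2 * pi * 1.2 * (0:9999) / 1000)
  expect_identical(add_noise(x, 1000, noise_spec(), seed = 1), x)

  # FFT oracle: mains-only noise concentrates at the 50 Hz bin
  y <- add_noise(numeric(2000), 1000, noise_spec(mains_amplitude = 1), seed = 1)
  sp <- Mod(stats::fft(y))^2
  bin50 <- 50 * 2000 / 1000 + 1
  expect_gt((sp[bin50] + sp[2000 + 2 - bin50]) / sum(sp), 0.999)

  # sample-statistics oracle: white noise SD within 5% at 1e5 samples
  w <- add_noise(numeric(1e5), 1000, noise_spec(white_sd = 0.1), seed = 4)
  expect_lt(abs(sd(w) - 0.1) / 0.1, 0.05)

  # determinism
  a <- add_noise(numeric(5000), 1000,
                 noise_spec(white_sd = 1, artifact_rate = 10,
                            artifact_amplitude = 2), seed = 9)
  b <- add_noise(numeric(5000), 1000,
                 noise_spec(white_sd = 1, artifact_rate = 10,
                            artifact_amplitude = 2), seed = 9)
  expect_identical(a, b)
})

test_that("simulated recordings are bit-reproducible for a fixed seed", {
  s1 <- simulate_recording(10, mean_hr = 72, seed = 7)
  s2 <- simulate_recording(10, mean_hr = 72, seed = 7)
  expect_identical(s1$recording$frames, s2$recording$frames)
  expect_identical(s1$truth, s2$truth)
})

test_that("clean simulated PPG inflection equals beat + PTT within a sample", {
  sim <- simulate_recording(30, mean_hr = 65, rr_jitter_sd = 0.02,
                            baseline_ptt = 0.22, seed = 11)
  g <- as.numeric(sim$recording$frames$ppg_green)
  tr <- sim$truth
  for (i in c(5, 15, 25)) {
    t0 <- tr$beat_time_s[i] + tr$ptt_s[i]
    win <- round((t0 + c(-0.05, 0.05)) * 1000)
    d <- diff(g[win[1]:win[2]])
    t_inf <- (win[1] + which.max(d) - 1 - 0.5) / 1000
    expect_lte(abs(t_inf - t0), 1 / 1000)
  }
})
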