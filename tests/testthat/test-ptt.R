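test_that("beat pairing applies the physiologic window and stays injective", {
  s1 <- pair_beats(1.0, 1.25)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$ptt_s, 0.25)

  # candidate below the window is rejected
  expect_equal(nrow(pair_beats(1.0, 1.05)), 0)
  # candidate beyond the window is rejected too
  expect_equal(nrow(pair_beats(1.0, 1.7)), 0)

  # each inflection used at most once, order preserved
  r <- c(1, 2, 3)
  infl <- c(1.25, 2.25)           # third beat has no pulse
  s2 <- pair_beats(r, infl)
  expect_equal(s2$beat_time_s, c(1, 2))
  expect_equal(s2$ptt_s, c(0.25, 0.25))

  # a dropped pulse must not steal the next beat's inflection
  s3 <- pair_beats(c(1, 2), c(2.25))
  expect_equal(s3$beat_time_s, 2)

  expect_error(pair_beats(c(2, 1), c(1.2)), class = "pttkit_param_error")

  # pairing error on a clean 300-beat simulation is tiny
  tl <- generate_beat_times(300, 72, 0.02, seed = 17)
  ptt <- ptt_ground_truth(tl, 0.25,
                          vaso_event(100, 200, -0.03, 30, 60))
  infl_truth <- tl$beat_time_s + ptt
  ser <- pair_beats(tl$beat_time_s, infl_truth)
  expect_equal(nrow(ser), nrow(tl))
  expect_lte(mean(abs(ser$ptt_s - ptt)), 0.002)
})

test_that("outlier flagging marks deviant beats without altering values", {
  const <- ptt_series_from(seq(1, 100), rep(0.25, 100))
  expect_true(all(clean_ptt_series(const)$quality))

  # one injected 3x outlier: exactly that beat flagged
  x <- rep(0.25, 100)
  x[40] <- 0.75
  s <- clean_ptt_series(ptt_series_from(seq(1, 100), x))
  expect_equal(which(!s$quality), 40L)
  expect_identical(s$ptt_s, x)  # values untouched

  # clean simulated series: flag fraction at most 2%
  tl <- generate_beat_times(300, 70, 0.02, seed = 19)
  ptt <- ptt_ground_truth(tl, 0.25)
  noisy <- ptt + withr::with_seed(20, rnorm(length(ptt), sd = 0.003))
  s2 <- clean_ptt_series(ptt_series_from(tl$beat_time_s, noisy))
  expect_lte(mean(!s2$quality), 0.02)

  expect_error(clean_ptt_series(ptt_series_from(numeric(0), numeric(0))),
               class = "pttkit_param_error")
})

test_that("intervention fits recover known response parameters", {
  make_series <- function(tau_on, tau_rec, seed, delta = -0.030,
                          noise_sd = 0.005) {
    tl <- generate_beat_times(900, 75, 0.02, seed = seed)
    ev <- vaso_event(300, 600, delta, tau_on, tau_rec)
    ptt <- ptt_ground_truth(tl, 0.25, ev)
    noisy <- ptt + withr::with_seed(seed + 1000,
                                    rnorm(length(ptt), sd = noise_sd))
    ptt_series_from(tl$beat_time_s, noisy)
  }

  # single-case oracle: known tau_recovery = 60 s recovered within 10%
  f <- fit_intervention(make_series(40, 60, seed = 1), 300, 600)
  expect_lt(abs(f$tau_recovery - 60) / 60, 0.10)
  expect_lt(abs(f$delta - (-0.030)) / 0.030, 0.10)
  expect_lt(abs(f$baseline_ptt - 0.25), 0.002)

  # null case: constant series
  const <- ptt_series_from(seq(0, 900, by = 0.8),
                           rep(0.25, length(seq(0, 900, by = 0.8))))
  f0 <- fit_intervention(const, 300, 600)
  expect_lt(abs(f0$delta), 1e-6)
  expect_equal(f0$baseline_ptt, 0.25, tolerance = 1e-9)

  # scale equivariance: doubling PTT doubles baseline/delta, taus unchanged
  s <- make_series(40, 60, seed = 2)
  s2 <- s
  s2$ptt_s <- 2 * s$ptt_s
  fa <- fit_intervention(s, 300, 600)
  fb <- fit_intervention(s2, 300, 600)
  expect_equal(fb$baseline_ptt / fa$baseline_ptt, 2, tolerance = 1e-6)
  expect_equal(fb$delta / fa$delta, 2, tolerance = 1e-6)
  expect_equal(fb$tau_recovery, fa$tau_recovery, tolerance = 1e-6)

  # quality-flagged beats are excluded from the fit
  s3 <- make_series(40, 60, seed = 3)
  s3$ptt_s[100] <- 5
  s3$quality[100] <- FALSE
  f3 <- fit_intervention(s3, 300, 600)
  expect_lt(abs(f3$baseline_ptt - 0.25), 0.002)

  expect_error(fit_intervention(ptt_series_from(1:20, rep(0.25, 20)), 5, 10),
               class = "pttkit_analysis_error")
})

test_that("tidy and glance expose the fit in broom shape", {
  tl <- generate_beat_times(700, 75, 0.02, seed = 4)
  ev <- vaso_event(200, 400, -0.03, 30, 50)
  ptt <- ptt_ground_truth(tl, 0.25, ev) +
    withr::with_seed(5, rnorm(nrow(tl), sd = 0.004))
  f <- fit_intervention(ptt_series_from(tl$beat_time_s, ptt), 200, 400)

  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_setequal(td$term, c("baseline", "delta", "tau_on", "tau_recovery"))
  expect_true(all(is.finite(td$std.error)))

  gl <- glance(f)
  expect_equal(nrow(gl), 1)
  expect_gte(gl$rss, 0)
  expect_equal(gl$n_beats, nrow(tl))
})

test_that("Moens-Korteweg velocity matches independent arithmetic", {
  expect_equal(moens_korteweg_pwv(vessel_params(1, 1, 1, 1)), 1)

  # quadrupling the diameter halves the velocity
  p1 <- vessel_params(E = 4e5, h = 1e-3, D = 8e-3)
  p4 <- vessel_params(E = 4e5, h = 1e-3, D = 32e-3)
  expect_equal(moens_korteweg_pwv(p1) / moens_korteweg_pwv(p4), 2,
               tolerance = 1e-12)

  # worked arithmetic oracle
  expect_equal(moens_korteweg_pwv(p1), sqrt(400 / 8.48), tolerance = 1e-12)

  # randomized agreement with a log-domain brute-force evaluation
  withr::with_seed(31, {
    for (i in 1:25) {
      E <- runif(1, 1e4, 1e7); h <- runif(1, 1e-4, 5e-3)
      D <- runif(1, 1e-3, 3e-2); rho <- runif(1, 900, 1200)
      oracle <- exp(0.5 * (log(E) + log(h) - log(rho) - log(D)))
      expect_equal(moens_korteweg_pwv(vessel_params(E, h, D, rho)), oracle,
                   tolerance = 1e-12)
    }
  })

  expect_error(vessel_params(-1, 1, 1), class = "pttkit_param_error")
})

test_that("PWV from transit time is consistent with the vessel model", {
  expect_equal(pwv_from_ptt(0.25, 1.0), 4.0)
  expect_equal(pwv_from_ptt(0.125, 1.0), 8.0)   # halving PTT doubles PWV

  # round trip: pwv * ptt recovers the implied path length
  p <- vessel_params(E = 4e5, h = 1e-3, D = 8e-3)
  v <- moens_korteweg_pwv(p)
  ptt <- 0.21
  expect_equal(pwv_from_ptt(ptt, v * ptt), v, tolerance = 1e-12)

  expect_error(pwv_from_ptt(0, 1), class = "pttkit_param_error")
})

test_that("phase summaries assign beats to therapy phases", {
  prof <- generate_session_profile()
  total_min <- max(prof$end_min)

  # constant series covers every phase with the same mean
  t_s <- seq(30, total_min * 60 - 30, by = 10)
  const <- ptt_series_from(t_s, rep(0.25, length(t_s)))
  ps <- phase_summary(const, prof)
  expect_equal(nrow(ps), nrow(prof))
  expect_true(all(abs(ps$mean_ptt_ms - 250) < 1e-9))
  # conservation: beats across phases sum to the usable beats in span
  expect_equal(sum(ps$n_beats), length(t_s))

  # a PTT drop confined to one oxygen phase lowers that phase's mean
  o2 <- prof[prof$label == "oxygen", ][2, ]
  dropped <- rep(0.25, length(t_s))
  in_o2 <- t_s / 60 >= o2$start_min & t_s / 60 < o2$end_min
  dropped[in_o2] <- 0.22
  ps2 <- phase_summary(ptt_series_from(t_s, dropped), prof)
  expect_lt(ps2$mean_ptt_ms[ps2$phase == o2$phase],
            min(ps2$mean_ptt_ms[ps2$label == "air_break"]))

  # phases with no beats report n = 0
  early <- ptt_series_from(seq(30, 600, by = 10), rep(0.25, 58))
  ps3 <- phase_summary(early, prof)
  expect_true(any(ps3$n_beats == 0))
})
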