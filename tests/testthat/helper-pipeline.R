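# Shared fixtures, all generated in code at test time.

FS <- 1000

# Minimal beat annotation from known times (bypasses detection when a test
# targets downstream behaviour only).
annotation_from_times <- function(times) {
  tibble::tibble(
    beat = seq_along(times),
    r_time_s = times,
    rr_s = if (length(times) > 1) c(diff(times), NA_real_) else
      rep(NA_real_, length(times))
  )
}

ptt_series_from <- function(beat_time_s, ptt_s) {
  out <- tibble::tibble(beat_time_s = beat_time_s, ptt_s = ptt_s,
                        quality = TRUE)
  class(out) <- c("ptt_series", class(out))
  out
}

# Full pipeline on a simulation: condition -> detect -> fiducials -> pair,
# matched per beat against the ground truth by nearest beat time.
run_ptt_pipeline <- function(sim, fs = FS) {
  rec <- sim$recording
  ecg <- condition_signal(as.numeric(rec$frames$ecg), fs, ecg_filter_spec())
  ppg <- condition_signal(as.numeric(rec$frames$ppg_green), fs, ppg_filter_spec())
  ann <- detect_r_peaks(ecg, fs)
  fid <- detect_ppg_fiducials(ppg, fs, search_guides = ann$r_time_s)
  ser <- pair_beats(ann$r_time_s, fid$inflection_s)
  tr <- sim$truth
  idx <- vapply(ser$beat_time_s,
                function(b) which.min(abs(tr$beat_time_s - b)), integer(1))
  list(annotation = ann, fiducials = fid, series = ser,
       truth = tr, ptt_err_s = ser$ptt_s - tr$ptt_s[idx])
}

# Random but valid recording for round-trip property tests.
random_recording <- function(n_frames, n_events = 0, seed = 1) {
  withr::with_seed(seed, {
    frames <- tibble::tibble(
      ecg = as.integer(sample.int(2^24, n_frames) - 2^23 - 1L),
      ppg_green = as.integer(sample.int(2^24, n_frames) - 2^23 - 1L),
      ppg_red = as.integer(sample.int(2^24, n_frames) - 2^23 - 1L),
      ppg_ir = as.integer(sample.int(2^24, n_frames) - 2^23 - 1L)
    )
    events <- if (n_events > 0 && n_frames > 0) {
      tibble::tibble(
        sample_index = sort(sample.int(n_frames, n_events, replace = FALSE)) - 1L,
        code = sample(unname(event_codes), n_events, replace = TRUE)
      )
    } else {
      NULL
    }
    recording(frames, sample_rate = sample(c(500, 1000, 2000), 1),
              start_time_ms = sample.int(1e6, 1),
              device_id = paste0("DEV-", seed), events = events)
  })
}
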