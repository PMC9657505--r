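# Sub-sample time t corresponds to 0-based sample index t * fs throughout the
# simulator, matching the sample indexing of the binary recording format.

beat_times_of <- function(timeline) {
  if (is.numeric(timeline)) return(as.numeric(timeline))
  if (is.data.frame(timeline) && "beat_time_s" %in% names(timeline)) {
    return(timeline$beat_time_s)
  }
  stop_param("`timeline` must be a cardiac_timeline or a numeric vector of beat times.")
}

timeline_duration <- function(timeline, fallback_tail = 1) {
  d <- attr(timeline, "duration")
  bt <- beat_times_of(timeline)
  if (!is.null(d)) return(d)
  if (length(bt) == 0) return(fallback_tail)
  max(bt) + fallback_tail
}

#' Default ECG morphology template
#'
#' One PQRST complex modelled as a sum of five Gaussian lobes. Offsets are
#' relative to the R maximum (seconds); the R amplitude strictly dominates
#' every other lobe so that the global per-beat maximum is the R-peak.
#'
#' @param offsets,amplitudes,widths Named numeric vectors over
#'   `c("P","Q","R","S","T")`: lobe centers relative to R (s), lobe peak
#'   amplitudes (signal units), and Gaussian standard deviations (s).
#' @return A list of class `ecg_morphology`.
#' @export
ecg_morphology <- function(
    offsets = c(P = -0.20, Q = -0.025, R = 0, S = 0.025, T = 0.30),
    amplitudes = c(P = 0.12, Q = -0.10, R = 1.0, S = -0.15, T = 0.30),
    widths = c(P = 0.025, Q = 0.010, R = 0.012, S = 0.010, T = 0.060)) {
  lobes <- c("P", "Q", "R", "S", "T")
  for (v in list(offsets, amplitudes, widths)) {
    if (!all(lobes %in% names(v))) {
      stop_param("ECG morphology vectors must be named over P, Q, R, S, T.")
    }
  }
  if (any(widths <= 0)) stop_param("ECG lobe widths must be positive.")
  if (abs(amplitudes[["R"]]) <= max(abs(amplitudes[setdiff(lobes, "R")]))) {
    stop_param("The R amplitude must strictly dominate all other lobes.")
  }
  structure(list(offsets = offsets[lobes], amplitudes = amplitudes[lobes],
                 widths = widths[lobes]),
            class = "ecg_morphology")
}

#' Synthesize a clean ECG signal from a beat timeline
#'
#' Places one PQRST complex (sum of five Gaussian lobes) per beat, with the
#' template's R maximum landing exactly on each beat time. Complexes
#' superpose additively; a timeline whose RR intervals fall below the 0.3 s
#' refractory floor is rejected because adjacent QRS complexes would merge.
#'
#' @param timeline A [generate_beat_times()] result or numeric beat times (s).
#' @param fs Sampling rate, Hz (>= 250).
#' @param morphology An [ecg_morphology()] template.
#' @param duration Signal length in seconds; defaults to the timeline's
#'   recorded duration (or last beat + 1 s).
#' @return Numeric vector of `round(duration * fs)` samples; sample `i`
#'   (0-based) is the signal at `i / fs` seconds.
#' @examples
#' tl <- generate_beat_times(10, 60, 0)
#' ecg <- synthesize_ecg(tl, fs = 1000)
#' @export
synthesize_ecg <- function(timeline, fs = 1000, morphology = ecg_morphology(),
                           duration = NULL) {
  check_scalar_num(fs, "fs", lower = 250)
  beats <- beat_times_of(timeline)
  if (is.null(duration)) duration <- timeline_duration(timeline)
  n <- round(duration * fs)
  x <- numeric(n)
  if (length(beats) == 0) return(x)
  if (length(beats) > 1 && min(diff(beats)) < 0.3) {
    stop_param(
      "RR interval below 0.3 s: PQRST complexes would overlap within the template support.",
      class = "pttkit_timeline_error"
    )
  }
  t <- seq_len(n) - 1
  for (b in beats) {
    for (k in seq_along(morphology$amplitudes)) {
      mu <- (b + morphology$offsets[[k]]) * fs
      s <- morphology$widths[[k]] * fs
      lo <- max(1L, floor(mu - 5 * s) + 1L)
      hi <- min(n, ceiling(mu + 5 * s) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      x[idx] <- x[idx] +
        morphology$amplitudes[[k]] * exp(-((idx - 1 - mu)^2) / (2 * s^2))
    }
  }
  x
}

#' Ground-truth per-beat pulse transit time
#'
#' Evaluates the PTT profile `baseline + sum(event responses)` at each beat
#' time. Vasoconstriction events ([vaso_event()] with negative `delta`)
#' shorten the PTT with a saturating-exponential onset and an exponential
#' recovery after the stimulus ends.
#'
#' @param timeline Beat timeline or numeric beat times, seconds.
#' @param baseline_ptt Resting PTT, seconds, in `[0.05, 0.6]`.
#' @param events Optional [vaso_event()] or list of events acting on PTT.
#' @return Numeric vector of PTT values (s), one per beat, all positive.
#' @export
ptt_ground_truth <- function(timeline, baseline_ptt = 0.25, events = NULL) {
  check_scalar_num(baseline_ptt, "baseline_ptt", lower = 0.05, upper = 0.6)
  beats <- beat_times_of(timeline)
  ptt <- baseline_ptt + vaso_response(beats, events)
  if (any(ptt <= 0)) {
    stop_param("Event modulation drives the PTT non-positive; reduce |delta|.")
  }
  ptt
}

# Onset threshold: a Gaussian lobe first exceeds 1% of its peak at
# `onset_k` standard deviations before its center.
ppg_onset_k <- sqrt(2 * log(100))

#' Default PPG pulse morphology
#'
#' A characteristic pulse wave built from two Gaussian lobes: a dominant
#' initial (systolic) wave and a smaller dicrotic wave. Pulse onset is
#' defined as the time the pulse first exceeds 1% of the systolic peak.
#' The defaults place the systolic peak about 0.12 s after onset and the
#' dicrotic peak 0.40 s after onset, inside the canonical morphology
#' windows of 0.10-0.15 s and 0.35-0.45 s respectively.
#'
#' @param amp_sys,sd_sys Systolic lobe amplitude (signal units) and Gaussian
#'   width (s).
#' @param amp_dicrotic,sd_dicrotic Dicrotic lobe amplitude and width; the
#'   dicrotic lobe must be strictly smaller than the systolic one.
#' @param dicrotic_delay_s Dicrotic peak time measured from pulse onset, s.
#' @return A list of class `ppg_morphology`.
#' @export
ppg_morphology <- function(amp_sys = 1, sd_sys = 0.040,
                           amp_dicrotic = 0.25, sd_dicrotic = 0.050,
                           dicrotic_delay_s = 0.40) {
  check_scalar_num(amp_sys, "amp_sys", lower = 0, strict_lower = TRUE)
  check_scalar_num(sd_sys, "sd_sys", lower = 0, strict_lower = TRUE)
  check_scalar_num(amp_dicrotic, "amp_dicrotic", lower = 0)
  check_scalar_num(sd_dicrotic, "sd_dicrotic", lower = 0, strict_lower = TRUE)
  check_scalar_num(dicrotic_delay_s, "dicrotic_delay_s", lower = 0)
  if (amp_dicrotic >= amp_sys) {
    stop_param("The dicrotic lobe must be smaller than the initial wave.")
  }
  structure(list(amp_sys = amp_sys, sd_sys = sd_sys,
                 amp_dicrotic = amp_dicrotic, sd_dicrotic = sd_dicrotic,
                 dicrotic_delay_s = dicrotic_delay_s),
            class = "ppg_morphology")
}

#' Synthesize a clean PPG signal with per-beat pulse transit times
#'
#' For each beat, one two-lobe pulse is placed so that the maximum of the
#' first derivative of the systolic upstroke — the inflection point used as
#' the PTT fiducial — occurs exactly at `beat_time + ptt`. Pulses superpose
#' additively where they overlap.
#'
#' For a Gaussian systolic lobe the upstroke inflection sits one standard
#' deviation before the lobe center, and the 1%-of-peak onset sits
#' `sqrt(2 log 100)` standard deviations before it; both are exact, so the
#' simulator's ground truth is analytic rather than numerical.
#'
#' @param timeline Beat timeline or numeric beat times (s).
#' @param ptt Per-beat PTT values (s), same length as the timeline.
#' @param fs Sampling rate, Hz (>= 100).
#' @param morphology A [ppg_morphology()].
#' @param duration Signal length, seconds (default: timeline duration).
#' @return Numeric sample vector.
#' @export
synthesize_ppg <- function(timeline, ptt, fs = 1000,
                           morphology = ppg_morphology(), duration = NULL) {
  check_scalar_num(fs, "fs", lower = 100)
  beats <- beat_times_of(timeline)
  if (length(ptt) != length(beats)) {
    stop_param("`ptt` must have one value per beat in `timeline`.")
  }
  if (is.null(duration)) duration <- timeline_duration(timeline)
  n <- round(duration * fs)
  x <- numeric(n)
  if (length(beats) == 0) return(x)

  m <- morphology
  add_lobe <- function(x, center_s, amp, sd_s) {
    mu <- center_s * fs
    s <- sd_s * fs
    lo <- max(1L, floor(mu - 6 * s) + 1L)
    hi <- min(n, ceiling(mu + 6 * s) + 1L)
    if (lo > hi) return(x)
    idx <- lo:hi
    x[idx] <- x[idx] + amp * exp(-((idx - 1 - mu)^2) / (2 * s^2))
    x
  }

  for (i in seq_along(beats)) {
    # systolic lobe center: inflection (max slope) at one sd before center
    m1 <- beats[i] + ptt[i] + m$sd_sys
    onset <- m1 - ppg_onset_k * m$sd_sys
    x <- add_lobe(x, m1, m$amp_sys, m$sd_sys)
    if (m$amp_dicrotic > 0) {
      x <- add_lobe(x, onset + m$dicrotic_delay_s, m$amp_dicrotic, m$sd_dicrotic)
    }
  }
  x
}

#' Noise model for simulated recordings
#'
#' Additive disturbances emulating what the device sees: wideband white
#' noise, 50 Hz mains pickup, slow sinusoidal baseline wander, and sparse
#' transient motion artifacts placed by a Poisson process.
#'
#' @param white_sd White Gaussian noise SD, signal units.
#' @param mains_amplitude Amplitude of the mains sinusoid, signal units.
#' @param mains_hz Mains frequency, Hz (default 50).
#' @param wander_amplitude,wander_freq Baseline wander amplitude (signal
#'   units) and frequency (Hz, must be < 0.5).
#' @param artifact_rate Expected artifact count per minute.
#' @param artifact_amplitude Peak amplitude of each artifact excursion.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(white_sd = 0, mains_amplitude = 0, mains_hz = 50,
                       wander_amplitude = 0, wander_freq = 0.2,
                       artifact_rate = 0, artifact_amplitude = 0) {
  check_scalar_num(white_sd, "white_sd", lower = 0)
  check_scalar_num(mains_amplitude, "mains_amplitude", lower = 0)
  check_scalar_num(mains_hz, "mains_hz", lower = 0, strict_lower = TRUE)
  check_scalar_num(wander_amplitude, "wander_amplitude", lower = 0)
  check_scalar_num(wander_freq, "wander_freq", lower = 0, upper = 0.5)
  check_scalar_num(artifact_rate, "artifact_rate", lower = 0)
  check_scalar_num(artifact_amplitude, "artifact_amplitude", lower = 0)
  structure(list(white_sd = white_sd, mains_amplitude = mains_amplitude,
                 mains_hz = mains_hz, wander_amplitude = wander_amplitude,
                 wander_freq = wander_freq, artifact_rate = artifact_rate,
                 artifact_amplitude = artifact_amplitude),
            class = "noise_spec")
}

#' Add simulated noise to a signal
#'
#' Output = input + white Gaussian noise + mains sinusoid + baseline wander
#' + Poisson-placed Gaussian-shaped transient artifacts. A zero
#' [noise_spec()] returns the input unchanged. Deterministic given `seed`.
#'
#' @param x Sample vector.
#' @param fs Sampling rate, Hz (> 100).
#' @param spec A [noise_spec()].
#' @param seed Integer seed for the random components.
#' @return Noisy sample vector, same length as `x`.
#' @export
add_noise <- function(x, fs, spec = noise_spec(), seed = 1L) {
  check_scalar_num(fs, "fs", lower = 100, strict_lower = TRUE)
  if (!inherits(spec, "noise_spec")) stop_param("`spec` must be a noise_spec.")
  n <- length(x)
  if (n == 0) return(x)
  t <- (seq_len(n) - 1) / fs

  if (spec$white_sd > 0) {
    x <- x + with_seed(derive_seed(seed, 2L), rnorm(n, sd = spec$white_sd))
  }
  if (spec$mains_amplitude > 0) {
    x <- x + spec$mains_amplitude * sin(2 * pi * spec$mains_hz * t)
  }
  if (spec$wander_amplitude > 0) {
    x <- x + spec$wander_amplitude * sin(2 * pi * spec$wander_freq * t)
  }
  if (spec$artifact_rate > 0 && spec$artifact_amplitude > 0) {
    dur_min <- n / fs / 60
    art <- with_seed(derive_seed(seed, 3L), {
      k <- rpois(1, spec$artifact_rate * dur_min)
      list(pos = runif(k, 0, n / fs), sign = sample(c(-1, 1), k, replace = TRUE))
    })
    for (j in seq_along(art$pos)) {
      mu <- art$pos[j] * fs
      s <- 0.1 * fs  # ~0.5 s excursion support
      lo <- max(1L, floor(mu - 3 * s) + 1L)
      hi <- min(n, ceiling(mu + 3 * s) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      x[idx] <- x[idx] + art$sign[j] * spec$artifact_amplitude *
        exp(-((idx - 1 - mu)^2) / (2 * s^2))
    }
  }
  x
}

#' Simulate a complete synchronized ECG/PPG recording
#'
#' One call from study conditions to a device-style [recording] plus its
#' ground-truth sidecar: builds the beat timeline, evaluates the per-beat
#' PTT profile, synthesizes the ECG and the green PPG channel, scales the
#' red and infrared channels from the green one (no oxygen-saturation
#' physiology is modelled), adds channel-independent noise, and quantizes to
#' 24-bit integer counts.
#'
#' @param duration Seconds (> 0).
#' @param mean_hr Mean heart rate, BPM.
#' @param rr_jitter_sd RR jitter SD, seconds.
#' @param baseline_ptt Resting PTT, seconds.
#' @param ptt_events,rr_events Optional [vaso_event()] lists modulating the
#'   per-beat PTT and the RR interval.
#' @param ecg_noise,ppg_noise [noise_spec()] per signal family.
#' @param fs Sampling rate, Hz.
#' @param seed Integer master seed; all random draws derive from it.
#' @param counts_per_unit Quantization gain from signal units to integer
#'   counts (default 1e5, comfortably inside the 24-bit range).
#' @param device_id Device identifier stored in the recording header.
#' @param events Optional event-marker tibble (`sample_index`, `code`).
#' @return A list of class `ptt_simulation` with elements `recording` (a
#'   [recording]) and `truth` (tibble: `beat`, `beat_time_s`, `rr_s`,
#'   `ptt_s`).
#' @examples
#' sim <- simulate_recording(10, mean_hr = 60, seed = 7)
#' sim$truth
#' @export
simulate_recording <- function(duration, mean_hr = 70, rr_jitter_sd = 0.02,
                               baseline_ptt = 0.25, ptt_events = NULL,
                               rr_events = NULL,
                               ecg_noise = noise_spec(),
                               ppg_noise = noise_spec(),
                               fs = 1000, seed = 1L,
                               counts_per_unit = 1e5,
                               device_id = "SIM-0001",
                               events = NULL) {
  tl <- generate_beat_times(duration, mean_hr, rr_jitter_sd,
                            rr_events = rr_events, seed = seed)
  ptt <- ptt_ground_truth(tl, baseline_ptt, ptt_events)
  ecg <- synthesize_ecg(tl, fs = fs, duration = duration)
  ppg <- synthesize_ppg(tl, ptt, fs = fs, duration = duration)

  ecg_n <- add_noise(ecg, fs, ecg_noise, seed = derive_seed(seed, 10L))
  g <- add_noise(ppg, fs, ppg_noise, seed = derive_seed(seed, 11L))
  r <- add_noise(0.5 * ppg, fs, ppg_noise, seed = derive_seed(seed, 12L))
  ir <- add_noise(0.7 * ppg, fs, ppg_noise, seed = derive_seed(seed, 13L))

  quantize <- function(x) {
    v <- round(x * counts_per_unit)
    v <- pmax(pmin(v, 2^23 - 1), -2^23)
    as.integer(v)
  }
  frames <- tibble::tibble(
    ecg = quantize(ecg_n), ppg_green = quantize(g),
    ppg_red = quantize(r), ppg_ir = quantize(ir)
  )
  rec <- recording(frames, sample_rate = fs, device_id = device_id,
                   events = events)
  truth <- tibble::tibble(
    beat = tl$beat,
    beat_time_s = tl$beat_time_s,
    rr_s = tl$rr_s,
    ptt_s = ptt
  )
  structure(list(recording = rec, truth = truth,
                 counts_per_unit = counts_per_unit, seed = seed),
            class = "ptt_simulation")
}

#' @export
print.ptt_simulation <- function(x, ...) {
  cat("<ptt_simulation>\n")
  print(x$recording)
  cat(sprintf("ground truth: %d beats\n", nrow(x$truth)))
  invisible(x)
}
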